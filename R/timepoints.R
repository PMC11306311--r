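#' Sampling schedule of the crossover sleep study
#'
#' Canonical table of the seven oral-fluid sampling time points. Clock times
#' follow the in-laboratory protocol: day 1 08:30 pm (t1), day 2 10:55 pm
#' (t2), day 3 08:10 am (t3), 01:55 pm (t4), 09:00 pm (t5), 10:55 pm (t6),
#' day 4 08:10 am (t7). `clock_hour` is hours since midnight of study day 1;
#' the scheduled sleep window is 11:30 pm to 07:30 am in the control
#' condition, and the sleep-deprivation condition stays awake through the
#' experimental night (the night between days 2 and 3, i.e. before t3),
#' reaching 40 consecutive hours of wakefulness.
#'
#' @return A data.frame with columns `timepoint` ("t1".."t7"), `day`,
#'   `clock` ("HH:MM"), and `clock_hour` (hours since study start).
#' @export
#' @examples
#' timepoint_schedule()
timepoint_schedule <- function() {
  data.frame(
    timepoint  = paste0("t", 1:7),
    day        = c(1L, 2L, 3L, 3L, 3L, 3L, 4L),
    clock      = c("20:30", "22:55", "08:10", "13:55", "21:00", "22:55", "08:10"),
    clock_hour = c(20 + 30 / 60,
                   24 + 22 + 55 / 60,
                   48 +  8 + 10 / 60,
                   48 + 13 + 55 / 60,
                   48 + 21,
                   48 + 22 + 55 / 60,
                   72 +  8 + 10 / 60),
    stringsAsFactors = FALSE
  )
}

# habitual wake-up time (07:30) in hours; bedtime is 23:30
.WAKE_HOUR <- 7.5

TIMEPOINT_LEVELS <- paste0("t", 1:7)
CONDITION_LEVELS <- c("control", "sleep_deprivation")
SAMPLE_TYPE_LEVELS <- c("study", "qc_pool", "blank", "dilution")
SLEEP_TIMEPOINTS <- paste0("t", 3:6)   # window where deprivation effects can show
GATE_TIMEPOINTS  <- c("t1", "t2", "t7") # robustness / proof-of-concept controls

#' Hours of sustained wakefulness at a sampling time point
#'
#' Deterministic clock arithmetic on the study schedule: subjects wake at
#' 07:30 and go to bed at 23:30 every day in the control condition; in the
#' sleep-deprivation condition the last wake-up before t3--t6 is 07:30 on
#' day 2 (the experimental night is skipped), and both conditions get a full
#' recovery night before t7.
#'
#' @param timepoint Character vector of time-point labels ("t1".."t7").
#' @param condition Character vector, "control" or "sleep_deprivation"
#'   (recycled against `timepoint`).
#' @return Numeric vector of hours awake at sampling.
#' @export
#' @examples
#' hours_awake("t3", "sleep_deprivation")  # 24.67 h
#' hours_awake("t3", "control")            # 0.67 h
hours_awake <- function(timepoint, condition) {
  sched <- timepoint_schedule()
  n <- max(length(timepoint), length(condition))
  timepoint <- rep_len(as.character(timepoint), n)
  condition <- rep_len(as.character(condition), n)
  i <- match(timepoint, sched$timepoint)
  if (anyNA(i)) {
    stop("unknown timepoint label(s): ",
         paste(unique(timepoint[is.na(i)]), collapse = ", "))
  }
  if (!all(condition %in% CONDITION_LEVELS)) {
    stop("condition must be one of: ", paste(CONDITION_LEVELS, collapse = ", "))
  }
  ch <- sched$clock_hour[i]
  day <- sched$day[i]
  # last wake-up preceding each sample, hours since study start
  last_wake <- (day - 1) * 24 + .WAKE_HOUR
  # deprivation condition: no sleep in the night before day 3, so for t3-t6
  # the last wake-up was 07:30 on day 2
  dep <- condition == "sleep_deprivation" & timepoint %in% SLEEP_TIMEPOINTS
  last_wake[dep] <- 24 + .WAKE_HOUR
  ch - last_wake
}
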