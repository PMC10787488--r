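# Domain types for the patient-flow model. All are lightweight validated S3
# lists; construction fails loudly so the engine can assume invariants.

WEEKDAYS <- c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")
WORKDAYS_DEFAULT <- c("Mon", "Tue", "Wed", "Thu", "Fri")
PATIENT_CLASSES <- c("TEP", "CLEP", "NEP")

#' Duration specification (summary moments plus hard bounds)
#'
#' A four-number parameterization of a positive duration: its mean and
#' standard deviation plus the minimum and maximum ever observed. These are
#' the numbers a hospital reports for each stay or procedure phase and they
#' are all the simulation needs: sampling fits a truncated lognormal to them
#' (see [fit_truncated_lognormal()]). `sd = 0` denotes a constant duration,
#' in which case `min == mean == max` is required.
#'
#' @param mean Mean duration (days or minutes, per `units`).
#' @param sd Standard deviation, same units; `>= 0`.
#' @param min,max Truncation bounds; `min <= mean <= max` and `min >= 0`.
#' @param units `"days"` or `"minutes"`.
#' @return An object of class `duration_spec`.
#' @examples
#' duration_spec(5.050, 2.350, 3, 11, "days")
#' @export
duration_spec <- function(mean, sd, min, max, units = c("days", "minutes")) {
  units <- match.arg(units)
  for (v in c(mean, sd, min, max)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop("duration_spec fields must be single non-missing numbers", call. = FALSE)
    }
  }
  if (min < 0) stop("duration_spec: min must be >= 0, got ", min, call. = FALSE)
  if (sd < 0) stop("duration_spec: sd must be >= 0, got ", sd, call. = FALSE)
  if (min > mean || mean > max) {
    stop("duration_spec: need min <= mean <= max, got ",
         min, " / ", mean, " / ", max, call. = FALSE)
  }
  if (sd == 0 && !(min == mean && mean == max)) {
    stop("duration_spec: sd = 0 requires min = mean = max (constant duration), got ",
         min, " / ", mean, " / ", max, call. = FALSE)
  }
  structure(list(mean = mean, sd = sd, min = min, max = max, units = units),
            class = "duration_spec")
}

#' @export
print.duration_spec <- function(x, ...) {
  cat(sprintf("<duration_spec> %.3f (SD %.3f), range %g-%g %s\n",
              x$mean, x$sd, x$min, x$max, x$units))
  invisible(x)
}

#' Daily-arrival specification for one patient class
#'
#' @param patient_class `"TEP"`, `"CLEP"` or `"NEP"`.
#' @param mean,sd Mean and SD of the daily arrival count; `mean > 0`, `sd >= 0`.
#' @param regime `"empirical"` (counts drawn from the fitted negative
#'   binomial) or `"saturating"` (TEP only: enough arrivals are generated each
#'   day to fill every bed left after the other classes are admitted).
#' @return An object of class `arrival_spec`.
#' @export
arrival_spec <- function(patient_class, mean, sd, regime = c("empirical", "saturating")) {
  regime <- match.arg(regime)
  patient_class <- match.arg(patient_class, PATIENT_CLASSES)
  if (!is.numeric(mean) || mean <= 0) stop("arrival_spec: mean must be > 0", call. = FALSE)
  if (!is.numeric(sd) || sd < 0) stop("arrival_spec: sd must be >= 0", call. = FALSE)
  if (regime == "saturating" && patient_class != "TEP") {
    stop("arrival_spec: the saturating regime applies only to TEP patients", call. = FALSE)
  }
  structure(list(patient_class = patient_class, mean = mean, sd = sd, regime = regime),
            class = "arrival_spec")
}

#' EP procedure class
#'
#' One procedure type performed in the EP labs: its share of EP-lab (TEP)
#' admissions and the four duration distributions that govern a patient of
#' this type — operative time and lab clean-up (minutes), total length of
#' stay and pre-operative stay (days).
#'
#' @param name Procedure name (unique within a configuration).
#' @param proportion Fraction of TEP admissions, `0 < proportion <= 1`
#'   (normalized against the other classes at config level).
#' @param operative_time,cleanup `duration_spec`s in minutes.
#' @param length_of_stay,preop_stay `duration_spec`s in days.
#' @return An object of class `procedure_class`.
#' @export
procedure_class <- function(name, proportion, operative_time, cleanup,
                            length_of_stay, preop_stay) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("procedure_class: name must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(proportion) || proportion <= 0 || proportion > 1) {
    stop("procedure_class '", name, "': proportion must be in (0, 1], got ",
         proportion, call. = FALSE)
  }
  specs <- list(operative_time = operative_time, cleanup = cleanup,
                length_of_stay = length_of_stay, preop_stay = preop_stay)
  for (nm in names(specs)) {
    if (!inherits(specs[[nm]], "duration_spec")) {
      stop("procedure_class '", name, "': ", nm, " must be a duration_spec", call. = FALSE)
    }
  }
  want_units <- c(operative_time = "minutes", cleanup = "minutes",
                  length_of_stay = "days", preop_stay = "days")
  for (nm in names(want_units)) {
    if (specs[[nm]]$units != want_units[[nm]]) {
      stop("procedure_class '", name, "': ", nm, " must be in ", want_units[[nm]], call. = FALSE)
    }
  }
  if (preop_stay$min > length_of_stay$max) {
    stop("procedure_class '", name, "': minimum pre-operative stay exceeds the ",
         "maximum length of stay", call. = FALSE)
  }
  structure(c(list(name = name, proportion = proportion), specs),
            class = "procedure_class")
}

#' Per-weekday split of procedures between the two on-duty physicians
#'
#' The department rosters two anonymous on-duty electrophysiologist slots per
#' workday; `p_first`/`p_second` give the historical share of procedures
#' handled by each slot on that weekday.
#'
#' @param weekday One of `"Mon".."Fri"` (or any configured workday).
#' @param p_first,p_second Probabilities in `[0, 1]` summing to 1 (within 1e-9).
#' @return An object of class `weekday_allocation`.
#' @export
weekday_allocation <- function(weekday, p_first, p_second) {
  weekday <- match.arg(weekday, WEEKDAYS)
  if (p_first < 0 || p_first > 1 || p_second < 0 || p_second > 1) {
    stop("weekday_allocation: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(p_first + p_second - 1) > 1e-9) {
    stop("weekday_allocation (", weekday, "): p_first + p_second must equal 1, got ",
         p_first + p_second, call. = FALSE)
  }
  structure(list(weekday = weekday, p_first = p_first, p_second = p_second),
            class = "weekday_allocation")
}

parse_hhmm <- function(x, field) {
  if (is.numeric(x) && length(x) == 1L) return(as.numeric(x))  # minutes already
  if (!is.character(x) || !grepl("^\\d{1,2}:\\d{2}$", x)) {
    stop("calendar: ", field, " must be an 'HH:MM' string, got '", x, "'", call. = FALSE)
  }
  parts <- as.integer(strsplit(x, ":", fixed = TRUE)[[1L]])
  if (parts[1L] > 23L || parts[2L] > 59L) {
    stop("calendar: ", field, " out of range: '", x, "'", call. = FALSE)
  }
  parts[1L] * 60 + parts[2L]
}

format_hhmm <- function(m) sprintf("%02d:%02d", m %/% 60, m %% 60)

#' Working calendar
#'
#' @param workdays Weekday names on which the EP labs operate.
#' @param lab_open,lab_close Lab working hours, `"HH:MM"` (default 08:00-22:00).
#' @param arrival_time Daily scheduled arrival instant, before `lab_open`
#'   (default 07:00, one hour before working hours); this is also the daily
#'   bed-turnover instant at which discharges free beds.
#' @param start_weekday Weekday of simulation day 1 (default `"Sun"`).
#' @return An object of class `sim_calendar` with times stored as
#'   minutes-of-day.
#' @export
sim_calendar <- function(workdays = WORKDAYS_DEFAULT, lab_open = "08:00",
                         lab_close = "22:00", arrival_time = "07:00",
                         start_weekday = "Sun") {
  workdays <- vapply(workdays, function(w) match.arg(w, WEEKDAYS), "")
  if (anyDuplicated(workdays)) stop("calendar: duplicated workdays", call. = FALSE)
  start_weekday <- match.arg(start_weekday, WEEKDAYS)
  open_m <- parse_hhmm(lab_open, "lab_open")
  close_m <- parse_hhmm(lab_close, "lab_close")
  arr_m <- parse_hhmm(arrival_time, "arrival_time")
  if (open_m >= close_m) {
    stop("calendar: lab_open (", format_hhmm(open_m), ") must precede lab_close (",
         format_hhmm(close_m), ")", call. = FALSE)
  }
  if (arr_m >= open_m) {
    stop("calendar: arrival_time must precede lab_open", call. = FALSE)
  }
  structure(list(workdays = unname(workdays), lab_open = open_m, lab_close = close_m,
                 arrival_time = arr_m, start_weekday = start_weekday),
            class = "sim_calendar")
}

#' Simulation horizon
#'
#' The run warms up with non-EP-lab patient flow only, then observes a
#' measurement window during which EP-lab (TEP) patients arrive and their
#' discharges are counted.
#'
#' @param warmup_days Warm-up days before TEP flow starts (default 10).
#' @param observation_days Length of the measured window (default 61).
#' @param replications Default number of replications per batch (default 1000).
#' @return An object of class `sim_horizon`.
#' @export
sim_horizon <- function(warmup_days = 10L, observation_days = 61L,
                        replications = 1000L) {
  for (v in c(warmup_days, observation_days, replications)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v)) {
      stop("horizon: warmup_days, observation_days and replications must be ",
           "positive integers", call. = FALSE)
    }
  }
  structure(list(warmup_days = as.integer(warmup_days),
                 observation_days = as.integer(observation_days),
                 replications = as.integer(replications)),
            class = "sim_horizon")
}

#' Department resources
#'
#' @param beds Ward beds shared by all patient classes.
#' @param labs EP labs (procedure rooms).
#' @param physicians_on_duty On-duty electrophysiologist slots per workday
#'   (default 2; each is a capacity-1 resource during that day).
#' @return An object of class `resource_set`.
#' @export
resource_set <- function(beds, labs, physicians_on_duty = 2L) {
  for (v in c(beds, labs, physicians_on_duty)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v)) {
      stop("resources: beds, labs and physicians_on_duty must be integers >= 1",
           call. = FALSE)
    }
  }
  structure(list(beds = as.integer(beds), labs = as.integer(labs),
                 physicians_on_duty = as.integer(physicians_on_duty)),
            class = "resource_set")
}
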