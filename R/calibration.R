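# Calibration: estimate a full model configuration from a raw patient-log
# table (one row per patient), plus a synthetic log generator used for
# round-trip testing of the estimator.

LOG_HEADER <- c("patient_id", "patient_class", "admission_date", "discharge_date",
                "procedure_class", "procedure_date", "procedure_start",
                "procedure_end", "physician_id")

#' Read a patient-log table
#'
#' Comma-delimited text with header exactly
#' `patient_id,patient_class,admission_date,discharge_date,procedure_class,procedure_date,procedure_start,procedure_end,physician_id`.
#' Dates are ISO-8601 (`YYYY-MM-DD`), times `"HH:MM"`; the procedure columns
#' and physician id are empty for non-EP-lab (CLEP/NEP) rows. Rows with a
#' missing admission or discharge date (incomplete records) are dropped with
#' a warning giving the count.
#'
#' @param path Path to the log file.
#' @return A `data.frame` with parsed `Date` columns.
#' @export
read_patient_log <- function(path) {
  if (!file.exists(path)) stop("patient log not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(df), LOG_HEADER)) {
    stop("patient log header must be exactly: ",
         paste(LOG_HEADER, collapse = ","), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("patient log is empty: ", path, call. = FALSE)
  bad_class <- setdiff(unique(df$patient_class), PATIENT_CLASSES)
  if (length(bad_class)) {
    stop("patient log: unknown patient_class value(s): ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  }
  incomplete <- df$admission_date == "" | df$discharge_date == ""
  if (any(incomplete)) {
    warning(sum(incomplete), " incomplete row(s) without both admission and ",
            "discharge dates dropped", call. = FALSE)
    df <- df[!incomplete, , drop = FALSE]
  }
  df$admission_date <- as.Date(df$admission_date)
  df$discharge_date <- as.Date(df$discharge_date)
  df$procedure_date <- as.Date(ifelse(df$procedure_date == "", NA,
                                      df$procedure_date))
  tep <- df$patient_class == "TEP"
  if (any(tep & (is.na(df$procedure_date) | df$procedure_class == ""))) {
    stop("patient log: TEP rows must carry procedure_class and procedure_date",
         call. = FALSE)
  }
  ok <- !tep | (df$admission_date <= df$procedure_date &
                  df$procedure_date <= df$discharge_date)
  if (any(!ok, na.rm = TRUE)) {
    stop("patient log: TEP rows must satisfy admission <= procedure <= discharge",
         call. = FALSE)
  }
  df
}

#' Write a patient-log table
#'
#' @param log A `data.frame` as returned by [read_patient_log()] or
#'   [generate_synthetic_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_log <- function(log, path) {
  stopifnot(identical(names(log), LOG_HEADER))
  out <- log
  for (col in names(out)) out[[col]] <- as.character(out[[col]])
  out[is.na(out)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

moments_spec <- function(x, units, what) {
  if (length(x) < 2L) {
    stop("estimate_config: fewer than 2 observations for ", what,
         "; the SD is undefined — collect more data or supply this input ",
         "directly in the configuration", call. = FALSE)
  }
  duration_spec(mean(x), stats::sd(x), min(x), max(x), units)
}

#' Estimate a model configuration from a patient log
#'
#' From the raw log the estimator derives, per patient class, the daily
#' arrival mean/SD over every calendar day in the admission span (days with
#' no arrivals count as zeros); per EP procedure class its admission-mix
#' proportion and the moment/bound summaries of operative minutes
#' (end minus start), length of stay (discharge minus admission, in whole
#' days, floored at 1) and pre-operative stay (procedure minus admission);
#' and per procedure weekday the two-way physician allocation from the two
#' most frequent physician ids on that weekday (any further ids are folded
#' into the second slot with a warning). Lab clean-up times are not
#' observable in an admission log and are taken from `cleanup_default`.
#' Resource counts and horizon settings are likewise not estimable from a
#' log and are taken from the arguments.
#'
#' @param log A patient-log `data.frame` ([read_patient_log()]).
#' @param calendar A [sim_calendar()] (defaults to the standard Mon-Fri
#'   08:00-22:00 calendar).
#' @param resources A [resource_set()] for the department.
#' @param horizon A [sim_horizon()].
#' @param cleanup_default A `duration_spec` (minutes) used as the clean-up
#'   spec for every estimated procedure class.
#' @return A validated [model_config()].
#' @export
estimate_config <- function(log, calendar = sim_calendar(),
                            resources = resource_set(beds = 87L, labs = 2L),
                            horizon = sim_horizon(),
                            cleanup_default = duration_spec(6.6, 4.6, 1, 40, "minutes")) {
  stopifnot(is.data.frame(log))
  for (cl in PATIENT_CLASSES) {
    if (!any(log$patient_class == cl)) {
      stop("estimate_config: no ", cl, " rows in the log", call. = FALSE)
    }
  }
  span <- seq(min(log$admission_date), max(log$admission_date), by = "day")
  arrivals <- lapply(PATIENT_CLASSES, function(cl) {
    counts <- table(factor(as.character(log$admission_date[log$patient_class == cl]),
                           levels = as.character(span)))
    arrival_spec(cl, mean(counts), stats::sd(counts))
  })
  names(arrivals) <- PATIENT_CLASSES

  los_days <- function(rows) {
    pmax(as.integer(rows$discharge_date - rows$admission_date), 1L)
  }
  tep <- log[log$patient_class == "TEP", , drop = FALSE]
  pcs <- lapply(split(tep, tep$procedure_class), function(rows) {
    nm <- rows$procedure_class[1L]
    start_m <- vapply(rows$procedure_start, parse_hhmm, 0, field = "procedure_start")
    end_m <- vapply(rows$procedure_end, parse_hhmm, 0, field = "procedure_end")
    # procedures started late may end past midnight: difference modulo 24 h
    oper_min <- (end_m - start_m) %% MINUTES_PER_DAY
    preop <- as.integer(rows$procedure_date - rows$admission_date)
    procedure_class(
      name = nm, proportion = nrow(rows) / nrow(tep),
      operative_time = moments_spec(oper_min, "minutes", paste0(nm, " operative time")),
      cleanup = cleanup_default,
      length_of_stay = moments_spec(los_days(rows), "days", paste0(nm, " length of stay")),
      preop_stay = moments_spec(preop, "days", paste0(nm, " pre-operative stay"))
    )
  })

  # locale-independent weekday: %w gives 0 (Sunday) .. 6 (Saturday)
  wd_of <- WEEKDAYS[as.integer(format(tep$procedure_date, "%w")) + 1L]
  wa <- lapply(calendar$workdays, function(wd) {
    phys <- tep$physician_id[wd_of == wd]
    if (length(phys) == 0L) {
      return(weekday_allocation(wd, 0.5, 0.5))  # no procedures seen: uninformative
    }
    counts <- sort(table(phys), decreasing = TRUE)
    if (length(counts) > 2L) {
      warning("estimate_config: ", length(counts) - 2L, " additional physician ",
              "id(s) on ", wd, " folded into the second on-duty slot", call. = FALSE)
      counts <- c(counts[1L], sum(counts[-1L]))
    }
    p1 <- counts[[1L]] / sum(counts)
    weekday_allocation(wd, p1, 1 - p1)
  })
  names(wa) <- calendar$workdays

  bed_only <- function(cl) {
    x <- los_days(log[log$patient_class == cl, , drop = FALSE])
    if (length(x) < 2L) {
      stop("estimate_config: fewer than 2 complete ", cl, " rows; the LOS SD ",
           "is undefined", call. = FALSE)
    }
    m <- mean(x)
    s <- stats::sd(x)
    duration_spec(m, s, min = 1, max = max(m + 6 * s, max(x)), units = "days")
  }

  model_config(calendar = calendar, horizon = horizon, resources = resources,
               arrivals = arrivals, procedure_classes = pcs,
               weekday_allocations = wa,
               clep_los = bed_only("CLEP"), nep_los = bed_only("NEP"))
}

#' Generate a synthetic patient log from a configuration
#'
#' Draws daily arrivals, procedure-class assignments, stays, operative times
#' and physician assignments from the configuration's fitted distributions
#' and emits a well-formed log table: per TEP row,
#' `admission <= procedure <= discharge`, the procedure lands on a workday
#' (pre-op extended over closed days exactly as in the simulation engine),
#' and the physician id is `"EP1"`/`"EP2"` according to the procedure-day
#' weekday allocation. The synthetic log emulates the *input* data a
#' department would export; it does not model resource contention, so it is
#' a fixture for the estimator, not a simulation output.
#'
#' @param config A [model_config()].
#' @param n_days Number of arrival days to generate (`>= 1`).
#' @param seed Integer RNG seed.
#' @param start_date First admission date; its weekday should match
#'   `config$calendar$start_weekday` for weekday-faithful logs (default:
#'   a Sunday).
#' @return A patient-log `data.frame` (columns as [read_patient_log()]).
#' @export
generate_synthetic_log <- function(config, n_days, seed,
                                   start_date = as.Date("2022-05-01")) {
  stopifnot(inherits(config, "model_config"))
  if (n_days < 1) stop("generate_synthetic_log: n_days must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  cal <- config$calendar
  arr_fit <- lapply(config$arrivals, function(a) fit_negative_binomial(a$mean, a$sd))
  pcs <- config$procedure_classes
  los_fit <- lapply(pcs, function(p) fit_truncated_lognormal(p$length_of_stay))
  pre_fit <- lapply(pcs, function(p) fit_truncated_lognormal(p$preop_stay))
  op_fit <- lapply(pcs, function(p) fit_truncated_lognormal(p$operative_time))
  clep_fit <- fit_truncated_lognormal(config$clep_los)
  nep_fit <- fit_truncated_lognormal(config$nep_los)

  rows <- vector("list", 4096L)
  nr <- 0L
  push <- function(row) {
    nr <<- nr + 1L
    if (nr > length(rows)) length(rows) <<- length(rows) * 2L
    rows[[nr]] <<- row
  }
  day_date <- function(d) start_date + (d - 1L)
  for (d in seq_len(n_days)) {
    for (cl in c("CLEP", "NEP")) {
      n <- sample_daily_arrivals(arr_fit[[cl]])
      if (n > 0L) {
        fit <- if (cl == "CLEP") clep_fit else nep_fit
        los <- sample_integer_days(fit, n)
        for (k in seq_len(n)) {
          push(list(cl, day_date(d), day_date(d) + los[k], "", NA, "", "", ""))
        }
      }
    }
    n <- sample_daily_arrivals(arr_fit$TEP)
    if (n > 0L) {
      cls <- draw_procedure_class(pcs, n)
      for (k in seq_len(n)) {
        ci <- cls[k]
        los <- sample_integer_days(los_fit[[ci]], 1L)
        preop <- sample_preop_given_los(pre_fit[[ci]], los)
        proc_day <- plan_procedure_day(d, preop, cal)
        extra <- proc_day - (d + preop)  # workday wait extends the stay
        oper <- sample_truncated(op_fit[[ci]], 1L)
        start_m <- cal$lab_open +
          floor(stats::runif(1L, 0, cal$lab_close - cal$lab_open - 1))
        wd <- weekday_of(proc_day, cal)
        slot <- assign_physician(wd, config$weekday_allocations[[wd]])
        push(list("TEP", day_date(d), day_date(d) + los + extra,
                  names(pcs)[ci], day_date(proc_day),
                  format_hhmm(start_m),
                  format_hhmm((start_m + round(oper)) %% MINUTES_PER_DAY),
                  paste0("EP", slot)))
      }
    }
  }
  rows <- rows[seq_len(nr)]
  df <- data.frame(
    patient_id = sprintf("P%05d", seq_len(nr)),
    patient_class = vapply(rows, function(r) r[[1L]], ""),
    admission_date = as.Date(vapply(rows, function(r) as.character(r[[2L]]), "")),
    discharge_date = as.Date(vapply(rows, function(r) as.character(r[[3L]]), "")),
    procedure_class = vapply(rows, function(r) r[[4L]], ""),
    procedure_date = as.Date(vapply(rows, function(r) {
      if (is.na(r[[5L]]) || identical(r[[5L]], NA)) NA_character_ else as.character(r[[5L]])
    }, "")),
    procedure_start = vapply(rows, function(r) r[[6L]], ""),
    procedure_end = vapply(rows, function(r) r[[7L]], ""),
    physician_id = vapply(rows, function(r) r[[8L]], "")
  )
  df
}
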