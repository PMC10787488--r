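# Model configuration: aggregate of calendar, horizon, resources, arrival
# specs, procedure classes, weekday allocations and the bed-only stay
# distributions, plus the packaged department defaults.

DEFAULT_SEED <- 20220501L

#' Assemble and validate a full model configuration
#'
#' @param calendar A [sim_calendar()].
#' @param horizon A [sim_horizon()].
#' @param resources A [resource_set()].
#' @param arrivals Named list with one [arrival_spec()] per patient class
#'   (`TEP`, `CLEP`, `NEP`).
#' @param procedure_classes List of [procedure_class()] objects; proportions
#'   are normalized to sum to 1.
#' @param weekday_allocations Named list with one [weekday_allocation()] per
#'   workday in `calendar$workdays`.
#' @param clep_los,nep_los [duration_spec()]s (days) for the length of stay of
#'   the two bed-only patient classes.
#' @param bed_policy What happens to an arrival finding no free bed:
#'   `"waitlist"` (default) keeps a FIFO bed queue — the patient is admitted
#'   once a bed frees up, their stay clock starting at admission; `"balk"`
#'   drops the patient (counted in the replication's `balked` totals).
#' @param seed Default master seed for batches run from this configuration.
#' @return An object of class `model_config`.
#' @seealso [default_config()], [load_config()]
#' @export
model_config <- function(calendar, horizon, resources, arrivals,
                         procedure_classes, weekday_allocations,
                         clep_los, nep_los,
                         bed_policy = c("waitlist", "balk"),
                         seed = DEFAULT_SEED) {
  bed_policy <- match.arg(bed_policy)
  stopifnot(inherits(calendar, "sim_calendar"), inherits(horizon, "sim_horizon"),
            inherits(resources, "resource_set"))
  if (!setequal(names(arrivals), PATIENT_CLASSES)) {
    stop("config: arrivals must have exactly the classes ",
         paste(PATIENT_CLASSES, collapse = ", "), call. = FALSE)
  }
  for (cl in PATIENT_CLASSES) {
    a <- arrivals[[cl]]
    if (!inherits(a, "arrival_spec") || a$patient_class != cl) {
      stop("config: arrivals$", cl, " must be an arrival_spec for class ", cl,
           call. = FALSE)
    }
  }
  if (length(procedure_classes) == 0L) {
    stop("config: at least one procedure class is required", call. = FALSE)
  }
  for (pc in procedure_classes) {
    if (!inherits(pc, "procedure_class")) {
      stop("config: procedure_classes must all be procedure_class objects", call. = FALSE)
    }
  }
  nms <- vapply(procedure_classes, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("config: duplicated procedure class names", call. = FALSE)
  names(procedure_classes) <- nms
  # Raw proportions need not sum to 1 exactly (rounded percentages may sum to
  # e.g. 100.1%); normalize by the raw sum, preserving the relative mix.
  raw <- vapply(procedure_classes, `[[`, 0, "proportion")
  procedure_classes <- lapply(procedure_classes, function(pc) {
    pc$proportion <- pc$proportion / sum(raw)
    pc
  })
  if (!setequal(names(weekday_allocations), calendar$workdays)) {
    stop("config: weekday_allocations must cover exactly the workdays (",
         paste(calendar$workdays, collapse = ", "), ")", call. = FALSE)
  }
  for (wd in calendar$workdays) {
    wa <- weekday_allocations[[wd]]
    if (!inherits(wa, "weekday_allocation") || wa$weekday != wd) {
      stop("config: weekday_allocations$", wd, " must be a weekday_allocation for ",
           wd, call. = FALSE)
    }
  }
  for (nm in c("clep_los", "nep_los")) {
    s <- get(nm)
    if (!inherits(s, "duration_spec") || s$units != "days") {
      stop("config: ", nm, " must be a duration_spec in days", call. = FALSE)
    }
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != round(seed)) {
    stop("config: seed must be an integer", call. = FALSE)
  }
  structure(list(calendar = calendar, horizon = horizon, resources = resources,
                 arrivals = arrivals[PATIENT_CLASSES],
                 procedure_classes = procedure_classes,
                 weekday_allocations = weekday_allocations[calendar$workdays],
                 clep_los = clep_los, nep_los = nep_los,
                 bed_policy = bed_policy, seed = as.integer(seed)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf("  resources: %d beds, %d EP labs, %d physicians on duty\n",
              x$resources$beds, x$resources$labs, x$resources$physicians_on_duty))
  cat(sprintf("  calendar:  %s, labs %s-%s, arrivals %s, day 1 = %s\n",
              paste(x$calendar$workdays, collapse = ""),
              format_hhmm(x$calendar$lab_open), format_hhmm(x$calendar$lab_close),
              format_hhmm(x$calendar$arrival_time), x$calendar$start_weekday))
  cat(sprintf("  horizon:   %d warm-up + %d observation days, %d replications\n",
              x$horizon$warmup_days, x$horizon$observation_days,
              x$horizon$replications))
  for (cl in PATIENT_CLASSES) {
    a <- x$arrivals[[cl]]
    cat(sprintf("  arrivals %s: %.3f (SD %.3f) per day [%s]\n",
                cl, a$mean, a$sd, a$regime))
  }
  cat(sprintf("  %d procedure classes; bed policy %s; seed %d\n",
              length(x$procedure_classes), x$bed_policy, x$seed))
  invisible(x)
}

# Table-transcribed default inputs for the modelled cardiology department:
# 11 EP procedure types with admission-mix proportions (raw values sum to
# 100.1% and are normalized), operative time / lab clean-up (minutes) and
# length of stay / pre-operative stay (days), each as mean, SD, min, max.
default_procedure_rows <- function() {
  list(
    list("Paroxysmal AF ablation",    18.4, c(204.947, 66.735, 65, 340),  c(7.467, 7.477, 2, 40), c(5.050, 2.350, 3, 11), c(2.000, 2.151, 1, 8)),
    list("Persistent AF ablation",     9.6, c(208.688, 51.927, 128, 321), c(5.800, 2.833, 2, 11), c(3.375, 1.061, 3, 6),  c(1.375, 1.061, 1, 4)),
    list("PVC ablation",              16.2, c(107.206, 40.630, 35, 202),  c(6.963, 4.485, 1, 25), c(2.810, 1.209, 2, 7),  c(1.400, 0.681, 0, 3)),
    list("SVT ablation",              17.6, c(99.067, 30.770, 70, 209),   c(5.130, 2.117, 1, 10), c(2.478, 0.730, 1, 4),  c(1.250, 0.550, 0, 2)),
    list("AFlutter/PAC/AT ablation",   5.9, c(212.545, 149.095, 70, 574), c(9.286, 9.032, 1, 28), c(4.000, 2.646, 2, 9),  c(1.333, 0.816, 1, 3)),
    list("GP ablation",                2.2, c(99.000, 52.849, 50, 155),   c(6.500, 2.121, 5, 8),  c(2.500, 0.707, 2, 3),  c(2.000, 0.000, 2, 2)),
    list("PFO closure",                2.2, c(35.333, 6.110, 30, 42),     c(7.500, 3.536, 5, 10), c(3.000, 0.000, 3, 3),  c(1.000, 0.000, 1, 1)),
    list("ICD implant",                1.5, c(99.250, 41.979, 65, 160),   c(6.667, 2.887, 5, 10), c(5.000, 0.000, 5, 5),  c(1.000, 0.000, 1, 1)),
    list("Dual-chamber PM implant",    5.9, c(104.063, 31.693, 49, 167),  c(8.444, 4.773, 2, 15), c(4.500, 1.732, 3, 7),  c(2.000, 1.414, 1, 3)),
    list("CRT PM implant",             3.7, c(190.200, 67.087, 94, 267),  c(5.600, 3.362, 2, 10), c(6.600, 3.715, 4, 12), c(2.200, 2.168, 1, 6)),
    list("Miscellaneous EP procedures", 16.9, c(86.741, 54.488, 27, 305), c(6.600, 4.619, 2, 25), c(2.917, 1.165, 2, 5),  c(1.167, 0.577, 1, 3))
  )
}

ds_from <- function(v, units) duration_spec(v[1L], v[2L], v[3L], v[4L], units)

#' Packaged default configuration
#'
#' The department the model was built around: 87 ward beds, 2 EP labs open
#' Monday-Friday 08:00-22:00 with 2 electrophysiologists on duty, daily
#' arrivals TEP 2.446 (SD 2.358), CLEP 3.875 (SD 2.684), NEP 13.161
#' (SD 5.990), 11 EP procedure classes with their duration summaries, and
#' per-weekday two-way physician allocations. Bed-only classes stay 5.427
#' (SD 4.261) days (CLEP) and 3.758 (SD 2.718) days (NEP), bounded at 1 day
#' and mean + 6 SD.
#'
#' @return A validated [model_config()].
#' @examples
#' cfg <- default_config()
#' cfg$resources$beds
#' @export
default_config <- function() {
  rows <- default_procedure_rows()
  pcs <- lapply(rows, function(r) {
    procedure_class(name = r[[1L]], proportion = r[[2L]] / 100,
                    operative_time = ds_from(r[[3L]], "minutes"),
                    cleanup = ds_from(r[[4L]], "minutes"),
                    length_of_stay = ds_from(r[[5L]], "days"),
                    preop_stay = ds_from(r[[6L]], "days"))
  })
  alloc <- list(
    Mon = weekday_allocation("Mon", 0.727, 0.273),
    Tue = weekday_allocation("Tue", 0.184, 0.816),
    Wed = weekday_allocation("Wed", 0.500, 0.500),
    Thu = weekday_allocation("Thu", 0.532, 0.468),
    Fri = weekday_allocation("Fri", 0.292, 0.708)
  )
  bed_only_los <- function(mean, sd) {
    duration_spec(mean, sd, min = 1, max = mean + 6 * sd, units = "days")
  }
  model_config(
    calendar = sim_calendar(),
    horizon = sim_horizon(),
    resources = resource_set(beds = 87L, labs = 2L, physicians_on_duty = 2L),
    arrivals = list(
      TEP = arrival_spec("TEP", 2.446, 2.358),
      CLEP = arrival_spec("CLEP", 3.875, 2.684),
      NEP = arrival_spec("NEP", 13.161, 5.990)
    ),
    procedure_classes = pcs,
    weekday_allocations = alloc,
    clep_los = bed_only_los(5.427, 4.261),
    nep_los = bed_only_los(3.758, 2.718),
    seed = DEFAULT_SEED
  )
}

# ---- YAML configuration files -------------------------------------------

need_key <- function(lst, key, where) {
  if (is.null(lst[[key]])) {
    stop("config file: missing required key '", key, "' in ", where, call. = FALSE)
  }
  lst[[key]]
}

ds_from_list <- function(lst, units, where) {
  for (k in c("mean", "sd", "min", "max")) need_key(lst, k, where)
  tryCatch(duration_spec(lst$mean, lst$sd, lst$min, lst$max, units),
           error = function(e) stop("config file: ", where, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Read a model configuration from a YAML file
#'
#' The schema mirrors [model_config()]: top-level sections `calendar`,
#' `horizon`, `resources`, `arrivals` (`TEP`/`CLEP`/`NEP`, each
#' `mean`/`sd`), `procedure_classes` (list of entries with `name`,
#' `proportion` and the four duration blocks `operative_time`, `cleanup`,
#' `length_of_stay`, `preop_stay`, each `mean`/`sd`/`min`/`max`),
#' `weekday_allocations` (`Mon: [p, p]`, ...), `clep_los`, `nep_los`,
#' `bed_policy` (`"waitlist"` or `"balk"`) and `seed`. Times of day are `"HH:MM"` strings; stays are in days, operative
#' and clean-up times in minutes. Missing optional sections fall back to the
#' defaults documented in the type constructors; procedure proportions are
#' normalized to sum to 1.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated [model_config()].
#' @seealso [write_config()] for the inverse.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("config file: failed to parse '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  if (!is.list(raw)) stop("config file: top level must be a mapping", call. = FALSE)
  config_from_list(raw)
}

config_from_list <- function(raw) {
  cal_raw <- raw$calendar %||% list()
  cal <- sim_calendar(
    workdays = cal_raw$workdays %||% WORKDAYS_DEFAULT,
    lab_open = cal_raw$lab_open %||% "08:00",
    lab_close = cal_raw$lab_close %||% "22:00",
    arrival_time = cal_raw$arrival_time %||% "07:00",
    start_weekday = cal_raw$start_weekday %||% "Sun"
  )
  hor_raw <- raw$horizon %||% list()
  hor <- sim_horizon(
    warmup_days = hor_raw$warmup_days %||% 10L,
    observation_days = hor_raw$observation_days %||% 61L,
    replications = hor_raw$replications %||% 1000L
  )
  res_raw <- need_key(raw, "resources", "top level")
  res <- resource_set(
    beds = need_key(res_raw, "beds", "resources"),
    labs = need_key(res_raw, "labs", "resources"),
    physicians_on_duty = res_raw$physicians_on_duty %||% 2L
  )
  arr_raw <- need_key(raw, "arrivals", "top level")
  arrivals <- lapply(PATIENT_CLASSES, function(cl) {
    a <- need_key(arr_raw, cl, "arrivals")
    arrival_spec(cl, need_key(a, "mean", paste0("arrivals$", cl)),
                 need_key(a, "sd", paste0("arrivals$", cl)),
                 regime = a$regime %||% "empirical")
  })
  names(arrivals) <- PATIENT_CLASSES
  pcs_raw <- need_key(raw, "procedure_classes", "top level")
  pcs <- lapply(pcs_raw, function(p) {
    nm <- need_key(p, "name", "procedure_classes")
    procedure_class(
      name = nm,
      proportion = need_key(p, "proportion", nm),
      operative_time = ds_from_list(need_key(p, "operative_time", nm), "minutes",
                                    paste0(nm, "$operative_time")),
      cleanup = ds_from_list(need_key(p, "cleanup", nm), "minutes",
                             paste0(nm, "$cleanup")),
      length_of_stay = ds_from_list(need_key(p, "length_of_stay", nm), "days",
                                    paste0(nm, "$length_of_stay")),
      preop_stay = ds_from_list(need_key(p, "preop_stay", nm), "days",
                                paste0(nm, "$preop_stay"))
    )
  })
  wa_raw <- need_key(raw, "weekday_allocations", "top level")
  wa <- lapply(cal$workdays, function(wd) {
    p <- need_key(wa_raw, wd, "weekday_allocations")
    if (length(p) != 2L) {
      stop("config file: weekday_allocations$", wd, " must be two probabilities",
           call. = FALSE)
    }
    weekday_allocation(wd, p[[1L]], p[[2L]])
  })
  names(wa) <- cal$workdays
  model_config(
    calendar = cal, horizon = hor, resources = res, arrivals = arrivals,
    procedure_classes = pcs, weekday_allocations = wa,
    clep_los = ds_from_list(need_key(raw, "clep_los", "top level"), "days", "clep_los"),
    nep_los = ds_from_list(need_key(raw, "nep_los", "top level"), "days", "nep_los"),
    bed_policy = raw$bed_policy %||% "waitlist",
    seed = raw$seed %||% DEFAULT_SEED
  )
}

ds_to_list <- function(s) list(mean = s$mean, sd = s$sd, min = s$min, max = s$max)

#' Write a model configuration to a YAML file
#'
#' The written file reads back with [load_config()] to a configuration equal
#' to the input (proportions are written in normalized form).
#'
#' @param config A [model_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  cal <- config$calendar
  out <- list(
    calendar = list(workdays = cal$workdays,
                    lab_open = format_hhmm(cal$lab_open),
                    lab_close = format_hhmm(cal$lab_close),
                    arrival_time = format_hhmm(cal$arrival_time),
                    start_weekday = cal$start_weekday),
    horizon = config$horizon[c("warmup_days", "observation_days", "replications")],
    resources = config$resources[c("beds", "labs", "physicians_on_duty")],
    arrivals = lapply(config$arrivals, function(a)
      list(mean = a$mean, sd = a$sd, regime = a$regime)),
    procedure_classes = lapply(unname(config$procedure_classes), function(p)
      list(name = p$name, proportion = p$proportion,
           operative_time = ds_to_list(p$operative_time),
           cleanup = ds_to_list(p$cleanup),
           length_of_stay = ds_to_list(p$length_of_stay),
           preop_stay = ds_to_list(p$preop_stay))),
    weekday_allocations = lapply(config$weekday_allocations, function(w)
      c(w$p_first, w$p_second)),
    clep_los = ds_to_list(config$clep_los),
    nep_los = ds_to_list(config$nep_los),
    bed_policy = config$bed_policy,
    seed = config$seed
  )
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
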