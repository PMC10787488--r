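# Discrete-event core. Time is day-structured: stays are integer days,
# lab events are continuous minutes measured from the start of simulation
# day 1 (absolute minute of day d, minute m = (d - 1) * 1440 + m). Each
# simulated day proceeds as: (1) bed turnover — every patient whose
# discharge day is today releases their bed at the morning turnover instant,
# (2) scheduled arrivals and admissions, (3) on workdays, the EP-lab day.

MINUTES_PER_DAY <- 1440

#' Weekday of a simulation day
#'
#' @param day 1-based simulation day index.
#' @param calendar A [sim_calendar()]; day 1 falls on `calendar$start_weekday`.
#' @return Weekday name (`"Sun".."Sat"`).
#' @export
weekday_of <- function(day, calendar) {
  start <- match(calendar$start_weekday, WEEKDAYS)
  WEEKDAYS[((start - 1L + day - 1L) %% 7L) + 1L]
}

#' Is a simulation day a lab workday?
#'
#' @inheritParams weekday_of
#' @return Logical.
#' @export
is_workday <- function(day, calendar) {
  weekday_of(day, calendar) %in% calendar$workdays
}

#' Earliest possible procedure day for an admitted EP-lab patient
#'
#' A patient admitted on `arrival_day` with a `preop_days`-night
#' pre-operative phase becomes eligible on day `arrival_day + preop_days`
#' (so `preop_days = 0` means a same-day candidate); if the labs are closed
#' on that day the patient waits for the next workday.
#'
#' @param arrival_day Admission day index.
#' @param preop_days Integer pre-operative stay in days (`>= 0`).
#' @param calendar A [sim_calendar()].
#' @return The day index of the first workday on or after
#'   `arrival_day + preop_days`.
#' @examples
#' cal <- sim_calendar()  # day 1 is a Sunday, labs Mon-Fri
#' plan_procedure_day(2, 1, cal)  # Mon arrival, 1 night pre-op -> Tue (day 3)
#' plan_procedure_day(6, 1, cal)  # Fri arrival -> candidate Sat, wait to Mon
#' @export
plan_procedure_day <- function(arrival_day, preop_days, calendar) {
  if (preop_days < 0) stop("plan_procedure_day: preop_days must be >= 0", call. = FALSE)
  if (length(calendar$workdays) == 0L) {
    stop("plan_procedure_day: calendar has no workdays", call. = FALSE)
  }
  d <- arrival_day + preop_days
  while (!is_workday(d, calendar)) d <- d + 1L
  d
}

# Run one EP-lab working day. Patients are already ordered FIFO and carry a
# physician slot (1 or 2). A procedure may start at the earliest time
# >= lab opening at which its assigned physician slot and any lab are free,
# and only if that time is strictly before lab closing; started procedures
# run to completion past closing. On completion the physician is released
# immediately; the lab is released after clean-up. Returns realized start
# times and which queue positions rolled over.
#
# slots: integer vector (1/2) per patient; oper, cleanup: minutes per patient;
# lab_free: absolute free times of each lab (persists across days).
run_lab_day_core <- function(slots, oper, cleanup, open_abs, close_abs, lab_free) {
  n <- length(slots)
  start <- rep(NA_real_, n)
  end <- rep(NA_real_, n)
  idx1 <- which(slots == 1L)
  idx2 <- which(slots == 2L)
  i1 <- 1L
  i2 <- 1L
  phys_free <- c(open_abs, open_abs)
  repeat {
    lab_min <- min(lab_free)
    cand1 <- if (i1 <= length(idx1)) max(open_abs, phys_free[1L], lab_min) else Inf
    cand2 <- if (i2 <= length(idx2)) max(open_abs, phys_free[2L], lab_min) else Inf
    if (cand1 <= cand2) {
      cand <- cand1
      slot <- 1L
    } else {
      cand <- cand2
      slot <- 2L
    }
    if (!is.finite(cand) || cand >= close_abs) break
    i <- if (slot == 1L) idx1[i1] else idx2[i2]
    if (slot == 1L) i1 <- i1 + 1L else i2 <- i2 + 1L
    j <- which.min(lab_free)
    start[i] <- cand
    end[i] <- cand + oper[i]
    phys_free[slot] <- end[i]
    lab_free[j] <- end[i] + cleanup[i]
  }
  # A slot whose own candidate passed closing may still leave the other slot
  # room; the loop above handles that by only breaking when neither can start.
  rolled <- which(is.na(start))
  list(start = start, end = end, rolled = rolled, lab_free = lab_free)
}

# Compile a configuration + scenario into the flat numeric structures the
# inner loop needs: fitted distribution parameters, per-day weekday/workday
# tables and effective resource counts.
compile_model <- function(config, scenario) {
  stopifnot(inherits(config, "model_config"), inherits(scenario, "scenario_spec"))
  if (config$resources$physicians_on_duty != 2L) {
    stop("the engine models two on-duty physician slots per workday (the ",
         "weekday allocations are two-way); physicians_on_duty must be 2",
         call. = FALSE)
  }
  cfg <- apply_scenario_modifications(config, scenario)
  cal <- cfg$calendar
  hor <- cfg$horizon
  beds <- scenario$bed_override %||% cfg$resources$beds
  labs <- scenario$lab_override %||% cfg$resources$labs
  n_days <- hor$warmup_days + hor$observation_days

  wd <- vapply(seq_len(n_days + 1L), weekday_of, "", calendar = cal)
  workday <- wd %in% cal$workdays
  # next workday on or after each day (NA once past the horizon)
  next_work <- rep(NA_integer_, n_days)
  nw <- NA_integer_
  for (d in rev(seq_len(n_days))) {
    if (workday[d]) nw <- d
    next_work[d] <- nw
  }
  p_first <- vapply(seq_len(n_days), function(d) {
    if (workday[d]) cfg$weekday_allocations[[wd[d]]]$p_first else NA_real_
  }, 0)

  pcs <- cfg$procedure_classes
  structure(list(
    beds = beds, labs = labs,
    warmup = hor$warmup_days, n_days = n_days,
    obs_days = hor$observation_days,
    open_m = cal$lab_open, close_m = cal$lab_close,
    workday = workday, next_work = next_work, p_first = p_first,
    tep_saturating = identical(scenario$tep_regime, "saturating"),
    waitlist = identical(cfg$bed_policy, "waitlist"),
    arr = lapply(cfg$arrivals, function(a) fit_negative_binomial(a$mean, a$sd)),
    class_names = names(pcs),
    class_prob = vapply(pcs, `[[`, 0, "proportion"),
    oper = lapply(pcs, function(p) fit_truncated_lognormal(p$operative_time)),
    clean = lapply(pcs, function(p) fit_truncated_lognormal(p$cleanup)),
    los = lapply(pcs, function(p) fit_truncated_lognormal(p$length_of_stay)),
    preop = lapply(pcs, function(p) fit_truncated_lognormal(p$preop_stay)),
    clep_los = fit_truncated_lognormal(cfg$clep_los),
    nep_los = fit_truncated_lognormal(cfg$nep_los)
  ), class = "compiled_model")
}

#' Run one simulation replication
#'
#' Simulates the full horizon day by day: the warm-up days carry only the two
#' bed-only patient classes; EP-lab (TEP) patient flow starts on the first
#' observation day. The result counts TEP discharges whose discharge day
#' falls inside the observation window. Deterministic given
#' `(config, scenario, seed)`.
#'
#' @param config A [model_config()].
#' @param scenario A [scenario_spec()] (e.g. [validation_scenario()]); its
#'   duration modifications and resource overrides are applied before
#'   simulation.
#' @param seed Integer RNG seed for this replication.
#' @param collect_patients If `TRUE`, attach a per-patient event table
#'   (`$patients`) with sampled durations and realized timestamps, usable as
#'   an event trace.
#' @return An object of class `replication_result` with fields
#'   `total_tep_discharges`, `daily_discharges` (length
#'   `observation_days`), `balked` (named count per class) and optionally
#'   `patients`.
#' @examples
#' r <- run_replication(default_config(), validation_scenario(), seed = 1)
#' r$total_tep_discharges
#' @export
run_replication <- function(config, scenario = validation_scenario(), seed,
                            collect_patients = FALSE) {
  cm <- compile_model(config, scenario)
  sim_compiled(cm, seed, collect_patients)
}

sim_compiled <- function(cm, seed, collect_patients = FALSE) {
  set.seed(as.integer(seed))
  n_days <- cm$n_days
  warmup <- cm$warmup
  free_beds <- cm$beds
  bed_release <- integer(n_days + 1L)
  daily_disch <- integer(n_days)
  balked <- c(TEP = 0L, CLEP = 0L, NEP = 0L)
  queue <- vector("list", n_days)
  lab_free <- rep(0, cm$labs)
  wait_q <- integer(0)  # FIFO bed queue (class labels), waitlist policy only

  # growable per-patient storage (TEP only)
  cap <- 1024L
  np <- 0L
  p_class <- integer(cap); p_adm <- integer(cap); p_los <- integer(cap)
  p_preop <- integer(cap); p_postop <- integer(cap)
  p_oper <- numeric(cap); p_clean <- numeric(cap); p_sched0 <- integer(cap)
  p_procday <- integer(cap); p_start <- numeric(cap); p_end <- numeric(cap)
  p_disch <- integer(cap); p_slot <- integer(cap)
  grow <- function(need) {
    while (cap < need) cap <<- cap * 2L
    length(p_class) <<- cap; length(p_adm) <<- cap; length(p_los) <<- cap
    length(p_preop) <<- cap; length(p_postop) <<- cap; length(p_oper) <<- cap
    length(p_clean) <<- cap; length(p_sched0) <<- cap; length(p_procday) <<- cap
    length(p_start) <<- cap; length(p_end) <<- cap; length(p_disch) <<- cap
    length(p_slot) <<- cap
  }

  for (d in seq_len(n_days)) {
    # 1. morning turnover: discharges free beds before today's admissions
    free_beds <- free_beds + bed_release[d]

    # 2. scheduled arrivals (every calendar day)
    n_clep <- sample_daily_arrivals(cm$arr$CLEP)
    n_nep <- sample_daily_arrivals(cm$arr$NEP)
    tep_flow <- d > warmup
    n_tep_adm <- 0L
    if (!cm$tep_saturating) {
      n_tep <- if (tep_flow) sample_daily_arrivals(cm$arr$TEP) else 0L
      # random interleaved arrival order across the three classes
      today <- c(rep(1L, n_tep), rep(2L, n_clep), rep(3L, n_nep))
      if (length(today) > 1L) today <- sample(today)
      if (cm$waitlist) {
        # FIFO bed queue: earlier days first, then today's interleaved order
        wait_q <- c(wait_q, today)
        n_admit <- min(length(wait_q), free_beds)
        head_q <- wait_q[seq_len(n_admit)]
        wait_q <- wait_q[-seq_len(n_admit)]
        adm <- tabulate(head_q, nbins = 3L)
      } else {
        n_admit <- min(length(today), free_beds)
        adm <- tabulate(today[seq_len(n_admit)], nbins = 3L)
        blk <- tabulate(today, nbins = 3L) - adm
        balked <- balked + c(TEP = blk[1L], CLEP = blk[2L], NEP = blk[3L])
      }
      n_tep_adm <- adm[1L]
      n_clep_adm <- adm[2L]
      n_nep_adm <- adm[3L]
    } else {
      # bed-only classes first, then TEP generated to fill every free bed
      today <- c(rep(2L, n_clep), rep(3L, n_nep))
      if (length(today) > 1L) today <- sample(today)
      if (cm$waitlist) {
        wait_q <- c(wait_q, today)
        n_admit <- min(length(wait_q), free_beds)
        head_q <- wait_q[seq_len(n_admit)]
        wait_q <- wait_q[-seq_len(n_admit)]
        adm <- tabulate(head_q, nbins = 3L)
      } else {
        n_admit <- min(length(today), free_beds)
        adm <- tabulate(today[seq_len(n_admit)], nbins = 3L)
        blk <- tabulate(today, nbins = 3L) - adm
        balked <- balked + c(TEP = 0L, CLEP = blk[2L], NEP = blk[3L])
      }
      n_clep_adm <- adm[2L]
      n_nep_adm <- adm[3L]
      if (tep_flow) n_tep_adm <- free_beds - n_admit
    }
    free_beds <- free_beds - n_clep_adm - n_nep_adm - n_tep_adm
    if (free_beds < 0) stop("internal error: negative free beds on day ", d)

    if (n_clep_adm > 0L) {
      los <- sample_integer_days(cm$clep_los, n_clep_adm)
      rel <- d + los
      rel <- rel[rel <= n_days]
      if (length(rel)) {
        tb <- tabulate(rel, nbins = n_days)
        bed_release <- bed_release + c(tb, 0L)
      }
    }
    if (n_nep_adm > 0L) {
      los <- sample_integer_days(cm$nep_los, n_nep_adm)
      rel <- d + los
      rel <- rel[rel <= n_days]
      if (length(rel)) {
        tb <- tabulate(rel, nbins = n_days)
        bed_release <- bed_release + c(tb, 0L)
      }
    }
    if (n_tep_adm > 0L) {
      if (np + n_tep_adm > cap) grow(np + n_tep_adm)
      cls <- draw_procedure_class_idx(cm$class_prob, n_tep_adm)
      for (k in seq_len(n_tep_adm)) {
        ci <- cls[k]
        los_k <- sample_integer_days(cm$los[[ci]], 1L)
        preop_k <- sample_preop_given_los(cm$preop[[ci]], los_k)
        np <- np + 1L
        p_class[np] <- ci
        p_adm[np] <- d
        p_los[np] <- los_k
        p_preop[np] <- preop_k
        p_postop[np] <- los_k - preop_k
        p_oper[np] <- sample_truncated(cm$oper[[ci]], 1L)
        p_clean[np] <- sample_truncated(cm$clean[[ci]], 1L)
        p_procday[np] <- NA_integer_
        p_start[np] <- NA_real_
        p_end[np] <- NA_real_
        p_disch[np] <- NA_integer_
        cand <- d + preop_k
        sched <- if (cand <= n_days) cm$next_work[cand] else NA_integer_
        p_sched0[np] <- if (is.na(sched)) NA_integer_ else sched
        if (!is.na(sched)) queue[[sched]] <- c(queue[[sched]], np)
      }
    }

    # 3. EP-lab day
    ids <- queue[[d]]
    if (cm$workday[d] && length(ids)) {
      ids <- ids[order(p_sched0[ids], p_adm[ids], ids)]
      slots <- ifelse(stats::runif(length(ids)) < cm$p_first[d], 1L, 2L)
      open_abs <- (d - 1L) * MINUTES_PER_DAY + cm$open_m
      close_abs <- (d - 1L) * MINUTES_PER_DAY + cm$close_m
      res <- run_lab_day_core(slots, p_oper[ids], p_clean[ids],
                              open_abs, close_abs, lab_free)
      lab_free <- res$lab_free
      done <- which(!is.na(res$start))
      for (k in done) {
        id <- ids[k]
        p_procday[id] <- d
        p_slot[id] <- slots[k]
        p_start[id] <- res$start[k]
        p_end[id] <- res$end[k]
        # post-op = LOS minus the *realized* pre-operative stay (which may
        # exceed the sampled one through workday/lab waits), floored at 0:
        # delays eat into recovery time, preserving the observed LOS
        # distribution, and discharge never precedes the procedure day.
        postop <- max(p_los[id] - (d - p_adm[id]), 0L)
        p_postop[id] <- postop
        disch <- d + postop
        p_disch[id] <- disch
        if (disch <= n_days) daily_disch[disch] <- daily_disch[disch] + 1L
        rel <- max(disch, d + 1L)  # zero post-op: bed held to next turnover
        if (rel <= n_days) bed_release[rel] <- bed_release[rel] + 1L
      }
      if (length(res$rolled)) {
        nw <- if (d + 1L <= n_days) cm$next_work[d + 1L] else NA_integer_
        if (!is.na(nw)) queue[[nw]] <- c(queue[[nw]], ids[res$rolled])
      }
    }
  }

  obs <- seq.int(warmup + 1L, n_days)
  daily <- daily_disch[obs]
  out <- list(total_tep_discharges = sum(daily), daily_discharges = daily,
              balked = balked)
  if (collect_patients && np > 0L) {
    sel <- seq_len(np)
    out$patients <- data.frame(
      id = sel,
      procedure_class = cm$class_names[p_class[sel]],
      arrival_day = p_adm[sel],
      los_days = p_los[sel],
      preop_days = p_preop[sel],
      postop_days = p_postop[sel],
      operative_minutes = p_oper[sel],
      cleanup_minutes = p_clean[sel],
      first_scheduled_day = p_sched0[sel],
      procedure_day = p_procday[sel],
      physician_slot = p_slot[sel],
      procedure_start = p_start[sel],
      procedure_end = p_end[sel],
      discharge_day = p_disch[sel]
    )
  }
  structure(out, class = "replication_result")
}

# sample.int with prob re-normalizes every call; this inner-loop variant
# reuses the cumulative mix.
draw_procedure_class_idx <- function(prob, n) {
  findInterval(stats::runif(n), cumsum(prob) / sum(prob)) + 1L
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("<replication_result> %d TEP discharges over %d observed days (balked: TEP %d, CLEP %d, NEP %d)\n",
              x$total_tep_discharges, length(x$daily_discharges),
              x$balked[["TEP"]], x$balked[["CLEP"]], x$balked[["NEP"]]))
  invisible(x)
}
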