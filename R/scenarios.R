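# Scenario construction: the validation run, the two capacity-limiting base
# cases (bed-limited and lab-limited), and percentage reductions of stay or
# operative time applied to the two AF-ablation procedure classes.

AF_CLASSES <- c("Paroxysmal AF ablation", "Persistent AF ablation")

#' Scenario specification
#'
#' A complete runnable experiment: optional resource overrides, the TEP
#' arrival regime, and a list of duration modifications to apply to the
#' configuration before simulating.
#'
#' @param name Scenario label.
#' @param bed_override,lab_override Optional resource overrides (`NULL` keeps
#'   the configuration's counts); `>= 1` when given.
#' @param tep_regime `"empirical"` (negative-binomial TEP arrivals) or
#'   `"saturating"` (TEP arrivals generated to fill every bed left after the
#'   bed-only classes are admitted).
#' @param modifications List of [duration_modification()]s.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, bed_override = NULL, lab_override = NULL,
                          tep_regime = c("empirical", "saturating"),
                          modifications = list()) {
  tep_regime <- match.arg(tep_regime)
  for (ov in list(bed_override, lab_override)) {
    if (!is.null(ov) && (!is.numeric(ov) || ov < 1 || ov != round(ov))) {
      stop("scenario_spec: resource overrides must be integers >= 1", call. = FALSE)
    }
  }
  for (m in modifications) {
    if (!inherits(m, "duration_modification")) {
      stop("scenario_spec: modifications must be duration_modification objects",
           call. = FALSE)
    }
  }
  structure(list(name = name,
                 bed_override = if (is.null(bed_override)) NULL else as.integer(bed_override),
                 lab_override = if (is.null(lab_override)) NULL else as.integer(lab_override),
                 tep_regime = tep_regime, modifications = modifications),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  ov <- c(if (!is.null(x$bed_override)) paste0(x$bed_override, " beds"),
          if (!is.null(x$lab_override)) paste0(x$lab_override, " labs"))
  cat(sprintf("<scenario_spec> '%s': %s TEP arrivals%s, %d modification(s)\n",
              x$name, x$tep_regime,
              if (length(ov)) paste0(", override ", paste(ov, collapse = ", ")) else "",
              length(x$modifications)))
  invisible(x)
}

#' Duration modification
#'
#' Reduces the total length of stay of the target procedure classes by
#' `reduction_pct` percent of the LOS mean, applied to a chosen phase of the
#' stay, or scales their operative time down by `reduction_pct` percent.
#'
#' @param phase `"preop"`, `"postop"`, `"both"` (stay phases; the expected
#'   reduction in days is `reduction_pct`% of the class LOS mean) or
#'   `"operative"` (multiplicative scaling of operative time).
#' @param reduction_pct Percentage in `(0, 100)`.
#' @param target_classes Procedure-class names (default: the two AF-ablation
#'   classes).
#' @return An object of class `duration_modification`.
#' @export
duration_modification <- function(phase = c("preop", "postop", "both", "operative"),
                                  reduction_pct, target_classes = AF_CLASSES) {
  phase <- match.arg(phase)
  if (!is.numeric(reduction_pct) || reduction_pct <= 0 || reduction_pct >= 100) {
    stop("duration_modification: reduction_pct must be in (0, 100)", call. = FALSE)
  }
  structure(list(phase = phase, reduction_pct = reduction_pct,
                 target_classes = target_classes),
            class = "duration_modification")
}

#' Validation scenario
#'
#' Empirical arrivals for all classes, no resource overrides, no duration
#' modifications — the configuration as observed, for comparison against real
#' discharge data.
#'
#' @return A [scenario_spec()].
#' @export
validation_scenario <- function() {
  scenario_spec("validation", tep_regime = "empirical")
}

#' Base case with fully occupied ward beds
#'
#' Resources unchanged; TEP arrivals switched to the saturating regime so
#' that, after the bed-only classes are admitted each morning, EP-lab
#' patients fill every remaining free bed. Ward beds, not EP labs, are the
#' binding constraint.
#'
#' @return A [scenario_spec()].
#' @export
cls_wards_base <- function() {
  scenario_spec("wards/base", tep_regime = "saturating")
}

#' Base case with fully occupied EP labs
#'
#' Ward beds increased to 110 and EP labs reduced to one, with saturating TEP
#' arrivals, so that lab time becomes the binding constraint.
#'
#' @return A [scenario_spec()].
#' @export
cls_eplabs_base <- function() {
  scenario_spec("eplabs/base", bed_override = 110L, lab_override = 1L,
                tep_regime = "saturating")
}

#' Apply a duration modification to a configuration
#'
#' For stay phases, the expected reduction in days is
#' `delta = reduction_pct/100 * LOS mean` per target class, and the LOS mean
#' always drops by the full `delta`; the phase decides where the saved days
#' come out of the patient's schedule:
#'
#' * `preop`: the pre-operative mean is shifted down by `delta` but floored
#'   at 1 day (the floor also binds the truncation minimum); whatever part of
#'   the shift the floor absorbs effectively comes out of the post-operative
#'   side, since the LOS still drops by `delta`.
#' * `postop`: the pre-op spec is untouched, so the post-operative stay (LOS
#'   minus pre-op) shrinks by construction.
#' * `both`: the pre-op shift is `delta` times the pre-op share of the LOS
#'   mean (1-day floor as above), the remainder comes off the post-op side.
#' * `operative`: the operative-time spec is scaled multiplicatively by
#'   `1 - reduction_pct/100` (mean, SD, min and max alike); stays are
#'   untouched.
#'
#' Stay specs are shifted as whole distributions: the SD is held fixed and
#' the truncation bounds are translated by the same amount as the mean
#' (floored at 1 day), then refit when sampled. A reduction that would push a
#' LOS mean below 1 day, or below the class's pre-operative mean, is a
#' validation error.
#'
#' @param base The [scenario_spec()] the modification belongs to (unused in
#'   the arithmetic; kept so call sites read as scenario construction).
#' @param mod A [duration_modification()].
#' @param config A [model_config()]; never mutated.
#' @return A modified copy of `config`.
#' @examples
#' cfg <- apply_reduction(cls_eplabs_base(),
#'                        duration_modification("operative", 30), default_config())
#' cfg$procedure_classes[["Paroxysmal AF ablation"]]$operative_time$mean  # 143.463
#' @export
apply_reduction <- function(base, mod, config) {
  stopifnot(inherits(mod, "duration_modification"), inherits(config, "model_config"))
  missing_cls <- setdiff(mod$target_classes, names(config$procedure_classes))
  if (length(missing_cls)) {
    stop("apply_reduction: target class(es) not in the configuration: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  frac <- mod$reduction_pct / 100
  for (nm in mod$target_classes) {
    pc <- config$procedure_classes[[nm]]
    if (mod$phase == "operative") {
      s <- pc$operative_time
      f <- 1 - frac
      pc$operative_time <- duration_spec(s$mean * f, s$sd * f, s$min * f,
                                         s$max * f, s$units)
    } else {
      delta <- frac * pc$length_of_stay$mean
      if (mod$phase %in% c("preop", "both")) {
        share <- if (mod$phase == "preop") 1 else
          pc$preop_stay$mean / pc$length_of_stay$mean
        # the 1-day floor binds the pre-op distribution only; the full
        # expected LOS reduction is applied below regardless, so any part of
        # the pre-op shift the floor absorbs comes out of the post-op side
        pc$preop_stay <- shift_stay_spec(pc$preop_stay,
                                         pc$preop_stay$mean - delta * share,
                                         floor_min = 1,
                                         what = paste0(nm, " pre-operative stay"))
      }
      new_los <- pc$length_of_stay$mean - delta
      if (new_los < 1) {
        stop("apply_reduction: ", nm, " (", mod$phase, "): reduced length-of-stay ",
             "mean ", signif(new_los, 4), " is below 1 day", call. = FALSE)
      }
      if (new_los < pc$preop_stay$mean) {
        stop("apply_reduction: ", nm, " (", mod$phase, "): reduced length-of-stay ",
             "mean ", signif(new_los, 4), " falls below the pre-operative mean ",
             signif(pc$preop_stay$mean, 4), call. = FALSE)
      }
      pc$length_of_stay <- shift_stay_spec(pc$length_of_stay, new_los,
                                           floor_min = 1,
                                           what = paste0(nm, " length of stay"))
    }
    config$procedure_classes[[nm]] <- pc
  }
  config
}

# Shift a stay spec's mean with SD held fixed, translating the truncation
# bounds by the same amount (the whole distribution moves left), with the
# minimum floored at floor_min days. Constant specs (sd = 0) shift all four
# numbers.
shift_stay_spec <- function(s, new_mean, floor_min, what) {
  new_mean <- max(new_mean, floor_min)
  if (s$sd == 0) {
    return(duration_spec(new_mean, 0, new_mean, new_mean, s$units))
  }
  shift <- s$mean - new_mean
  new_min <- max(s$min - shift, floor_min)
  new_max <- max(s$max - shift, new_mean)
  duration_spec(new_mean, s$sd, min(new_min, new_mean), new_max, s$units)
}

apply_scenario_modifications <- function(config, scenario) {
  for (m in scenario$modifications) {
    config <- apply_reduction(scenario, m, config)
  }
  config
}

#' Enumerate the full scenario grid
#'
#' Every cell of the two capacity-limiting analyses: for each base case
#' (bed-limited `wards`, lab-limited `eplabs`), the base itself plus the four
#' phases (`operative`, `preop`, `postop`, `both`) at 10/20/30% reductions —
#' 26 scenarios in total, with stable names like `"wards/preop/20"`.
#'
#' @return Named list of [scenario_spec()]s.
#' @export
scenario_grid <- function() {
  out <- list()
  for (cls in c("wards", "eplabs")) {
    base <- if (cls == "wards") cls_wards_base() else cls_eplabs_base()
    out[[base$name]] <- base
    for (phase in c("operative", "preop", "postop", "both")) {
      for (pct in c(10, 20, 30)) {
        nm <- paste(cls, phase, pct, sep = "/")
        sc <- base
        sc$name <- nm
        sc$modifications <- list(duration_modification(phase, pct))
        out[[nm]] <- sc
      }
    }
  }
  out
}
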