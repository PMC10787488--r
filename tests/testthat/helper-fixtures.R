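# Shared fixtures: constant-duration specs and a tiny fully deterministic
# department used for hand-computed timeline oracles.

const_spec <- function(v, units) duration_spec(v, 0, v, v, units)

all_workdays <- c("Mon", "Tue", "Wed", "Thu", "Fri")

# A minimal department: one procedure class with constant durations, two
# anonymous physician slots with p_first = 1 (everything through slot 1),
# negligible bed-only arrivals. Deterministic under the saturating regime.
tiny_config <- function(beds = 2L, labs = 1L, oper = 60, cleanup = 30,
                        los = 3, preop = 1, warmup = 1L, obs = 9L,
                        start_weekday = "Mon", p_first = 1,
                        tep_mean = 1, tep_sd = 1) {
  model_config(
    calendar = sim_calendar(start_weekday = start_weekday),
    horizon = sim_horizon(warmup_days = warmup, observation_days = obs,
                          replications = 10L),
    resources = resource_set(beds = beds, labs = labs),
    arrivals = list(
      TEP = arrival_spec("TEP", tep_mean, tep_sd),
      CLEP = arrival_spec("CLEP", 1e-9, 0),
      NEP = arrival_spec("NEP", 1e-9, 0)
    ),
    procedure_classes = list(
      procedure_class("Test procedure", 1,
                      operative_time = const_spec(oper, "minutes"),
                      cleanup = const_spec(cleanup, "minutes"),
                      length_of_stay = const_spec(los, "days"),
                      preop_stay = const_spec(preop, "days"))
    ),
    weekday_allocations = lapply(stats::setNames(nm = all_workdays), function(w)
      weekday_allocation(w, p_first, 1 - p_first)),
    clep_los = const_spec(1, "days"),
    nep_los = const_spec(1, "days")
  )
}

saturating_scenario <- function() scenario_spec("sat", tep_regime = "saturating")

# every (class, phase) duration spec of a config, flattened for bound checks
all_duration_specs <- function(config) {
  out <- list()
  for (pc in config$procedure_classes) {
    for (ph in c("operative_time", "cleanup", "length_of_stay", "preop_stay")) {
      out[[paste(pc$name, ph)]] <- pc[[ph]]
    }
  }
  out$clep_los <- config$clep_los
  out$nep_los <- config$nep_los
  out
}
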