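test_that("procedure-day planning respects pre-op nights and workdays", {
  cal <- sim_calendar()  # day 1 = Sunday, labs Mon-Fri
  expect_equal(plan_procedure_day(2, 1, cal), 3)   # Mon arrival -> Tue
  expect_equal(plan_procedure_day(6, 1, cal), 9)   # Fri arrival -> Sat -> Mon
  expect_equal(plan_procedure_day(4, 0, cal), 4)   # zero pre-op: same day
  expect_equal(plan_procedure_day(1, 0, cal), 2)   # Sunday -> Monday
  expect_error(plan_procedure_day(1, -1, cal), ">= 0")
})

test_that("a lab day follows the hand-computed timeline", {
  open <- 480
  close <- 1320
  # one patient, 60 min: starts at opening, lab busy until cleanup done
  r <- epflowsim:::run_lab_day_core(slots = 1L, oper = 60, cleanup = 10,
                                    open_abs = open, close_abs = close,
                                    lab_free = 0)
  expect_equal(r$start, 480)
  expect_equal(r$end, 540)
  expect_equal(r$lab_free, 550)
  expect_length(r$rolled, 0L)

  # two slots serialize on a single lab through the cleanup gap
  r2 <- epflowsim:::run_lab_day_core(slots = c(1L, 2L), oper = c(60, 60),
                                     cleanup = c(30, 30), open_abs = open,
                                     close_abs = close, lab_free = 0)
  expect_equal(r2$start, c(480, 570))

  # four 840-minute procedures, 2 labs, 2 slots: the 840-min window fits
  # exactly one start per physician slot; the other two roll over
  r3 <- epflowsim:::run_lab_day_core(slots = c(1L, 2L, 1L, 2L),
                                     oper = rep(840, 4), cleanup = rep(0, 4),
                                     open_abs = open, close_abs = close,
                                     lab_free = c(0, 0))
  expect_equal(r3$start, c(480, 480, NA, NA))
  expect_equal(r3$rolled, c(3L, 4L))

  # a start strictly before closing is allowed; at closing it is not
  r4 <- epflowsim:::run_lab_day_core(slots = c(1L, 1L, 1L),
                                     oper = c(839, 1, 60), cleanup = rep(0, 3),
                                     open_abs = open, close_abs = close,
                                     lab_free = 0)
  expect_equal(r4$start, c(480, 1319, NA))  # 1319 < 1320 ok; then 1320 rolls
  expect_equal(r4$rolled, 3L)
})

test_that("a deterministic saturating run matches the full hand timeline", {
  cfg <- tiny_config()  # 2 beds, 1 lab, const: oper 60, cleanup 30, los 3, preop 1
  r <- run_replication(cfg, saturating_scenario(), seed = 42,
                       collect_patients = TRUE)
  # Mon day 1 is warm-up; beds fill Tue day 2; procedures Wed day 3 at
  # 08:00 and 09:30 (cleanup gap); discharge day 5 (admission + LOS); the
  # Fri day 5 cohort waits over the weekend, operates Mon day 8 with zero
  # post-op left and frees beds Tue day 9.
  expect_equal(r$total_tep_discharges, 4L)
  expect_equal(r$daily_discharges, c(0L, 0L, 0L, 2L, 0L, 0L, 2L, 0L, 0L))
  p <- r$patients
  expect_equal(p$arrival_day, c(2L, 2L, 5L, 5L, 9L, 9L))
  expect_equal(p$procedure_day, c(3L, 3L, 8L, 8L, 10L, 10L))
  expect_equal(p$procedure_start - (p$procedure_day - 1) * 1440,
               rep(c(480, 570), 3))
  expect_equal(p$procedure_end - p$procedure_start, rep(60, 6))
  expect_equal(p$discharge_day, c(5L, 5L, 8L, 8L, 12L, 12L))
  expect_equal(p$postop_days, c(2L, 2L, 0L, 0L, 2L, 2L))
})

test_that("replications are deterministic and conserve discharge counts", {
  cfg <- default_config()
  r1 <- run_replication(cfg, validation_scenario(), seed = 7)
  r2 <- run_replication(cfg, validation_scenario(), seed = 7)
  expect_identical(r1$total_tep_discharges, r2$total_tep_discharges)
  expect_identical(r1$daily_discharges, r2$daily_discharges)
  expect_equal(sum(r1$daily_discharges), r1$total_tep_discharges)
  expect_length(r1$daily_discharges, cfg$horizon$observation_days)
  expect_true(r1$total_tep_discharges >= 0)
})

test_that("negligible TEP arrival rates produce no TEP discharges", {
  cfg <- tiny_config(tep_mean = 1e-9, tep_sd = 0, obs = 20L)
  r <- run_replication(cfg, validation_scenario(), seed = 1)
  expect_equal(r$total_tep_discharges, 0L)
})

test_that("lab and physician capacity are never exceeded", {
  cfg <- default_config()
  for (sc in list(cls_wards_base(), cls_eplabs_base())) {
    r <- run_replication(cfg, sc, seed = 13, collect_patients = TRUE)
    p <- r$patients[!is.na(r$patients$procedure_day), ]
    labs <- if (identical(sc$name, "eplabs/base")) 1L else 2L
    # sweep the start/end events: concurrent procedures <= labs
    ev <- rbind(data.frame(t = p$procedure_start, d = 1L),
                data.frame(t = p$procedure_end, d = -1L))
    ev <- ev[order(ev$t, ev$d), ]
    expect_lte(max(cumsum(ev$d)), labs)
    # within a physician slot and day, procedures never overlap
    by_slot <- split(p, list(p$procedure_day, p$physician_slot), drop = TRUE)
    for (g in by_slot) {
      g <- g[order(g$procedure_start), ]
      if (nrow(g) > 1L) {
        expect_true(all(g$procedure_start[-1L] >= g$procedure_end[-nrow(g)]))
      }
    }
    # no start outside working hours or on a closed day
    start_min <- p$procedure_start - (p$procedure_day - 1) * 1440
    expect_true(all(start_min >= cfg$calendar$lab_open &
                      start_min < cfg$calendar$lab_close))
    expect_true(all(vapply(p$procedure_day, is_workday, TRUE,
                           calendar = cfg$calendar)))
    # discharge never precedes the procedure day or exceeds admission + LOS
    done <- !is.na(p$discharge_day)
    expect_true(all(p$discharge_day[done] >= p$procedure_day[done]))
    expect_true(all(p$discharge_day[done] ==
                      pmax(p$arrival_day[done] + p$los_days[done],
                           p$procedure_day[done])))
  }
})

test_that("the saturating regime fills every bed left by the other classes", {
  # with negligible CLEP/NEP arrivals, TEP admissions on the first
  # observation day equal the full bed count
  cfg <- tiny_config(beds = 10L, obs = 5L)
  r <- run_replication(cfg, saturating_scenario(), seed = 3,
                       collect_patients = TRUE)
  expect_equal(sum(r$patients$arrival_day == 2L), 10L)
})

test_that("adding beds or labs never reduces mean throughput (paired seeds)", {
  cfg <- default_config()
  mean_total <- function(scenario, reps = 20L) {
    run_batch(cfg, scenario, n_reps = reps, master_seed = 2024)$mean_total
  }
  wards_more_beds <- scenario_spec("wards+beds", bed_override = 97L,
                                   tep_regime = "saturating")
  expect_gte(mean_total(wards_more_beds), mean_total(cls_wards_base()))
  eplabs_more_labs <- scenario_spec("eplabs+lab", bed_override = 110L,
                                    lab_override = 2L, tep_regime = "saturating")
  expect_gte(mean_total(eplabs_more_labs), mean_total(cls_eplabs_base()))
})
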