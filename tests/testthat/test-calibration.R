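test_that("synthetic logs satisfy the patient-log invariants", {
  cfg <- default_config()
  log <- generate_synthetic_log(cfg, n_days = 40L, seed = 77)
  expect_true(all(log$patient_class %in% c("TEP", "CLEP", "NEP")))
  tep <- log[log$patient_class == "TEP", ]
  expect_gt(nrow(tep), 0L)
  expect_true(all(tep$admission_date <= tep$procedure_date))
  expect_true(all(tep$procedure_date <= tep$discharge_date))
  expect_true(all(tep$physician_id %in% c("EP1", "EP2")))
  # procedures land on workdays only
  wd <- as.integer(format(tep$procedure_date, "%w"))
  expect_true(all(wd %in% 1:5))
  expect_true(all(log$discharge_date > log$admission_date))
  # deterministic under a fixed seed
  expect_identical(log, generate_synthetic_log(cfg, n_days = 40L, seed = 77))
})

test_that("log files round-trip and malformed logs are rejected", {
  cfg <- default_config()
  log <- generate_synthetic_log(cfg, n_days = 15L, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_patient_log(log, path)
  log2 <- read_patient_log(path)
  expect_equal(log2$admission_date, log$admission_date)
  expect_equal(log2$procedure_class, log$procedure_class)
  expect_equal(log2$physician_id, log$physician_id)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,wrong_column", bad)
  expect_error(read_patient_log(bad), "header")
  writeLines(paste(epflowsim:::LOG_HEADER, collapse = ","), bad)
  expect_error(read_patient_log(bad), "empty")
  expect_error(read_patient_log(withr::local_tempfile(fileext = ".csv")),
               "not found")
})

test_that("estimator arithmetic is exact on a hand-built log", {
  d0 <- as.Date("2022-05-01")  # a Sunday
  mk <- function(id, cls, adm, dis, pc = "", proc = NA, s = "", e = "", phy = "") {
    data.frame(patient_id = id, patient_class = cls,
               admission_date = d0 + adm, discharge_date = d0 + dis,
               procedure_class = pc,
               procedure_date = if (is.na(proc)) as.Date(NA) else d0 + proc,
               procedure_start = s, procedure_end = e, physician_id = phy)
  }
  # TEP admissions on the three span days: counts 2, 3, 1 -> mean 2.0
  log <- rbind(
    mk("t1", "TEP", 0, 5, "Ablation", 2, "08:00", "10:00", "A"),  # preop 2, los 5
    mk("t2", "TEP", 0, 3, "Ablation", 1, "09:00", "10:30", "A"),
    mk("t3", "TEP", 1, 4, "Ablation", 2, "12:00", "13:00", "B"),
    mk("t4", "TEP", 1, 2, "Ablation", 2, "21:30", "01:30", "A"),  # past midnight
    mk("t5", "TEP", 1, 6, "Ablation", 3, "10:00", "11:00", "A"),
    mk("t6", "TEP", 2, 5, "Ablation", 3, "08:00", "09:00", "B"),
    mk("c1", "CLEP", 0, 4), mk("c2", "CLEP", 2, 3),
    mk("n1", "NEP", 0, 2), mk("n2", "NEP", 1, 4)
  )
  cfg <- estimate_config(log)
  expect_equal(cfg$arrivals$TEP$mean, 2.0)
  expect_equal(cfg$arrivals$TEP$sd, 1.0)
  expect_equal(cfg$arrivals$CLEP$mean, 2 / 3)
  ab <- cfg$procedure_classes[["Ablation"]]
  expect_equal(ab$proportion, 1)
  # t1: los 5, preop 2; t4 operative crosses midnight: 240 minutes
  expect_equal(ab$length_of_stay$mean, mean(c(5, 3, 3, 1, 5, 3)))
  expect_equal(ab$preop_stay$mean, mean(c(2, 1, 1, 1, 2, 1)))
  expect_equal(ab$operative_time$mean, mean(c(120, 90, 60, 240, 60, 60)))
  expect_equal(ab$operative_time$max, 240)
  # procedures fell on Mon (1) and Tue/Wed; Tuesday saw A, A, B -> 2/3
  tue <- cfg$weekday_allocations[["Tue"]]
  expect_equal(sort(c(tue$p_first, tue$p_second)), c(1 / 3, 2 / 3))
  # CLEP LOS from per-patient stays 4 and 1
  expect_equal(cfg$clep_los$mean, 2.5)
})

test_that("estimator refuses logs with undefined spread", {
  d0 <- as.Date("2022-05-02")
  one <- data.frame(patient_id = c("t1", "c1", "c2", "n1", "n2"),
                    patient_class = c("TEP", "CLEP", "CLEP", "NEP", "NEP"),
                    admission_date = d0 + 0:4, discharge_date = d0 + 3:7,
                    procedure_class = c("Ablation", "", "", "", ""),
                    procedure_date = c(d0 + 1, rep(as.Date(NA), 4)),
                    procedure_start = c("08:00", "", "", "", ""),
                    procedure_end = c("09:00", "", "", "", ""),
                    physician_id = c("A", "", "", "", ""))
  expect_error(estimate_config(one), "fewer than 2")
})

test_that("estimation recovers the generating parameters (round trip)", {
  cfg <- default_config()
  n_days <- 400L
  log <- generate_synthetic_log(cfg, n_days = n_days, seed = 314)
  est <- suppressWarnings(estimate_config(log))

  # arrival means within 3 standard errors of the generating values
  for (cl in c("TEP", "CLEP", "NEP")) {
    se <- est$arrivals[[cl]]$sd / sqrt(n_days)
    expect_lt(abs(est$arrivals[[cl]]$mean - cfg$arrivals[[cl]]$mean), 3 * se)
  }

  # admission-mix proportions within 3 SE of the normalized mix
  n_tep <- sum(log$patient_class == "TEP")
  for (nm in c("Paroxysmal AF ablation", "SVT ablation")) {
    p0 <- cfg$procedure_classes[[nm]]$proportion
    se <- sqrt(p0 * (1 - p0) / n_tep)
    expect_lt(abs(est$procedure_classes[[nm]]$proportion - p0), 3 * se)
  }

  # stay and operative moments against the *realized* sampling distribution
  # (truncation and integer rounding shift the realized mean away from the
  # spec moments, so a direct large sample of the generator's distribution
  # is the honest oracle)
  pa <- est$procedure_classes[["Paroxysmal AF ablation"]]
  pa0 <- cfg$procedure_classes[["Paroxysmal AF ablation"]]
  set.seed(1)
  los_oracle <- mean(sample_integer_days(
    fit_truncated_lognormal(pa0$length_of_stay), 1e5))
  oper_oracle <- mean(sample_truncated(
    fit_truncated_lognormal(pa0$operative_time), 1e5))
  expect_equal(pa$length_of_stay$mean, los_oracle, tolerance = 0.05)
  expect_equal(pa$operative_time$mean, oper_oracle, tolerance = 0.05)
  expect_true(pa$length_of_stay$min >= pa0$length_of_stay$min)
  expect_true(pa$operative_time$max <= pa0$operative_time$max + 1)

  # weekday allocations as unordered pairs (slot labels are unobservable)
  for (wd in c("Mon", "Tue", "Fri")) {
    a0 <- cfg$weekday_allocations[[wd]]
    a1 <- est$weekday_allocations[[wd]]
    expect_equal(sort(c(a1$p_first, a1$p_second)),
                 sort(c(a0$p_first, a0$p_second)), tolerance = 0.12)
  }

  # bed-only stays
  expect_equal(est$clep_los$mean, cfg$clep_los$mean, tolerance = 0.07)
  expect_equal(est$nep_los$mean, cfg$nep_los$mean, tolerance = 0.07)
})
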