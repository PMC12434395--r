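test_that("drug kill rate obeys the Emax and kernel identities", {
  p <- drug_params()
  expect_equal(drug_kill_rate(0, 0:10, p), rep(0, 11))
  # dose = EC50: peak kill is kill_max / 2 (kernel peaks at 1)
  tau <- seq(0, p$effect_duration, by = 0.01)
  peak <- max(drug_kill_rate(p$ec50, tau, p))
  expect_equal(peak, p$kill_max / 2, tolerance = 1e-4)
  # saturation: plateau at kill_max as dose -> Inf
  peak_hi <- max(drug_kill_rate(1e6 * p$ec50, tau, p))
  expect_equal(peak_hi, p$kill_max, tolerance = 1e-3)
  # truncation beyond effect_duration; resistant multiplier
  expect_equal(drug_kill_rate(1, p$effect_duration + 1, p), 0)
  expect_equal(drug_kill_rate(1, 5, p, resistant = TRUE),
               p$resistance_factor * drug_kill_rate(1, 5, p))
  expect_error(drug_kill_rate(1, -1, p), "time_since_dose")
  expect_error(drug_kill_rate(-1, 1, p), "dose")
})

test_that("effect peak arrives earlier at higher dose", {
  p <- drug_params()
  tau <- seq(0, p$effect_duration, by = 0.01)
  peaks <- vapply(c(0.1, 0.5, 1.0), function(d) {
    tau[which.max(drug_kill_rate(d, tau, p))]
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("ST protocol gives exactly three fixed doses then stops", {
  st <- protocol_st()
  doses <- vapply(0:5, function(k) {
    as.numeric(next_dose(st, n_given = k))
  }, numeric(1))
  expect_equal(doses, c(60, 60, 60, 0, 0, 0))
})

test_that("AT controller modulates dose by target volume bands", {
  at <- protocol_at()
  # unchanged volume: multiplier 1, dose unchanged
  expect_equal(as.numeric(next_dose(at, 500, 500, last_dose = 60)), 60)
  # growth >= 10%: x1.5 capped at 60
  expect_equal(as.numeric(next_dose(at, 600, 500, last_dose = 30)), 45)
  expect_equal(as.numeric(next_dose(at, 600, 500, last_dose = 50)), 60)
  # shrinkage >= 10%: halved
  expect_equal(as.numeric(next_dose(at, 400, 500, last_dose = 60)), 30)
  # below min_dose: omitted but nominal retained
  d <- next_dose(at, 400, 500, last_dose = 1.5)
  expect_equal(as.numeric(d), 0)
  expect_equal(attr(d, "nominal"), 0.75)
  expect_error(next_dose(at, 500, 500, last_dose = NULL), "last nominal")
  expect_error(next_dose(at, -5, 500, last_dose = 60), "positive")
  # malformed band table is rejected
  expect_error(protocol_at(rule_table = data.frame(lower = c(-Inf, 0.2),
                                                   upper = c(0.1, Inf),
                                                   multiplier = c(1, 1))),
               "partition")
})

test_that("repeated shrinkage drives the AT dose to omission", {
  at <- protocol_at()
  dose <- 60; vol <- 1000
  seqd <- numeric(0)
  nominal <- 60
  for (k in 1:10) {
    vol_new <- vol * 0.8
    d <- next_dose(at, vol_new, vol, last_dose = nominal)
    nominal <- attr(d, "nominal")
    seqd <- c(seqd, as.numeric(d))
    vol <- vol_new
  }
  expect_true(all(diff(seqd) <= 0))
  expect_true(any(seqd == 0))               # eventually omitted
  expect_true(any(seqd > 0 & seqd < 3))     # passes through very low doses
})

invivo_model <- function(gs = 0.08, gr = 0.06, K = 3e7) {
  competition_model(population_params(gs, K, "sensitive"),
                    population_params(gr, K, "resistant"), 1, 1)
}

test_that("vehicle course reproduces untreated growth and dose accounting is exact", {
  m <- invivo_model()
  cfg <- sim_config(seed = 42, sampling_times = c(0, 1))
  init <- gen_mouse_cohort("80:20", 1, m, cfg)[[1]]
  veh <- run_course(m, drug_params_invivo(), protocol_vehicle(), init)
  expect_equal(sum(veh$dose_log$dose), 0)
  # untreated tumor grows monotonically to endpoint
  v1 <- veh$volumes$volume_mm3[veh$volumes$flank == 1]
  expect_true(all(diff(v1) > -1e-6))
  expect_true(veh$event)
  st <- run_course(m, drug_params_invivo(), protocol_st(), init)
  expect_equal(sum(st$dose_log$dose), 180)  # 3 x 60 exactly
  expect_equal(st$dose_log$dose[st$dose_log$dose > 0],
               rep(60, 3))
  # ST delays the endpoint relative to vehicle in a sensitive-majority tumor
  expect_gt(st$event_day, veh$event_day)
})

test_that("AT decisions never consult the nontarget flank", {
  m <- invivo_model()
  cfg <- sim_config(seed = 42, sampling_times = c(0, 1))
  init <- gen_mouse_cohort("80:20", 1, m, cfg)[[1]]
  # perturb only the nontarget flank; dose log must be unchanged
  init2 <- init
  nontarget <- setdiff(1:2, init$target_flank)
  init2$state_at_enroll[, nontarget] <- init$state_at_enroll[, nontarget] * 0.5
  at1 <- run_course(m, drug_params_invivo(), protocol_at(), init)
  at2 <- run_course(m, drug_params_invivo(), protocol_at(), init2)
  n <- min(nrow(at1$dose_log), nrow(at2$dose_log))
  expect_equal(at1$dose_log$dose[seq_len(n)], at2$dose_log$dose[seq_len(n)])
})

test_that("fully resistant tumors with no resistant kill match vehicle timing", {
  m <- invivo_model()
  cfg <- sim_config(seed = 13, sampling_times = c(0, 1))
  drug0 <- drug_params_invivo()
  drug0$resistance_factor <- 0
  init <- gen_mouse_cohort("0:100", 1, m, cfg)[[1]]
  veh <- run_course(m, drug0, protocol_vehicle(), init)
  st <- run_course(m, drug0, protocol_st(), init)
  at <- run_course(m, drug0, protocol_at(), init)
  expect_lte(abs(st$event_day - veh$event_day), 1)
  expect_lte(abs(at$event_day - veh$event_day), 1)
})

test_that("competitive release: resistant regrowth is faster after ST than vehicle", {
  m <- invivo_model()
  cfg <- sim_config(seed = 99, sampling_times = c(0, 1))
  init <- gen_mouse_cohort("80:20", 1, m, cfg)[[1]]
  veh <- run_course(m, drug_params_invivo(), protocol_vehicle(), init)
  st <- run_course(m, drug_params_invivo(), protocol_st(), init)
  rate <- function(course) {
    v <- course$volumes[course$volumes$flank == 1, ]
    hi <- min(40, max(v$day))
    win <- v$day >= 14 & v$day <= hi  # post-treatment window
    stats::coef(stats::lm(log(v$resistant_cells[win]) ~ v$day[win]))[[2]]
  }
  expect_gt(rate(st), rate(veh))
})

test_that("Kaplan-Meier medians and log-rank match first principles", {
  km <- kaplan_meier_logrank(c(1, 2, 3), c(1, 1, 1))
  expect_equal(unname(km$medians[[1]]), 2)
  # identical groups: p = 1
  km2 <- kaplan_meier_logrank(rep(c(1, 2, 3), 2), rep(1, 6),
                              rep(c("a", "b"), each = 3))
  expect_equal(km2$p, 1)
  expect_equal(km2$chisq, 0, tolerance = 1e-12)
  # all censored input is flagged
  expect_warning(kaplan_meier_logrank(c(5, 6), c(0, 0)), "censored")
  # separated groups: medians recovered, p small
  km3 <- kaplan_meier_logrank(c(rep(5, 10), rep(10, 10)), rep(1, 20),
                              rep(c("a", "b"), each = 10))
  expect_equal(unname(km3$medians), c(5, 10))
  expect_lt(km3$p, 0.01)
})

test_that("log-rank agrees with an independent risk-table computation", {
  set.seed(31)
  time <- c(sample(1:15, 10, TRUE), sample(4:20, 10, TRUE))
  event <- rep(1, 20); event[c(3, 11, 18)] <- 0
  group <- rep(c("a", "b"), each = 10)
  km <- kaplan_meier_logrank(time, event, group)
  oracle <- logrank_oracle(time, event, group)
  expect_equal(km$chisq, oracle$chisq, tolerance = 1e-10)
  expect_equal(km$p, oracle$p, tolerance = 1e-10)
})

test_that("a small matched trial prefers AT over ST under a fitness cost", {
  m <- invivo_model()
  cfg <- sim_config(seed = 8, sampling_times = c(0, 1))
  drug <- drug_params_invivo()
  drug$resistance_factor <- 0.2
  tr <- suppressWarnings(
    run_trial(cohort_ratios = "80:20",
              arms = list(ST = protocol_st(), AT = protocol_at()),
              n_per_arm = 2, model = m, drug = drug, config = cfg))
  med <- tr$medians
  at_med <- med$median_weeks[med$arm == "AT"]
  st_med <- med$median_weeks[med$arm == "ST"]
  # undefined AT median (too few deaths) counts as longer survival
  expect_true(is.na(at_med) || at_med >= st_med)
  expect_true(all(tr$subjects$cum_dose[tr$subjects$arm == "ST" &
                                         tr$subjects$enrolled] == 180))
})
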