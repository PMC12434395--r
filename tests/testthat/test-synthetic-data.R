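test_that("sim_config validates its invariants", {
  expect_error(sim_config(noise_cv = -0.1), "noise_cv")
  expect_error(sim_config(cn_noise_sd = -1), "cn_noise_sd")
  expect_error(sim_config(sampling_times = c(0, 2, 1)), "increasing")
  expect_error(sim_config(sampling_times = numeric(0)), "non-empty")
  expect_s3_class(sim_config(seed = 3), "sim_config")
})

test_that("all generators are byte-deterministic under a fixed seed", {
  pair <- test_pair()
  m <- competition_model(pair$s, pair$r, 1, 1)
  cfg <- sim_config(seed = 11, noise_cv = 0.05, sampling_times = 0:10)
  expect_identical(gen_monoculture(pair$s, 1e4, cfg),
                   gen_monoculture(pair$s, 1e4, cfg))
  expect_identical(gen_coculture(m, "50:50", 1e5, cfg),
                   gen_coculture(m, "50:50", 1e5, cfg))
  expect_identical(gen_drug_pulse(m, drug_params(), c(0, 0.5), cfg),
                   gen_drug_pulse(m, drug_params(), c(0, 0.5), cfg))
  expect_identical(gen_cn_series(30, 8, c(0, 0.3), c(0.8, 0.7), cfg),
                   gen_cn_series(30, 8, c(0, 0.3), c(0.8, 0.7), cfg))
  mv <- competition_model(population_params(0.08, 3e7),
                          population_params(0.06, 3e7, "resistant"), 1, 1)
  expect_identical(gen_mouse_cohort("80:20", 2, mv, cfg),
                   gen_mouse_cohort("80:20", 2, mv, cfg))
})

test_that("monoculture generator honours zero-growth and doubling identities", {
  cfg0 <- sim_config(seed = 1, noise_cv = 0, sampling_times = 0:5)
  flat <- gen_monoculture(population_params(0, 1e6), 500, cfg0)
  expect_true(all(flat$count == 500))
  dbl <- gen_monoculture(population_params(1, 1e12), 1000, cfg0)
  expect_equal(dbl$count[dbl$time_days == 1 & dbl$replicate == 1], 2000,
               tolerance = 1e-9)
  expect_error(gen_monoculture(population_params(1, 1e6), 0, cfg0), "n0")
})

test_that("noisy monoculture data are invertible by the growth fit", {
  p <- population_params(0.5, 1e6)
  cfg <- sim_config(seed = 21, n_replicates = 3, noise_cv = 0.05,
                    sampling_times = seq(0, 30, 1))
  fit <- fit_monoculture(gen_monoculture(p, 1e4, cfg))
  expect_lt(abs(coef(fit)[["growth_rate"]] - 0.5) / 0.5, 0.05)
  expect_lt(abs(coef(fit)[["carrying_capacity"]] - 1e6) / 1e6, 0.10)
})

test_that("coculture generator decouples and symmetrises correctly", {
  cfg0 <- sim_config(seed = 2, noise_cv = 0, sampling_times = 0:12)
  pair <- test_pair()
  m0 <- competition_model(pair$s, pair$r, 0, 0)
  cc <- gen_coculture(m0, "50:50", 2e5, cfg0)
  for (pop in c("sensitive", "resistant")) {
    pp <- if (pop == "sensitive") pair$s else pair$r
    got <- cc$count[cc$population == pop & cc$replicate == 1]
    expect_equal(got, logistic_solution(1e5, pp, 0:12), tolerance = 1e-6)
  }
  # identical parameters, 50:50 seeding: S(t) = R(t)
  msym <- competition_model(population_params(0.5, 1e6),
                            population_params(0.5, 1e6, "resistant"), 1, 1)
  sym <- gen_coculture(msym, "50:50", 2e5, cfg0)
  expect_equal(sym$count[sym$population == "sensitive"],
               sym$count[sym$population == "resistant"], tolerance = 1e-8)
  expect_error(gen_coculture(m0, c(-0.2, 1.2), 1e5, cfg0), "non-negative")
})

test_that("drug pulse at dose zero reproduces the untreated coculture", {
  pair <- test_pair()
  m <- competition_model(pair$s, pair$r, 1, 1)
  cfg <- sim_config(seed = 5, noise_cv = 0, sampling_times = 0:20)
  pulse <- gen_drug_pulse(m, drug_params(), 0, cfg)
  untr <- gen_coculture(m, "50:50", 2.5e5, cfg)
  expect_equal(pulse$count, untr$count, tolerance = 1e-8)
  expect_error(gen_drug_pulse(m, drug_params(), -1, cfg), ">= 0")
  expect_error(gen_drug_pulse(m, drug_params(), 0.5, cfg, pulse_day = 99),
               "sampling window")
})

test_that("sensitive-fraction nadir deepens and arrives earlier with dose", {
  pair <- test_pair()
  m <- competition_model(pair$s, pair$r, 1, 1)
  cfg <- sim_config(seed = 5, noise_cv = 0, sampling_times = seq(0, 34, 0.5))
  pulse <- gen_drug_pulse(m, drug_params(), c(0.1, 0.5, 1.0), cfg)
  res <- t(vapply(c(0.1, 0.5, 1.0), function(d) {
    tr <- pulse[pulse$condition == sprintf("dose=%g", d), ]
    nd <- sensitive_fraction_nadir(tr, 6)
    c(nd$lag_days, nd$nadir_fraction)
  }, numeric(2)))
  expect_true(all(diff(res[, 1]) <= 0))   # nadir not later at higher dose
  expect_true(all(diff(res[, 2]) < 0))    # nadir strictly deeper
  expect_true(all(res[, 1] >= 5 & res[, 1] <= 12))
})

test_that("mouse cohort reflects jitter settings and injected mixture", {
  mv <- competition_model(population_params(0.08, 3e7),
                          population_params(0.06, 3e7, "resistant"), 1, 1)
  cfg <- sim_config(seed = 9, sampling_times = c(0, 1))
  # no jitter: both flanks identical
  co0 <- gen_mouse_cohort("80:20", 2, mv, cfg, jitter_cv = 0, rate_cv = 0)
  expect_equal(co0[[1]]$flanks[1, ], co0[[1]]$flanks[2, ])
  # pure sensitive mix: resistant compartment identically zero
  cos <- gen_mouse_cohort("100:0", 2, mv, cfg)
  expect_true(all(vapply(cos, function(m) all(m$flanks[, "R"] == 0),
                         logical(1))))
  expect_true(all(vapply(cos, function(m) m$state_at_enroll["R", ] == 0,
                         logical(2))))
  # jittered cohort: enrollment days vary but are all reported
  co <- gen_mouse_cohort("80:20", 8, mv, cfg, jitter_cv = 0.3)
  days <- vapply(co, `[[`, numeric(1), "enroll_day")
  expect_true(all(is.finite(days) | is.na(days)))
  expect_gt(stats::sd(days, na.rm = TRUE), 0)
})

test_that("copy-number generator obeys the purity mixture equation", {
  # noiseless, r = 0 everywhere: later samples equal baseline after
  # purity correction
  cfg0 <- sim_config(seed = 3, cn_noise_sd = 0, sampling_times = c(0, 1))
  ser <- gen_cn_series(40, 10, c(0, 0, 0), c(1, 0.6, 0.8), cfg0,
                       decoy_fraction = 0)
  gt <- ground_truth(ser)
  base <- ser$segments[ser$segments$sample_id == "S01", "copy_number"]
  for (sid in c("S02", "S03")) {
    obs <- ser$segments[ser$segments$sample_id == sid, "copy_number"]
    rho <- ser$manifest$purity[ser$manifest$sample_id == sid]
    expect_equal((obs - 2 * (1 - rho)) / rho, base, tolerance = 1e-12)
  }
  # mixture identity at purity 1: observed = c0 + r * delta
  ser2 <- gen_cn_series(40, 10, c(0, 0.4), c(1, 1), cfg0,
                        decoy_fraction = 0)
  gt2 <- ground_truth(ser2)
  obs2 <- ser2$segments[ser2$segments$sample_id == "S02", "copy_number"]
  expect_equal(obs2, gt2$baseline_cn + 0.4 * gt2$true_deltas,
               tolerance = 1e-12)
  # full subclone at purity 1 equals the subclone profile
  ser3 <- gen_cn_series(40, 10, c(0, 1), c(1, 1), cfg0, decoy_fraction = 0)
  gt3 <- ground_truth(ser3)
  obs3 <- ser3$segments[ser3$segments$sample_id == "S02", "copy_number"]
  expect_equal(obs3, gt3$baseline_cn + gt3$true_deltas, tolerance = 1e-12)
  expect_error(gen_cn_series(40, 10, c(0, 1.5), c(1, 1), cfg0), "\\[0, 1\\]")
  expect_error(gen_cn_series(40, 45, c(0, 1), c(1, 1), cfg0),
               "n_resistant_segments")
})

test_that("ground truth always accompanies generated data", {
  cfg <- sim_config(seed = 4, sampling_times = 0:5)
  gt1 <- ground_truth(gen_monoculture(population_params(1, 1e6), 100, cfg))
  expect_true(!is.null(gt1$true_params) && !is.null(gt1$subseed))
  ser <- gen_cn_series(30, 5, c(0, 0.2), c(0.9, 0.9), cfg)
  gt2 <- ground_truth(ser)
  expect_true(all(gt2$true_deltas[gt2$true_resistant_segments] != 0))
  expect_true(all(gt2$true_subclone_ratios >= 0 &
                    gt2$true_subclone_ratios <= 1))
})
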