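test_that("purity correction inverts the diploid contamination model", {
  expect_equal(purity_correct(3, 1), 3)
  expect_equal(purity_correct(3, 0.5), 4)
  expect_warning(out <- purity_correct(0.2, 0.5), "clipped")
  expect_equal(out, 0)
  expect_error(purity_correct(3, 0), "purity")
  expect_error(purity_correct(3, 1.2), "purity")
  # round trip with the generator at zero noise
  cfg0 <- sim_config(seed = 6, cn_noise_sd = 0, sampling_times = c(0, 1))
  ser <- gen_cn_series(40, 10, c(0, 0.35), c(0.8, 0.55), cfg0,
                       decoy_fraction = 0)
  gt <- ground_truth(ser)
  obs <- ser$segments[ser$segments$sample_id == "S02", "copy_number"]
  expect_equal(purity_correct(obs, 0.55),
               (1 - 0.35) * gt$baseline_cn + 0.35 * (gt$baseline_cn +
                                                       gt$true_deltas),
               tolerance = 1e-12)
})

test_that("resistance-specific segment calling filters clonal and decoy segments", {
  # later = baseline exactly: empty set
  ser0 <- make_shift_series(matrix(0, 5, 2))
  expect_length(call_resistance_segments(ser0), 0)
  # one monotone segment 0 -> 0.2 -> 0.4 is included
  sm <- matrix(0, 5, 2); sm[3, ] <- c(0.2, 0.4)
  expect_equal(as.integer(call_resistance_segments(ser0 <-
                                                     make_shift_series(sm))),
               3L)
  # a decoy shifting +0.4 then back to 0 is excluded
  sm2 <- sm; sm2[5, ] <- c(0.4, 0)
  expect_equal(as.integer(call_resistance_segments(make_shift_series(sm2))),
               3L)
  # baseline-only series has nothing to call against
  only_base <- make_shift_series(matrix(0.1, 3, 1))
  only_base$segments <- only_base$segments[only_base$segments$sample_id ==
                                             "S01", ]
  only_base$manifest <- only_base$manifest[1, ]
  expect_error(call_resistance_segments(only_base), "after the baseline")
})

test_that("calling separates true from decoy segments on generated genomes", {
  cfg <- sim_config(seed = 17, cn_noise_sd = 0.05, sampling_times = c(0, 1))
  ser <- gen_cn_series(120, 20, c(0, 0.15, 0.35, 0.6),
                       c(0.7, 0.6, 0.7, 0.6), cfg, decoy_fraction = 0.1)
  gt <- ground_truth(ser)
  called <- call_resistance_segments(ser)
  expect_gt(length(intersect(called, gt$true_resistant_segments)), 10)
  expect_length(intersect(called, gt$decoy_segments), 0)
})

test_that("mixture estimator solves the exact identities", {
  # single segment, shifts 0.2 / 0.4: delta resolved to 1 by parsimony
  f1 <- estimate_subclone_ratio(make_shift_series(matrix(c(0.2, 0.4), 1)),
                                segments = 1, refine = FALSE)
  expect_equal(f1$ratios$ratio, c(0, 0.2, 0.4), tolerance = 1e-9)
  expect_equal(unname(f1$deltas), 1L)
  # two segments, true deltas (+1, -2), r = (0.2, 0.4): exact recovery
  sm <- rbind(c(0.2, 0.4), c(-0.4, -0.8))
  f2 <- estimate_subclone_ratio(make_shift_series(sm), segments = 1:2,
                                refine = FALSE)
  expect_equal(f2$ratios$ratio, c(0, 0.2, 0.4), tolerance = 1e-9)
  expect_equal(unname(f2$deltas), c(1L, -2L))
  expect_lt(f2$sse, 1e-12)
  # all shifts zero: r = 0 with an explicit flag
  f3 <- estimate_subclone_ratio(make_shift_series(matrix(0, 2, 2)),
                                segments = 1:2, refine = FALSE)
  expect_true(all(f3$ratios$ratio == 0))
  expect_match(paste(f3$warnings, collapse = " "), "no emergent subclone")
  expect_error(estimate_subclone_ratio(make_shift_series(sm),
                                       segments = integer(0)),
               "empty")
})

test_that("scale degeneracy is resolved by parsimony", {
  # doubled deltas with halved ratios produce identical data; the
  # reported solution must be the minimal-delta one
  sm <- rbind(c(0.2, 0.4), c(-0.4, -0.8)) * 2  # = deltas (2,-4), r (0.2,0.4)
  f <- estimate_subclone_ratio(make_shift_series(sm), segments = 1:2,
                               refine = FALSE)
  expect_equal(unname(f$deltas), c(1L, -2L))
  expect_equal(f$ratios$ratio, c(0, 0.4, 0.8), tolerance = 1e-9)
})

test_that("ALS matches brute-force search on small noiseless instances", {
  cases <- list(
    list(delta = c(1L), r = c(0.3, 0.5)),
    list(delta = c(1L, -2L), r = c(0.2, 0.4)),
    list(delta = c(2L, -1L, 3L), r = c(0.15, 0.45)),
    list(delta = c(-1L, -2L), r = c(0.25, 0.5)),
    list(delta = c(2L, 2L), r = c(0.2, 0.3)),     # gcd-degenerate
    list(delta = c(3L, -3L), r = c(0.1, 0.3)))    # gcd-degenerate
  for (cs in cases) {
    shift <- cs$r %*% t(cs$delta)  # samples x segments
    ser <- make_shift_series(t(shift))
    fit <- estimate_subclone_ratio(ser, segments = seq_along(cs$delta),
                                   refine = FALSE)
    bf <- brute_force_mixture(shift)
    expect_equal(unname(fit$deltas), bf$delta)
    expect_equal(fit$ratios$ratio[-1], bf$r, tolerance = 1e-9)
    expect_lt(abs(fit$sse - bf$sse), 1e-10)
  }
})

test_that("two-sample series carry a reliability warning", {
  f <- estimate_subclone_ratio(make_shift_series(matrix(c(0.3, 0.3), 2, 1)),
                               segments = 1:2, refine = FALSE)
  expect_match(paste(f$warnings, collapse = " "), "two samples")
  # three or more samples: no such warning
  f3 <- estimate_subclone_ratio(make_shift_series(rbind(c(0.2, 0.4),
                                                        c(0.2, 0.4))),
                                segments = 1:2, refine = FALSE)
  expect_no_match(paste(f3$warnings, collapse = " "), "two samples")
})

test_that("noisy generated genomes are recovered within 0.05 absolute", {
  hits <- vapply(1:10, function(i) {
    cfg <- sim_config(seed = 3000 + i, cn_noise_sd = 0.05,
                      sampling_times = c(0, 1))
    ser <- gen_cn_series(60, 20, c(0, 0.1, 0.3, 0.6),
                         c(0.7, 0.6, 0.65, 0.55), cfg)
    fit <- suppressWarnings(estimate_subclone_ratio(ser))
    max(abs(fit$ratios$ratio - c(0, 0.1, 0.3, 0.6))) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("bootstrap CI collapses on noiseless data and flags tiny segment sets", {
  sm <- rbind(c(0.2, 0.4), c(-0.4, -0.8), c(0.2, 0.4), c(0.4, 0.8))
  fit <- estimate_subclone_ratio(make_shift_series(sm), segments = 1:4,
                                 refine = FALSE)
  fit <- bootstrap_ci(fit, n_boot = 50, seed = 2)
  expect_true(all(fit$ratios$ci_high - fit$ratios$ci_low < 1e-6))
  expect_false(fit$unstable_ci)
  # three called segments: unstable flag raised
  fit3 <- estimate_subclone_ratio(make_shift_series(sm[1:3, , drop = FALSE]),
                                  segments = 1:3, refine = FALSE)
  expect_warning(fit3 <- bootstrap_ci(fit3, n_boot = 20, seed = 2),
                 "unstable")
  expect_true(fit3$unstable_ci)
})

test_that("CI width shrinks as the resistant segment count grows", {
  width_at <- function(nres, seed) {
    cfg <- sim_config(seed = seed, cn_noise_sd = 0.05,
                      sampling_times = c(0, 1))
    ser <- gen_cn_series(200, nres, c(0, 0.2, 0.5), c(0.7, 0.7, 0.7), cfg)
    fit <- suppressWarnings(estimate_subclone_ratio(ser))
    fit <- suppressWarnings(bootstrap_ci(fit, n_boot = 80, seed = seed))
    mean(fit$ratios$ci_high[-1] - fit$ratios$ci_low[-1])
  }
  w10 <- mean(vapply(1:5, function(i) width_at(10, 4000 + i), numeric(1)))
  w40 <- mean(vapply(1:5, function(i) width_at(40, 4100 + i), numeric(1)))
  expect_lt(w40, w10)
})

test_that("subclone growth rates follow both interval definitions", {
  sm <- rbind(c(0.1, 0.3, 0.35))
  fit <- suppressWarnings(
    estimate_subclone_ratio(make_shift_series(sm, days = c(0, 100, 200, 300)),
                            segments = 1, refine = FALSE))
  gr <- subclone_growth_rate(fit)
  expect_equal(nrow(gr), 3)
  expect_equal(gr$rate_per_day, c(0.1 / 100, 0.2 / 100, 0.05 / 100),
               tolerance = 1e-9)
  grb <- subclone_growth_rate(fit, method = "baseline")
  expect_equal(grb$rate_per_day, c(0.1 / 100, 0.3 / 200, 0.35 / 300),
               tolerance = 1e-9)
  # constant ratio: zero rates
  fitc <- estimate_subclone_ratio(make_shift_series(rbind(c(0.2, 0.2))),
                                  segments = 1, refine = FALSE)
  expect_true(all(subclone_growth_rate(fitc)$rate_per_day[-1] == 0))
  fit$ratios$day[2] <- fit$ratios$day[1]
  expect_error(subclone_growth_rate(fit), "duplicate")
})

test_that("burden correlation matches a first-principles covariance computation", {
  rates <- c(0.001, 0.004, 0.002, 0.006, 0.003)
  marker <- 35 + 9000 * rates + c(0.5, -0.8, 0.2, 1.1, -0.4)
  ct <- correlate_burden(rates, marker)
  r_manual <- sum((rates - mean(rates)) * (marker - mean(marker))) /
    sqrt(sum((rates - mean(rates))^2) * sum((marker - mean(marker))^2))
  expect_equal(ct$r, r_manual, tolerance = 1e-12)
  expect_equal(ct$r_squared, r_manual^2, tolerance = 1e-12)
  # perfect collinearity
  expect_equal(correlate_burden(rates, 2 * rates + 1)$r, 1)
  expect_equal(correlate_burden(rates, -2 * rates + 1)$r, -1)
  expect_error(correlate_burden(rates[1:2], marker[1:2]), ">= 3")
  expect_error(correlate_burden(rates, rep(1, 5)), "variance")
})
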