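#' Synthetic study-shaped data generators
#'
#' These generators emulate the experimental designs the package analyses
#' (monoculture and coculture growth in low-resource conditions, single
#' drug-pulse cocultures, two-flank mouse cohorts, longitudinal copy-number
#' series) with known ground truth, so every downstream estimator can be
#' validated end to end. All randomness flows from the [sim_config()] seed;
#' every dataset carries a `ground_truth` attribute recording the
#' parameters and sub-seed that produced it.
#'
#' @name synthetic_data
NULL

new_trajectory <- function(df, ground_truth) {
  rownames(df) <- NULL
  attr(df, "ground_truth") <- ground_truth
  df
}

#' Ground truth attached to a synthetic dataset
#'
#' @param x a generated dataset.
#' @return The generator's ground-truth list (true parameters, sub-seed).
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' Generate a monoculture growth trajectory
#'
#' Closed-form logistic growth evaluated at the configured sampling days,
#' multiplied by lognormal measurement noise with the configured CV
#' (median-1 noise, so log-scale fits are unbiased).
#'
#' @param params true [population_params].
#' @param n0 seeding density in cells (> 0).
#' @param config a [sim_config()].
#' @param condition condition label, e.g. `"low_resource"`.
#' @return Tidy trajectory `data.frame` (`time_days`, `population`, `count`,
#'   `replicate`, `condition`, `seeding_ratio`) with a `ground_truth`
#'   attribute.
#' @examples
#' cfg <- sim_config(seed = 7, noise_cv = 0)
#' tr <- gen_monoculture(population_params(1, 1e9), 1000, cfg)
#' tr$count[tr$time_days == 1]  # one doubling/day far below K
#' @export
gen_monoculture <- function(params, n0, config,
                            condition = "low_resource") {
  stopifnot(inherits(params, "population_params"),
            inherits(config, "sim_config"))
  if (n0 <= 0) stop("`n0` must be > 0")
  tt <- config$sampling_times
  mu <- logistic_solution(n0, params, tt)
  sub <- derive_subseeds(config$seed, 1L)
  counts <- with_seed(sub, {
    unlist(lapply(seq_len(config$n_replicates), function(rep) {
      mu * lognormal_noise(length(tt), config$noise_cv)
    }))
  })
  df <- data.frame(
    time_days = rep(tt, config$n_replicates),
    population = params$label,
    count = counts,
    replicate = rep(seq_len(config$n_replicates), each = length(tt)),
    condition = condition,
    seeding_ratio = if (params$label == "sensitive") "100:0" else "0:100",
    stringsAsFactors = FALSE)
  new_trajectory(df, list(true_params = params, n0 = n0, subseed = sub,
                          config = config))
}

#' Generate a coculture growth trajectory under competition
#'
#' Integrates the two-population competition model from the given seeding
#' ratio, then applies multiplicative measurement noise per population,
#' replicate and time point. Supports the experimental ratio sets
#' `{85:15, 50:50, 15:85}` and `{95:5 ... 5:95}`.
#'
#' @param model a [competition_model] (the ground truth).
#' @param seeding_ratio `"85:15"` style string or a length-2 numeric
#'   (sensitive, resistant) summing to 1 (or to 100).
#' @param total_n0 total seeded cells.
#' @param config a [sim_config()].
#' @param condition condition label.
#' @return Tidy trajectory `data.frame` as in [gen_monoculture()].
#' @export
gen_coculture <- function(model, seeding_ratio, total_n0 = 2.5e5, config,
                          condition = "low_resource") {
  stopifnot(inherits(model, "competition_model"),
            inherits(config, "sim_config"))
  frac <- parse_seeding_ratio(seeding_ratio)
  tt <- config$sampling_times
  mean_traj <- simulate_competition(model, frac[["sensitive"]] * total_n0,
                                    frac[["resistant"]] * total_n0, tt)
  sub <- derive_subseeds(config$seed, 1L)
  reps <- with_seed(sub, {
    do.call(rbind, lapply(seq_len(config$n_replicates), function(rep) {
      d <- mean_traj
      d$count <- d$count * lognormal_noise(nrow(d), config$noise_cv)
      d$replicate <- rep
      d
    }))
  })
  reps$condition <- condition
  reps$seeding_ratio <- ratio_label(frac)
  new_trajectory(reps, list(true_model = model, seeding = frac,
                            total_n0 = total_n0, subseed = sub,
                            config = config))
}

#' Drug-effect parameters
#'
#' Emax dose response with a gamma-shaped delay kernel: the instantaneous
#' kill rate applied to sensitive cells a time `tau` after a dose `D` is
#' \deqn{k(D, \tau) = k_{max} \frac{D}{D + EC_{50}} \; K(\tau)}
#' where `K` is a gamma density (shape `lag_shape`, mean shrinking with
#' dose, see below) normalised to peak at 1 and truncated at
#' `effect_duration`. The resistant population receives the same rate
#' multiplied by `resistance_factor`. The effective delay mean is
#' `lag_mean * (1 - lag_dose_shift * D/(D + EC50))`, so the effect peaks
#' earlier at higher dose.
#'
#' @param kill_max maximal kill rate, per day.
#' @param ec50 dose of half-maximal effect (umol/L in vitro, mg/kg in vivo).
#' @param lag_mean mean of the delay kernel at vanishing dose, days.
#' @param lag_shape gamma shape of the delay kernel (> 1).
#' @param effect_duration days after which a dose no longer acts.
#' @param resistance_factor multiplier in `[0, 1]` applied to the kill rate
#'   of resistant cells.
#' @param lag_dose_shift fraction by which the delay mean contracts at
#'   saturating dose, in `[0, 1)`.
#' @return A `drug_params` object.
#' @export
drug_params <- function(kill_max = 1.2, ec50 = 0.2, lag_mean = 7,
                        lag_shape = 6, effect_duration = 13,
                        resistance_factor = 0.1, lag_dose_shift = 0.5) {
  if (kill_max < 0) stop("`kill_max` must be >= 0")
  if (ec50 <= 0) stop("`ec50` must be > 0")
  if (lag_shape <= 1) stop("`lag_shape` must be > 1")
  if (resistance_factor < 0 || resistance_factor > 1) {
    stop("`resistance_factor` must be in [0, 1]")
  }
  if (lag_dose_shift < 0 || lag_dose_shift >= 1) {
    stop("`lag_dose_shift` must be in [0, 1)")
  }
  structure(list(kill_max = kill_max, ec50 = ec50, lag_mean = lag_mean,
                 lag_shape = lag_shape, effect_duration = effect_duration,
                 resistance_factor = resistance_factor,
                 lag_dose_shift = lag_dose_shift),
            class = "drug_params")
}

#' In-vivo carboplatin preset of [drug_params()]
#'
#' Same kernel as the in-vitro preset but on the mg/kg scale with a shorter
#' delay, sized so a 60 mg/kg dose clearly overcomes tumor growth.
#' @export
drug_params_invivo <- function() {
  drug_params(kill_max = 0.35, ec50 = 15, lag_mean = 4, lag_shape = 3,
              effect_duration = 14, resistance_factor = 0.1,
              lag_dose_shift = 0.3)
}

#' Generate single drug-pulse coculture experiments
#'
#' Emulates the dose-titration design: 50:50 cocultures grown in
#' low-resource conditions, a single drug dose administered on a fixed day,
#' and counts of both populations harvested over time. One trajectory per
#' dose; dose 0 is the untreated control.
#'
#' @param model a [competition_model].
#' @param drug a [drug_params()].
#' @param dose_series numeric vector of doses (>= 0), e.g.
#'   `c(0, 0.1, 0.5, 1)` umol/L.
#' @param config a [sim_config()]; `sampling_times` must cover `pulse_day`.
#' @param pulse_day day the dose is administered (default 6).
#' @param seeding_ratio seeding composition (default 50:50).
#' @param total_n0 total seeded cells.
#' @return A `data.frame` stacking one trajectory per dose; `condition`
#'   holds `dose=<d>`; attribute `ground_truth` carries the inputs.
#' @export
gen_drug_pulse <- function(model, drug, dose_series, config,
                           pulse_day = 6, seeding_ratio = "50:50",
                           total_n0 = 2.5e5) {
  stopifnot(inherits(model, "competition_model"),
            inherits(drug, "drug_params"),
            inherits(config, "sim_config"))
  if (any(dose_series < 0)) stop("doses must be >= 0")
  tt <- config$sampling_times
  if (pulse_day < min(tt) || pulse_day > max(tt)) {
    stop("`pulse_day` must lie within the sampling window")
  }
  frac <- parse_seeding_ratio(seeding_ratio)
  subs <- derive_subseeds(config$seed, length(dose_series))
  out <- vector("list", length(dose_series))
  for (i in seq_along(dose_series)) {
    dose <- dose_series[i]
    ks <- function(t) kill_rate_at(dose, t - pulse_day, drug)
    kr <- function(t) drug$resistance_factor *
      kill_rate_at(dose, t - pulse_day, drug)
    mean_traj <- simulate_competition(model,
                                      frac[["sensitive"]] * total_n0,
                                      frac[["resistant"]] * total_n0,
                                      tt, kill_s = ks, kill_r = kr)
    reps <- with_seed(subs[i], {
      do.call(rbind, lapply(seq_len(config$n_replicates), function(rep) {
        d <- mean_traj
        d$count <- d$count * lognormal_noise(nrow(d), config$noise_cv)
        d$replicate <- rep
        d
      }))
    })
    reps$condition <- sprintf("dose=%g", dose)
    reps$seeding_ratio <- ratio_label(frac)
    out[[i]] <- reps
  }
  df <- do.call(rbind, out)
  new_trajectory(df, list(true_model = model, drug = drug,
                          dose_series = dose_series, pulse_day = pulse_day,
                          seeding = frac, total_n0 = total_n0,
                          subseeds = subs, config = config))
}

#' Generate an untreated two-flank mouse cohort
#'
#' Each mouse carries two flank tumors seeded from the same injected S:R
#' mixture, with independent lognormal initial-size jitter per flank and a
#' lognormal growth-rate multiplier per mouse. Untreated growth follows the
#' competition model mapped to volume through `cells_per_mm3`; the
#' enrollment day is the first day the larger (target) tumor reaches the
#' enrollment volume, or `NA` if never reached within the horizon
#' (censored at enrollment).
#'
#' @param ratio_mix injected sensitive:resistant mixture (`"80:20"` style).
#' @param n_mice number of mice (>= 1).
#' @param model in-vivo [competition_model] (cell-count scale).
#' @param config a [sim_config()]; its seed drives all jitter.
#' @param n0_volume_mm3 mean initial tumor volume per flank, mm3.
#' @param jitter_cv CV of the lognormal initial-size jitter (default 0.3).
#' @param rate_cv CV of the lognormal per-mouse growth-rate multiplier.
#' @param enroll_volume enrollment threshold for the target tumor, mm3.
#' @param horizon_days days to follow untreated growth for enrollment.
#' @param cells_per_mm3 volume conversion constant (cells per mm3).
#' @return A list of `course_init` objects (one per mouse) with fields
#'   `mouse_id`, `flanks` (2 x 2 matrix of initial S/R cells), `rate_mult`,
#'   `target_flank`, `enroll_day`; the list carries a `ground_truth`
#'   attribute.
#' @export
gen_mouse_cohort <- function(ratio_mix, n_mice, model, config,
                             n0_volume_mm3 = 50, jitter_cv = 0.3,
                             rate_cv = 0.2, enroll_volume = 300,
                             horizon_days = 120, cells_per_mm3 = 1e4) {
  stopifnot(inherits(model, "competition_model"),
            inherits(config, "sim_config"))
  if (n_mice < 1L) stop("`n_mice` must be >= 1")
  frac <- parse_seeding_ratio(ratio_mix)
  sub <- derive_subseeds(config$seed, 1L)
  cohort <- with_seed(sub, {
    lapply(seq_len(n_mice), function(i) {
      jit <- lognormal_noise(2L, jitter_cv)
      rate_mult <- lognormal_noise(1L, rate_cv)
      n0_cells <- n0_volume_mm3 * cells_per_mm3 * jit
      flanks <- rbind(flank1 = n0_cells[1] * frac,
                      flank2 = n0_cells[2] * frac)
      colnames(flanks) <- c("S", "R")
      list(mouse_id = i, flanks = flanks, rate_mult = rate_mult)
    })
  })
  # Untreated growth determines the enrollment day of the target (larger)
  # flank; integrate once per mouse on a daily grid.
  tt <- seq(0, horizon_days, by = 1)
  cohort <- lapply(cohort, function(m) {
    scaled <- scale_model_rates(model, m$rate_mult)
    vols <- vapply(1:2, function(f) {
      tr <- simulate_competition(scaled, m$flanks[f, "S"], m$flanks[f, "R"], tt)
      totals <- tapply(tr$count, tr$time_days, sum)
      as.numeric(totals) / cells_per_mm3
    }, numeric(length(tt)))
    m$target_flank <- which.max(vols[length(tt), ])
    hit <- which(vols[, m$target_flank] >= enroll_volume)
    m$enroll_day <- if (length(hit)) tt[hit[1]] else NA_real_
    m$volumes_at_enroll <- if (length(hit)) vols[hit[1], ] else vols[length(tt), ]
    # cell-level state at enrollment, for the therapy engine
    day0 <- if (length(hit)) tt[hit[1]] else horizon_days
    m$state_at_enroll <- vapply(1:2, function(f) {
      tr <- simulate_competition(scaled, m$flanks[f, "S"], m$flanks[f, "R"],
                                 c(0, max(day0, 1e-3)))
      c(S = tr$count[tr$population == "sensitive"][2],
        R = tr$count[tr$population == "resistant"][2])
    }, numeric(2))
    m
  })
  attr(cohort, "ground_truth") <- list(true_model = model, ratio = frac,
                                       subseed = sub, config = config,
                                       cells_per_mm3 = cells_per_mm3,
                                       enroll_volume = enroll_volume)
  cohort
}

scale_model_rates <- function(model, mult) {
  ps <- model$params_s; pr <- model$params_r
  ps$growth_rate <- ps$growth_rate * mult
  pr$growth_rate <- pr$growth_rate * mult
  competition_model(ps, pr, model$alpha_sr, model$alpha_rs)
}

#' Generate a longitudinal segment-level copy-number series
#'
#' Emulates shallow-WGS segment profiles of a tumor in which a resistant
#' subclone with private integer copy-number alterations expands over time.
#' Baseline clonal copy numbers are drawn from an HGSC-like distribution
#' over 1..6; resistant segments receive nonzero integer deltas in
#' \{-2, -1, 1, 2\}. The observed segment mean at sample `t` is
#' \deqn{\rho_t[(1-r_t)c_0 + r_t(c_0+\Delta)] + 2(1-\rho_t) + \epsilon}
#' with Gaussian segment noise. A configurable fraction of non-resistant
#' segments receives non-monotone "other CNA" perturbations (decoys) that a
#' correct caller must reject.
#'
#' @param n_segments total number of segments (> n_resistant_segments).
#' @param n_resistant_segments segments carrying resistance-specific CNAs.
#' @param ratio_trajectory true subclonal ratio per sample, in `[0, 1]`;
#'   the first sample is the baseline (typically 0).
#' @param purities tumor purity per sample, in `(0, 1]`.
#' @param config a [sim_config()] (`cn_noise_sd` used).
#' @param sample_days day of each sample (defaults to 0, 90, 180, ...).
#' @param decoy_fraction fraction of non-resistant segments given
#'   non-monotone perturbations.
#' @param marker_coef scale tying the marker series (CA125-like, kIU/L) to
#'   subclone expansion rate when generating `marker_value`.
#' @return A list of class `cn_series`: `segments` (BED-like `data.frame`
#'   with `chromosome`, `start`, `end`, `copy_number`, `sample_id`),
#'   `manifest` (`sample_id`, `day`, `purity`, `marker_value`), plus a
#'   `ground_truth` attribute with true deltas, ratios and decoy ids.
#' @export
gen_cn_series <- function(n_segments = 500, n_resistant_segments = 20,
                          ratio_trajectory, purities, config,
                          sample_days = NULL, decoy_fraction = 0.05,
                          marker_coef = 1e4) {
  stopifnot(inherits(config, "sim_config"))
  if (n_resistant_segments <= 0 || n_resistant_segments >= n_segments) {
    stop("need 0 < n_resistant_segments < n_segments")
  }
  if (any(ratio_trajectory < 0 | ratio_trajectory > 1)) {
    stop("subclonal ratios must be in [0, 1]")
  }
  n_samp <- length(ratio_trajectory)
  if (length(purities) != n_samp) {
    stop("`purities` must match `ratio_trajectory` in length")
  }
  if (any(purities <= 0 | purities > 1)) stop("purities must be in (0, 1]")
  if (is.null(sample_days)) sample_days <- 90 * (seq_len(n_samp) - 1)
  if (is.unsorted(sample_days, strictly = TRUE)) {
    stop("`sample_days` must be strictly increasing")
  }

  subs <- derive_subseeds(config$seed, 3L)
  sub <- subs[1]
  gt <- with_seed(sub, {
    # HGSC-like clonal copy-number distribution over 1..6
    c0 <- sample(1:6, n_segments, replace = TRUE,
                 prob = c(0.08, 0.40, 0.28, 0.14, 0.06, 0.04))
    res_idx <- sort(sample.int(n_segments, n_resistant_segments))
    delta <- integer(n_segments)
    for (i in res_idx) {
      choices <- setdiff(c(-2L, -1L, 1L, 2L), seq(-10L, -c0[i]))
      delta[i] <- sample(choices, 1L)
    }
    pool <- setdiff(seq_len(n_segments), res_idx)
    n_decoy <- round(decoy_fraction * length(pool))
    decoy_idx <- if (n_decoy > 0) sort(sample(pool, n_decoy)) else integer(0)
    # decoy bump: transient shift in one interior sample, back to baseline
    decoy_amp <- if (n_decoy > 0) {
      stats::runif(n_decoy, 0.3, 0.8) * sample(c(-1, 1), n_decoy, TRUE)
    } else numeric(0)
    decoy_sample <- if (n_decoy > 0 && n_samp > 2) {
      sample(2:(n_samp - 1), n_decoy, replace = TRUE)
    } else rep(min(2L, n_samp), n_decoy)
    list(c0 = c0, res_idx = res_idx, delta = delta, decoy_idx = decoy_idx,
         decoy_amp = decoy_amp, decoy_sample = decoy_sample)
  })

  seg_len <- 3e6
  coords <- data.frame(
    chromosome = paste0("chr", rep(1:22, length.out = n_segments)),
    start = seg_len * (seq_len(n_segments) - 1),
    end = seg_len * seq_len(n_segments))

  sample_ids <- sprintf("S%02d", seq_len(n_samp))
  noise <- with_seed(subs[2],
                     matrix(stats::rnorm(n_segments * n_samp, 0,
                                         config$cn_noise_sd),
                            n_segments, n_samp))
  seg_list <- lapply(seq_len(n_samp), function(t) {
    r <- ratio_trajectory[t]; rho <- purities[t]
    tumor_cn <- (1 - r) * gt$c0 + r * (gt$c0 + gt$delta)
    if (length(gt$decoy_idx) && n_samp > 1) {
      bump <- ifelse(gt$decoy_sample == t, gt$decoy_amp, 0)
      tumor_cn[gt$decoy_idx] <- tumor_cn[gt$decoy_idx] + bump
    }
    obs <- rho * tumor_cn + 2 * (1 - rho) + noise[, t]
    data.frame(coords, copy_number = obs, sample_id = sample_ids[t],
               stringsAsFactors = FALSE)
  })
  segments <- do.call(rbind, seg_list)

  # marker loosely tracks subclone expansion rate (kIU/L scale)
  rate <- c(0, diff(ratio_trajectory) / diff(sample_days))
  marker <- with_seed(subs[3],
                      pmax(5, 35 + marker_coef * rate *
                             lognormal_noise(n_samp, 0.1)))
  manifest <- data.frame(sample_id = sample_ids, day = sample_days,
                         purity = purities, marker_value = marker,
                         stringsAsFactors = FALSE)
  out <- list(segments = segments, manifest = manifest)
  class(out) <- "cn_series"
  attr(out, "ground_truth") <- list(
    true_subclone_ratios = ratio_trajectory, purities = purities,
    baseline_cn = gt$c0, true_deltas = gt$delta,
    true_resistant_segments = gt$res_idx, decoy_segments = gt$decoy_idx,
    subseed = sub, config = config)
  out
}

#' @export
print.cn_series <- function(x, ...) {
  gt <- ground_truth(x)
  cat(sprintf("Longitudinal copy-number series: %d samples x %d segments\n",
              nrow(x$manifest), nrow(x$segments) / nrow(x$manifest)))
  cat(sprintf("  true subclonal ratios: %s\n",
              paste(signif(gt$true_subclone_ratios, 3), collapse = ", ")))
  cat(sprintf("  resistant segments: %d; decoys: %d\n",
              length(gt$true_resistant_segments), length(gt$decoy_segments)))
  invisible(x)
}
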