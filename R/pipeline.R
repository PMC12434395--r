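#' Default pipeline configuration
#'
#' Returns the full default configuration of [run_pipeline()] as a nested
#' list: a `seed`, the stage list, and one parameter block per stage.
#' The defaults describe the synthetic demo study: low-resource coculture
#' growth with a fitness cost of 0.08 doublings/day, a three-arm
#' (vehicle/ST/AT) mouse trial on 80:20 and pure cohorts, and a
#' five-sample longitudinal copy-number series with an expanding resistant
#' subclone.
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = c("growth", "fitness", "trial", "subclone", "correlate"),
    growth = list(
      gs = 0.50, gr = 0.42, Ks = 1e6, Kr = 8e5, alpha = 1.0,
      n0 = 1e4, noise_cv = 0.05, n_replicates = 3L,
      sampling_days = as.numeric(0:20),
      seeding_ratios = c("15:85", "50:50", "85:15"),
      reference_ratio = "15:85",
      ratio_fit_max_day = 12),
    trial = list(
      cohorts = c("100:0", "80:20", "0:100"),
      n_per_arm = 4L,
      gs = 0.08, gr = 0.06, K = 3e7, alpha = 1.0),
    subclone = list(
      n_segments = 120L, n_resistant_segments = 20L,
      ratios = c(0, 0.1, 0.25, 0.45, 0.6),
      purities = c(0.7, 0.6, 0.65, 0.55, 0.6),
      cn_noise_sd = 0.05, n_boot = 150L, subsample_fraction = 0.75),
    correlate = list(n_patients = 5L))
}

merge_config <- function(user, defaults, where = "config") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown %s key(s): %s", where,
                 paste(unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      merge_config(user[[k]], defaults[[k]], paste0(where, "$", k))
    } else user[[k]]
  }
  defaults
}

#' Run the end-to-end synthetic pipeline
#'
#' Orchestrates simulate -> fit -> estimate -> report over the requested
#' stages in dependency order, writing every artifact (tidy TSVs, JSON fit
#' reports, the resolved configuration) under `out_dir`. All randomness
#' flows from the configured seed, so two runs of the same configuration
#' produce byte-identical numeric outputs. Stages: `growth` (monoculture
#' and coculture simulation + logistic fits + competition deviation),
#' `fitness` (ratio series, reference slope, alignment and pooling;
#' requires `growth`), `trial` (three-arm in-silico mouse trial),
#' `subclone` (copy-number series simulation + mixture estimation +
#' bootstrap CI), `correlate` (subclone growth vs burden marker across
#' simulated patients; requires `subclone`).
#'
#' @param config configuration list (see [default_pipeline_config()]) or
#'   path to a YAML file with the same structure; unknown keys are
#'   rejected.
#' @param out_dir output directory (created if needed).
#' @return A run report (list of produced artifacts and key results),
#'   invisibly classed `pipeline_report`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("costar_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config, default_pipeline_config())
  stages <- cfg$stages
  known <- c("growth", "fitness", "trial", "subclone", "correlate")
  if (length(setdiff(stages, known))) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  if ("fitness" %in% stages && !"growth" %in% stages) {
    stop("stage 'fitness' requires stage 'growth' (missing upstream stage)")
  }
  if ("correlate" %in% stages && !"subclone" %in% stages) {
    stop("stage 'correlate' requires stage 'subclone' (missing upstream stage)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out_dir, "resolved-config.yaml"))
  report <- list(out_dir = out_dir, seed = cfg$seed, artifacts = character(0),
                 warnings = character(0))
  seeds <- derive_subseeds(cfg$seed, 64L)
  art <- function(p) report$artifacts <<- c(report$artifacts, p)

  cocultures <- NULL
  fits <- NULL
  if ("growth" %in% stages) {
    g <- cfg$growth
    message("stage growth: simulating monocultures and cocultures")
    ps <- population_params(g$gs, g$Ks, "sensitive")
    pr <- population_params(g$gr, g$Kr, "resistant")
    model <- competition_model(ps, pr, alpha_sr = g$alpha,
                               alpha_rs = g$alpha)
    base_cfg <- sim_config(seed = seeds[1], n_replicates = g$n_replicates,
                           noise_cv = g$noise_cv,
                           sampling_times = g$sampling_days)
    mono_s <- gen_monoculture(ps, g$n0, base_cfg)
    cfg2 <- base_cfg; cfg2$seed <- seeds[2]
    mono_r <- gen_monoculture(pr, g$n0, cfg2)
    write_trajectory(rbind(mono_s, mono_r),
                     file.path(out_dir, "monocultures.tsv"))
    art("monocultures.tsv")
    fit_s <- fit_monoculture(mono_s)
    fit_r <- fit_monoculture(mono_r)
    fits <- list(sensitive = fit_s, resistant = fit_r)
    write_fit_json(list(
      sensitive = fit_s[c("coefficients", "se", "convergence", "flags")],
      resistant = fit_r[c("coefficients", "se", "convergence", "flags")]),
      file.path(out_dir, "monoculture-fits.json"))
    art("monoculture-fits.json")

    cocultures <- list()
    for (i in seq_along(g$seeding_ratios)) {
      ccfg <- base_cfg; ccfg$seed <- seeds[2L + i]
      cocultures[[g$seeding_ratios[i]]] <-
        gen_coculture(model, g$seeding_ratios[i], g$n0, ccfg)
    }
    write_trajectory(do.call(rbind, cocultures),
                     file.path(out_dir, "cocultures.tsv"))
    art("cocultures.tsv")

    # competition deviation of the first coculture from the
    # independent-growth null predicted from the monoculture fits
    frac <- parse_seeding_ratio(g$seeding_ratios[1])
    pred <- predict_coculture(fit_s, fit_r, frac[1] * g$n0, frac[2] * g$n0,
                              g$sampling_days)
    dev <- competition_deviation(cocultures[[1]], pred, seed = seeds[10])
    write_fit_json(dev, file.path(out_dir, "competition-deviation.json"))
    art("competition-deviation.json")
    report$growth <- list(fit_sensitive = coef(fit_s),
                          fit_resistant = coef(fit_r), deviation = dev)
  }

  if ("fitness" %in% stages) {
    g <- cfg$growth
    message("stage fitness: fitting the fitness gap g = gs - gr")
    # the log-ratio slope equals gs - gr only in the exponential phase;
    # restrict the fit window to the pre-saturation days
    clip_window <- function(tr) tr[tr$time_days <= g$ratio_fit_max_day, ]
    ref <- ratio_series(clip_window(cocultures[[g$reference_ratio]]))
    others <- lapply(setdiff(names(cocultures), g$reference_ratio),
                     function(k) ratio_series(clip_window(cocultures[[k]])))
    ref_fit <- fit_reference_slope(ref, seed = seeds[11])
    pooled <- align_and_pool(ref_fit, others, seed = seeds[12])
    aligned <- pooled$data
    write_trajectory(aligned, file.path(out_dir, "aligned-ratio-series.tsv"))
    art("aligned-ratio-series.tsv")
    write_fit_json(list(g = pooled$g, intercept = pooled$intercept,
                        stderr_g = pooled$stderr_g, boot_se = pooled$boot_se,
                        r_squared = pooled$r_squared,
                        offsets = as.list(pooled$offsets),
                        reference_g = ref_fit$g,
                        true_g = g$gs - g$gr),
                   file.path(out_dir, "fitness-fit.json"))
    art("fitness-fit.json")
    report$fitness <- list(g = pooled$g, reference_g = ref_fit$g,
                           true_g = g$gs - g$gr)
  }

  if ("trial" %in% stages) {
    tr <- cfg$trial
    message("stage trial: running the in-silico adaptive-therapy trial")
    ps <- population_params(tr$gs, tr$K, "sensitive")
    pr <- population_params(tr$gr, tr$K, "resistant")
    model <- competition_model(ps, pr, alpha_sr = tr$alpha,
                               alpha_rs = tr$alpha)
    tcfg <- sim_config(seed = seeds[13], sampling_times = c(0, 1))
    trial <- run_trial(cohort_ratios = tr$cohorts, n_per_arm = tr$n_per_arm,
                       model = model, drug = drug_params_invivo(),
                       config = tcfg)
    utils::write.table(trial$subjects, file.path(out_dir, "trial-subjects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    art("trial-subjects.tsv")
    write_fit_json(list(medians = trial$medians, logrank = trial$logrank),
                   file.path(out_dir, "trial-summary.json"))
    art("trial-summary.json")
    report$trial <- trial
  }

  sub_fits <- NULL
  if ("subclone" %in% stages) {
    sb <- cfg$subclone
    message("stage subclone: simulating and deconvolving copy-number series")
    scfg <- sim_config(seed = seeds[14], cn_noise_sd = sb$cn_noise_sd,
                       sampling_times = c(0, 1))
    series <- gen_cn_series(sb$n_segments, sb$n_resistant_segments,
                            sb$ratios, sb$purities, scfg)
    write_cn_series(series, file.path(out_dir, "cn-segments.tsv"),
                    file.path(out_dir, "cn-manifest.tsv"))
    art("cn-segments.tsv"); art("cn-manifest.tsv")
    segs <- call_resistance_segments(series)
    fit <- estimate_subclone_ratio(series, segs)
    fit <- bootstrap_ci(fit, n_boot = sb$n_boot,
                        subsample_fraction = sb$subsample_fraction,
                        seed = seeds[15])
    write_fit_json(list(ratios = fit$ratios,
                        deltas = as.list(fit$deltas),
                        warnings = fit$warnings,
                        true_ratios = ground_truth(series)$true_subclone_ratios),
                   file.path(out_dir, "subclone-estimates.json"))
    art("subclone-estimates.json")
    report$subclone <- fit
    sub_fits <- list(fit)
  }

  if ("correlate" %in% stages) {
    sb <- cfg$subclone
    message("stage correlate: subclone growth rate vs burden marker")
    n_pat <- cfg$correlate$n_patients
    rates <- numeric(0); markers <- numeric(0)
    for (p in seq_len(n_pat)) {
      scfg <- sim_config(seed = seeds[20L + p],
                         cn_noise_sd = sb$cn_noise_sd,
                         sampling_times = c(0, 1))
      rr <- with_seed(seeds[40L + p],
                      cumsum(c(0, stats::runif(3, 0, 0.3))))
      rr <- pmin(rr, 1)
      series <- gen_cn_series(sb$n_segments, sb$n_resistant_segments, rr,
                              rep(0.6, length(rr)), scfg)
      fit <- estimate_subclone_ratio(series)
      gr <- subclone_growth_rate(fit)
      man <- series$manifest
      rates <- c(rates, gr$rate_per_day)
      markers <- c(markers, man$marker_value[match(gr$to, man$sample_id)])
    }
    corr <- correlate_burden(rates, markers)
    write_fit_json(unclass(corr), file.path(out_dir, "burden-correlation.json"))
    art("burden-correlation.json")
    report$correlation <- corr
  }

  class(report) <- "pipeline_report"
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ")\n")
  cat("Artifacts in", x$out_dir, ":\n")
  for (a in x$artifacts) cat("  -", a, "\n")
  if (!is.null(x$fitness)) {
    cat(sprintf("Fitness gap: g = %.4f (true %.4f)\n", x$fitness$g,
                x$fitness$true_g))
  }
  if (!is.null(x$correlation)) print(x$correlation)
  invisible(x)
}
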