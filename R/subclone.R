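#' Purity-correct a segment copy-number profile
#'
#' Removes the diploid-normal contamination: with tumor purity `rho`, the
#' observed segment mean is `rho * CN_tumor + 2 * (1 - rho)`, so the
#' tumor-intrinsic copy number is `(CN_obs - 2 * (1 - rho)) / rho`.
#' Negative corrected values are clipped to 0 with a warning.
#'
#' @param copy_number observed segment mean copy numbers.
#' @param purity tumor purity `rho` in `(0, 1]`.
#' @return Tumor-intrinsic copy numbers.
#' @examples
#' purity_correct(3, 0.5)  # 4
#' @export
purity_correct <- function(copy_number, purity) {
  if (length(purity) != 1L || purity <= 0 || purity > 1) {
    stop("`purity` must be a single value in (0, 1]")
  }
  cn <- (copy_number - 2 * (1 - purity)) / purity
  if (any(cn < 0)) {
    warning(sprintf("%d purity-corrected value(s) < 0 clipped to 0",
                    sum(cn < 0)))
    cn[cn < 0] <- 0
  }
  cn
}

# Purity-corrected segment-by-sample matrix from a cn_series-style object
# (list with $segments and $manifest); samples ordered by day, the first
# being the baseline. Assumes harmonised segmentation (validated).
corrected_matrix <- function(series) {
  man <- series$manifest[order(series$manifest$day), ]
  segs <- series$segments
  base <- segs[segs$sample_id == man$sample_id[1],
               c("chromosome", "start", "end")]
  key <- function(d) paste(d$chromosome, d$start, d$end)
  mat <- vapply(seq_len(nrow(man)), function(i) {
    d <- segs[segs$sample_id == man$sample_id[i], ]
    if (nrow(d) != nrow(base) || !all(key(d) == key(base))) {
      stop("segmentation is not harmonised across samples")
    }
    suppressWarnings(purity_correct(d$copy_number, man$purity[i]))
  }, numeric(nrow(base)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(base))
  colnames(mat) <- man$sample_id
  list(mat = mat, manifest = man, coords = base)
}

#' Call resistance-specific copy-number segments
#'
#' Selects segments whose purity-corrected shift from the baseline
#' (earliest) sample exceeds `shift_threshold` in the final sample *and*
#' changes monotonically (within `monotone_tolerance`) across the ordered
#' samples. Clonally shared segments (no shift) and "other CNA" segments
#' (non-monotone transient shifts) are excluded: only alterations whose
#' magnitude grows with the expanding subclone qualify as
#' resistance-specific.
#'
#' @param series a [gen_cn_series()]-shaped object (list with `segments`
#'   and `manifest`) with at least two samples.
#' @param shift_threshold minimum absolute final shift, CN units. The
#'   working threshold is noise-adaptive: the larger of this floor and 3x
#'   the robust noise scale (MAD about 0) of the final shifts, most of
#'   which are unshifted null segments.
#' @param monotone_tolerance maximum allowed backward step between
#'   consecutive samples, CN units; likewise floored, with 2x the robust
#'   step-noise scale as the working value.
#' @return Integer vector of selected segment indices (rows of the
#'   baseline profile), with the shift matrix in attribute `shifts` and
#'   the working thresholds in attribute `thresholds`.
#' @export
call_resistance_segments <- function(series, shift_threshold = 0.1,
                                     monotone_tolerance = 0.05) {
  cm <- corrected_matrix(series)
  if (ncol(cm$mat) < 2L) stop("need at least one sample after the baseline")
  shifts <- cm$mat[, -1, drop = FALSE] - cm$mat[, 1]
  final <- shifts[, ncol(shifts)]
  sigma <- stats::mad(final, center = 0)
  thr <- max(shift_threshold, 3 * sigma)
  sel <- abs(final) > thr
  tol <- monotone_tolerance
  if (ncol(shifts) > 1L) {
    # monotone toward the final shift: each consecutive step in the
    # direction of the final shift, allowing backward steps up to that
    # step's own robust noise scale (null segments dominate each column)
    steps <- cbind(shifts[, 1], shifts[, -1, drop = FALSE] -
                     shifts[, -ncol(shifts), drop = FALSE])
    step_sigma <- apply(steps, 2, stats::mad, center = 0)
    tol <- pmax(monotone_tolerance, 2 * step_sigma)
    dir <- sign(final)
    mono <- rowSums(sweep(steps * dir, 2, -tol, `<=`)) == 0
    sel <- sel & mono
  }
  structure(which(sel), shifts = shifts,
            thresholds = list(shift = thr, monotone = tol))
}

#' Estimate the subclonal ratio trajectory from called segments
#'
#' Linear-mixture deconvolution: the purity-corrected shift of a
#' resistance-specific segment from baseline satisfies
#' `shift[t, seg] = r_t * delta_seg` with `delta_seg` a nonzero integer
#' copy-number alteration private to the subclone and `r_t` its frequency
#' at sample `t`. Estimation alternates least squares: given `r`,
#' `delta_seg = round(sum_t r_t shift / sum_t r_t^2)` forced nonzero;
#' given `delta`, `r_t = sum_seg delta shift / sum_seg delta^2` clipped to
#' `[0, 1]`; iterated to a fixed point from several initialisations (sign
#' of the final shift, plus integer scalings of the final-shift vector),
#' keeping the solution with the lowest residual sum of squares. The
#' scale degeneracy (doubling `delta`, halving `r`) is resolved by
#' parsimony: the reported solution has minimal `sum(|delta|)` (gcd
#' reduction). A reliability warning is attached when the patient has only
#' two samples (one shift), where subclonal expansion cannot be separated
#' from pervasive copy-number instability.
#'
#' @param series a [gen_cn_series()]-shaped object.
#' @param segments segment indices from [call_resistance_segments()]; if
#'   missing they are called with default thresholds.
#' @param max_iter alternation cap per start.
#' @param refine after the initial fit, re-admit segments anywhere in the
#'   genome whose whole-series shifts are consistent with an integer
#'   multiple of the fitted ratio trajectory, and refit once. This
#'   recovers low-amplitude (|delta| = 1) resistance segments that the
#'   final-shift threshold misses at low purity.
#' @return A `subclone_fit`: `ratios` (`data.frame` with `sample_id`,
#'   `day`, `ratio`, baseline row at 0), `deltas` (named integer vector),
#'   `sse`, `converged`, `warnings`.
#' @export
estimate_subclone_ratio <- function(series, segments = NULL,
                                    max_iter = 100L, refine = TRUE) {
  cm <- corrected_matrix(series)
  if (is.null(segments)) segments <- call_resistance_segments(series)
  if (length(segments) == 0L) stop("empty resistance-specific segment set")
  shifts <- (cm$mat[, -1, drop = FALSE] - cm$mat[, 1])[segments, ,
                                                       drop = FALSE]
  warn <- character(0)
  if (ncol(cm$mat) < 3L) {
    warn <- c(warn, paste("only two samples: subclonal expansion cannot be",
                          "distinguished from ongoing copy-number",
                          "instability; the ratio may be overestimated"))
  }
  als <- als_mixture(t(shifts), max_iter = max_iter)  # samples x segments
  if (all(abs(shifts) < 1e-12)) {
    warn <- c(warn, "no emergent subclone: all shifts are zero")
  } else if (refine && sum(als$r^2) > 1e-12) {
    shifts_all <- cm$mat[, -1, drop = FALSE] - cm$mat[, 1]
    sig <- pmax(apply(shifts_all, 2, stats::mad, center = 0), 1e-8)
    r <- als$r
    dhat <- round(as.vector(shifts_all %*% r) / sum(r^2))
    dhat <- pmax(pmin(dhat, 3L), -3L)
    resid <- abs(shifts_all - outer(dhat, r))
    fit_ok <- rowSums(sweep(resid, 2, 3 * sig, `>`)) == 0
    evid <- abs(shifts_all[, ncol(shifts_all)]) >=
      pmax(0.1, 2 * sig[length(sig)])
    segments2 <- which(dhat != 0 & fit_ok & evid)
    if (length(segments2) >= 2L) {
      segments <- segments2
      shifts <- shifts_all[segments, , drop = FALSE]
      als <- als_mixture(t(shifts), max_iter = max_iter,
                         delta_init = dhat[segments])
    }
  }
  ratios <- data.frame(
    sample_id = cm$manifest$sample_id,
    day = cm$manifest$day,
    ratio = c(0, als$r))
  structure(list(ratios = ratios, deltas = stats::setNames(als$delta,
                                                           segments),
                 segments = segments, sse = als$sse,
                 converged = als$converged, warnings = warn,
                 shifts = shifts, manifest = cm$manifest),
            class = "subclone_fit")
}

# Alternating least squares for shift = r %*% t(delta), shift is
# samples x segments. Deltas are nonzero integers clamped to [-max_delta,
# max_delta] (subclonal CNAs of larger magnitude are implausible).
# Multi-start; ties on SSE broken by minimal sum(|delta|). Returns r
# (length n_samples), delta (integers), sse.
als_mixture <- function(shift, max_iter = 100L, delta_init = NULL,
                        max_delta = 3L, fix_scale = FALSE) {
  nt <- nrow(shift); ns <- ncol(shift)
  final <- shift[nt, ]
  if (all(abs(shift) < 1e-12)) {
    return(list(r = rep(0, nt), delta = rep(1L, ns), sse = 0,
                converged = TRUE))
  }
  nonzero_round <- function(x, fallback) {
    d <- pmax(pmin(round(x), max_delta), -max_delta)
    zero <- d == 0
    d[zero] <- ifelse(sign(x[zero]) != 0, sign(x[zero]), fallback[zero])
    as.integer(d)
  }
  sgn <- sign(final)
  for (j in which(sgn == 0)) {
    v <- shift[, j]
    sgn[j] <- if (all(v == 0)) 1 else sign(v[which.max(abs(v))])
  }

  starts <- list()
  if (!is.null(delta_init)) starts <- c(starts, list(as.integer(delta_init)))
  if (!fix_scale) starts <- c(starts, list(as.integer(sgn)))
  # candidate scalings: treat each segment's |final shift| (divided by
  # 1..3) as the unit corresponding to |delta| = 1..3
  units <- if (fix_scale) numeric(0) else
    unique(as.vector(outer(abs(final[abs(final) > 1e-9]), 1:3, "/")))
  units <- units[units > 1e-9]
  if (length(units) > 12L) units <- sort(units)[seq(1, length(units),
                                                    length.out = 12L)]
  for (u in units) {
    starts <- c(starts, list(nonzero_round(final / u, sgn)))
  }
  starts <- unique(starts)

  cands <- list()
  for (d0 in starts) {
    delta <- d0
    r <- rep(0, nt)
    converged <- FALSE
    clipped <- FALSE
    for (it in seq_len(max_iter)) {
      r_raw <- as.vector(shift %*% delta) / sum(delta^2)
      r_new <- pmin(pmax(r_raw, 0), 1)
      denom <- sum(r_new^2)
      if (denom < 1e-18) {
        delta_new <- delta
      } else {
        raw <- as.vector(r_new %*% shift) / denom
        delta_new <- nonzero_round(raw, delta)
      }
      clipped <- any(r_raw > 1 + 1e-6)
      if (all(delta_new == delta) && max(abs(r_new - r)) < 1e-12) {
        r <- r_new; delta <- delta_new; converged <- TRUE
        break
      }
      r <- r_new; delta <- delta_new
    }
    sse <- sum((shift - r %*% t(delta))^2)
    cands[[length(cands) + 1L]] <- list(r = r, delta = delta, sse = sse,
                                        converged = converged,
                                        clipped = clipped)
  }
  # Scale selection: raw SSE minimisation is biased toward finer delta
  # scalings, whose denser integer lattice can chase noise. Among fixed
  # points whose SSE is statistically comparable to the best (within 50%),
  # prefer the most parsimonious (minimal sum |delta|), then lowest SSE.
  sses <- vapply(cands, `[[`, numeric(1), "sse")
  sumd <- vapply(cands, function(x) sum(abs(x$delta)), numeric(1))
  clip <- vapply(cands, `[[`, logical(1), "clipped")
  eligible <- which(sses <= 1.5 * min(sses) + 1e-9)
  # a candidate that rams r into the upper bound is a scale artefact;
  # ignore it whenever an unclipped candidate is also eligible
  if (any(!clip[eligible])) eligible <- eligible[!clip[eligible]]
  pick <- eligible[order(sumd[eligible], sses[eligible])][1]
  best <- cands[[pick]]
  # parsimony: gcd reduction of |delta| with the complementary r rescale
  # (skipped when the scale is pinned to a reference fit)
  g <- if (fix_scale) 1L else Reduce(gcd2, abs(best$delta))
  if (g > 1L && max(best$r) * g <= 1) {
    best$delta <- as.integer(best$delta / g)
    best$r <- best$r * g
    best$sse <- sum((shift - best$r %*% t(best$delta))^2)
  }
  best
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' @export
print.subclone_fit <- function(x, ...) {
  cat("Subclonal ratio estimate (linear-mixture, integer deltas)\n")
  r <- x$ratios
  if (!is.null(r$ci_low)) {
    for (i in seq_len(nrow(r))) {
      cat(sprintf("  %s (day %g): r = %.3f [%.3f, %.3f]\n", r$sample_id[i],
                  r$day[i], r$ratio[i], r$ci_low[i], r$ci_high[i]))
    }
  } else {
    for (i in seq_len(nrow(r))) {
      cat(sprintf("  %s (day %g): r = %.3f\n", r$sample_id[i], r$day[i],
                  r$ratio[i]))
    }
  }
  cat(sprintf("  %d segments, deltas in [%d, %d], SSE %.4g\n",
              length(x$deltas), min(x$deltas), max(x$deltas), x$sse))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
coef.subclone_fit <- function(object, ...) {
  stats::setNames(object$ratios$ratio, object$ratios$sample_id)
}

#' @export
summary.subclone_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.subclone_fit <- function(x, ...) {
  r <- x$ratios
  graphics::plot(r$day, r$ratio, type = "b", ylim = c(0, 1),
                 xlab = "day", ylab = "subclonal ratio", ...)
  if (!is.null(r$ci_low)) {
    graphics::arrows(r$day, r$ci_low, r$day, r$ci_high, angle = 90,
                     code = 3, length = 0.04)
  }
  invisible(x)
}

#' Subsampling bootstrap confidence intervals for the subclonal ratio
#'
#' Repeats the mixture estimation `n_boot` times (default 150) on random
#' segment subsamples of size `subsample_fraction` (default 75%) of the
#' called set, drawn with replacement (an m-out-of-n bootstrap: without
#' replacement the replicate spread underestimates the estimator's
#' sampling variance by roughly the complement of the subsample fraction),
#' and reports per-sample percentile confidence intervals. With fewer
#' than 4 called segments the interval is flagged unstable.
#'
#' @param fit a `subclone_fit` from [estimate_subclone_ratio()].
#' @param n_boot bootstrap replicates (default 150).
#' @param subsample_fraction fraction of segments per replicate (0.75).
#' @param conf confidence level (0.95).
#' @param seed RNG seed.
#' @return The `subclone_fit` with `ci_low`/`ci_high` columns added to
#'   `$ratios`, plus `boot_ratios` (replicate x sample matrix) and an
#'   `unstable_ci` flag.
#' @export
bootstrap_ci <- function(fit, n_boot = 150, subsample_fraction = 0.75,
                         conf = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "subclone_fit"))
  nseg <- nrow(fit$shifts)
  unstable <- nseg < 4L
  if (unstable) {
    warning("fewer than 4 called segments: bootstrap CI is unstable")
  }
  m <- max(1L, floor(subsample_fraction * nseg))
  shift_t <- t(fit$shifts)  # samples x segments
  boot <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      take <- sample.int(nseg, m, replace = TRUE)
      als_mixture(shift_t[, take, drop = FALSE],
                  delta_init = fit$deltas[take], fix_scale = TRUE)$r
    }, numeric(nrow(shift_t))))
  })
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  fit$ratios$ci_low <- c(0, ci[1, ])
  fit$ratios$ci_high <- c(0, ci[2, ])
  fit$boot_ratios <- boot
  fit$unstable_ci <- unstable
  fit$n_boot <- n_boot
  fit$subsample_fraction <- subsample_fraction
  fit
}

#' Rate of change of the subclonal ratio
#'
#' Per-interval rates `(r_t2 - r_t1)/(t2 - t1)` in fraction/day between
#' consecutive samples (default), or each later sample compared with the
#' diagnostic baseline (`method = "baseline"`).
#'
#' @param fit a `subclone_fit` (>= 2 time points).
#' @param method `"interval"` (consecutive pairs) or `"baseline"`.
#' @return `data.frame` with `from`, `to`, `day_from`, `day_to`,
#'   `rate_per_day`.
#' @export
subclone_growth_rate <- function(fit, method = c("interval", "baseline")) {
  method <- match.arg(method)
  r <- fit$ratios
  if (nrow(r) < 2L) stop("need >= 2 time points")
  if (anyDuplicated(r$day)) stop("duplicate sample days")
  idx_from <- if (method == "interval") seq_len(nrow(r) - 1L) else
    rep(1L, nrow(r) - 1L)
  idx_to <- 2:nrow(r)
  data.frame(from = r$sample_id[idx_from], to = r$sample_id[idx_to],
             day_from = r$day[idx_from], day_to = r$day[idx_to],
             rate_per_day = (r$ratio[idx_to] - r$ratio[idx_from]) /
               (r$day[idx_to] - r$day[idx_from]))
}

#' Correlate subclone growth rate with a tumor-burden marker
#'
#' Pearson correlation (R, R-squared, two-sided p) between per-interval
#' subclone rates of change and the burden-marker value (CA125-like) at
#' the later time point of each interval, pooled across patients.
#'
#' @param rates numeric vector of rates (fraction/day).
#' @param marker numeric vector of marker values at each interval's later
#'   time point (same length, >= 3 pairs).
#' @return List of class `burden_correlation`: `r`, `r_squared`, `p`, `n`.
#' @export
correlate_burden <- function(rates, marker) {
  if (length(rates) != length(marker)) stop("length mismatch")
  ok <- is.finite(rates) & is.finite(marker)
  rates <- rates[ok]; marker <- marker[ok]
  if (length(rates) < 3L) stop("need >= 3 pairs")
  if (stats::sd(rates) == 0 || stats::sd(marker) == 0) {
    stop("zero variance in rates or marker")
  }
  ct <- stats::cor.test(rates, marker, method = "pearson")
  structure(list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                 p = ct$p.value, n = length(rates)),
            class = "burden_correlation")
}

#' @export
print.burden_correlation <- function(x, ...) {
  cat(sprintf("Subclone growth vs burden marker: R = %.3f, R^2 = %.3f, P = %.3g (n = %d)\n",
              x$r, x$r_squared, x$p, x$n))
  invisible(x)
}
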