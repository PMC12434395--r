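#' Log2 sensitive:resistant ratio series from a coculture trajectory
#'
#' Computes `log2(S/R)` per time point and replicate. During exponential
#' coexistence this series is linear in time with slope `gs - gr` in
#' doublings/day, which is why base 2 is the working scale. Points where
#' either population has a zero count are dropped with a warning (set
#' `pseudocount` to add a small constant instead).
#'
#' @param traj tidy trajectory with both populations (`time_days`,
#'   `population`, `count`, optional `replicate`, `seeding_ratio`).
#' @param pseudocount added to all counts before the ratio (default 0).
#' @return `data.frame` of class `ratio_series` with `time_days`,
#'   `log2_ratio`, `replicate` and a `seeding_ratio` attribute.
#' @export
ratio_series <- function(traj, pseudocount = 0) {
  if (is.null(traj$replicate)) traj$replicate <- 1L
  s <- traj[traj$population == "sensitive", ]
  r <- traj[traj$population == "resistant", ]
  if (nrow(s) == 0L || nrow(r) == 0L) {
    stop("trajectory must contain both populations")
  }
  m <- merge(s[, c("time_days", "replicate", "count")],
             r[, c("time_days", "replicate", "count")],
             by = c("time_days", "replicate"), suffixes = c("_s", "_r"))
  m$count_s <- m$count_s + pseudocount
  m$count_r <- m$count_r + pseudocount
  bad <- m$count_s <= 0 | m$count_r <= 0
  if (any(bad)) {
    warning(sprintf("dropped %d point(s) with zero counts", sum(bad)))
    m <- m[!bad, ]
  }
  if (nrow(m) == 0L) stop("all points dropped (zero counts)")
  out <- data.frame(time_days = m$time_days,
                    log2_ratio = log2(m$count_s / m$count_r),
                    replicate = m$replicate)
  out <- out[order(out$time_days, out$replicate), ]
  rownames(out) <- NULL
  attr(out, "seeding_ratio") <- unique(traj$seeding_ratio)[1]
  class(out) <- c("ratio_series", "data.frame")
  out
}

new_fitness_fit <- function(g, intercept, stderr_g, r_squared, offsets,
                            residuals, data, n_series, boot_se = NA_real_) {
  structure(list(g = g, intercept = intercept, stderr_g = stderr_g,
                 r_squared = r_squared, offsets = offsets,
                 residuals = residuals, data = data, n_series = n_series,
                 boot_se = boot_se),
            class = "fitness_fit")
}

#' Fit the fitness gap g = gs - gr from a reference ratio series
#'
#' Ordinary least squares of `log2(S/R)` on time, replicates entering as
#' independent points. The slope is the fitness gap `g = gs - gr` in
#' doublings/day; a positive slope means sensitive cells outgrow resistant
#' ones. Conventionally fitted on the lowest sensitive seeding ratio, then
#' extended to other ratios with [align_and_pool()]. A replicate-cluster
#' bootstrap standard error is reported alongside the OLS one.
#'
#' @param series a [ratio_series()] with >= 3 time points.
#' @param n_boot replicate-cluster bootstrap resamples for `boot_se`
#'   (0 disables).
#' @param seed bootstrap seed.
#' @return A `fitness_fit` object: `g`, `intercept`, `stderr_g`,
#'   `r_squared`, per-series `offsets` (0 for the reference), residuals.
#' @export
fit_reference_slope <- function(series, n_boot = 200, seed = 1L) {
  if (length(unique(series$time_days)) < 3L) {
    stop("need >= 3 distinct time points")
  }
  if (stats::sd(series$time_days) == 0) stop("zero variance in time")
  fit <- stats::lm(log2_ratio ~ time_days, data = series)
  co <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))
  g <- unname(co[2]); b <- unname(co[1])
  se <- sm$coefficients["time_days", "Std. Error"]
  boot_se <- NA_real_
  reps <- unique(series$replicate)
  if (n_boot > 0 && length(reps) > 1L) {
    slopes <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      take <- sample(reps, length(reps), replace = TRUE)
      dd <- do.call(rbind, lapply(take, function(rr) {
        series[series$replicate == rr, , drop = FALSE]
      }))
      unname(stats::coef(stats::lm(log2_ratio ~ time_days, data = dd))[2])
    }, numeric(1)))
    boot_se <- stats::sd(slopes)
  }
  lbl <- attr(series, "seeding_ratio")
  if (is.null(lbl)) lbl <- "reference"
  dat <- series
  dat$series <- lbl
  dat$aligned_time <- dat$time_days
  offsets <- stats::setNames(0, lbl)
  new_fitness_fit(g, b, se, sm$r.squared, offsets,
                  stats::residuals(fit), dat, n_series = 1L,
                  boot_se = boot_se)
}

#' Align ratio series from other seeding ratios and refit the pooled slope
#'
#' Each non-reference series is shifted in time by the offset that places
#' its first observed point (replicate-mean at the earliest day) exactly on
#' the reference line: `offset = (first_log2_ratio - intercept)/g -
#' first_time`. All aligned points are then pooled into one OLS refit.
#' Under pure exponential growth the log-ratio slope does not depend on
#' seeding composition, so pooling across seeding ratios is valid and the
#' per-series offsets recover the staggering of the compositions.
#'
#' @param reference_fit a `fitness_fit` from [fit_reference_slope()].
#' @param other_series list of [ratio_series()] objects (other seeding
#'   ratios).
#' @param n_boot replicate-cluster bootstrap resamples for `boot_se`.
#' @param seed bootstrap seed.
#' @return A pooled `fitness_fit`; `offsets` holds the per-series time
#'   shifts (0 for the reference) and `data` the aligned points.
#' @export
align_and_pool <- function(reference_fit, other_series, n_boot = 200,
                           seed = 1L) {
  stopifnot(inherits(reference_fit, "fitness_fit"))
  if (inherits(other_series, "ratio_series")) other_series <- list(other_series)
  g <- reference_fit$g; b <- reference_fit$intercept
  intercept_only <- FALSE
  if (!is.finite(g) || g == 0) {
    warning("reference slope is zero; falling back to intercept-only alignment")
    intercept_only <- TRUE
  }
  ref_lbl <- names(reference_fit$offsets)[1]
  pooled <- reference_fit$data[, c("time_days", "log2_ratio", "replicate",
                                   "series", "aligned_time")]
  offsets <- stats::setNames(0, ref_lbl)
  for (i in seq_along(other_series)) {
    ser <- other_series[[i]]
    lbl <- attr(ser, "seeding_ratio")
    if (is.null(lbl)) lbl <- sprintf("series_%d", i)
    if (lbl %in% names(offsets)) lbl <- sprintf("%s_%d", lbl, i)
    t1 <- min(ser$time_days)
    y1 <- mean(ser$log2_ratio[ser$time_days == t1])
    off <- if (intercept_only) 0 else (y1 - b) / g - t1
    d <- data.frame(time_days = ser$time_days,
                    log2_ratio = ser$log2_ratio,
                    replicate = ser$replicate,
                    series = lbl,
                    aligned_time = ser$time_days + off)
    offsets[lbl] <- off
    pooled <- rbind(pooled, d)
  }
  fit <- stats::lm(log2_ratio ~ aligned_time, data = pooled)
  sm <- suppressWarnings(summary(fit))
  boot_se <- NA_real_
  clusters <- unique(pooled[, c("series", "replicate")])
  if (n_boot > 0 && nrow(clusters) > 1L) {
    slopes <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      take <- clusters[sample.int(nrow(clusters), nrow(clusters),
                                  replace = TRUE), , drop = FALSE]
      dd <- do.call(rbind, lapply(seq_len(nrow(take)), function(k) {
        pooled[pooled$series == take$series[k] &
                 pooled$replicate == take$replicate[k], , drop = FALSE]
      }))
      unname(stats::coef(stats::lm(log2_ratio ~ aligned_time, data = dd))[2])
    }, numeric(1)))
    boot_se <- stats::sd(slopes)
  }
  new_fitness_fit(unname(stats::coef(fit)[2]), unname(stats::coef(fit)[1]),
                  sm$coefficients["aligned_time", "Std. Error"],
                  sm$r.squared, offsets, stats::residuals(fit), pooled,
                  n_series = length(offsets), boot_se = boot_se)
}

#' @export
print.fitness_fit <- function(x, ...) {
  cat("Fitness-gap fit: g = gs - gr\n")
  cat(sprintf("  g = %.4f doublings/day (OLS se %.4f%s), R^2 = %.4f\n",
              x$g, x$stderr_g,
              if (is.finite(x$boot_se)) sprintf(", cluster-bootstrap se %.4f",
                                                x$boot_se) else "",
              x$r_squared))
  cat(sprintf("  %d series pooled; offsets: %s\n", x$n_series,
              paste(sprintf("%s=%+.2f d", names(x$offsets), x$offsets),
                    collapse = ", ")))
  invisible(x)
}

#' @export
coef.fitness_fit <- function(object, ...) {
  c(g = object$g, intercept = object$intercept)
}

#' @export
summary.fitness_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  residual RMS: %.4f log2 units over %d points\n",
              sqrt(mean(object$residuals^2)), nrow(object$data)))
  invisible(object)
}

#' @export
predict.fitness_fit <- function(object, aligned_time = NULL, ...) {
  if (is.null(aligned_time)) aligned_time <- object$data$aligned_time
  object$intercept + object$g * aligned_time
}

#' @export
residuals.fitness_fit <- function(object, ...) object$residuals

#' @export
plot.fitness_fit <- function(x, ...) {
  d <- x$data
  cols <- grDevices::hcl.colors(max(3L, x$n_series), "Dark 3")
  idx <- as.integer(factor(d$series))
  graphics::plot(d$aligned_time, d$log2_ratio, col = cols[idx],
                 xlab = "aligned time (days)", ylab = "log2(S/R)",
                 main = sprintf("fitness gap g = %.3f doublings/day", x$g),
                 ...)
  graphics::abline(x$intercept, x$g, col = "grey30", lty = 2)
  graphics::legend("topleft", legend = unique(d$series),
                   col = cols[unique(idx)], pch = 1, bty = "n", cex = 0.8)
  invisible(x)
}
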