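#' Simulation configuration
#'
#' Bundles the knobs shared by all synthetic-data generators: the master
#' seed, replicate count, measurement-noise levels and the sampling grid.
#' A fixed `seed` makes every generator byte-reproducible.
#'
#' @param seed integer master seed; all randomness in the generators flows
#'   from it. Sub-seeds for independent datasets are drawn from this stream
#'   and recorded in each dataset's ground truth.
#' @param n_replicates number of technical replicates per condition.
#' @param noise_cv coefficient of variation of the multiplicative
#'   (lognormal, median 1) measurement noise applied to cell counts.
#'   Dimensionless; 0 disables count noise.
#' @param cn_noise_sd standard deviation (copy-number units) of the additive
#'   Gaussian noise on observed segment mean copy number.
#' @param sampling_times numeric vector of measurement days, strictly
#'   increasing.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, noise_cv = 0.05)
#' cfg
#' @export
sim_config <- function(seed = 1L,
                       n_replicates = 3L,
                       noise_cv = 0.05,
                       cn_noise_sd = 0.05,
                       sampling_times = 0:20) {
  seed <- as.integer(seed)
  if (length(seed) != 1L || is.na(seed)) stop("`seed` must be a single integer")
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1")
  if (noise_cv < 0) stop("`noise_cv` must be >= 0")
  if (cn_noise_sd < 0) stop("`cn_noise_sd` must be >= 0")
  if (length(sampling_times) < 1L) stop("`sampling_times` must be non-empty")
  if (is.unsorted(sampling_times, strictly = TRUE)) {
    stop("`sampling_times` must be strictly increasing")
  }
  structure(
    list(seed = seed,
         n_replicates = as.integer(n_replicates),
         noise_cv = noise_cv,
         cn_noise_sd = cn_noise_sd,
         sampling_times = as.numeric(sampling_times)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat("  seed:          ", x$seed, "\n")
  cat("  replicates:    ", x$n_replicates, "\n")
  cat("  count noise CV:", x$noise_cv, "\n")
  cat("  CN noise sd:   ", x$cn_noise_sd, "\n")
  cat("  sampling days: ", x$sampling_times[1], "...",
      x$sampling_times[length(x$sampling_times)],
      sprintf("(%d points)\n", length(x$sampling_times)))
  invisible(x)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Draw n sub-seeds from the master seed (splittable-stream stand-in: one
# master stream hands out independent sub-seeds, recorded in ground truth).
derive_subseeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Multiplicative lognormal noise with median 1 and coefficient of variation
# cv (meanlog 0 so log-scale residuals are centred at 0).
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
}

# Parse a seeding ratio given as "85:15", c(85, 15) or c(0.85, 0.15) into
# fractions (sensitive, resistant) summing to 1.
parse_seeding_ratio <- function(x) {
  if (is.character(x)) {
    parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
    if (length(parts) != 2L || anyNA(parts)) {
      stop("seeding ratio string must look like \"85:15\"")
    }
    x <- parts
  }
  if (length(x) != 2L || any(x < 0)) {
    stop("seeding ratio must be two non-negative numbers")
  }
  s <- sum(x)
  if (s <= 0) stop("seeding ratio must have a positive sum")
  frac <- x / s
  names(frac) <- c("sensitive", "resistant")
  frac
}

ratio_label <- function(frac) {
  sprintf("%g:%g", round(100 * frac[[1]]), round(100 * frac[[2]]))
}
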