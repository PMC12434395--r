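# Shared fixtures and independent oracles, all built in code.

# Build a cn_series from a segments-x-later-samples shift matrix at purity 1
# (baseline clonal CN defaults to 2 everywhere).
make_shift_series <- function(shift_mat, c0 = NULL, purity = 1,
                              days = NULL) {
  ns <- nrow(shift_mat); nt <- ncol(shift_mat) + 1L
  if (is.null(c0)) c0 <- rep(2, ns)
  if (is.null(days)) days <- 90 * (0:(nt - 1))
  purity <- rep_len(purity, nt)
  segs <- do.call(rbind, lapply(seq_len(nt), function(t) {
    cn_tumor <- if (t == 1) c0 else c0 + shift_mat[, t - 1]
    obs <- purity[t] * cn_tumor + 2 * (1 - purity[t])
    data.frame(chromosome = "chr1",
               start = 3e6 * (seq_len(ns) - 1), end = 3e6 * seq_len(ns),
               copy_number = obs, sample_id = sprintf("S%02d", t),
               stringsAsFactors = FALSE)
  }))
  man <- data.frame(sample_id = sprintf("S%02d", seq_len(nt)), day = days,
                    purity = purity, marker_value = 35,
                    stringsAsFactors = FALSE)
  structure(list(segments = segs, manifest = man), class = "cn_series")
}

# Brute-force oracle for the integer-delta linear mixture: exhaustive
# search over delta in {-dmax..dmax}\{0} per segment, least-squares r per
# sample clipped to [0,1]; minimal SSE, ties by minimal sum |delta|.
brute_force_mixture <- function(shift, dmax = 3) {  # samples x segments
  ns <- ncol(shift)
  grid <- as.matrix(expand.grid(rep(list(setdiff(-dmax:dmax, 0)), ns)))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    d <- grid[i, ]
    r <- pmin(pmax(as.vector(shift %*% d) / sum(d^2), 0), 1)
    sse <- sum((shift - r %*% t(d))^2)
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 &&
         sum(abs(d)) < sum(abs(best$delta)))) {
      best <- list(delta = as.integer(d), r = r, sse = sse)
    }
  }
  best
}

# Independent Mantel-Cox log-rank computation from the risk table
# (two groups, no ties handling beyond the standard hypergeometric terms).
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(max(g) == 2L)
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at1 <- sum(time >= t & g == 1); at2 <- sum(time >= t & g == 2)
    d1 <- sum(time == t & event == 1 & g == 1)
    d2 <- sum(time == t & event == 1 & g == 2)
    d <- d1 + d2; n <- at1 + at2
    if (n <= 1 || d == 0) next
    O1 <- O1 + d1
    E1 <- E1 + d * at1 / n
    V <- V + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Default in-vitro sensitive/resistant pair used across growth tests.
test_pair <- function(gs = 0.5, gr = 0.42, Ks = 1e6, Kr = 8e5) {
  list(s = population_params(gs, Ks, "sensitive"),
       r = population_params(gr, Kr, "resistant"))
}

# Exponential-phase coculture (K far above the sampling window) for
# fitness-gap tests.
gen_exp_coculture <- function(gs, gr, seeding, seed, noise_cv = 0.05,
                              days = 0:14, n_replicates = 3) {
  m <- competition_model(population_params(gs, 1e9),
                         population_params(gr, 1e9, "resistant"), 1, 1)
  cfg <- sim_config(seed = seed, n_replicates = n_replicates,
                    noise_cv = noise_cv, sampling_times = days)
  gen_coculture(m, seeding, 2.5e5, cfg)
}
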