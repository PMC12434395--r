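#' Per-population logistic growth parameters
#'
#' @param growth_rate intrinsic growth rate in doublings/day (the unit in
#'   which fitness gaps are reported; the internal exponential rate is
#'   `log(2) * growth_rate`). May be zero or negative.
#' @param carrying_capacity population ceiling K in cells; must be positive.
#' @param label population label, `"sensitive"` or `"resistant"`.
#' @return A `population_params` object.
#' @examples
#' population_params(0.5, 1e6, "sensitive")
#' @export
population_params <- function(growth_rate, carrying_capacity,
                              label = c("sensitive", "resistant")) {
  label <- match.arg(label)
  if (!is.finite(growth_rate)) stop("`growth_rate` must be finite")
  if (!is.finite(carrying_capacity) || carrying_capacity <= 0) {
    stop("`carrying_capacity` must be > 0")
  }
  structure(list(growth_rate = growth_rate,
                 carrying_capacity = carrying_capacity,
                 label = label),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("%s population: growth rate %.4g doublings/day, K = %.4g cells\n",
              x$label, x$growth_rate, x$carrying_capacity))
  invisible(x)
}

#' Two-population Lotka-Volterra competition model
#'
#' Couples two logistic populations through competition coefficients:
#' \deqn{dS/dt = \ln 2\, g_s S (1 - (S + \alpha_{sr} R)/K_s)}
#' \deqn{dR/dt = \ln 2\, g_r R (1 - (R + \alpha_{rs} S)/K_r)}
#' `alpha_sr` is the per-capita effect of resistant cells on the sensitive
#' population and `alpha_rs` the converse. `alpha = 1` with equal K is the
#' fully shared-resource regime; `alpha = 0` decouples the populations.
#'
#' @param params_s,params_r [population_params] for the sensitive and
#'   resistant populations.
#' @param alpha_sr,alpha_rs non-negative competition coefficients.
#' @return A `competition_model` object.
#' @export
competition_model <- function(params_s, params_r,
                              alpha_sr = 1, alpha_rs = 1) {
  stopifnot(inherits(params_s, "population_params"),
            inherits(params_r, "population_params"))
  if (alpha_sr < 0 || alpha_rs < 0) stop("competition coefficients must be >= 0")
  structure(list(params_s = params_s, params_r = params_r,
                 alpha_sr = alpha_sr, alpha_rs = alpha_rs),
            class = "competition_model")
}

#' @export
print.competition_model <- function(x, ...) {
  cat("Two-population competition model\n")
  print(x$params_s)
  print(x$params_r)
  cat(sprintf("  alpha_sr = %.3g (R on S), alpha_rs = %.3g (S on R)\n",
              x$alpha_sr, x$alpha_rs))
  invisible(x)
}

#' Closed-form logistic growth
#'
#' Evaluates the logistic solution with intrinsic rate `log(2) *
#' growth_rate`, so that with `K >> n0` the population doubles once per day
#' per unit growth rate. `N(0) = n0`; for `n0 > 0` and positive rate,
#' `N(t) -> K`.
#'
#' @param n0 initial population size (cells), `>= 0`.
#' @param params a [population_params] object.
#' @param t numeric vector of times in days.
#' @return Numeric vector of population sizes at `t`.
#' @examples
#' p <- population_params(1, 1e9)
#' logistic_solution(1000, p, t = 0:3)  # doubles daily far below K
#' @export
logistic_solution <- function(n0, params, t) {
  stopifnot(inherits(params, "population_params"))
  if (n0 < 0) stop("`n0` must be >= 0")
  K <- params$carrying_capacity
  a <- log(2) * params$growth_rate
  if (n0 == 0) return(rep(0, length(t)))
  if (a == 0) return(rep(n0, length(t)))
  # N(t) = K / (1 + ((K - n0)/n0) exp(-a t))
  K / (1 + ((K - n0) / n0) * exp(-a * t))
}

# Right-hand side of the competition ODE system; optional per-population
# kill rates (per day) are supplied by the therapy engine.
competition_rhs <- function(t, state, parms) {
  S <- max(state[["S"]], 0)
  R <- max(state[["R"]], 0)
  m <- parms$model
  ks <- if (is.null(parms$kill_s)) 0 else parms$kill_s(t)
  kr <- if (is.null(parms$kill_r)) 0 else parms$kill_r(t)
  dS <- log(2) * m$params_s$growth_rate * S *
    (1 - (S + m$alpha_sr * R) / m$params_s$carrying_capacity) - ks * S
  dR <- log(2) * m$params_r$growth_rate * R *
    (1 - (R + m$alpha_rs * S) / m$params_r$carrying_capacity) - kr * R
  list(c(dS, dR))
}

#' Simulate two-population competition dynamics
#'
#' Numerically integrates the Lotka-Volterra competition system of a
#' [competition_model] from given seeds. With both competition coefficients
#' zero each population follows its independent closed-form logistic.
#'
#' @param model a [competition_model].
#' @param n0_s,n0_r initial sensitive / resistant cell counts, `>= 0`.
#' @param times strictly increasing numeric vector of days; the first
#'   element is the initial time.
#' @param kill_s,kill_r optional functions of time returning per-day kill
#'   rates applied to each population (used by the therapy engine).
#' @param rtol,atol integration tolerances passed to [deSolve::ode()].
#' @return A trajectory `data.frame` with columns `time_days`, `population`,
#'   `count`.
#' @seealso [logistic_solution()], [predict_coculture()]
#' @export
simulate_competition <- function(model, n0_s, n0_r, times,
                                 kill_s = NULL, kill_r = NULL,
                                 rtol = 1e-10, atol = 1e-6) {
  stopifnot(inherits(model, "competition_model"))
  if (n0_s < 0 || n0_r < 0) stop("initial counts must be >= 0")
  if (length(times) < 2L || is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing with >= 2 points")
  }
  out <- deSolve::ode(y = c(S = unname(n0_s), R = unname(n0_r)), times = times,
                      func = competition_rhs,
                      parms = list(model = model, kill_s = kill_s,
                                   kill_r = kill_r),
                      method = "lsoda", rtol = rtol, atol = atol)
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    stop(sprintf("competition integration failed (istate=%d) with gs=%g gr=%g Ks=%g Kr=%g",
                 istate, model$params_s$growth_rate,
                 model$params_r$growth_rate,
                 model$params_s$carrying_capacity,
                 model$params_r$carrying_capacity))
  }
  out <- as.data.frame(out)
  data.frame(
    time_days = rep(out$time, 2L),
    population = rep(c("sensitive", "resistant"), each = nrow(out)),
    count = pmax(c(out$S, out$R), 0),
    stringsAsFactors = FALSE)
}

#' Fit a logistic growth model to a monoculture trajectory
#'
#' Nonlinear least squares of log counts against the closed-form logistic
#' (multiplicative-noise assumption; set `log_scale = FALSE` for raw-scale
#' residuals). Parameters are estimated on the log scale to enforce
#' positivity; standard errors are mapped back by the delta method. On
#' failure to converge, up to five restarts are drawn from a Latin-hypercube
#' around data-driven heuristics (early log-slope for the rate, maximum
#' count for K).
#'
#' @param traj trajectory `data.frame` with columns `time_days`, `count`
#'   and optionally `replicate` (replicates enter as independent points) and
#'   `population` (must then be a single population).
#' @param log_scale fit on log-count residuals (default) or raw counts.
#' @param label population label recorded in the returned parameters.
#' @return An object of class `growth_fit` with components `params`
#'   ([population_params] at the estimates), `coefficients` (growth_rate,
#'   carrying_capacity, n0), `se`, `sigma`, `convergence`, `flags`
#'   (identifiability warnings) and the fitted model frame.
#' @examples
#' p <- population_params(0.5, 1e6)
#' tr <- data.frame(time_days = 0:25,
#'                  count = logistic_solution(1e4, p, 0:25))
#' fit <- fit_monoculture(tr)
#' coef(fit)
#' @export
fit_monoculture <- function(traj, log_scale = TRUE, label = "sensitive") {
  if (!is.null(traj$population)) {
    pops <- unique(traj$population)
    if (length(pops) > 1L) stop("`traj` contains more than one population")
    label <- pops
  }
  keep <- is.finite(traj$count) & traj$count > 0
  d <- data.frame(t = traj$time_days[keep], y = traj$count[keep])
  if (nrow(d) == 0L) stop("all counts are zero or missing")
  if (length(unique(d$t)) < 5L) {
    stop("need >= 5 distinct time points to fit a logistic")
  }
  flags <- character(0)

  # Degenerate input: essentially constant counts carry no rate information.
  if (stats::sd(log(d$y)) < 1e-8) {
    flags <- c(flags, "growth_rate unidentifiable: counts are constant")
    pp <- population_params(0, mean(d$y), label)
    return(new_growth_fit(pp, c(growth_rate = NA_real_,
                                carrying_capacity = mean(d$y),
                                n0 = mean(d$y)),
                          se = c(NA_real_, NA_real_, NA_real_),
                          sigma = 0, convergence = FALSE, flags = flags,
                          data = d, log_scale = log_scale))
  }

  # Start heuristics: rate from the early log2-slope, K from the max count.
  ord <- order(d$t)
  tt <- d$t[ord]; yy <- d$y[ord]
  n_early <- max(3L, min(6L, nrow(d) %/% 3L))
  r0 <- tryCatch(stats::coef(stats::lm(log2(yy[seq_len(n_early)]) ~
                                         tt[seq_len(n_early)]))[[2]],
                 error = function(e) 0.3)
  if (!is.finite(r0) || r0 <= 0) r0 <- 0.3
  K0 <- 1.2 * max(yy)
  n00 <- max(min(yy[tt == min(tt)]), 1)

  model_fun <- function(lr, lK, ln0, t) {
    K <- exp(lK); n0 <- exp(ln0); a <- log(2) * exp(lr)
    K / (1 + ((K - n0) / n0) * exp(-a * t))
  }
  resp <- if (log_scale) log(d$y) else d$y
  rhs <- if (log_scale) {
    stats::as.formula("resp ~ log(model_fun(lr, lK, ln0, t))")
  } else {
    stats::as.formula("resp ~ model_fun(lr, lK, ln0, t)")
  }
  dd <- data.frame(resp = resp, t = d$t)

  starts <- list(c(lr = log(r0), lK = log(K0), ln0 = log(n00)))
  # Latin-hypercube restarts around the heuristics (factor 1/4 .. 4).
  lh <- lhs::randomLHS(5L, 3L)
  for (i in seq_len(nrow(lh))) {
    starts[[i + 1L]] <- c(lr = log(r0) + log(4) * (2 * lh[i, 1] - 1),
                          lK = log(K0) + log(4) * (2 * lh[i, 2] - 1),
                          ln0 = log(n00) + log(4) * (2 * lh[i, 3] - 1))
  }
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(rhs, data = dd, start = as.list(st),
                                         control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("logistic fit failed to converge after 5 Latin-hypercube restarts")
  }

  est <- stats::coef(fit)
  se_log <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, 3))
  co <- c(growth_rate = exp(est[["lr"]]),
          carrying_capacity = exp(est[["lK"]]),
          n0 = exp(est[["ln0"]]))
  se <- c(co[[1]] * se_log[[1]], co[[2]] * se_log[[2]], co[[3]] * se_log[[3]])
  names(se) <- names(co)

  # K is identified only if the data approach the plateau.
  if (max(d$y) < 0.5 * co[["carrying_capacity"]]) {
    flags <- c(flags,
               "carrying_capacity unidentifiable: data do not approach plateau")
  }
  pp <- population_params(co[["growth_rate"]], co[["carrying_capacity"]], label)
  new_growth_fit(pp, co, se, sigma = summary(fit)$sigma,
                 convergence = TRUE, flags = flags, data = d,
                 log_scale = log_scale)
}

new_growth_fit <- function(params, coefficients, se, sigma, convergence,
                           flags, data, log_scale) {
  structure(list(params = params, coefficients = coefficients, se = se,
                 sigma = sigma, convergence = convergence, flags = flags,
                 data = data, log_scale = log_scale),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Logistic growth fit (", x$params$label, ")\n", sep = "")
  est <- rbind(estimate = x$coefficients, std.error = x$se)
  print(signif(est, 4))
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
summary.growth_fit <- function(object, ...) {
  cat(sprintf("Logistic growth fit (%s), %d points, %s-scale residuals\n",
              object$params$label, nrow(object$data),
              if (object$log_scale) "log" else "linear"))
  print(object)
  cat(sprintf("Residual sigma: %.4g; converged: %s\n",
              object$sigma, object$convergence))
  invisible(object)
}

#' @export
predict.growth_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) t <- object$data$t
  logistic_solution(object$coefficients[["n0"]], object$params, t)
}

#' @export
residuals.growth_fit <- function(object, ...) {
  p <- predict(object)
  if (object$log_scale) log(object$data$y) - log(p) else object$data$y - p
}

#' @export
plot.growth_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$y, log = "y", xlab = "day",
                 ylab = "cells", main = paste("logistic fit:", x$params$label),
                 ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "red3")
  invisible(x)
}

#' Predicted coculture growth under the independent-growth null
#'
#' The "predicted from monoculture" trajectory: each population grows from
#' its coculture seeding density with the parameters measured in
#' monoculture and no interaction (competition coefficients zero).
#' Deviation of observed cocultures from this prediction is the signature
#' of competition.
#'
#' @param params_s,params_r monoculture [population_params] (or
#'   `growth_fit` objects, whose parameters are used).
#' @param n0_s,n0_r coculture seeding densities in cells.
#' @param times days at which to evaluate.
#' @return Trajectory `data.frame` (`time_days`, `population`, `count`).
#' @export
predict_coculture <- function(params_s, params_r, n0_s, n0_r, times) {
  if (inherits(params_s, "growth_fit")) params_s <- params_s$params
  if (inherits(params_r, "growth_fit")) params_r <- params_r$params
  m <- competition_model(params_s, params_r, alpha_sr = 0, alpha_rs = 0)
  simulate_competition(m, n0_s, n0_r, times)
}

#' Deviation of observed coculture growth from the independent-growth null
#'
#' For each population, the mean over time points of
#' `log2(observed/predicted)` with a confidence interval over replicates.
#' Negative values mean growth is suppressed below what the monoculture
#' parameters predict, the signature of resource competition. With the
#' handful of replicates typical of these experiments a percentile
#' bootstrap undercovers badly, so the default interval is a replicate-
#' level t-interval; `method = "bootstrap"` gives the percentile version.
#'
#' @param observed trajectory `data.frame` with `time_days`, `population`,
#'   `count` and optionally `replicate`.
#' @param predicted trajectory from [predict_coculture()]; time grids are
#'   inner-joined.
#' @param method `"t"` (replicate t-interval, default) or `"bootstrap"`
#'   (percentile over replicate resamples).
#' @param n_boot bootstrap resamples over replicates for the interval.
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return `data.frame` with one row per population: `deviation` (mean log2
#'   ratio), `ci_low`, `ci_high`, `n_points`.
#' @export
competition_deviation <- function(observed, predicted,
                                  method = c("t", "bootstrap"),
                                  n_boot = 1000, conf = 0.95, seed = 1L) {
  method <- match.arg(method)
  if (is.null(observed$replicate)) observed$replicate <- 1L
  pred <- predicted
  names(pred)[names(pred) == "count"] <- "pred_count"
  d <- merge(observed, pred[, c("time_days", "population", "pred_count")],
             by = c("time_days", "population"))
  if (nrow(d) == 0L) stop("no overlapping time points between observed and predicted")
  if (any(d$pred_count <= 0)) stop("predicted counts must be positive")
  d <- d[d$count > 0, ]
  d$l2 <- log2(d$count / d$pred_count)

  alpha <- (1 - conf) / 2
  res <- lapply(split(d, d$population), function(dp) {
    per_rep <- tapply(dp$l2, dp$replicate, mean)
    reps <- as.numeric(per_rep)
    est <- mean(reps)
    if (length(reps) > 1L) {
      if (method == "t") {
        half <- stats::qt(1 - alpha, df = length(reps) - 1) *
          stats::sd(reps) / sqrt(length(reps))
        ci <- est + c(-half, half)
      } else {
        bm <- with_seed(seed, {
          vapply(seq_len(n_boot), function(i) {
            mean(sample(reps, length(reps), replace = TRUE))
          }, numeric(1))
        })
        ci <- stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE)
      }
    } else {
      ci <- c(NA_real_, NA_real_)
    }
    data.frame(population = dp$population[1], deviation = est,
               ci_low = ci[1], ci_high = ci[2], n_points = nrow(dp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
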