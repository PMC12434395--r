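#' Instantaneous drug kill rate after a dose
#'
#' Emax dose response modulated by a gamma-shaped delay kernel normalised
#' to peak at 1: at the effect peak the sensitive-population kill rate is
#' `kill_max * dose / (dose + ec50)` per day (so a dose equal to `ec50`
#' peaks at half `kill_max`). The kernel's mean delay contracts with dose
#' (see [drug_params()]), so the effect arrives earlier at higher dose; the
#' kernel is truncated beyond `effect_duration`. The resistant population
#' receives this rate multiplied by `resistance_factor` (apply externally
#' or via `resistant = TRUE`).
#'
#' @param dose administered dose (>= 0), in the units of `ec50`.
#' @param time_since_dose days since administration (>= 0; vectorised).
#' @param p a [drug_params()].
#' @param resistant apply the resistant-population multiplier.
#' @return Per-day kill rate(s).
#' @export
drug_kill_rate <- function(dose, time_since_dose, p, resistant = FALSE) {
  if (any(time_since_dose < 0)) stop("`time_since_dose` must be >= 0")
  if (dose < 0) stop("`dose` must be >= 0")
  r <- kill_rate_at(dose, time_since_dose, p)
  if (resistant) r <- r * p$resistance_factor
  r
}

# internal: 0 before the dose and beyond effect_duration
kill_rate_at <- function(dose, tau, p) {
  if (dose == 0 || p$kill_max == 0) return(rep(0, length(tau)))
  emax_frac <- dose / (dose + p$ec50)
  m_eff <- p$lag_mean * (1 - p$lag_dose_shift * emax_frac)
  rate <- p$lag_shape / m_eff
  mode <- (p$lag_shape - 1) / rate
  peak <- stats::dgamma(mode, shape = p$lag_shape, rate = rate)
  k <- p$kill_max * emax_frac *
    stats::dgamma(pmax(tau, 0), shape = p$lag_shape, rate = rate) / peak
  k[tau < 0 | tau > p$effect_duration] <- 0
  k
}

# total kill rate at time t from a dose log (data.frame day, dose)
kill_from_log <- function(t, dose_log, p, resistant = FALSE) {
  if (nrow(dose_log) == 0L) return(0)
  tot <- 0
  for (i in seq_len(nrow(dose_log))) {
    if (dose_log$dose[i] > 0 && t >= dose_log$day[i]) {
      tot <- tot + kill_rate_at(dose_log$dose[i], t - dose_log$day[i], p)
    }
  }
  if (resistant) tot <- tot * p$resistance_factor
  tot
}

#' Therapy protocols
#'
#' Constructors for the three dosing protocols compared in the in-silico
#' trial. Standard therapy (ST) gives a fixed dose every `interval` days
#' for `n_doses` doses; vehicle is the same schedule at dose 0; adaptive
#' therapy (AT) gives one initial dose and then modulates the dose at
#' weekly decisions from the fractional change of the *target* tumor
#' volume since the last decision, through an ordered band table. The
#' default AT bands are a reconstruction constrained by the printed
#' protocol facts (initial 60 mg/kg, weekly interval, doses shrinking to
#' below 3 mg/kg or omission): growth of at least +10% multiplies the dose
#' by 1.5 (capped at `max_dose`); change within +/-10% keeps it; shrinkage
#' of at least 10% halves it; a dose falling below `min_dose` is omitted
#' (0 administered) while the nominal dose keeps shrinking or recovering.
#' Nontarget tumor volumes are never consulted.
#'
#' @param dose,initial_dose dose in mg/kg.
#' @param interval days between doses/decisions.
#' @param n_doses number of fixed doses (ST/vehicle).
#' @param rule_table `data.frame(lower, upper, multiplier)`: bands of
#'   fractional volume change `[lower, upper)` partitioning the real line.
#' @param min_dose doses below this are omitted, mg/kg.
#' @param max_dose cap on the modulated dose, mg/kg.
#' @return A `therapy_protocol` object.
#' @export
protocol_st <- function(dose = 60, interval = 4, n_doses = 3) {
  structure(list(name = "ST", type = "ST", initial_dose = dose,
                 interval = interval, n_doses = n_doses),
            class = "therapy_protocol")
}

#' @rdname protocol_st
#' @export
protocol_vehicle <- function(interval = 4, n_doses = 3) {
  structure(list(name = "vehicle", type = "vehicle", initial_dose = 0,
                 interval = interval, n_doses = n_doses),
            class = "therapy_protocol")
}

#' @rdname protocol_st
#' @export
protocol_at <- function(initial_dose = 60, interval = 7,
                        rule_table = default_at_bands(),
                        min_dose = 1, max_dose = 60) {
  stopifnot(is.data.frame(rule_table),
            all(c("lower", "upper", "multiplier") %in% names(rule_table)))
  if (any(rule_table$multiplier < 0)) stop("band multipliers must be >= 0")
  rule_table <- rule_table[order(rule_table$lower), ]
  if (rule_table$lower[1] != -Inf ||
      rule_table$upper[nrow(rule_table)] != Inf ||
      (nrow(rule_table) > 1 &&
       any(rule_table$upper[-nrow(rule_table)] != rule_table$lower[-1]))) {
    stop("rule_table bands must partition the real line")
  }
  structure(list(name = "AT", type = "AT", initial_dose = initial_dose,
                 interval = interval, rule_table = rule_table,
                 min_dose = min_dose, max_dose = max_dose),
            class = "therapy_protocol")
}

#' @rdname protocol_st
#' @export
default_at_bands <- function() {
  data.frame(lower = c(-Inf, -0.10, 0.10),
             upper = c(-0.10, 0.10, Inf),
             multiplier = c(0.5, 1.0, 1.5))
}

#' @export
print.therapy_protocol <- function(x, ...) {
  if (x$type == "AT") {
    cat(sprintf("AT protocol: initial %g mg/kg, every %g days, bands:\n",
                x$initial_dose, x$interval))
    print(x$rule_table, row.names = FALSE)
    cat(sprintf("  min dose %g mg/kg (omitted below), cap %g mg/kg\n",
                x$min_dose, x$max_dose))
  } else {
    cat(sprintf("%s protocol: %g mg/kg every %g days x%d doses\n",
                x$name, x$initial_dose, x$interval, x$n_doses))
  }
  invisible(x)
}

#' Next dose under a protocol
#'
#' For ST/vehicle, returns the fixed dose while doses remain, else 0. For
#' AT, computes the fractional change of the target tumor volume since the
#' last decision, looks up the band multiplier, and scales the last
#' *nominal* dose; the administered dose is zero when the nominal dose
#' falls below `min_dose` (omission), but the nominal value is retained in
#' the `"nominal"` attribute so later growth can recover dosing.
#'
#' @param protocol a `therapy_protocol`.
#' @param target_volume_now,target_volume_at_last_dose target tumor
#'   volumes (mm3) now and at the previous decision (AT only; must be > 0).
#' @param last_dose the previous nominal dose in mg/kg (AT only).
#' @param n_given number of doses already administered (ST/vehicle only).
#' @return Administered dose in mg/kg, with attribute `nominal`.
#' @export
next_dose <- function(protocol, target_volume_now = NULL,
                      target_volume_at_last_dose = NULL,
                      last_dose = NULL, n_given = 0L) {
  stopifnot(inherits(protocol, "therapy_protocol"))
  if (protocol$type %in% c("ST", "vehicle")) {
    d <- if (n_given < protocol$n_doses) protocol$initial_dose else 0
    return(structure(d, nominal = d))
  }
  if (is.null(last_dose) || is.na(last_dose)) {
    stop("AT decision requires the last nominal dose")
  }
  if (is.null(target_volume_now) || is.null(target_volume_at_last_dose) ||
      target_volume_now <= 0 || target_volume_at_last_dose <= 0) {
    stop("AT decision requires positive target tumor volumes")
  }
  change <- (target_volume_now - target_volume_at_last_dose) /
    target_volume_at_last_dose
  rt <- protocol$rule_table
  band <- which(change >= rt$lower & change < rt$upper)[1]
  nominal <- min(rt$multiplier[band] * last_dose, protocol$max_dose)
  administered <- if (nominal < protocol$min_dose) 0 else nominal
  structure(administered, nominal = nominal)
}

#' Simulate one treated mouse course
#'
#' Integrates the two-flank competition dynamics with drug kill terms
#' between dosing decisions, applying the protocol at its interval from
#' treatment start (day 0 = enrollment). AT decisions use the target flank
#' only. The course stops when either flank reaches the endpoint volume
#' (default 1440 mm3) or at the experiment end.
#'
#' @param model in-vivo [competition_model] on the cell-count scale.
#' @param drug a [drug_params()] on the mg/kg scale.
#' @param protocol a `therapy_protocol`.
#' @param course_init one element of a [gen_mouse_cohort()] list.
#' @param cells_per_mm3 volume conversion constant.
#' @param endpoint_volume culling threshold, mm3 (1440 = the 1.44-cm3
#'   reading of the humane endpoint; set `endpoint_area = TRUE` for the
#'   cross-sectional-area reading instead).
#' @param endpoint_area use `pi/4 * short * long >= 144 mm2` on the
#'   ellipsoid diameters implied by a spherical tumor (area reading).
#' @param experiment_end_days days from treatment start at which survivors
#'   are censored (default 140 = 20 weeks).
#' @return A `tumor_course` list: `mouse_id`, `volumes` (`data.frame` day,
#'   flank, volume_mm3, sensitive_cells, resistant_cells), `dose_log`
#'   (day, dose, nominal), `enroll_day`, `event_day` (days from treatment
#'   start), `event` (TRUE = endpoint reached, FALSE = censored).
#' @export
run_course <- function(model, drug, protocol, course_init,
                       cells_per_mm3 = 1e4, endpoint_volume = 1440,
                       endpoint_area = FALSE, experiment_end_days = 140) {
  scaled <- scale_model_rates(model, course_init$rate_mult)
  target <- course_init$target_flank
  state <- course_init$state_at_enroll  # 2x2: rows S,R; cols flank
  decision_days <- seq(0, experiment_end_days,
                       by = protocol$interval)
  dose_log <- data.frame(day = numeric(0), dose = numeric(0),
                         nominal = numeric(0))
  vols <- NULL
  nominal <- NA_real_
  vol_at_last_decision <- NA_real_
  n_given <- 0L
  event_day <- NA_real_

  flank_volume <- function(st) (st["S"] + st["R"]) / cells_per_mm3
  at_endpoint <- function(v) {
    if (endpoint_area) {
      # spherical tumor of volume v has diameter d; cross-section pi d^2/4
      d <- (6 * v / pi)^(1 / 3)
      pi * d^2 / 4 >= 144
    } else {
      v >= endpoint_volume
    }
  }

  for (k in seq_along(decision_days)) {
    day <- decision_days[k]
    tv <- flank_volume(state[, target])
    if (protocol$type == "AT") {
      if (k == 1L) {
        dose <- protocol$initial_dose
        nominal <- protocol$initial_dose
      } else {
        d <- next_dose(protocol, tv, vol_at_last_decision, nominal)
        dose <- as.numeric(d)
        nominal <- attr(d, "nominal")
      }
      # band comparisons are against the volume at the last *administered*
      # dose ("last-dosed volume")
      if (dose > 0 || k == 1L) vol_at_last_decision <- tv
    } else {
      dose <- as.numeric(next_dose(protocol, n_given = n_given))
      if (dose > 0) n_given <- n_given + 1L
      nominal <- dose
    }
    dose_log <- rbind(dose_log,
                      data.frame(day = day, dose = dose, nominal = nominal))

    seg_end <- if (k < length(decision_days)) decision_days[k + 1] else
      experiment_end_days
    if (seg_end <= day) break
    tt <- seq(day, seg_end, by = 1)
    if (tt[length(tt)] < seg_end) tt <- c(tt, seg_end)
    seg <- lapply(1:2, function(f) {
      ks <- function(t) kill_from_log(t, dose_log, drug)
      kr <- function(t) kill_from_log(t, dose_log, drug, resistant = TRUE)
      simulate_competition(scaled, state["S", f], state["R", f], tt,
                           kill_s = ks, kill_r = kr, rtol = 1e-7, atol = 1)
    })
    seg_df <- do.call(rbind, lapply(1:2, function(f) {
      s <- seg[[f]]
      sc <- s$count[s$population == "sensitive"]
      rc <- s$count[s$population == "resistant"]
      data.frame(day = tt, flank = f, volume_mm3 = (sc + rc) / cells_per_mm3,
                 sensitive_cells = sc, resistant_cells = rc)
    }))
    vols <- rbind(vols, seg_df[seg_df$day > day | k == 1L, ])
    # daily endpoint monitoring on either flank
    daily <- split(seg_df, seg_df$day)
    for (dd in names(daily)) {
      if (any(at_endpoint(daily[[dd]]$volume_mm3))) {
        event_day <- as.numeric(dd)
        break
      }
    }
    # advance state to segment end
    for (f in 1:2) {
      s <- seg[[f]]
      state["S", f] <- s$count[s$population == "sensitive"][length(tt)]
      state["R", f] <- s$count[s$population == "resistant"][length(tt)]
    }
    if (!is.na(event_day)) break
  }
  if (!is.na(event_day)) vols <- vols[vols$day <= event_day, ]
  structure(list(mouse_id = course_init$mouse_id,
                 volumes = vols, dose_log = dose_log,
                 enroll_day = course_init$enroll_day,
                 event_day = if (is.na(event_day)) experiment_end_days else event_day,
                 event = !is.na(event_day),
                 protocol = protocol$name),
            class = "tumor_course")
}

#' @export
print.tumor_course <- function(x, ...) {
  cat(sprintf("Mouse %s [%s]: %s at day %g; cumulative dose %g mg/kg (%d administrations)\n",
              x$mouse_id, x$protocol,
              if (x$event) "endpoint" else "censored", x$event_day,
              sum(x$dose_log$dose), sum(x$dose_log$dose > 0)))
  invisible(x)
}

#' Run an in-silico adaptive-therapy trial
#'
#' For each injected S:R cohort ratio, generates one mouse cohort (shared
#' across arms so protocols are compared on matched tumors) and runs every
#' protocol arm, then summarises per-arm Kaplan-Meier medians, pairwise
#' log-rank (Mantel-Cox) tests, cumulative dose and dose per day on study.
#'
#' @param cohort_ratios character vector of injected mixtures, e.g.
#'   `c("100:0", "80:20", "0:100")`.
#' @param arms named list of `therapy_protocol`s.
#' @param n_per_arm mice per arm (>= 2).
#' @param model in-vivo [competition_model].
#' @param drug [drug_params()] on the mg/kg scale.
#' @param config a [sim_config()]; seed drives cohort generation.
#' @param clock `"treatment"` (survival from treatment initiation) or
#'   `"injection"` (adds the enrollment day).
#' @param ... passed to [run_course()].
#' @return A `trial_result`: `subjects` (per-mouse times in weeks, event
#'   flags, dose summaries), `medians`, `logrank` (pairwise within cohort).
#' @export
run_trial <- function(cohort_ratios = c("100:0", "80:20", "0:100"),
                      arms = list(vehicle = protocol_vehicle(),
                                  ST = protocol_st(), AT = protocol_at()),
                      n_per_arm = 5, model, drug, config,
                      clock = c("treatment", "injection"), ...) {
  clock <- match.arg(clock)
  if (n_per_arm < 2) stop("need >= 2 mice per arm")
  if (is.null(names(arms))) {
    names(arms) <- vapply(arms, `[[`, "", "name")
  }
  subseeds <- derive_subseeds(config$seed, length(cohort_ratios))
  subjects <- NULL
  for (ci in seq_along(cohort_ratios)) {
    ratio <- cohort_ratios[ci]
    ccfg <- config
    ccfg$seed <- subseeds[ci]
    cohort <- gen_mouse_cohort(ratio, n_per_arm, model, ccfg)
    for (arm in names(arms)) {
      for (m in cohort) {
        if (is.na(m$enroll_day)) {
          subjects <- rbind(subjects, data.frame(
            cohort = ratio, arm = arm, mouse_id = m$mouse_id,
            time_weeks = NA_real_, event = FALSE, enrolled = FALSE,
            cum_dose = NA_real_, dose_per_day = NA_real_))
          next
        }
        course <- run_course(model, drug, arms[[arm]], m, ...)
        t_days <- course$event_day +
          if (clock == "injection") course$enroll_day else 0
        cum <- sum(course$dose_log$dose)
        subjects <- rbind(subjects, data.frame(
          cohort = ratio, arm = arm, mouse_id = m$mouse_id,
          time_weeks = t_days / 7, event = course$event, enrolled = TRUE,
          cum_dose = cum,
          dose_per_day = cum / max(course$event_day, 1)))
      }
    }
  }
  enr <- subjects[subjects$enrolled, ]
  medians <- do.call(rbind, lapply(split(enr, list(enr$cohort, enr$arm),
                                         drop = TRUE), function(d) {
    km <- kaplan_meier_logrank(d$time_weeks, d$event)
    data.frame(cohort = d$cohort[1], arm = d$arm[1], n = nrow(d),
               events = sum(d$event), median_weeks = km$medians[[1]])
  }))
  rownames(medians) <- NULL
  pairs <- utils::combn(names(arms), 2, simplify = FALSE)
  logrank <- do.call(rbind, lapply(unique(enr$cohort), function(co) {
    do.call(rbind, lapply(pairs, function(pr) {
      d <- enr[enr$cohort == co & enr$arm %in% pr, ]
      if (length(unique(d$arm)) < 2L || sum(d$event) == 0) {
        return(data.frame(cohort = co, arm1 = pr[1], arm2 = pr[2],
                          chisq = NA_real_, p = NA_real_))
      }
      lr <- kaplan_meier_logrank(d$time_weeks, d$event, d$arm)
      data.frame(cohort = co, arm1 = pr[1], arm2 = pr[2],
                 chisq = lr$chisq, p = lr$p)
    }))
  }))
  rownames(logrank) <- NULL
  structure(list(subjects = subjects, medians = medians, logrank = logrank),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("In-silico trial result\n\nMedian survival (weeks):\n")
  m <- x$medians
  m$median_weeks <- ifelse(is.na(m$median_weeks), "undefined",
                           sprintf("%.2f", m$median_weeks))
  print(m, row.names = FALSE)
  cat("\nPairwise log-rank (Mantel-Cox):\n")
  print(transform(x$logrank, p = signif(p, 3), chisq = signif(chisq, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Kaplan-Meier medians and Mantel-Cox log-rank test
#'
#' Product-limit median survival per group (reported as `NA` with an
#' explicit flag when the survival curve never crosses 0.5, mirroring
#' "median survival could not be defined") and, for two or more groups,
#' the Mantel-Cox log-rank chi-square and p-value.
#'
#' @param time survival times.
#' @param event event indicator (TRUE/1 = event, FALSE/0 = censored).
#' @param group optional group factor; omit for a single group.
#' @return List with `medians` (named numeric, `NA` = undefined),
#'   `median_defined` logical vector, `chisq`, `df`, `p` (NA for a single
#'   group).
#' @export
kaplan_meier_logrank <- function(time, event, group = NULL) {
  if (length(time) < 1L) stop("need >= 1 subject")
  event <- as.integer(event)
  if (all(event == 0)) warning("all subjects censored; medians undefined")
  if (is.null(group)) group <- rep("all", length(time))
  group <- factor(group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  tab <- summary(sf)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list("all", names(tab)))
  med <- tab[, "median"]
  names(med) <- sub("^group=", "", rownames(tab))
  chisq <- df <- p <- NA_real_
  if (nlevels(group) >= 2L && sum(event) > 0) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    chisq <- sd$chisq
    df <- length(sd$n) - 1
    p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  list(medians = med, median_defined = !is.na(med),
       chisq = chisq, df = df, p = p)
}

#' Sensitive-fraction nadir after a drug pulse
#'
#' Locates the post-treatment trough of the sensitive proportion
#' `S/(S+R)`: the minimum of the (replicate-averaged) fraction series
#' after its post-pulse maximum. Returns the trough time, its lag after
#' the pulse, and the fraction depth.
#'
#' @param traj trajectory containing both populations (one condition).
#' @param pulse_day day the dose was administered.
#' @return List with `nadir_day`, `lag_days`, `nadir_fraction`.
#' @export
sensitive_fraction_nadir <- function(traj, pulse_day) {
  if (is.null(traj$replicate)) traj$replicate <- 1L
  s <- traj[traj$population == "sensitive", ]
  r <- traj[traj$population == "resistant", ]
  st <- tapply(s$count, s$time_days, mean)
  rt <- tapply(r$count, r$time_days, mean)
  tt <- as.numeric(names(st))
  fr <- as.numeric(st) / (as.numeric(st) + as.numeric(rt))
  post <- which(tt >= pulse_day)
  if (length(post) < 3L) stop("too few points after the pulse")
  imax <- post[which.max(fr[post])]
  tail_idx <- imax:length(tt)
  imin <- tail_idx[which.min(fr[tail_idx])]
  list(nadir_day = tt[imin], lag_days = tt[imin] - pulse_day,
       nadir_fraction = fr[imin])
}
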