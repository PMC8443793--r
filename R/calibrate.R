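## Hierarchical Bayesian calibration against blood and urine biomonitoring
## series.  Observation model: zero-truncated normal errors around the
## model-predicted blood concentrations (DPHP, MPHP; mg/L) and urinary
## deposition rates (OH-/cx-MPHP; mg/h), with stream-specific error SDs
## under gamma(0.01, 0.01) priors.  Global parameters theta are shared by
## all subjects; omega_j are subject-specific.

#' Define which parameters are calibrated globally and per subject
#'
#' @param global character vector of raw parameter names shared across
#'   subjects (partition coefficients, fractions metabolised, half-lives,
#'   binding, recirculation and urinary rates are the natural choices).
#' @param subject character vector of subject-specific raw parameter names
#'   (uptake lags, permeabilities, dose fractions, physiology).
#' @param priors prior table, see [parameter_priors()].
#' @param sigma_prior shape and rate of the gamma prior on each error SD.
#' @return list of class `dphpk_calspec`.
#' @export
calibration_spec <- function(global, subject, priors = parameter_priors(),
                             sigma_prior = c(0.01, 0.01)) {
  if (length(intersect(global, subject)))
    stop("global and subject parameter sets must be disjoint: ",
         paste(intersect(global, subject), collapse = ", "))
  missing <- setdiff(c(global, subject), priors$name)
  if (length(missing))
    stop("no prior specified for: ", paste(missing, collapse = ", "))
  structure(list(global = global, subject = subject,
                 priors = priors[match(c(global, subject), priors$name), ],
                 sigma_prior = sigma_prior),
            class = "dphpk_calspec")
}

#' Per-void urinary deposition rates
#'
#' Converts void concentrations and volumes into deposition rates:
#' `rate_i = conc_i * volume_i / (t_i - t_(i-1))` (mg/h), with the dose
#' time as the opening bound of the first interval.
#'
#' @param urine data.frame with columns `time` (h), `volume` (mL),
#'   `conc_OH`, `conc_cx` (mg/L); or a `bm_dataset`, in which case a list
#'   of per-subject rate frames is returned.
#' @return data.frame `time`, `rate_OH`, `rate_cx` (mg/h).
#' @export
urine_rates <- function(urine) {
  if (inherits(urine, "bm_dataset"))
    return(lapply(urine$subjects, function(s) urine_rates(s$urine)))
  stopifnot(all(c("time", "volume", "conc_OH", "conc_cx") %in% names(urine)))
  tt <- urine$time
  if (any(diff(c(0, tt)) <= 0))
    stop("void times must be strictly increasing and positive")
  if (any(urine$volume <= 0)) stop("void volumes must be > 0")
  gap <- diff(c(0, tt))
  ## mg/h = (mg/L) * (mL / 1000) / h
  data.frame(time = tt,
             rate_OH = urine$conc_OH * urine$volume / 1000 / gap,
             rate_cx = urine$conc_cx * urine$volume / 1000 / gap)
}

.ztnorm_logdens <- function(y, mu, sigma) {
  stats::dnorm(y, mu, sigma, log = TRUE) -
    stats::pnorm(mu / sigma, log.p = TRUE)
}

## observation tables for one subject, in the order predictions are made
.subject_obs <- function(subj) {
  ur <- urine_rates(subj$urine)
  list(t_blood = subj$blood$time,
       y_DPHP = subj$blood$CBloodDPHP, y_MPHP = subj$blood$CBloodMPHP,
       t_void = subj$urine$time, y_OH = ur$rate_OH, y_cx = ur$rate_cx)
}

## simulate one subject at raw-parameter overrides and predict the four
## observation streams (interval-averaged urine rates from cumulative
## urinary excretion, matching how the void data are reduced)
.predict_subject <- function(overrides, subj, obs, engine = "compiled",
                             t_end = 48) {
  raw <- default_parameters(utils::modifyList(
    list(BW = subj$BW), as.list(overrides)))
  scen <- exposure_scenario(subj$dose, t_end = t_end, dt = 0.25)
  ## the solver's accuracy does not depend on the output grid: report the
  ## dense solution only where observations sit
  times <- sort(unique(c(0, obs$t_blood, obs$t_void, t_end)))
  p <- build_subject(raw, scen)
  res <- simulate_pbpk(p, engine = engine, times = times, derived = FALSE)
  Vven <- p$derived[["Vven"]]
  ib <- match(obs$t_blood, res$times)
  iv <- match(c(0, obs$t_void), res$times)
  cum_rate <- function(cum) diff(cum[iv]) / diff(c(0, obs$t_void))
  list(mu_DPHP = res$states[ib, "Aven"] / Vven,
       mu_MPHP = res$states[ib, "Mven"] / Vven,
       mu_OH = cum_rate(res$states[, "UOH"]),
       mu_cx = cum_rate(res$states[, "Ucx"]))
}

.loglik_streams <- function(obs, pred, sigmas) {
  sum(.ztnorm_logdens(obs$y_DPHP, pred$mu_DPHP, sigmas[["DPHP"]])) +
    sum(.ztnorm_logdens(obs$y_MPHP, pred$mu_MPHP, sigmas[["MPHP"]])) +
    sum(.ztnorm_logdens(obs$y_OH, pred$mu_OH, sigmas[["OH"]])) +
    sum(.ztnorm_logdens(obs$y_cx, pred$mu_cx, sigmas[["cx"]]))
}

#' Log-likelihood of a biomonitoring dataset
#'
#' Sum over included subjects and the four observation streams of
#' zero-truncated normal log-densities of the observations around the
#' model predictions (truncation normalisation included).  A failed
#' simulation yields `-Inf` with a warning naming the subject.
#'
#' @param ds `bm_dataset`.
#' @param theta named vector of global raw-parameter values.
#' @param omega named list (by subject id) of named subject-parameter
#'   vectors; may be empty.
#' @param sigmas named vector with elements `OH`, `cx`, `DPHP`, `MPHP`.
#' @param engine solver engine.
#' @param t_end simulation horizon, h.
#' @return scalar log-likelihood.
#' @export
bm_log_likelihood <- function(ds, theta = NULL, omega = list(),
                              sigmas, engine = "compiled", t_end = 48) {
  stopifnot(inherits(ds, "bm_dataset"))
  ll <- 0
  for (subj in ds$subjects) {
    if (isTRUE(subj$exclude)) next
    obs <- .subject_obs(subj)
    ov <- c(as.list(theta), as.list(omega[[subj$id]]))
    pred <- tryCatch(.predict_subject(ov, subj, obs, engine, t_end),
                     error = function(e) e)
    if (inherits(pred, "error")) {
      warning("simulation failed for subject ", subj$id, ": ",
              conditionMessage(pred))
      return(-Inf)
    }
    ll <- ll + .loglik_streams(obs, pred, sigmas)
  }
  ll
}

#' Hierarchical Bayesian calibration by adaptive Metropolis-within-Gibbs
#'
#' Random-walk Metropolis in blocks: one joint proposal for the global
#' parameters theta (requiring one simulation per included subject), one
#' joint proposal per subject for omega_j (one simulation), and one
#' log-scale proposal per error SD (no simulation; cached predictions are
#' reused).  Proposal scales adapt toward a 0.234 acceptance rate during
#' burn-in only.  Parameters are proposed on the native scale and
#' rejected outside their truncated prior support.
#'
#' @param spec `dphpk_calspec`.
#' @param ds `bm_dataset`; subjects flagged `exclude` are skipped.
#' @param iterations number of MCMC iterations (0 returns the initial
#'   state only).
#' @param thin keep every `thin`-th iteration.
#' @param seed integer seed.
#' @param burn_frac fraction of iterations treated as burn-in (adaptation
#'   window; burned draws are retained but flagged).
#' @param init optional named list with elements `theta`, `omega`,
#'   `sigmas`; defaults to prior medians and observation-scale SDs.
#' @param use_likelihood set `FALSE` to sample the prior only (sampler
#'   validation); no simulations are run.
#' @param scale_moves optional list of ridge ("crab") moves, each a list
#'   with elements `global` and `subject` naming one global and one
#'   subject-level parameter tied by a multiplicative non-identifiability
#'   (e.g. a shared metabolite-fate fraction against per-subject dose
#'   fractions, which enter the urinary signal only through their
#'   product).  Each move proposes `global * m`, `subject_j / m` jointly
#'   with a log-normal multiplier and the exact Jacobian correction,
#'   dramatically improving mixing along the ridge.
#' @param engine solver engine.
#' @param t_end simulation horizon, h.
#' @return object of class `dphpk_posterior`.
#' @export
mcmc_calibrate <- function(spec, ds, iterations = 2000, thin = 10, seed = 1,
                           burn_frac = 0.2, init = NULL,
                           use_likelihood = TRUE, scale_moves = list(),
                           engine = "compiled", t_end = 48) {
  stopifnot(inherits(spec, "dphpk_calspec"), inherits(ds, "bm_dataset"))
  set.seed(seed)
  subjects <- Filter(function(s) !isTRUE(s$exclude), ds$subjects)
  J <- length(subjects)
  if (use_likelihood && J == 0) stop("no included subjects in dataset")
  ids <- vapply(subjects, `[[`, "", "id")
  pg <- spec$priors[match(spec$global, spec$priors$name), , drop = FALSE]
  ps <- spec$priors[match(spec$subject, spec$priors$name), , drop = FALSE]
  kg <- nrow(pg); ks <- nrow(ps)

  prior_median <- function(tab) {
    if (nrow(tab) == 0) return(numeric(0))
    stats::setNames(.prior_quantile(matrix(0.5, 1, nrow(tab)), tab)[1, ],
                    tab$name)
  }
  theta <- prior_median(pg)
  omega <- matrix(rep(prior_median(ps), each = max(J, 1)), nrow = max(J, 1),
                  dimnames = list(ids, ps$name))
  sigmas <- c(OH = 0.01, cx = 0.001, DPHP = 0.02, MPHP = 0.02)
  if (!is.null(init)) {
    if (!is.null(init$theta)) theta[names(init$theta)] <- init$theta
    if (!is.null(init$sigmas)) sigmas[names(init$sigmas)] <- init$sigmas
    if (!is.null(init$omega))
      for (id in rownames(omega))
        if (!is.null(init$omega[[id]]))
          omega[id, names(init$omega[[id]])] <- init$omega[[id]]
  }

  obs <- lapply(subjects, .subject_obs)
  lp_prior_vec <- function(x, tab)
    sum(vapply(seq_len(nrow(tab)),
               function(i) .prior_logdensity(x[[i]], tab[i, ]), 0))
  lp_sigma <- function(s)
    sum(stats::dgamma(s, spec$sigma_prior[1], spec$sigma_prior[2],
                      log = TRUE))

  predict_j <- function(j) {
    ## single-column matrix rows drop their names; restore them explicitly
    ov <- c(as.list(theta),
            as.list(stats::setNames(omega[j, ], colnames(omega))))
    .predict_subject(ov, subjects[[j]], obs[[j]], engine, t_end)
  }
  ll_j <- function(j, pred) .loglik_streams(obs[[j]], pred, sigmas)

  pred <- list(); ll <- numeric(max(J, 1))
  if (use_likelihood) {
    for (j in seq_len(J)) {
      pred[[j]] <- predict_j(j)
      ll[j] <- ll_j(j, pred[[j]])
    }
    if (!all(is.finite(ll)))
      stop("initial state has non-finite likelihood")
  } else ll[] <- 0

  ## proposal scales: fraction of prior range (or of value for sigmas)
  sc_theta <- 0.1; sc_omega <- rep(0.1, max(J, 1)); sc_sigma <- 0.3
  sc_scale <- 0.2; sc_am <- 1
  wg <- (pg$upper - pg$lower); ws <- (ps$upper - ps$lower)
  acc <- list(theta = 0, omega = rep(0, max(J, 1)), sigma = 0, scl = 0)
  try_n <- list(theta = 0, omega = rep(0, max(J, 1)), sigma = 0, scl = 0)
  burn <- floor(burn_frac * iterations)

  n_keep <- if (iterations > 0) floor(iterations / thin) else 0
  cn <- c(if (kg) paste0(pg$name, "|global"),
          if (ks && J) as.vector(outer(ps$name, ids,
                                       function(a, b) paste0(a, "|", b))),
          paste0("sigma_", names(sigmas)), "logpost")
  draws <- matrix(NA_real_, n_keep, length(cn), dimnames = list(NULL, cn))
  keep_row <- 0L
  state_vec <- function(lp) c(if (kg) theta,
                              if (ks && J) as.vector(omega),
                              sigmas, lp)
  logpost <- function() {
    lp_prior_vec(theta, pg) +
      (if (ks && J) sum(vapply(seq_len(J), function(j)
        lp_prior_vec(omega[j, ], ps), 0)) else 0) +
      lp_sigma(sigmas) + sum(ll)
  }

  adapt <- function(sc, rate, batch) {
    step <- min(0.5, 3 / sqrt(batch + 1))
    exp(log(sc) + step * (rate - 0.234))
  }
  batch <- 0L

  ## running moments of theta for covariance-adaptive proposals
  th_n <- 0; th_mean <- theta * 0; th_m2 <- matrix(0, kg, kg)
  th_chol <- NULL

  for (it in seq_len(iterations)) {
    ## --- global block (adaptive Metropolis: empirical-covariance
    ## proposal once enough burn-in draws have accumulated) ---
    if (kg > 0) {
      th_n <- th_n + 1
      dlt <- theta - th_mean
      th_mean <- th_mean + dlt / th_n
      th_m2 <- th_m2 + tcrossprod(dlt, theta - th_mean)
      if (it <= burn && th_n > 10 * kg && it %% 25 == 0) {
        S <- th_m2 / (th_n - 1) * 2.38^2 / kg +
          diag(1e-12 * wg^2, kg)
        th_chol <- tryCatch(chol(S), error = function(e) NULL)
      }
      prop <- if (!is.null(th_chol))
        theta + sc_am * drop(stats::rnorm(kg) %*% th_chol)
      else theta + stats::rnorm(kg, 0, sc_theta * wg)
      lpp <- lp_prior_vec(prop, pg)
      try_n$theta <- try_n$theta + 1
      if (is.finite(lpp)) {
        old_theta <- theta; theta <- stats::setNames(prop, pg$name)
        if (use_likelihood) {
          newpred <- lapply(seq_len(J), function(j)
            tryCatch(predict_j(j), error = function(e) NULL))
          ok <- !any(vapply(newpred, is.null, TRUE))
          newll <- if (ok) vapply(seq_len(J), function(j)
            ll_j(j, newpred[[j]]), 0) else rep(-Inf, J)
        } else { newll <- ll; newpred <- pred; ok <- TRUE }
        lr <- (lpp + sum(newll)) - (lp_prior_vec(old_theta, pg) + sum(ll))
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          ll <- newll; if (use_likelihood) pred <- newpred
          acc$theta <- acc$theta + 1
        } else theta <- old_theta
      }
    }
    ## --- subject blocks ---
    if (ks > 0 && J > 0) {
      for (j in seq_len(J)) {
        prop <- omega[j, ] + stats::rnorm(ks, 0, sc_omega[j] * ws)
        lpp <- lp_prior_vec(prop, ps)
        try_n$omega[j] <- try_n$omega[j] + 1
        if (!is.finite(lpp)) next
        old <- omega[j, ]; omega[j, ] <- prop
        if (use_likelihood) {
          np <- tryCatch(predict_j(j), error = function(e) NULL)
          nl <- if (is.null(np)) -Inf else ll_j(j, np)
        } else { np <- pred[[j]] %||% NULL; nl <- 0 }
        lr <- (lpp + nl) - (lp_prior_vec(old, ps) + ll[j])
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          ll[j] <- nl; if (use_likelihood) pred[[j]] <- np
          acc$omega[j] <- acc$omega[j] + 1
        } else omega[j, ] <- old
      }
    }
    ## --- ridge scale moves (global * m, subject_j / m) ---
    for (mv in scale_moves) {
      gi <- match(mv$global, pg$name); si <- match(mv$subject, ps$name)
      if (is.na(gi) || is.na(si) || J == 0) next
      m <- exp(stats::rnorm(1, 0, sc_scale))
      new_theta <- theta; new_theta[gi] <- theta[gi] * m
      new_omega <- omega; new_omega[, si] <- omega[, si] / m
      lpp <- lp_prior_vec(new_theta, pg) +
        sum(vapply(seq_len(J), function(j)
          lp_prior_vec(new_omega[j, ], ps), 0))
      try_n$scl <- try_n$scl + 1
      if (is.finite(lpp)) {
        old_theta <- theta; old_omega <- omega
        lp_old <- lp_prior_vec(theta, pg) +
          sum(vapply(seq_len(J), function(j)
            lp_prior_vec(omega[j, ], ps), 0))
        theta <- new_theta; omega <- new_omega
        if (use_likelihood) {
          newpred <- lapply(seq_len(J), function(j)
            tryCatch(predict_j(j), error = function(e) NULL))
          ok <- !any(vapply(newpred, is.null, TRUE))
          newll <- if (ok) vapply(seq_len(J), function(j)
            ll_j(j, newpred[[j]]), 0) else rep(-Inf, J)
        } else { newll <- ll; newpred <- pred }
        ## Jacobian of (g, w_1..w_J) -> (g m, w/m) is m^(1-J)
        lr <- (lpp + sum(newll)) - (lp_old + sum(ll)) + (1 - J) * log(m)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          ll <- newll; if (use_likelihood) pred <- newpred
          acc$scl <- acc$scl + 1
        } else { theta <- old_theta; omega <- old_omega }
      }
    }
    ## --- error-SD block (no simulations; cached predictions reused) ---
    prop <- sigmas * exp(stats::rnorm(4, 0, sc_sigma))
    try_n$sigma <- try_n$sigma + 1
    old_s <- sigmas; old_ll <- ll
    sigmas <- prop
    if (use_likelihood)
      ll <- vapply(seq_len(J), function(j) ll_j(j, pred[[j]]), 0)
    ## log-scale proposal: Jacobian term sum(log prop) - sum(log old)
    lr <- (lp_sigma(prop) + sum(ll) + sum(log(prop))) -
          (lp_sigma(old_s) + sum(old_ll) + sum(log(old_s)))
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      acc$sigma <- acc$sigma + 1
    } else { sigmas <- old_s; ll <- old_ll }

    ## --- adaptation during burn-in ---
    if (it <= burn && it %% 25 == 0) {
      batch <- batch + 1L
      if (try_n$theta > 0) {
        if (acc$theta == 0 && batch >= 8 && sc_theta < 1e-6)
          stop("no accepted global moves over the adaptation window")
        rate <- acc$theta / try_n$theta
        if (is.null(th_chol)) sc_theta <- adapt(sc_theta, rate, batch)
        else sc_am <- adapt(sc_am, rate, batch)
      }
      for (j in seq_len(max(J, 1)))
        if (try_n$omega[j] > 0)
          sc_omega[j] <- adapt(sc_omega[j], acc$omega[j] / try_n$omega[j],
                               batch)
      if (try_n$sigma > 0)
        sc_sigma <- adapt(sc_sigma, acc$sigma / try_n$sigma, batch)
      if (try_n$scl > 0)
        sc_scale <- adapt(sc_scale, acc$scl / try_n$scl, batch)
      acc <- list(theta = 0, omega = rep(0, max(J, 1)), sigma = 0, scl = 0)
      try_n <- list(theta = 0, omega = rep(0, max(J, 1)), sigma = 0, scl = 0)
    }
    if (it %% thin == 0) {
      keep_row <- keep_row + 1L
      draws[keep_row, ] <- state_vec(logpost())
    }
  }

  if (n_keep == 0)
    draws <- matrix(state_vec(logpost()), 1, length(cn),
                    dimnames = list(NULL, cn))
  structure(list(draws = draws, iterations = iterations, thin = thin,
                 seed = seed, burn_in = floor(burn / thin), spec = spec,
                 subject_ids = ids,
                 final = list(theta = theta, omega = omega, sigmas = sigmas)),
            class = "dphpk_posterior")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dphpk_posterior <- function(x, ...) {
  cat(sprintf("Posterior sample: %d retained draws (thin %d, %d burn-in rows flagged)\n",
              nrow(x$draws), x$thin, x$burn_in))
  print(utils::head(posterior_summaries(x), 10))
  invisible(x)
}

## retained post-burn-in draw matrix
.post_draws <- function(ps) {
  d <- ps$draws
  if (ps$burn_in > 0 && nrow(d) > ps$burn_in)
    d <- d[-seq_len(ps$burn_in), , drop = FALSE]
  d
}

#' Posterior medians and 95% credible intervals
#'
#' Empirical 2.5th/50th/97.5th percentiles of the retained post-burn-in
#' draws for every sampled parameter.
#'
#' @param ps `dphpk_posterior`.
#' @return data.frame: `parameter`, `median`, `lo2.5`, `hi97.5`.
#' @export
posterior_summaries <- function(ps) {
  stopifnot(inherits(ps, "dphpk_posterior"))
  d <- .post_draws(ps)
  if (nrow(d) < 1) stop("no retained draws")
  cols <- setdiff(colnames(d), "logpost")
  qs <- t(apply(d[, cols, drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.5, 0.975), names = FALSE))
  data.frame(parameter = cols, median = qs[, 2], lo2.5 = qs[, 1],
             hi97.5 = qs[, 3], row.names = NULL)
}

#' Pointwise 95% posterior predictive band for a model output
#'
#' Simulates the subject at each retained (optionally subsampled) draw and
#' reads off per-time-point 2.5th and 97.5th percentiles; the central curve
#' is the highest-posterior draw.
#'
#' @param ps `dphpk_posterior`.
#' @param subj one subject of a `bm_dataset` (element of `ds$subjects`).
#' @param output derived output name (e.g. `"CBloodDPHP"`, `"RUrineOH"`).
#' @param grid output time grid, hours.
#' @param n_draws number of draws to simulate (subsampled evenly).
#' @param engine solver engine.
#' @return data.frame `time`, `lo`, `centre`, `hi`.
#' @export
credible_band <- function(ps, subj, output = "CBloodDPHP",
                          grid = seq(0, 48, 0.5), n_draws = 100,
                          engine = "compiled") {
  stopifnot(inherits(ps, "dphpk_posterior"))
  d <- .post_draws(ps)
  if (nrow(d) < 50)
    warning("fewer than 50 retained draws; band will be ragged")
  idx <- unique(round(seq(1, nrow(d), length.out = min(n_draws, nrow(d)))))
  run_one <- function(row) {
    ov <- .row_overrides(ps, row, subj$id)
    raw <- default_parameters(utils::modifyList(list(BW = subj$BW), ov))
    res <- simulate_pbpk(build_subject(raw,
      exposure_scenario(subj$dose, t_end = max(grid), dt = 0.5)),
      engine = engine, times = grid)
    res$outputs[[output]]
  }
  curves <- vapply(idx, function(i) run_one(d[i, ]), numeric(length(grid)))
  centre <- run_one(d[which.max(d[, "logpost"]), ])
  data.frame(time = grid,
             lo = apply(curves, 1, stats::quantile, 0.025, names = FALSE),
             centre = centre,
             hi = apply(curves, 1, stats::quantile, 0.975, names = FALSE))
}

#' Write a posterior sample as CSV
#'
#' Two files: the retained draws (one column per sampled parameter plus
#' the log-posterior) and the median / 95% credible-interval summary
#' table.
#'
#' @param ps `dphpk_posterior`.
#' @param draws_path CSV path for the draws.
#' @param summary_path CSV path for the summary table.
#' @return invisibly, the summary data.frame.
#' @export
write_posterior <- function(ps, draws_path, summary_path) {
  stopifnot(inherits(ps, "dphpk_posterior"))
  utils::write.csv(as.data.frame(ps$draws), draws_path, row.names = FALSE)
  sm <- posterior_summaries(ps)
  utils::write.csv(sm, summary_path, row.names = FALSE)
  invisible(sm)
}

## overrides (theta + omega_j) encoded in one draw row, for subject `id`
.row_overrides <- function(ps, row, id) {
  nm <- names(row)
  out <- list()
  for (g in ps$spec$global)
    out[[g]] <- row[[paste0(g, "|global")]]
  for (s in ps$spec$subject) {
    key <- paste0(s, "|", id)
    if (key %in% nm) out[[s]] <- row[[key]]
  }
  out
}
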