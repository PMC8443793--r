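## Uncertainty analysis over Latin hypercube designs and two-phase global
## sensitivity analysis: Morris elementary-effects screening, retention of
## the most influential parameters, then variance-based eFAST on the
## retained set.

.check_prior_spec <- function(spec) {
  need <- c("name", "dist", "par1", "par2", "lower", "upper")
  if (!is.data.frame(spec) || !all(need %in% names(spec)))
    stop("prior spec must be a data.frame with columns: ",
         paste(need, collapse = ", "))
  if (!all(spec$dist %in% c("uniform", "normal", "lognormal")))
    stop("unknown distribution tag(s): ",
         paste(setdiff(spec$dist, c("uniform", "normal", "lognormal")),
               collapse = ", "))
  if (any(!is.finite(spec$lower)) || any(!is.finite(spec$upper)) ||
      any(spec$lower >= spec$upper))
    stop("prior bounds must be finite with lower < upper")
  invisible(spec)
}

## quantile transform from the unit cube to the (truncated) priors
.prior_quantile <- function(u, spec) {
  out <- u
  for (j in seq_len(nrow(spec))) {
    s <- spec[j, ]
    out[, j] <- switch(s$dist,
      uniform = s$lower + u[, j] * (s$upper - s$lower),
      normal = {
        plo <- stats::pnorm(s$lower, s$par1, s$par2)
        phi <- stats::pnorm(s$upper, s$par1, s$par2)
        stats::qnorm(plo + u[, j] * (phi - plo), s$par1, s$par2)
      },
      lognormal = {
        plo <- stats::plnorm(s$lower, s$par1, s$par2)
        phi <- stats::plnorm(s$upper, s$par1, s$par2)
        stats::qlnorm(plo + u[, j] * (phi - plo), s$par1, s$par2)
      })
  }
  colnames(out) <- spec$name
  out
}

## prior log-density on native scale (truncated); -Inf outside support
.prior_logdensity <- function(x, s) {
  if (x < s$lower || x > s$upper) return(-Inf)
  switch(s$dist,
    uniform = -log(s$upper - s$lower),
    normal = stats::dnorm(x, s$par1, s$par2, log = TRUE) -
      log(stats::pnorm(s$upper, s$par1, s$par2) -
          stats::pnorm(s$lower, s$par1, s$par2)),
    lognormal = stats::dlnorm(x, s$par1, s$par2, log = TRUE) -
      log(stats::plnorm(s$upper, s$par1, s$par2) -
          stats::plnorm(s$lower, s$par1, s$par2)))
}

#' Independent draws from the parameter priors
#'
#' @param spec prior specification data.frame, see [parameter_priors()].
#' @param n number of draws.
#' @param seed integer seed (draws are reproducible given the seed).
#' @return n x k matrix in native units, columns named by parameter; the
#'   design provenance is recorded in attributes `design` and `seed`.
#' @export
sample_priors <- function(spec = parameter_priors(), n, seed = 1) {
  .check_prior_spec(spec)
  stopifnot(n >= 1)
  set.seed(seed)
  u <- matrix(stats::runif(n * nrow(spec)), nrow = n)
  d <- .prior_quantile(u, spec)
  attr(d, "design") <- "random"
  attr(d, "seed") <- seed
  d
}

#' Maximin Latin hypercube design over the parameter priors
#'
#' One point per equal-probability stratum per dimension, optimised toward
#' maximal minimal inter-point distance, then mapped through the truncated
#' prior quantile functions.
#'
#' @inheritParams sample_priors
#' @param n number of design points (the uncertainty analysis default
#'   is 200).
#' @return n x k design matrix in native units (attributes as in
#'   [sample_priors()]).
#' @export
lhd_maximin <- function(spec = parameter_priors(), n = 200, seed = 1) {
  .check_prior_spec(spec)
  stopifnot(n >= 2)
  set.seed(seed)
  u <- lhs::maximinLHS(n, nrow(spec))
  d <- .prior_quantile(u, spec)
  attr(d, "design") <- "maximin-LHD"
  attr(d, "seed") <- seed
  d
}

#' Metric function for sensitivity/uncertainty batches
#'
#' Builds the closure mapping a named raw-parameter vector (a design row)
#' to the named screening-metric vector of a simulation, holding all other
#' parameters at `base` and dosing per `scen`.
#'
#' @param base raw parameter vector used for parameters not in the design.
#' @param scen exposure scenario.
#' @param engine passed to [simulate_pbpk()].
#' @param atol,rtol solver tolerances.  The defaults are tighter than the
#'   single-simulation defaults because batch runs monitor molar mass
#'   balance across extreme parameter corners, and the residual is pure
#'   integration error.
#' @return function(named numeric) -> named metric vector (NA on failure).
#' @export
pbpk_metric_fun <- function(base = default_parameters(),
                            scen = exposure_scenario(0.738),
                            engine = "compiled",
                            atol = 1e-10, rtol = 1e-7) {
  force(base); force(scen); force(engine); force(atol); force(rtol)
  function(x) {
    p <- build_subject(default_parameters(
      utils::modifyList(as.list(base), as.list(x))), scen)
    res <- simulate_pbpk(p, engine = engine, atol = atol, rtol = rtol)
    list(metrics = extract_metrics(res)$metrics,
         balance = max(abs(res$outputs$balance)) / max(p$extra[["DOSE"]], 1e-12),
         min_state = min(res$states))
  }
}

#' Run the model over a design matrix
#'
#' One simulation per design row; per-row failures are recorded and the
#' batch continues.  Mass balance is monitored for every run, mirroring the
#' uncertainty-analysis practice of checking conservation across the whole
#' tested parameter range.
#'
#' @param design design matrix from [lhd_maximin()] or [sample_priors()]
#'   (columns are raw parameter names).
#' @param scen exposure scenario.
#' @param base raw parameter vector for parameters not varied.
#' @param engine passed to [simulate_pbpk()].
#' @return list of class `dphpk_batch`: `metrics` (n x 18 matrix),
#'   `balance` (max |residual| / dose per run), `min_state`, `ok` (logical),
#'   `errors` (messages for failed rows).
#' @export
run_batch <- function(design, scen = exposure_scenario(0.738),
                      base = default_parameters(), engine = "compiled") {
  fun <- pbpk_metric_fun(base, scen, engine)
  n <- nrow(design)
  metrics <- NULL
  balance <- rep(NA_real_, n)
  min_state <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  errors <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    out <- tryCatch(fun(design[i, ]), error = function(e) e)
    if (inherits(out, "error")) {
      errors[i] <- conditionMessage(out)
      next
    }
    if (is.null(metrics))
      metrics <- matrix(NA_real_, n, length(out$metrics),
                        dimnames = list(NULL, names(out$metrics)))
    metrics[i, ] <- out$metrics
    balance[i] <- out$balance
    min_state[i] <- out$min_state
    ok[i] <- TRUE
  }
  structure(list(metrics = metrics, balance = balance,
                 min_state = min_state, ok = ok, errors = errors,
                 design = design),
            class = "dphpk_batch")
}

#' Morris (elementary effects) screening design
#'
#' Trajectory (winding-stairs) design on the unit cube with `levels`
#' grid levels and step `delta = levels / (2 * (levels - 1))`: `r`
#' trajectories of `k + 1` points each, every parameter perturbed exactly
#' once per trajectory.
#'
#' @param k number of parameters.
#' @param r number of elementary effects per parameter (trajectories).
#' @param levels number of grid levels (even).
#' @param seed integer seed.
#' @return list with `X` (the `r*(k+1)` x k unit-cube design), `traj`,
#'   `param` (index perturbed at each non-base row) and `delta`.
#' @export
morris_design <- function(k, r, levels = 8, seed = 1) {
  stopifnot(k >= 1, r >= 1, levels >= 2)
  set.seed(seed)
  delta <- levels / (2 * (levels - 1))
  base_levels <- (seq_len(levels / 2) - 1) / (levels - 1)  # so x+delta <= 1
  X <- matrix(NA_real_, r * (k + 1), k)
  traj <- integer(r * (k + 1))
  param <- integer(r * (k + 1))   # 0 = trajectory base point
  row <- 0L
  for (tr in seq_len(r)) {
    x <- base_levels[sample.int(length(base_levels), k, replace = TRUE)]
    dirs <- sample(c(-1, 1), k, replace = TRUE)
    ## make sure each step stays inside [0, 1]
    dirs <- ifelse(x + dirs * delta < 0 | x + dirs * delta > 1, -dirs, dirs)
    ord <- sample.int(k)
    row <- row + 1L
    X[row, ] <- x; traj[row] <- tr; param[row] <- 0L
    for (j in ord) {
      x[j] <- x[j] + dirs[j] * delta
      row <- row + 1L
      X[row, ] <- x; traj[row] <- tr; param[row] <- j
    }
  }
  list(X = X, traj = traj, param = param, delta = delta, levels = levels,
       seed = seed)
}

#' Morris elementary-effects screening
#'
#' Runs the model over a trajectory design and summarises, per parameter
#' and metric, the mean absolute elementary effect `mu*` (overall
#' influence) and the standard deviation `sigma` of the elementary effects
#' (non-linearity / interaction).
#'
#' @param fun function mapping a named parameter vector (native units) to a
#'   named numeric metric vector, e.g. from [pbpk_metric_fun()] (whose
#'   richer return value is also understood), or any plain function for
#'   testing.
#' @param spec prior spec (rows define the parameters varied and their
#'   truncated supports).
#' @param r number of elementary effects per parameter.
#' @param levels grid levels.
#' @param seed integer seed.
#' @return object of class `dphpk_morris`: list with matrices `mu_star`
#'   and `sigma` (parameters x metrics), the run count `n_runs`, and the
#'   unit-cube design.
#' @export
morris_screen <- function(fun, spec = parameter_priors(), r = 5,
                          levels = 8, seed = 1) {
  .check_prior_spec(spec)
  stopifnot(r >= 2)
  k <- nrow(spec)
  des <- morris_design(k, r, levels, seed)
  Xn <- .prior_quantile(des$X, spec)
  vals <- NULL
  for (i in seq_len(nrow(Xn))) {
    out <- tryCatch(fun(Xn[i, ]), error = function(e) NULL)
    if (is.list(out) && !is.null(out$metrics)) out <- out$metrics
    if (is.null(vals) && !is.null(out))
      vals <- matrix(NA_real_, nrow(Xn), length(out),
                     dimnames = list(NULL, names(out)))
    if (!is.null(out)) vals[i, ] <- out
  }
  if (is.null(vals)) stop("every screening run failed")
  nm <- ncol(vals)
  ee <- array(NA_real_, c(k, nm, r))
  for (row in seq_len(nrow(Xn))) {
    j <- des$param[row]
    if (j == 0L) next
    ## elementary effect on the unit-cube scale
    step <- des$X[row, j] - des$X[row - 1L, j]
    ee[j, , des$traj[row]] <- (vals[row, ] - vals[row - 1L, ]) / step
  }
  mu_star <- apply(ee, c(1, 2), function(v) mean(abs(v), na.rm = TRUE))
  sigma <- apply(ee, c(1, 2), function(v) stats::sd(v, na.rm = TRUE))
  dimnames(mu_star) <- dimnames(sigma) <- list(spec$name, colnames(vals))
  if (all(mu_star == 0, na.rm = TRUE))
    warning("all elementary effects are zero: constant metric across design")
  structure(list(mu_star = mu_star, sigma = sigma, n_runs = nrow(Xn),
                 r = r, levels = levels, seed = seed, design = des),
            class = "dphpk_morris")
}

#' Retain influential parameters after Morris screening
#'
#' A parameter is retained when, for at least one metric, its `mu*` lies
#' within the stated fraction of that metric's maximum `mu*`.  The default
#' reading is relative (`mu* >= (1 - frac) * max mu*`); the alternative
#' absolute reading on the per-metric normalised scale
#' (`mu*/max >= 1 - frac`, identical here) and the raw absolute rule
#' (`mu* >= max - frac`) are selectable.
#'
#' @param m `dphpk_morris` result.
#' @param frac retention margin (default 0.2).
#' @param rule `"relative"` (default) or `"absolute"`.
#' @return character vector of retained parameter names (union over
#'   metrics), ordered as in the screening spec.
#' @export
retain_parameters <- function(m, frac = 0.2, rule = c("relative", "absolute")) {
  stopifnot(inherits(m, "dphpk_morris"))
  rule <- match.arg(rule)
  ms <- m$mu_star
  keep <- rep(FALSE, nrow(ms))
  for (j in seq_len(ncol(ms))) {
    mx <- max(ms[, j], na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0) next
    keep <- keep | if (rule == "relative") ms[, j] >= (1 - frac) * mx
                   else ms[, j] >= mx - frac
  }
  rownames(ms)[keep]
}

#' eFAST search-curve design
#'
#' For each parameter of interest, `n_per_param` model runs along a
#' space-filling sinusoidal search curve: the parameter of interest is
#' driven at the maximum frequency `omega_max = floor((Ns - 1) / (2 M))`
#' and the complementary set at low frequencies at most
#' `floor(omega_max / (2 M))`, the standard anti-interference choice.
#'
#' @param k number of parameters.
#' @param n_per_param runs per parameter (Ns).
#' @param M interference factor (number of harmonics), default 4.
#' @param seed integer seed for the random phase shifts.
#' @return list with per-parameter unit-cube design blocks `X` (a list of
#'   Ns x k matrices), `omega` (frequency vectors) and `n_runs`.
#' @export
efast_design <- function(k, n_per_param = 1000, M = 4, seed = 1) {
  stopifnot(k >= 3)
  Ns <- n_per_param
  omega_max <- floor((Ns - 1) / (2 * M))
  if (floor(omega_max / (2 * M)) < 1)
    stop("n_per_param too small for M = ", M,
         ": need at least ", 4 * M^2 + 1, " runs per parameter")
  set.seed(seed)
  s <- 2 * pi * (seq_len(Ns) - 1) / Ns
  Xs <- vector("list", k)
  omegas <- vector("list", k)
  maxc <- floor(omega_max / (2 * M))
  for (i in seq_len(k)) {
    omega <- rep_len(seq_len(maxc), k)   # complementary frequencies
    omega[i] <- omega_max
    phi <- stats::runif(k, 0, 2 * pi)
    X <- matrix(NA_real_, Ns, k)
    for (j in seq_len(k))
      X[, j] <- 0.5 + asin(sin(omega[j] * s + phi[j])) / pi
    Xs[[i]] <- X
    omegas[[i]] <- omega
  }
  list(X = Xs, omega = omegas, M = M, n_per_param = Ns,
       n_runs = k * Ns, seed = seed)
}

#' Extended Fourier Amplitude Sensitivity Test (eFAST)
#'
#' Spectral estimation of first-order (`Si`) and total (`STi`) sensitivity
#' indices per parameter and metric over the truncated priors.
#'
#' @inheritParams morris_screen
#' @param n_per_param model runs per parameter.
#' @param M interference factor.
#' @return object of class `dphpk_efast`: list with matrices `Si`, `STi`
#'   (parameters x metrics) and the total run count `n_runs`.
#' @export
efast <- function(fun, spec, n_per_param = 1000, M = 4, seed = 1) {
  .check_prior_spec(spec)
  k <- nrow(spec)
  des <- efast_design(k, n_per_param, M, seed)
  Ns <- des$n_per_param
  Si <- STi <- NULL
  for (i in seq_len(k)) {
    Xn <- .prior_quantile(des$X[[i]], spec)
    vals <- NULL
    for (rr in seq_len(Ns)) {
      out <- tryCatch(fun(Xn[rr, ]), error = function(e) NULL)
      if (is.list(out) && !is.null(out$metrics)) out <- out$metrics
      if (is.null(vals) && !is.null(out))
        vals <- matrix(NA_real_, Ns, length(out),
                       dimnames = list(NULL, names(out)))
      if (!is.null(out)) vals[rr, ] <- out
    }
    if (is.null(vals)) stop("every eFAST run failed")
    if (is.null(Si)) {
      Si <- matrix(NA_real_, k, ncol(vals),
                   dimnames = list(spec$name, colnames(vals)))
      STi <- Si
    }
    omega_i <- des$omega[[i]][i]
    cutoff <- omega_i / 2          # everything below: complementary block
    for (mcol in seq_len(ncol(vals))) {
      y <- vals[, mcol]
      if (anyNA(y)) next
      sp <- Mod(stats::fft(y - mean(y)) / Ns)^2
      ## one-sided spectrum over frequencies 1 .. floor((Ns-1)/2)
      nf <- floor((Ns - 1) / 2)
      A <- 2 * sp[2:(nf + 1)]
      V <- sum(A)
      if (V <= 0) { Si[i, mcol] <- 0; STi[i, mcol] <- 0; next }
      harm <- (1:M) * omega_i
      harm <- harm[harm <= nf]
      Si[i, mcol] <- sum(A[harm]) / V
      Vlow <- sum(A[seq_len(min(floor(cutoff), nf))])
      STi[i, mcol] <- 1 - Vlow / V
    }
  }
  structure(list(Si = Si, STi = STi, n_runs = des$n_runs, M = M,
                 n_per_param = Ns, seed = seed),
            class = "dphpk_efast")
}
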