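## Synthetic six-volunteer biomonitoring datasets with the statistical
## structure the calibration assumes: simulate each subject at known
## ("truth") parameters, then observe blood concentrations and urine-void
## concentrations through zero-truncated normal error models.

#' Study design for synthetic biomonitoring data
#'
#' Defaults emulate the six-volunteer single-oral-dose study: body weights
#' 74-108 kg, doses 0.639-0.783 mg/kg, sampling over 48 h.  The blood
#' schedule is dense early (0.5 h steps to 4 h, to resolve the absorption
#' phase and the early MPHP peak) then sparse; urine voids arrive with
#' uniform 2-4 h gaps so ~8 h recirculation harmonics stay resolvable.
#' Noise SDs default to the calibrated error-model scale.
#'
#' @param volunteers data.frame with columns `volunteer`, `BW`, `dose`
#'   (and optionally per-subject `FracMetabOH`, `FracMetabcx`).
#' @param blood_times blood sampling schedule, h.
#' @param void_gap range (h) of uniform inter-void gaps.
#' @param void_volume range (mL) of uniform void volumes.
#' @param horizon last observation time, h.
#' @param sigmas named noise SDs: `DPHP`, `MPHP` (mg/L), `OH`, `cx` (mg/h).
#' @param exclude volunteer ids flagged as excluded from calibration
#'   (dataset-level flag; data are still generated).
#' @return list of class `dphpk_design`.
#' @export
study_design <- function(volunteers = volunteer_table(),
                         blood_times = c(seq(0.5, 4, by = 0.5),
                                         6, 8, 12, 24, 36, 48),
                         void_gap = c(2, 4),
                         void_volume = c(100, 400),
                         horizon = 48,
                         sigmas = c(DPHP = 0.018, MPHP = 0.019,
                                    OH = 0.01, cx = 0.0005),
                         exclude = character()) {
  stopifnot(all(c("volunteer", "BW", "dose") %in% names(volunteers)),
            all(sigmas > 0), length(void_gap) == 2, void_gap[1] > 0)
  if (max(blood_times) > horizon)
    stop("blood schedule extends beyond the horizon")
  structure(list(volunteers = volunteers, blood_times = blood_times,
                 void_gap = void_gap, void_volume = void_volume,
                 horizon = horizon, sigmas = sigmas, exclude = exclude),
            class = "dphpk_design")
}

#' Draw subject-specific parameters around a shared truth
#'
#' Holds the global parameter values fixed and draws the named
#' subject-specific parameters independently from their truncated priors,
#' one set per volunteer; used to create the ground truth for
#' parameter-recovery experiments.
#'
#' @param base named list/vector of raw-parameter overrides shared by all
#'   subjects (the global truth).
#' @param subject_params character vector of parameter names drawn per
#'   subject (empty: all subjects share `base`).
#' @param n number of subjects.
#' @param priors prior table.
#' @param seed integer seed.
#' @return list of length `n` of named override lists; the drawn values
#'   are also returned as a matrix in attribute `truth_table`.
#' @export
perturb_truth <- function(base = list(), subject_params = character(),
                          n = 6, priors = parameter_priors(), seed = 1) {
  out <- replicate(n, as.list(base), simplify = FALSE)
  tab <- NULL
  if (length(subject_params)) {
    spec <- priors[match(subject_params, priors$name), , drop = FALSE]
    if (anyNA(spec$name))
      stop("no prior for: ",
           paste(subject_params[is.na(spec$name)], collapse = ", "))
    draws <- sample_priors(spec, n, seed)
    tab <- draws
    for (i in seq_len(n))
      out[[i]] <- utils::modifyList(out[[i]],
                                    as.list(draws[i, , drop = TRUE]))
  }
  attr(out, "truth_table") <- tab
  out
}

#' Generate a synthetic biomonitoring dataset
#'
#' Simulates every subject at its truth parameters and observes: blood
#' DPHP/MPHP concentrations at the design schedule through zero-truncated
#' normal errors; urine voids at random gaps, with the void concentration
#' derived from a noisy interval deposition rate and the drawn void volume
#' (so that [urine_rates()] inverts the construction exactly at zero
#' noise).
#'
#' @param design `dphpk_design` from [study_design()].
#' @param truth per-subject raw-parameter override lists, e.g. from
#'   [perturb_truth()]; recycled if a single list is given.
#' @param seed integer seed.
#' @param noise_scale multiplier on the design noise SDs (0 gives
#'   noise-free observations equal to the model predictions).
#' @param engine solver engine.
#' @return object of class `bm_dataset`; the per-subject truth is stored
#'   in attribute `truth`.
#' @export
generate_dataset <- function(design = study_design(), truth = list(list()),
                             seed = 1, noise_scale = 1,
                             engine = "compiled") {
  stopifnot(inherits(design, "dphpk_design"))
  set.seed(seed)
  vols <- design$volunteers
  n <- nrow(vols)
  if (length(truth) == 1L) truth <- rep(truth, n)
  stopifnot(length(truth) == n)
  sg <- design$sigmas * noise_scale

  rztnorm <- function(m, sd) {
    if (sd <= 0) return(pmax(m, 0))
    lo <- stats::pnorm(0, m, sd)
    stats::qnorm(stats::runif(length(m), lo, 1), m, sd)
  }

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    id <- vols$volunteer[i]
    ov <- as.list(truth[[i]])
    if ("FracMetabOH" %in% names(vols) && is.null(ov$FracMetabOH))
      ov$FracMetabOH <- vols$FracMetabOH[i]
    if ("FracMetabcx" %in% names(vols) && is.null(ov$FracMetabcx))
      ov$FracMetabcx <- vols$FracMetabcx[i]
    raw <- default_parameters(utils::modifyList(list(BW = vols$BW[i]), ov))
    scen <- exposure_scenario(vols$dose[i], t_end = design$horizon, dt = 0.1)
    res <- simulate_pbpk(build_subject(raw, scen), engine = engine)
    o <- res$outputs

    bt <- design$blood_times
    blood <- data.frame(
      time = bt,
      CBloodDPHP = rztnorm(stats::approx(o$time, o$CBloodDPHP, bt)$y,
                           sg[["DPHP"]]),
      CBloodMPHP = rztnorm(stats::approx(o$time, o$CBloodMPHP, bt)$y,
                           sg[["MPHP"]]))

    ## urine voids: random gaps; observe interval mean deposition rate
    ## with truncated-normal error, then back out the void concentration
    tv <- c()
    t_cur <- 0
    repeat {
      t_cur <- t_cur + stats::runif(1, design$void_gap[1], design$void_gap[2])
      if (t_cur > design$horizon) break
      tv <- c(tv, t_cur)
    }
    vol_ml <- stats::runif(length(tv), design$void_volume[1],
                           design$void_volume[2])
    gaps <- diff(c(0, tv))
    cum_oh <- stats::approx(o$time, res$states[, "UOH"], c(0, tv))$y
    cum_cx <- stats::approx(o$time, res$states[, "Ucx"], c(0, tv))$y
    rate_oh <- rztnorm(diff(cum_oh) / gaps, sg[["OH"]])
    rate_cx <- rztnorm(diff(cum_cx) / gaps, sg[["cx"]])
    urine <- data.frame(
      time = tv, volume = vol_ml,
      conc_OH = rate_oh * gaps / (vol_ml / 1000),
      conc_cx = rate_cx * gaps / (vol_ml / 1000))

    subjects[[i]] <- list(id = id, BW = vols$BW[i], dose = vols$dose[i],
                          blood = blood, urine = urine,
                          exclude = id %in% design$exclude)
  }
  names(subjects) <- vols$volunteer
  structure(list(subjects = subjects, seed = seed, design = design),
            class = "bm_dataset", truth = truth)
}

#' @export
print.bm_dataset <- function(x, ...) {
  cat(sprintf("Biomonitoring dataset: %d subjects\n", length(x$subjects)))
  for (s in x$subjects)
    cat(sprintf("  %s: BW %.0f kg, dose %.3f mg/kg, %d blood samples, %d voids%s\n",
                s$id, s$BW, s$dose, nrow(s$blood), nrow(s$urine),
                if (isTRUE(s$exclude)) " [excluded]" else ""))
  invisible(x)
}

#' Write a biomonitoring dataset as CSV
#'
#' Long format with the column dictionary `subject, stream, time_h, value,
#' unit, volume_ml`.  Streams: `blood_DPHP`, `blood_MPHP` (mg/L),
#' `urine_OH`, `urine_cx` (mg/L with the void volume), plus per-subject
#' `meta_BW` (kg), `meta_dose` (mg/kg) and `meta_exclude` rows.
#'
#' @param ds `bm_dataset`.
#' @param path output CSV path.
#' @return invisibly, the data.frame written.
#' @export
write_bm_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "bm_dataset"))
  rows <- list()
  for (s in ds$subjects) {
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s$id,
      stream = c("meta_BW", "meta_dose", "meta_exclude"),
      time_h = 0, value = c(s$BW, s$dose, as.numeric(isTRUE(s$exclude))),
      unit = c("kg", "mg/kg", "flag"), volume_ml = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s$id, stream = "blood_DPHP", time_h = s$blood$time,
      value = s$blood$CBloodDPHP, unit = "mg/L", volume_ml = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s$id, stream = "blood_MPHP", time_h = s$blood$time,
      value = s$blood$CBloodMPHP, unit = "mg/L", volume_ml = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s$id, stream = "urine_OH", time_h = s$urine$time,
      value = s$urine$conc_OH, unit = "mg/L", volume_ml = s$urine$volume)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s$id, stream = "urine_cx", time_h = s$urine$time,
      value = s$urine$conc_cx, unit = "mg/L", volume_ml = s$urine$volume)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read a biomonitoring dataset from CSV
#'
#' Inverse of [write_bm_dataset()].
#'
#' @param path CSV path in the declared column dictionary.
#' @return `bm_dataset`.
#' @export
read_bm_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "stream", "time_h", "value", "unit", "volume_ml")
  if (!all(need %in% names(d)))
    stop("dataset file must have columns: ", paste(need, collapse = ", "))
  subjects <- lapply(split(d, d$subject), function(ds) {
    gv <- function(stream) ds[ds$stream == stream, , drop = FALSE]
    bD <- gv("blood_DPHP"); bM <- gv("blood_MPHP")
    uO <- gv("urine_OH"); ucx <- gv("urine_cx")
    if (!identical(bD$time_h, bM$time_h) ||
        !identical(uO$time_h, ucx$time_h))
      stop("blood (or urine) streams have mismatched time grids for subject ",
           ds$subject[1])
    list(id = ds$subject[1],
         BW = gv("meta_BW")$value[1],
         dose = gv("meta_dose")$value[1],
         blood = data.frame(time = bD$time_h, CBloodDPHP = bD$value,
                            CBloodMPHP = bM$value),
         urine = data.frame(time = uO$time_h, volume = uO$volume_ml,
                            conc_OH = uO$value, conc_cx = ucx$value),
         exclude = isTRUE(gv("meta_exclude")$value[1] > 0))
  })
  ord <- order(names(subjects))
  structure(list(subjects = subjects[ord], seed = NA, design = NULL),
            class = "bm_dataset")
}
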