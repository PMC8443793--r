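#' Molecular weights used for mole conversion
#'
#' Named vector of molecular weights (g/mol) for the parent diester DPHP,
#' its monoester MPHP and the three second-order metabolites measured in
#' urine.  These are standard formula weights (DPHP C28H46O4, MPHP C18H26O4,
#' OH-MPHP C18H26O5, cx-MPHP C18H24O6, oxo-MPHP C18H24O5) and can be
#' overridden wherever a function takes an `mw` argument.
#'
#' @export
dphp_mw <- c(
  DPHP     = 446.66,
  MPHP     = 306.40,
  OH_MPHP  = 322.40,
  cx_MPHP  = 336.38,
  oxo_MPHP = 320.38
)

#' Default tissue:blood partition coefficients
#'
#' Partition coefficients for DPHP and MPHP predicted from log Pow by
#' tissue-composition algorithms (inputs to this package, not computed here).
#' Stomach, rapidly and slowly perfused tissues take surrogate values from
#' gut, spleen and muscle respectively; the blood-cells entry doubles as the
#' red-cell:plasma ratio used in the well-stirred clearance model.
#'
#' @return data.frame with columns `tissue`, `DPHP`, `MPHP` and a logical
#'   `surrogate` column naming borrowed values.
#' @export
partition_defaults <- function() {
  data.frame(
    tissue = c("adipose", "liver", "muscle", "blood_cells", "gut", "spleen",
               "stomach", "rapidly_perfused", "slowly_perfused"),
    DPHP = c(63.4, 5.89, 3.29, 3.01, 7.4, 3.7, 7.4, 3.7, 3.29),
    MPHP = c(29.10, 54.8, 7.51, 6.67, 25.2, 12.20, 25.2, 12.20, 7.51),
    surrogate = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Six-volunteer oral-dose study design values
#'
#' Body weights, administered single oral doses and measured fractions of
#' MPHP metabolised to cx- and OH-MPHP for the six male volunteers of the
#' oral-dose biomonitoring study emulated by the synthetic-data generator.
#'
#' @return data.frame with one row per volunteer (A-F).
#' @export
volunteer_table <- function() {
  data.frame(
    volunteer = c("A", "B", "C", "D", "E", "F"),
    BW = c(83, 75, 76, 74, 90, 108),
    dose = c(0.717, 0.639, 0.781, 0.783, 0.775, 0.733),
    FracMetabcx = c(0.02, 0.017, 0.02, 0.023, 0.018, 0.018),
    FracMetabOH = c(0.396, 0.340, 0.374, 0.359, 0.334, 0.329),
    stringsAsFactors = FALSE
  )
}

#' Baseline (default) model parameters
#'
#' The complete raw parameter set for one simulated subject: physiology
#' (fractional organ masses as % body weight, fractional blood flows as
#' % cardiac output), metabolic half-lives, absorption/elimination rates,
#' binding, dose fractionation, lag times and tissue:blood partition
#' coefficients.  Units follow the table conventions of the source data:
#' organ masses in % BW (except `VT`, a fraction), flows in % cardiac
#' output, half-lives in minutes, first-order rates in 1/h, lags in hours.
#'
#' Two conventions deserve emphasis:
#' \itemize{
#'   \item `fuDPHP`/`fuMPHP` are plasma \emph{unbound} fractions; the bound
#'     fraction is `1 - fu`.  Very small values (high binding) hold chemical
#'     in plasma and slow both distribution and metabolism.
#'   \item Cardiac output is `QCC * BW^0.75` L/h (allometric scaling).
#' }
#'
#' @param overrides named list or vector of parameter values replacing
#'   defaults.  Unknown names are an error.
#' @return named numeric vector of class `dphpk_raw_params`.
#' @examples
#' p <- default_parameters(list(BW = 83))
#' p[["BW"]]
#' @export
default_parameters <- function(overrides = NULL) {
  pc <- partition_defaults()
  pcv <- function(chem, tis) pc[[chem]][match(tis, pc$tissue)]
  p <- c(
    ## physiology
    BW = 72.3, VT = 0.95,
    VLiC = 3.09, VFaC = 19.5, VGuC = 1.50, VStC = 0.22,
    VSpdC = 60.7, VRpdC = 3.71, VBldC = 5.0, VLymphC = 0.36,
    QCC = 14,
    QHepartC = 6.0, QFaC = 5.0, QGuC = 14.9, QStC = 1.1,
    QSpdC = 27.0, QRpdC = 42.0, QLymphC = 0.04,
    ## metabolic clearance (minutes; in vitro protocol ratio mL/mg)
    ThalfDPHP = 3, ThalfMPHP = 8.05, ThalfDPHPgut = 60,
    incubation_ratio = 2,
    MPY = 34, MPYgut = 3.9,
    ## plasma unbound fractions (see Details)
    fuDPHP = 0.0025, fuMPHP = 0.0146,
    ## gastric emptying and absorption
    kmax = 10.2, kmin = 0.005, tau_ge = 1,
    kGa = 25.1, DRINKTIME = 0.25,
    BELLYPERM = 0.685, GIPERM = 5.1,
    BELLYPERMLymph = 0.685, GIPERMLymph = 5.1,
    K1Lymph = 0.2,
    FracDOSEHep = 0.1, FracDOSELymph = 0.05,
    ## enterohepatic recirculation and faecal loss
    k1_DPHP_gut = 0.1, k1_MPHP_gut = 0.1,
    k1_DPHP_liver = 10, k1_MPHP_liver = 1,
    ## MPHP metabolite fate and urinary elimination
    FracMetabOH = 0.36, FracMetabcx = 0.02,
    K1_MOH = 0.1, K1_cx = 0.1,
    ## lags (hours)
    Gutlag = 0.5, Lymphlag = 2, Bilelag = 6,
    ## tissue:blood partition coefficients
    PfaD = pcv("DPHP", "adipose"), PliD = pcv("DPHP", "liver"),
    PspdD = pcv("DPHP", "slowly_perfused"), PrpdD = pcv("DPHP", "rapidly_perfused"),
    PguD = pcv("DPHP", "gut"), PbaD = pcv("DPHP", "blood_cells"),
    PfaM = pcv("MPHP", "adipose"), PliM = pcv("MPHP", "liver"),
    PspdM = pcv("MPHP", "slowly_perfused"), PrpdM = pcv("MPHP", "rapidly_perfused"),
    PguM = pcv("MPHP", "gut"), PbaM = pcv("MPHP", "blood_cells")
  )
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    bad <- setdiff(names(overrides), names(p))
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    p[names(overrides)] <- overrides
  }
  class(p) <- c("dphpk_raw_params", "numeric")
  p
}

#' Prior / uncertainty distributions for the 59 varied parameters
#'
#' One row per parameter varied in the uncertainty, sensitivity and
#' calibration analyses.  `dist` is one of `"normal"`, `"lognormal"`,
#' `"uniform"`; normal and lognormal laws are truncated at their 5th and
#' 95th percentiles, uniforms at their bounds.  The table preserves two
#' documented inconsistencies of the source values verbatim rather than
#' resolving them: `GIPERM` has default 5.1 but distribution U(0.1, 0.3),
#' and the half-life defaults (DPHP 3 min, MPHP 8.05 min) sit outside their
#' stated distributions (U(15, 60) and N(30.54, 2.39)).
#'
#' @return data.frame with columns `name`, `dist`, `par1`, `par2`,
#'   `lower`, `upper` (truncation bounds in native units).
#' @export
parameter_priors <- function() {
  u <- function(name, a, b) data.frame(name = name, dist = "uniform",
                                       par1 = a, par2 = b)
  n <- function(name, m, s) data.frame(name = name, dist = "normal",
                                       par1 = m, par2 = s)
  ln <- function(name, ml, sl) data.frame(name = name, dist = "lognormal",
                                          par1 = ml, par2 = sl)
  pc_u <- function(name, def) u(name, def / 5, def * 5)
  pd <- default_parameters()
  tab <- rbind(
    n("BW", 72.3, 9.05),
    n("VLiC", 3.09, 0.8), ln("VFaC", 3.42, 0.43), u("VGuC", 1.19, 1.84),
    n("VStC", 0.22, 0.07), n("VSpdC", 60.7, 9.4), n("VRpdC", 3.7, 0.26),
    u("VBldC", 2.5, 10), u("VLymphC", 0.18, 0.72),
    n("QCC", 13.8, 2.5),
    n("QHepartC", 6.89, 0.52), n("QFaC", 5.3, 0.3), u("QGuC", 13.2, 16.6),
    n("QStC", 1.1, 0.08), n("QSpdC", 28.7, 1.91), n("QRpdC", 43.1, 2.78),
    u("QLymphC", 0.02, 0.08),
    u("ThalfDPHP", 15, 60), n("ThalfMPHP", 30.54, 2.39),
    u("ThalfDPHPgut", 15, 60),
    u("k1_DPHP_gut", 0.05, 0.15), u("k1_MPHP_gut", 0.05, 0.15),
    u("k1_DPHP_liver", 5, 15), u("k1_MPHP_liver", 0.5, 1.5),
    n("MPY", 34, 5), u("MPYgut", 1.95, 7.8),
    u("fuDPHP", 1e-5, 0.01), u("fuMPHP", 0.001, 0.01),
    u("kmax", 5.1, 20.4), u("kmin", 0.0025, 0.01),
    u("kGa", 12.55, 50.2), u("DRINKTIME", 0.125, 0.5),
    u("BELLYPERM", 0.34, 0.99), u("GIPERM", 0.1, 0.3),
    u("BELLYPERMLymph", 0.34, 0.99), u("GIPERMLymph", 2.6, 7.6),
    u("K1Lymph", 0.1, 0.3),
    u("FracDOSEHep", 0.01, 0.2), u("FracDOSELymph", 0.002, 0.1),
    u("FracMetabOH", 0.2, 0.45), u("FracMetabcx", 0.005, 0.03),
    u("K1_MOH", 0.05, 0.15), u("K1_cx", 0.05, 0.15),
    u("Gutlag", 0.1, 2), u("Lymphlag", 0.5, 6), u("Bilelag", 3, 9),
    u("tau_ge", 0.5, 2),
    pc_u("PfaD", pd[["PfaD"]]), pc_u("PliD", pd[["PliD"]]),
    pc_u("PspdD", pd[["PspdD"]]), pc_u("PrpdD", pd[["PrpdD"]]),
    pc_u("PguD", pd[["PguD"]]), pc_u("PbaD", pd[["PbaD"]]),
    pc_u("PfaM", pd[["PfaM"]]), pc_u("PliM", pd[["PliM"]]),
    pc_u("PspdM", pd[["PspdM"]]), pc_u("PrpdM", pd[["PrpdM"]]),
    pc_u("PguM", pd[["PguM"]]), pc_u("PbaM", pd[["PbaM"]])
  )
  ## truncation bounds: 5th/95th percentiles for (log)normals, support for U
  tab$lower <- NA_real_
  tab$upper <- NA_real_
  isu <- tab$dist == "uniform"
  tab$lower[isu] <- tab$par1[isu]
  tab$upper[isu] <- tab$par2[isu]
  isn <- tab$dist == "normal"
  tab$lower[isn] <- stats::qnorm(0.05, tab$par1[isn], tab$par2[isn])
  tab$upper[isn] <- stats::qnorm(0.95, tab$par1[isn], tab$par2[isn])
  isl <- tab$dist == "lognormal"
  tab$lower[isl] <- stats::qlnorm(0.05, tab$par1[isl], tab$par2[isl])
  tab$upper[isl] <- stats::qlnorm(0.95, tab$par1[isl], tab$par2[isl])
  rownames(tab) <- NULL
  tab
}

#' Posterior median global parameter values from the calibrated model
#'
#' Published posterior medians for the calibrated global parameters,
#' re-expressed in this package's parameterisation (unbound fractions
#' `fu = 1 - FB`; half-lives in minutes; partition coefficients named by
#' tissue and chemical).  Useful as a plug-in "calibrated" parameter set for
#' qualitative route-comparison and peak-ordering simulations.
#'
#' @return named numeric vector of raw-parameter overrides.
#' @export
calibrated_medians <- function() {
  c(
    fuDPHP = 1 - 0.991, fuMPHP = 1 - 0.975,
    ThalfDPHPgut = 56.80, ThalfDPHP = 4.38,
    PbaD = 22.92, PguD = 20, PliD = 4.22,
    PbaM = 31.84, PliM = 14.92, PguM = 38.57,
    K1_MOH = 0.973, K1_cx = 0.778,
    FracMetabOH = 0.24, FracMetabcx = 0.011,
    k1_DPHP_liver = 3.09, k1_MPHP_liver = 0.9,
    k1_DPHP_gut = 0.3, k1_MPHP_gut = 0.4
  )
}
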