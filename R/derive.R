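## In vitro / in silico parameter derivation:
## substrate-depletion half-life -> intrinsic clearance -> whole-organ
## clearance (well-stirred model), plus fraction unbound from log Pow and
## fractions metabolised from molar metabolite recoveries.

#' Half-life from a first-order decay constant
#'
#' @param k decay constant (1/min), strictly positive.
#' @return half-life in minutes, `ln(2)/k`.
#' @export
calc_half_life <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0))
    stop("decay constant k must be finite and > 0")
  log(2) / k
}

#' In vitro intrinsic clearance from substrate-depletion half-life
#'
#' Converts a microsomal substrate-depletion half-life into an intrinsic
#' clearance per mg microsomal protein, using the incubation volume to
#' protein-mass ratio of the assay (2 mL/mg at the protocol protein
#' concentration of 0.5 mg/mL).
#'
#' @param t_half half-life in minutes (or `NULL` to derive from `k`).
#' @param incubation_volume incubation volume, mL.
#' @param microsomal_protein microsomal protein in the incubation, mg.
#' @param k optional decay constant (1/min); exactly one of `k`, `t_half`
#'   must be supplied, and if both are, they must satisfy `k*t_half = ln 2`.
#' @return intrinsic clearance, mL/min/mg protein.
#' @export
calc_clint_invitro <- function(t_half = NULL, incubation_volume = 1,
                               microsomal_protein = 0.5, k = NULL) {
  if (is.null(t_half) && is.null(k))
    stop("supply t_half or k")
  if (!is.null(k)) {
    th_k <- calc_half_life(k)
    if (!is.null(t_half) &&
        abs(k * t_half - log(2)) > 1e-9 * log(2))
      stop("inconsistent k and t_half: k*t_half must equal ln(2)")
    t_half <- th_k
  }
  if (any(t_half <= 0)) stop("t_half must be > 0")
  if (any(incubation_volume <= 0)) stop("incubation_volume must be > 0")
  if (any(microsomal_protein <= 0)) stop("microsomal_protein must be > 0")
  (log(2) / t_half) * (incubation_volume / microsomal_protein)
}

#' Scale in vitro intrinsic clearance to the whole organ
#'
#' Multiplies the per-mg-protein in vitro clearance by the microsomal
#' protein yield (mg protein per g tissue) and the tissue mass, converting
#' minutes to hours and mL to L.  Applies to liver (hepatic yield, liver
#' mass) and, with the gut yield and gut mass substituted, to the gut wall.
#'
#' @param cl_invitro intrinsic clearance, mL/min/mg protein.
#' @param mpy microsomal protein yield, mg/g tissue.
#' @param tissue_mass tissue mass, g.
#' @return whole-organ intrinsic clearance, L/h.
#' @export
scale_clint <- function(cl_invitro, mpy, tissue_mass) {
  if (any(cl_invitro < 0) || any(mpy < 0) || any(tissue_mass < 0))
    stop("clearance scaling inputs must be non-negative")
  cl_invitro * mpy * tissue_mass * 60 / 1000
}

#' Well-stirred organ clearance
#'
#' The well-stirred (venous equilibration) model of organ clearance,
#' accounting for the plasma unbound fraction and the red-cell:plasma
#' concentration ratio:
#' `CL = Q * fu * CLint / (Q + fu * CLint / R)`.
#'
#' @param clint whole-organ intrinsic clearance, L/h.
#' @param Q organ blood flow, L/h.
#' @param fu plasma fraction unbound, in (0, 1].
#' @param R red blood cell to plasma concentration ratio (> 0).
#' @return organ clearance, L/h; bounded above by both `Q*R` and `fu*clint`.
#' @export
calc_well_stirred_clearance <- function(clint, Q, fu, R) {
  if (any(Q <= 0)) stop("organ blood flow Q must be > 0")
  if (any(R <= 0)) stop("red cell:plasma ratio R must be > 0")
  if (any(fu <= 0) || any(fu > 1)) stop("fu must be in (0, 1]")
  if (any(clint < 0)) stop("clint must be >= 0")
  Q * fu * clint / (Q + fu * clint / R)
}

#' Fraction unbound in plasma predicted from log Pow
#'
#' Empirical regression for chemicals predominantly uncharged at pH 7.4:
#' `fu = 1 / (10^x + 1)` with `x = 0.4485*logP - 0.4782`.  Strictly
#' decreasing in logP and maps the real line onto (0, 1).  Note that for
#' extremely lipophilic chemicals the regression extrapolates far outside
#' its calibration range and predicts smaller unbound fractions than the
#' packaged defaults, which are taken from published algorithm output.
#'
#' @param logP octanol-water log partition coefficient.
#' @return fraction unbound, in (0, 1).
#' @export
calc_fraction_unbound <- function(logP) {
  if (any(!is.finite(logP))) stop("logP must be finite")
  x <- 0.4485 * logP - 0.4782
  1 / (10^x + 1)
}

#' Fractions of MPHP metabolised to OH- and cx-MPHP
#'
#' Expresses each measured metabolite in moles and divides the OH- and
#' cx-MPHP amounts by the molar sum over all four measured metabolites
#' (MPHP, OH-MPHP, cx-MPHP, oxo-MPHP).
#'
#' @param amounts named vector of amounts with names `MPHP`, `OH_MPHP`,
#'   `cx_MPHP`, `oxo_MPHP`.  Interpreted as moles when `mw` is `NULL`,
#'   otherwise as masses divided by the matching molecular weights.
#' @param mw optional named molecular-weight vector (see [dphp_mw]).
#' @return named vector `c(FracMetabOH =, FracMetabcx =)`.
#' @export
calc_fraction_metabolised <- function(amounts, mw = NULL) {
  need <- c("MPHP", "OH_MPHP", "cx_MPHP", "oxo_MPHP")
  if (!all(need %in% names(amounts)))
    stop("amounts must be named with: ", paste(need, collapse = ", "))
  a <- amounts[need]
  if (any(a < 0)) stop("metabolite amounts must be >= 0")
  if (!is.null(mw)) a <- a / mw[need]
  tot <- sum(a)
  if (tot <= 0) stop("total metabolite amount must be > 0")
  c(FracMetabOH = unname(a[["OH_MPHP"]] / tot),
    FracMetabcx = unname(a[["cx_MPHP"]] / tot))
}

#' Write a derived-parameter report
#'
#' Flat key/value/units CSV of the kinetic parameters derived from in vitro
#' and in silico inputs for one subject.
#'
#' @param params a built subject parameter set from [build_subject()].
#' @param path output CSV path.
#' @return the report data.frame, invisibly.
#' @export
write_parameter_report <- function(params, path) {
  stopifnot(inherits(params, "dphpk_params"))
  d <- c(params$derived, params$extra)
  rep <- data.frame(
    key = c("CLint_H_DPHP", "CL_H_DPHP", "CLint_gut_DPHP", "CL_gut_DPHP",
            "CLint_H_MPHP", "CL_H_MPHP", "QC", "Q_liver_total", "V_liver"),
    value = c(d[["clint_h_D"]], d[["CLH_ws_D"]], d[["clint_gut_D"]],
              d[["CLgut_ws_D"]], d[["clint_h_M"]], d[["CLH_ws_M"]],
              d[["QC"]], d[["QliT"]], d[["Vli"]]),
    units = c("L/h", "L/h", "L/h", "L/h", "L/h", "L/h", "L/h", "L/h", "L"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(rep, path, row.names = FALSE)
  invisible(rep)
}
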