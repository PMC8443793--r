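## Flat parameter configuration files: key,value,units CSV using the same
## parameter names as the published table (FracDOSEHep, K1Lymph, ...), so
## the table can be grepped against the config line by line.

.param_units <- c(
  BW = "kg", VT = "fraction BW",
  VLiC = "% BW", VFaC = "% BW", VGuC = "% BW", VStC = "% BW",
  VSpdC = "% BW", VRpdC = "% BW", VBldC = "% BW", VLymphC = "% BW",
  QCC = "L/h/kg^0.75",
  QHepartC = "% CO", QFaC = "% CO", QGuC = "% CO", QStC = "% CO",
  QSpdC = "% CO", QRpdC = "% CO", QLymphC = "% CO",
  ThalfDPHP = "min", ThalfMPHP = "min", ThalfDPHPgut = "min",
  incubation_ratio = "mL/mg",
  MPY = "mg/g", MPYgut = "mg/g",
  fuDPHP = "fraction unbound", fuMPHP = "fraction unbound",
  kmax = "1/h", kmin = "1/h", tau_ge = "h",
  kGa = "1/h", DRINKTIME = "h",
  BELLYPERM = "1/h", GIPERM = "1/h",
  BELLYPERMLymph = "1/h", GIPERMLymph = "1/h",
  K1Lymph = "1/h",
  FracDOSEHep = "fraction dose", FracDOSELymph = "fraction dose",
  k1_DPHP_gut = "1/h", k1_MPHP_gut = "1/h",
  k1_DPHP_liver = "1/h", k1_MPHP_liver = "1/h",
  FracMetabOH = "fraction", FracMetabcx = "fraction",
  K1_MOH = "1/h", K1_cx = "1/h",
  Gutlag = "h", Lymphlag = "h", Bilelag = "h",
  PfaD = "tissue:blood", PliD = "tissue:blood", PspdD = "tissue:blood",
  PrpdD = "tissue:blood", PguD = "tissue:blood", PbaD = "RBC:plasma",
  PfaM = "tissue:blood", PliM = "tissue:blood", PspdM = "tissue:blood",
  PrpdM = "tissue:blood", PguM = "tissue:blood", PbaM = "RBC:plasma"
)

#' Write a raw parameter set as a flat key/value/units config
#'
#' @param raw raw parameter vector from [default_parameters()].
#' @param path output CSV path.
#' @return invisibly, the data.frame written.
#' @export
write_parameter_config <- function(raw = default_parameters(), path) {
  d <- data.frame(key = names(raw), value = as.numeric(raw),
                  units = unname(.param_units[names(raw)]),
                  stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}

#' Read a flat parameter config
#'
#' Unknown keys are an error (so typos cannot silently revert a parameter
#' to its default); missing keys keep their defaults.
#'
#' @param path CSV with columns `key`, `value` (units column optional and
#'   ignored on input).
#' @return raw parameter vector (class `dphpk_raw_params`).
#' @export
read_parameter_config <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("key", "value") %in% names(d)))
  default_parameters(stats::setNames(as.list(d$value), d$key))
}
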