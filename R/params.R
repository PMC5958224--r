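# The quenching parameter catalogue: equation-level functions over
# basic_signals, the 89-entry chlorophyll catalogue, and the 16 multicolor
# parameters.

stage_get <- function(s, prefix, stage) {
  key <- paste0(prefix, "_", stage)
  x <- s[[key]]
  if (is.null(x)) stopf("missing signal '%s'", key)
  x
}

#' Maximum quantum yield of PSII, Fv/Fm
#'
#' `Fv/Fm = (Fm - Fo)/Fm`.
#'
#' @param s A `basic_signals` object.
#' @return Dimensionless, in \[0, 1\] for `0 <= Fo <= Fm`.
#' @export
fv_fm <- function(s) {
  if (s$Fm <= 0) stopf("Fm must be > 0")
  (s$Fm - s$Fo) / s$Fm
}

#' Non-photochemical quenching at a flash stage
#'
#' `NPQ_x = (Fm - Fm_x)/Fm_x` (Stern-Volmer form).
#'
#' @param s A `basic_signals` object.
#' @param stage One of `L1`-`L4`, `Lss`, `D1`-`D3`.
#' @return Dimensionless, >= 0 when `Fm >= Fm_x`.
#' @export
npq <- function(s, stage) {
  fm_x <- stage_get(s, "Fm", stage)
  if (fm_x <= 0) stopf("Fm_%s must be > 0", stage)
  (s$Fm - fm_x) / fm_x
}

#' Fluorescence decline ratio at a light-phase stage
#'
#' `Rfd_Ln = (Fp - Ft_Ln)/Ft_Ln`, a vitality index of the induction decline
#' from the Kautsky peak. Negative values (Ft above Fp) are allowed with a
#' warning.
#'
#' @param s A `basic_signals` object.
#' @param stage One of `L1`-`L4` (`Lss` also accepted).
#' @return Dimensionless.
#' @export
rfd <- function(s, stage) {
  ft_x <- stage_get(s, "Ft", stage)
  if (ft_x <= 0) stopf("Ft_%s must be > 0", stage)
  out <- (s$Fp - ft_x) / ft_x
  if (out < 0) warnf("Rfd_%s is negative (Ft above Fp)", stage)
  out
}

#' PSII operating efficiency at a flash stage
#'
#' `PhiPSII_x = (Fm_x - Ft_x)/Fm_x`.
#'
#' @inheritParams npq
#' @return Dimensionless, in \[0, 1\] when `Ft_x <= Fm_x`.
#' @export
phi_psii <- function(s, stage) {
  fm_x <- stage_get(s, "Fm", stage)
  ft_x <- stage_get(s, "Ft", stage)
  if (fm_x <= 0) stopf("Fm_%s must be > 0", stage)
  (fm_x - ft_x) / fm_x
}

#' Coefficient of non-photochemical quenching at a flash stage
#'
#' `qN_x = (Fm - Fm_x)/(Fm - Fo_x)`.
#'
#' @inheritParams npq
#' @return Dimensionless, in \[0, 1\] when `Fo_x <= Fm_x <= Fm`.
#' @export
qn <- function(s, stage) {
  fm_x <- stage_get(s, "Fm", stage)
  fo_x <- stage_get(s, "Fo", stage)
  if (s$Fm - fo_x <= 0) stopf("Fm must exceed Fo_%s", stage)
  (s$Fm - fm_x) / (s$Fm - fo_x)
}

#' Coefficient of photochemical quenching (puddle model)
#'
#' `qP_x = (Fm_x - Ft_x)/(Fm_x - Fo_x)`.
#'
#' @inheritParams npq
#' @return Dimensionless.
#' @export
qp <- function(s, stage) {
  fm_x <- stage_get(s, "Fm", stage)
  ft_x <- stage_get(s, "Ft", stage)
  fo_x <- stage_get(s, "Fo", stage)
  if (fm_x - fo_x == 0) stopf("Fm_%s equals Fo_%s", stage, stage)
  (fm_x - ft_x) / (fm_x - fo_x)
}

#' Coefficient of photochemical quenching, lake model
#'
#' Two forms are provided. The `"printed"` form is
#' `qL_x = qP_x / (Fo_x / Ft_x)`, i.e. `qP * Ft/Fo'`; the `"standard"`
#' (lake-model) form is `qL_x = qP_x * (Fo_x / Ft_x)`. The printed form is
#' the package default for fidelity with the source convention; note it is
#' the reciprocal-factor variant of the standard definition, so its values
#' can exceed 1.
#'
#' @inheritParams npq
#' @param form `"printed"` or `"standard"`.
#' @return Dimensionless.
#' @export
ql <- function(s, stage, form = c("printed", "standard")) {
  form <- match.arg(form)
  ft_x <- stage_get(s, "Ft", stage)
  fo_x <- stage_get(s, "Fo", stage)
  if (ft_x <= 0) stopf("Ft_%s must be > 0", stage)
  if (fo_x <= 0) stopf("Fo_%s must be > 0", stage)
  ratio <- fo_x / ft_x
  q <- qp(s, stage)
  if (form == "printed") q / ratio else q * ratio
}

#' Names of the default chlorophyll parameter catalogue
#'
#' 36 base entries (Fo, Fm, Fv, Fp and Ft/Fm/Fo/Fv at each of the eight
#' flash stages) plus 53 derived entries (Fv/Fm; Fv/Fm_x, NPQ_x, qN_x,
#' qP_x, qL_x, PhiPSII_x at each stage; Rfd at L1-L4) - 89 in total.
#'
#' @return Character vector of 89 unique names.
#' @export
catalogue_names <- function() {
  base <- c("Fo", "Fm", "Fv", "Fp",
            unlist(lapply(STAGES, function(st)
              paste0(c("Ft_", "Fm_", "Fo_", "Fv_"), st))))
  derived <- c("Fv/Fm",
               unlist(lapply(STAGES, function(st)
                 paste0(c("Fv/Fm_", "NPQ_", "qN_", "qP_", "qL_",
                          "PhiPSII_"), st))),
               paste0("Rfd_", c("L1", "L2", "L3", "L4")))
  c(base, derived)
}

#' Compute the full chlorophyll parameter catalogue
#'
#' Evaluates all 89 parameters of the default catalogue from a complete set
#' of base signals. The catalogue composition is versioned
#' (`catalogue_version` attribute) so the count is pinned while the
#' enumeration stays editable.
#'
#' @param s A `basic_signals` object.
#' @param ql_form Passed to [ql()].
#' @return Named numeric vector of length 89, class `parameter_set`.
#' @export
compute_catalogue <- function(s, ql_form = "printed") {
  nms <- catalogue_names()
  need <- c("Fo", "Fm", "Fv", "Fp",
            unlist(lapply(STAGES, function(st)
              paste0(c("Ft_", "Fm_", "Fo_", "Fv_"), st))))
  missing <- setdiff(need, names(s))
  if (length(missing)) stopf("missing signal '%s'", missing[1])
  out <- numeric(0)
  for (nm in need) out[nm] <- s[[nm]]
  out["Fv/Fm"] <- fv_fm(s)
  for (st in STAGES) {
    out[paste0("Fv/Fm_", st)] <-
      stage_get(s, "Fv", st) / stage_get(s, "Fm", st)
    out[paste0("NPQ_", st)] <- npq(s, st)
    out[paste0("qN_", st)] <- qn(s, st)
    out[paste0("qP_", st)] <- qp(s, st)
    out[paste0("qL_", st)] <- ql(s, st, ql_form)
    out[paste0("PhiPSII_", st)] <- phi_psii(s, st)
  }
  for (st in c("L1", "L2", "L3", "L4")) {
    out[paste0("Rfd_", st)] <- rfd(s, st)
  }
  out <- out[nms]
  structure(out, class = c("parameter_set", "numeric"),
            catalogue_version = "default-89-v1")
}

#' Multicolor band means from a UV frame stack
#'
#' Averages the exposures of each band over the plant mask: `BF` (440 nm),
#' `GF` (520 nm), `RF` (680 nm), `IrF` (740 nm).
#'
#' @param stack A [simulate_multicolor()] stack (or any `frame_stack` with a
#'   `band` element).
#' @param mask Logical plant mask.
#' @return Named numeric vector of 4 band means.
#' @export
multicolor_signals <- function(stack, mask) {
  if (is.null(stack$band)) stopf("stack has no band labels")
  tr <- extract_trace(stack, mask)
  vapply(c("BF", "GF", "RF", "IrF"), function(b) {
    mean(tr$mean_counts[tr$band == b])
  }, numeric(1))
}

#' The 16 multicolor parameters
#'
#' The four band means plus all 12 ordered pairwise ratios (e.g. `IrF/BF`
#' and `BF/IrF` are distinct entries).
#'
#' @param m Named numeric vector with entries `BF`, `GF`, `RF`, `IrF`, all
#'   > 0.
#' @return Named numeric vector of length 16, class `parameter_set`.
#' @export
multicolor_parameters <- function(m) {
  bands <- c("BF", "GF", "RF", "IrF")
  if (!all(bands %in% names(m))) {
    stopf("m must name BF, GF, RF, IrF")
  }
  m <- m[bands]
  if (any(m <= 0)) stopf("nonpositive band mean")
  out <- as.numeric(m)
  names(out) <- bands
  for (a in bands) for (b in bands) {
    if (a != b) out[paste0(a, "/", b)] <- m[[a]] / m[[b]]
  }
  structure(out, class = c("parameter_set", "numeric"),
            catalogue_version = "multicolor-16-v1")
}
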