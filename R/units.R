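# Concentration units used across the assays. Soluble fluorogenic substrates
# are tracked in uM (or mM), bulk colloidal chitin as % w/v (grams per 100 mL
# of suspension).

.chitkin_units <- c("uM", "mM", "percent_wv")

# molecular mass of one N-acetylglucosamine unit in the chitin polymer, g/mol
CHITIN_MONOMER_MASS_G_MOL <- 203.21

#' Convert bulk chitin concentration from % w/v to monomer millimolar
#'
#' Under the infinite-polymer approximation there is one enzyme binding site
#' per N-acetylglucosamine unit, so a bulk chitin suspension can be expressed
#' as a molar concentration of monomer units: `pct` % w/v corresponds to
#' `pct * 10` g/L, divided by the 203.21 g/mol monomer mass.
#'
#' @param pct Chitin concentration in % w/v (grams per 100 mL). Must be
#'   finite and non-negative.
#' @return Monomer concentration in mM.
#' @examples
#' percent_wv_to_monomer_mM(0.03) # ~ 1.5 mM
#' @export
percent_wv_to_monomer_mM <- function(pct) {
  if (!is.numeric(pct) || any(!is.finite(pct)) || any(pct < 0)) {
    stop("`pct` must be finite and non-negative", call. = FALSE)
  }
  pct * 10 / CHITIN_MONOMER_MASS_G_MOL * 1000
}

#' Convert monomer millimolar to bulk chitin % w/v
#'
#' Inverse of [percent_wv_to_monomer_mM()].
#'
#' @param mM Monomer concentration in mM.
#' @return Chitin concentration in % w/v.
#' @export
monomer_mM_to_percent_wv <- function(mM) {
  if (!is.numeric(mM) || any(!is.finite(mM)) || any(mM < 0)) {
    stop("`mM` must be finite and non-negative", call. = FALSE)
  }
  mM * CHITIN_MONOMER_MASS_G_MOL / 1e4
}

# Express an enzyme concentration given in nM in the same unit as a substrate
# or product concentration axis, so that kcat = Vmax / [E] is unit-consistent.
enzyme_nM_to_conc <- function(enzyme_nM, unit) {
  unit <- match.arg(unit, .chitkin_units)
  switch(unit,
    uM = enzyme_nM * 1e-3,
    mM = enzyme_nM * 1e-6,
    percent_wv = monomer_mM_to_percent_wv(enzyme_nM * 1e-6)
  )
}
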