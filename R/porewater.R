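# Equilibrium-partitioning porewater estimation.
#
# The dissolved porewater concentration of a hydrophobic organic chemical is
# estimated from its bulk sediment concentration through single-phase
# partitioning into the sediment organic carbon:
#
#   C_pw = C_sed / (K_oc * f_oc)
#
# with C_sed in µg/kg dry wt, K_oc the organic carbon-water partition
# coefficient in L/kg, and f_oc the mass fraction of organic carbon, giving
# C_pw in µg/L. No black-carbon or salinity corrections are applied.

#' Organic-carbon mass fraction from percent TOC
#'
#' @param toc_percent Total organic carbon as percent of dry mass, in
#'   (0, 100].
#' @return Mass fraction in (0, 1].
#' @export
#' @examples
#' foc_from_toc(2.0) # 0.02
foc_from_toc <- function(toc_percent) {
  if (any(!is.finite(toc_percent) | toc_percent <= 0 | toc_percent > 100))
    stop("toc_percent must be in (0, 100]", call. = FALSE)
  toc_percent / 100
}

#' Estimate dissolved porewater concentration
#'
#' Single-phase equilibrium partitioning: `c_sed / (koc * foc)`. Vectorized.
#'
#' @param c_sed Sediment concentration, µg/kg dry wt (>= 0).
#' @param koc Organic carbon-water partition coefficient, L/kg (> 0).
#' @param foc Organic-carbon mass fraction, in (0, 1].
#' @return Porewater concentration, µg/L.
#' @export
#' @examples
#' estimate_porewater(1000, 10000, 0.02) # 5 µg/L
estimate_porewater <- function(c_sed, koc, foc) {
  if (any(!is.finite(koc) | koc <= 0)) stop("koc must be positive", call. = FALSE)
  if (any(!is.finite(foc) | foc <= 0 | foc > 1))
    stop("foc must be in (0, 1]", call. = FALSE)
  if (any(c_sed < 0)) stop("c_sed must be non-negative", call. = FALSE)
  c_sed / (koc * foc)
}

#' Tablewise porewater estimation
#'
#' Applies [estimate_porewater()] to every measurement row, recording why a
#' value could not be computed rather than dropping rows: chemicals without a
#' literature partition coefficient get status `no_koc`, sites without usable
#' TOC get `no_toc` (both with `c_pw = NA`), and censored measurements get
#' `c_pw = 0` with status `censored`. Only `ok` and `censored` rows feed
#' porewater-based screening downstream.
#'
#' @param m Normalized measurement table.
#' @param registry Validated chemical registry (supplies `koc`).
#' @param sites Site table (supplies `toc_percent`).
#' @return Data frame with `site_id`, `chemical_id`, `c_pw` (µg/L), `status`
#'   in `ok | no_koc | no_toc | censored`.
#' @export
porewater_table <- function(m, registry, sites) {
  validate_registry(registry)
  validate_sites(sites)
  koc <- registry$koc[match(m$chemical_id, registry$chemical_id)]
  toc <- sites$toc_percent[match(m$site_id, sites$site_id)]
  status <- rep("ok", nrow(m))
  status[is.na(koc)] <- "no_koc"
  status[status == "ok" & (is.na(toc) | toc <= 0)] <- "no_toc"
  status[status == "ok" & m$censored] <- "censored"
  c_pw <- rep(NA_real_, nrow(m))
  ok <- status == "ok"
  c_pw[ok] <- estimate_porewater(m$c_sed[ok], koc[ok], foc_from_toc(toc[ok]))
  c_pw[status == "censored"] <- 0
  data.frame(site_id = m$site_id, chemical_id = m$chemical_id,
             c_pw = c_pw, status = status, stringsAsFactors = FALSE)
}
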