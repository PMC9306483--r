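# Defined mixture scores: PAH TEC/PEC quotients, equilibrium-partitioning
# sediment benchmark toxic units, and the alkylphenol toxic-equivalency
# quotient.

#' Summed concentration of the 16 priority-pollutant PAHs
#'
#' Per-site sum of detected concentrations over the registry chemicals
#' flagged `is_pah16` (censored values contribute zero). The sum is a bulk
#' sediment concentration and is not TOC-normalized.
#'
#' @param m Normalized measurement table.
#' @param registry Validated chemical registry. A membership flag count other
#'   than 16 triggers a warning (user-defined subsets are allowed).
#' @return Data frame with `site_id`, `sum_pah16` (µg/kg dry wt); every site
#'   present in `m` appears, with 0 when no member was detected.
#' @export
sum_pah16 <- function(m, registry) {
  validate_registry(registry)
  n_members <- sum(registry$is_pah16)
  if (n_members != 16L)
    warning("registry flags ", n_members, " chemicals as is_pah16 (expected 16)")
  members <- registry$chemical_id[registry$is_pah16]
  sites <- sort(unique(m$site_id))
  sub <- m[m$chemical_id %in% members, , drop = FALSE]
  tot <- setNames(rep(0, length(sites)), sites)
  if (nrow(sub)) {
    s <- tapply(sub$c_sed, sub$site_id, sum)
    tot[names(s)] <- s
  }
  data.frame(site_id = sites, sum_pah16 = as.numeric(tot),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' PAH mixture quotients and effect category
#'
#' Quotients of the summed 16-PAH concentration against the consensus-based
#' threshold effect concentration (TEC, 1610 µg/kg) and probable effect
#' concentration (PEC, 22800 µg/kg). Adverse effects are categorized as
#' `likely` when PECQ > 1, `unlikely` when TECQ < 1 (values equal to 1 do
#' not trigger the higher category), and `possible` in between.
#'
#' @param sum_pah16 Per-site summed 16-PAH concentrations (numeric vector,
#'   µg/kg dry wt).
#' @param tec,pec Positive effect concentrations; defaults 1610 and 22800.
#' @return Data frame with `sum_pah16`, `tecq`, `pecq`, `category`.
#' @export
#' @examples
#' pah_quotients(196000) # PECQ 8.6, category "likely"
pah_quotients <- function(sum_pah16, tec = 1610, pec = 22800) {
  if (tec <= 0 || pec <= 0) stop("tec and pec must be positive", call. = FALSE)
  tecq <- sum_pah16 / tec
  pecq <- sum_pah16 / pec
  category <- ifelse(pecq > 1, "likely", ifelse(tecq > 1, "possible", "unlikely"))
  data.frame(sum_pah16 = sum_pah16, tecq = tecq, pecq = pecq,
             category = category, stringsAsFactors = FALSE)
}

#' Equilibrium-partitioning sediment benchmark toxic units
#'
#' For every registry chemical flagged `is_esb_pah`, the TOC-normalized
#' concentration in µg/g organic carbon is `c_sed / (10 * toc_percent)`
#' (µg/kg divided by 10 g OC per kg per percent). Dividing by the chemical's
#' final chronic value (FCV, µg/g OC) gives its toxic unit; the per-site sum
#' over the member set is the narcosis-additive score, with values above 1
#' flagging potential adverse effects on sensitive benthic organisms.
#'
#' @param m Normalized measurement table.
#' @param sites Site table (supplies `toc_percent`). Sites with TOC <= 0 or
#'   missing are skipped with status `no_toc`.
#' @param registry Validated chemical registry; a detected member without an
#'   FCV is a hard error listing the chemicals.
#' @return List with `by_site` (`site_id`, `esbtu_sum`, `status`) and
#'   `by_chemical` (`site_id`, `chemical_id`, `toxic_unit`).
#' @export
esbtu <- function(m, sites, registry) {
  validate_registry(registry)
  validate_sites(sites)
  members <- registry$chemical_id[registry$is_esb_pah]
  sub <- m[m$chemical_id %in% members, , drop = FALSE]

  fcv <- registry$fcv[match(sub$chemical_id, registry$chemical_id)]
  detected_no_fcv <- unique(sub$chemical_id[is.na(fcv) & !sub$censored & sub$c_sed > 0])
  if (length(detected_no_fcv))
    .stop_rows("final chronic value missing for detected ESB members",
               detected_no_fcv)

  toc <- sites$toc_percent[match(sub$site_id, sites$site_id)]
  usable <- !is.na(toc) & toc > 0
  tu <- rep(NA_real_, nrow(sub))
  ok <- usable & !is.na(fcv)
  tu[ok] <- sub$c_sed[ok] / (10 * toc[ok]) / fcv[ok]
  tu[usable & is.na(fcv)] <- 0 # censored member without FCV contributes nothing

  site_ids <- sort(unique(m$site_id))
  site_toc <- sites$toc_percent[match(site_ids, sites$site_id)]
  status <- ifelse(is.na(site_toc) | site_toc <= 0, "no_toc", "ok")
  sums <- setNames(rep(0, length(site_ids)), site_ids)
  if (any(ok)) {
    s <- tapply(tu[ok], sub$site_id[ok], sum)
    sums[names(s)] <- s
  }
  sums[status == "no_toc"] <- NA_real_
  by_site <- data.frame(site_id = site_ids, esbtu_sum = as.numeric(sums),
                        status = status, stringsAsFactors = FALSE)
  by_chem <- data.frame(site_id = sub$site_id[ok], chemical_id = sub$chemical_id[ok],
                        toxic_unit = tu[ok], stringsAsFactors = FALSE)
  by_chem <- by_chem[order(by_chem$site_id, by_chem$chemical_id), ]
  rownames(by_chem) <- NULL
  list(by_site = by_site, by_chemical = by_chem)
}

#' Alkylphenol toxic equivalents
#'
#' Per-site nonylphenol-equivalent concentration of the alkylphenol
#' (detergent-metabolite) mixture: the sum of each member's concentration
#' times its toxic equivalency factor (TEF) relative to 4-nonylphenol, the
#' reference compound (TEF 1). Censored members contribute zero, so the
#' result is biased low when members fall below reporting limits.
#'
#' @param m Normalized measurement table.
#' @param registry Validated chemical registry; a detected alkylphenol
#'   member without a TEF is a hard error.
#' @return Data frame with `site_id`, `teq` (µg/kg as nonylphenol
#'   equivalents).
#' @export
alkylphenol_teq <- function(m, registry) {
  validate_registry(registry)
  members <- registry$chemical_id[registry$is_alkylphenol]
  sub <- m[m$chemical_id %in% members, , drop = FALSE]
  tef <- registry$tef[match(sub$chemical_id, registry$chemical_id)]
  bad <- unique(sub$chemical_id[is.na(tef) & !sub$censored & sub$c_sed > 0])
  if (length(bad))
    .stop_rows("toxic equivalency factor missing for detected alkylphenols", bad)
  contrib <- ifelse(is.na(tef), 0, sub$c_sed * tef)

  sites <- sort(unique(m$site_id))
  teq <- setNames(rep(0, length(sites)), sites)
  if (nrow(sub)) {
    s <- tapply(contrib, sub$site_id, sum)
    teq[names(s)] <- s
  }
  data.frame(site_id = sites, teq = as.numeric(teq),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Organic carbon-adjusted alkylphenol mixture quotient
#'
#' `teq / (isqg * toc_percent)` with the freshwater interim sediment quality
#' guideline of 1400 µg/kg, which applies at 1% organic carbon; TOC enters
#' in percent, exactly reproducing that convention. Values above 1 flag
#' potential narcosis effects (strict `>`).
#'
#' @param teq Nonylphenol-equivalent concentration, µg/kg (>= 0).
#' @param toc_percent Site TOC in percent (> 0).
#' @param isqg Guideline value, µg/kg; default 1400.
#' @return Dimensionless quotient. Vectorized.
#' @export
#' @examples
#' alkylphenol_tq(2800, 1.0) # 2.0
alkylphenol_tq <- function(teq, toc_percent, isqg = 1400) {
  if (any(!is.finite(toc_percent) | toc_percent <= 0))
    stop("toc_percent must be positive", call. = FALSE)
  if (isqg <= 0) stop("isqg must be positive", call. = FALSE)
  if (any(teq < 0)) stop("teq must be non-negative", call. = FALSE)
  teq / (isqg * toc_percent)
}

#' Per-site alkylphenol mixture summary
#'
#' Combines [alkylphenol_teq()] and [alkylphenol_tq()]; sites without usable
#' TOC get `tq_ap = NA` with status `no_toc`.
#'
#' @param m Normalized measurement table.
#' @param sites Site table.
#' @param registry Validated chemical registry.
#' @param isqg Guideline value, µg/kg; default 1400.
#' @return Data frame with `site_id`, `teq`, `tq_ap`, `status`.
#' @export
alkylphenol_mixtures <- function(m, sites, registry, isqg = 1400) {
  tq_df <- alkylphenol_teq(m, registry)
  toc <- sites$toc_percent[match(tq_df$site_id, sites$site_id)]
  usable <- !is.na(toc) & toc > 0
  tq_df$tq_ap <- NA_real_
  tq_df$tq_ap[usable] <- alkylphenol_tq(tq_df$teq[usable], toc[usable], isqg)
  tq_df$status <- ifelse(usable, "ok", "no_toc")
  tq_df
}

#' Per-site PAH mixture summary
#'
#' Combines [sum_pah16()] and [pah_quotients()].
#'
#' @param m Normalized measurement table.
#' @param registry Validated chemical registry.
#' @param tec,pec Effect concentrations; defaults 1610 and 22800 µg/kg.
#' @return Data frame with `site_id`, `sum_pah16`, `tecq`, `pecq`,
#'   `category`.
#' @export
pah_mixtures <- function(m, registry, tec = 1610, pec = 22800) {
  s <- sum_pah16(m, registry)
  cbind(s["site_id"], pah_quotients(s$sum_pah16, tec, pec))
}
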