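# Chemical priority levels, site priority scores, and watershed correlations.
#
# Chemicals are prioritized by how often and how strongly they exceed the
# screening thresholds of the three lines of evidence (sediment TQ_Max,
# porewater TQ_Max, EAR_Max). Sites are scored by eight methods, each
# normalized to priority levels 1 (highest concern) through 4 (lowest), and
# averaged into an overall score; a lower score means higher priority.

#' Default chemical-priority threshold ladder
#'
#' The top rung (P1) and the lowest rung are fixed by the screening design:
#' P1 requires a sediment or porewater TQ_Max above 10 or an EAR_Max above
#' 0.1 at more than the prevalence fraction of sites; the lowest rung (0.1 /
#' 0.001) separates low-priority from uncategorized chemicals. The
#' intermediate rungs P2 and P3 interpolate geometrically (x10 spacing),
#' consistent with the fixed endpoints; they are reported as a design
#' assumption and are fully configurable.
#'
#' @return Data frame with `level`, `tq_threshold`, `ear_threshold`.
#' @export
priority_ladder <- function() {
  data.frame(level = c("P1", "P2", "P3"),
             tq_threshold = c(10, 1, 0.1),
             ear_threshold = c(0.1, 0.01, 0.001),
             stringsAsFactors = FALSE)
}

#' Classify chemicals into priority levels
#'
#' A chemical is assigned the highest rung of the ladder at which it exceeds
#' the rung's TQ threshold (sediment or porewater TQ_Max, strict `>`) or EAR
#' threshold (EAR_Max, strict `>`) at more than `prevalence` of the sites.
#' Chemicals never exceeding the lowest rung anywhere, or never detected,
#' are `low`. Chemicals exceeding the lowest rung at some sites but at no
#' more than the prevalence fraction are `uncategorized`. Detected chemicals
#' screenable by none of the three methods are `no_benchmarks`.
#'
#' @param tqmax Per-chemical TQ_Max table (both media allowed; column
#'   `medium` distinguishes them).
#' @param ear_max `ear_max` data frame from [aggregate_ear()].
#' @param m Normalized measurement table (supplies detection).
#' @param registry Validated chemical registry.
#' @param n_sites Total number of sites.
#' @param prevalence Site-fraction cutoff, strict `>`; default 0.2.
#' @param ladder Threshold ladder, see [priority_ladder()].
#' @return Data frame with `chemical_id`, `level` in
#'   `P1 | P2 | P3 | low | uncategorized | no_benchmarks`, `detected`, and
#'   per-rung exceedance-site counts (`n_sites_P1`, ...).
#' @export
chemical_priority <- function(tqmax, ear_max, m, registry, n_sites,
                              prevalence = 0.2, ladder = priority_ladder()) {
  validate_registry(registry)
  chems <- registry$chemical_id
  det <- tapply(!m$censored & m$c_sed > 0, m$chemical_id, any)
  detected <- setNames(rep(FALSE, length(chems)), chems)
  detected[names(det)] <- det

  screenable <- chems %in% tqmax$chemical_id | chems %in% ear_max$chemical_id

  # number of sites where any of the three metrics exceeds the rung
  rung_counts <- function(tq_thr, ear_thr) {
    ex_tq <- tqmax[!is.na(tqmax$tq_max) & tqmax$tq_max > tq_thr, ]
    ex_ear <- ear_max[ear_max$ear_max > ear_thr, ]
    keys <- unique(rbind(ex_tq[, c("site_id", "chemical_id")],
                         ex_ear[, c("site_id", "chemical_id")]))
    cnt <- table(factor(keys$chemical_id, levels = chems))
    as.integer(cnt)
  }
  counts <- sapply(seq_len(nrow(ladder)), function(i)
    rung_counts(ladder$tq_threshold[i], ladder$ear_threshold[i]))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(chems))
  colnames(counts) <- ladder$level

  level <- character(length(chems))
  lowest <- counts[, ncol(counts)]
  for (j in seq_along(chems)) {
    if (!detected[j]) { level[j] <- "low"; next }
    if (!screenable[j]) { level[j] <- "no_benchmarks"; next }
    assigned <- NA_character_
    for (i in seq_len(nrow(ladder))) {
      if (counts[j, i] / n_sites > prevalence) { assigned <- ladder$level[i]; break }
    }
    if (!is.na(assigned)) level[j] <- assigned
    else if (lowest[j] >= 1L) level[j] <- "uncategorized"
    else level[j] <- "low"
  }
  out <- data.frame(chemical_id = chems, level = level,
                    detected = as.logical(detected),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ladder)))
    out[[paste0("n_sites_", ladder$level[i])]] <- counts[, i]
  out
}

#' The eight site-prioritization methods
#' @return Character vector of method names accepted by
#'   [site_method_level()].
#' @export
site_methods <- function() {
  c("sediment_tq_max_count", "porewater_tq_max_count", "ear_max_count",
    "pah_mixture", "alkylphenol_mixture",
    "sediment_tq_sample", "porewater_tq_sample", "ear_sample")
}

#' Map a method value onto a site priority level
#'
#' Deterministic binning of each method's statistic into priority levels 4
#' (lowest priority) through 1 (highest):
#' \describe{
#'   \item{count methods (`*_tq_max_count`, `ear_max_count`)}{number of
#'     chemicals exceeding the method's per-chemical threshold (TQ_Max > 1
#'     for the two TQ counts, EAR_Max > 0.01 for the EAR count):
#'     0 / 1-9 / 10-19 / >=20 map to 4 / 3 / 2 / 1.}
#'   \item{`pah_mixture`}{`value` is a logical vector
#'     `c(tec, pec, esbtu)` of quotient exceedances: none of TEC -> 4, TEC
#'     only -> 3, PEC or the toxic-unit sum -> 2, PEC and the toxic-unit
#'     sum -> 1.}
#'   \item{`alkylphenol_mixture`}{quotient value: 0 -> 4, below 1 -> 3,
#'     below 10 -> 2, >= 10 -> 1 (values in (0, 0.01) clamp to 3).}
#'   \item{`*_tq_sample`}{summed quotient: below 10 -> 4, below 100 -> 3,
#'     below 1000 -> 2, >= 1000 -> 1 (values below 1 or above 10000 clamp
#'     to the nearest bin).}
#'   \item{`ear_sample`}{below 0.1 -> 4, below 1 -> 3, below 10 -> 2,
#'     >= 10 -> 1.}
#' }
#' Larger burdens never map to a numerically larger (less severe) level.
#'
#' @param method One of [site_methods()].
#' @param value Count, quotient value, or (for `pah_mixture`) length-3
#'   logical.
#' @return Integer level in 1..4, or `NA` if `value` is `NA`.
#' @export
#' @examples
#' site_method_level("sediment_tq_max_count", 22) # 1
#' site_method_level("ear_sample", 0.5)           # 3
site_method_level <- function(method, value) {
  if (!method %in% site_methods())
    stop("unknown site-prioritization method: ", method, call. = FALSE)
  if (method == "pah_mixture") {
    stopifnot(is.logical(value), length(value) == 3L)
    if (anyNA(value)) return(NA_integer_)
    tec <- value[1]; pec <- value[2]; esb <- value[3]
    return(if (pec && esb) 1L else if (pec || esb) 2L else if (tec) 3L else 4L)
  }
  if (length(value) != 1L) stop("value must be a single number", call. = FALSE)
  if (is.na(value)) return(NA_integer_)
  if (value < 0) stop("method value must be non-negative", call. = FALSE)
  switch(method,
    sediment_tq_max_count = ,
    porewater_tq_max_count = ,
    ear_max_count = {
      if (value == 0) 4L else if (value <= 9) 3L else if (value <= 19) 2L else 1L
    },
    alkylphenol_mixture = {
      if (value == 0) 4L else if (value < 1) 3L else if (value < 10) 2L else 1L
    },
    sediment_tq_sample = ,
    porewater_tq_sample = {
      if (value < 10) 4L else if (value < 100) 3L else if (value < 1000) 2L else 1L
    },
    ear_sample = {
      if (value < 0.1) 4L else if (value < 1) 3L else if (value < 10) 2L else 1L
    })
}

#' Overall site priority score
#'
#' Arithmetic mean of the available (non-`NA`) method levels. A lower score
#' indicates higher priority.
#'
#' @param levels Numeric/integer vector of method levels in 1..4, `NA` for
#'   unavailable methods.
#' @return List with `score` and `n_methods_available`.
#' @export
#' @examples
#' overall_score(c(1, 1, 1, 2, 2, 3, 4, 4))$score # 2.25
overall_score <- function(levels) {
  avail <- !is.na(levels)
  if (!any(avail)) stop("no methods available for site score", call. = FALSE)
  if (any(levels[avail] < 1 | levels[avail] > 4))
    stop("method levels must be in 1..4", call. = FALSE)
  list(score = mean(levels[avail]), n_methods_available = sum(avail))
}

#' Assemble the per-site priority table
#'
#' Builds one row per site with the eight method levels, the overall score,
#' and the count of available methods. Sites absent from a component table
#' contribute the appropriate degenerate value (a count/sum of 0) when the
#' method's inputs exist at all; a method whose inputs are entirely missing
#' for a site (e.g. no usable TOC for the organic-carbon-adjusted methods)
#' is `NA` and excluded from the mean.
#'
#' @param site_ids Character vector of all study sites.
#' @param tq_exceed `per_site` counts from [count_exceedances()] at
#'   threshold 1 (both media).
#' @param ear_exceed `per_site` counts from [flag_chemicals()] at threshold
#'   0.01 (note: the site-count method uses 0.01, not the chemical screening
#'   threshold 0.001).
#' @param tq_agg `by_sample` aggregates from [aggregate_tq()].
#' @param ear_agg `by_sample` from [aggregate_ear()].
#' @param pah Per-site PAH mixture table from [pah_mixtures()].
#' @param esb `by_site` from [esbtu()].
#' @param ap Per-site alkylphenol table from [alkylphenol_mixtures()].
#' @param have_ear Is EAR screening available at all (any usable ACC data)?
#' @return Data frame (one row per site) with the eight level columns,
#'   `overall_score`, `n_methods_available`, plus the raw values
#'   (`sediment_tq_sample`, ...) used for ranking.
#' @export
site_priority <- function(site_ids, tq_exceed, ear_exceed, tq_agg, ear_agg,
                          pah, esb, ap, have_ear = TRUE) {
  pick <- function(df, key, col, default = 0) {
    v <- df[[col]][match(site_ids, df[[key]])]
    v[is.na(v)] <- default
    v
  }
  sed_cnt <- pick(tq_exceed[tq_exceed$medium == "sediment", ], "site_id", "n_chemicals")
  pw_cnt <- pick(tq_exceed[tq_exceed$medium == "porewater", ], "site_id", "n_chemicals")
  ear_cnt <- pick(ear_exceed, "site_id", "n_chemicals")
  sed_sum <- pick(tq_agg[tq_agg$medium == "sediment", ], "site_id", "tq_sample")
  pw_sum <- pick(tq_agg[tq_agg$medium == "porewater", ], "site_id", "tq_sample")
  ear_sum <- pick(ear_agg, "site_id", "ear_sample")

  tecq <- pah$tecq[match(site_ids, pah$site_id)]
  pecq <- pah$pecq[match(site_ids, pah$site_id)]
  esb_sum <- esb$esbtu_sum[match(site_ids, esb$site_id)]
  tq_ap <- ap$tq_ap[match(site_ids, ap$site_id)]

  lvl <- function(method, values)
    vapply(values, function(v) site_method_level(method, v), integer(1))
  pah_lvl <- mapply(function(t, p, e) {
    if (is.na(t) || is.na(p)) return(NA_integer_)
    # toxic-unit sum unavailable (no usable TOC): judge on TEC/PEC alone
    site_method_level("pah_mixture", c(t > 1, p > 1, !is.na(e) && e > 1))
  }, tecq, pecq, esb_sum)

  out <- data.frame(
    site_id = site_ids,
    sediment_tq_max_count = lvl("sediment_tq_max_count", sed_cnt),
    porewater_tq_max_count = lvl("porewater_tq_max_count", pw_cnt),
    ear_max_count = if (have_ear) lvl("ear_max_count", ear_cnt) else NA_integer_,
    pah_mixture = as.integer(pah_lvl),
    alkylphenol_mixture = lvl("alkylphenol_mixture", tq_ap),
    sediment_tq_sample = lvl("sediment_tq_sample", sed_sum),
    porewater_tq_sample = lvl("porewater_tq_sample", pw_sum),
    ear_sample = if (have_ear) lvl("ear_sample", ear_sum) else NA_integer_,
    stringsAsFactors = FALSE)
  sc <- apply(out[, site_methods()], 1, function(r) unlist(overall_score(r)))
  out$overall_score <- sc["score", ]
  out$n_methods_available <- as.integer(sc["n_methods_available", ])
  out$sediment_tq_sample_value <- sed_sum
  out$porewater_tq_sample_value <- pw_sum
  out$ear_sample_value <- ear_sum
  out
}

#' Rank sites by overall priority
#'
#' Ascending overall score (lower = higher priority); ties broken by
#' descending sediment TQ_Sample, then lexicographic site id, so the
#' ordering is a deterministic function of the table contents only.
#'
#' @param sp Site priority table from [site_priority()] (needs
#'   `overall_score` and `sediment_tq_sample_value`).
#' @return `sp` reordered, with a `rank` column added.
#' @export
rank_sites <- function(sp) {
  o <- order(sp$overall_score, -sp$sediment_tq_sample_value, sp$site_id)
  out <- sp[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Spearman correlations of screening metrics with watershed attributes
#'
#' Tie-aware (midrank) rank correlation with an asymptotic two-sided
#' p-value for every metric x attribute pair. Raw p-values are compared
#' with `alpha` by default, matching common screening practice; an optional
#' Benjamini-Hochberg adjustment across all pairs can be switched on.
#'
#' @param metrics Data frame with `site_id` and one column per screening
#'   metric (e.g. TQ_Sample, EAR_Sample).
#' @param sites Site table; all numeric columns except `toc_percent` are
#'   treated as watershed attributes.
#' @param alpha Significance level; default 0.05.
#' @param adjust Apply Benjamini-Hochberg correction across pairs before
#'   comparing with `alpha`? Default `FALSE`.
#' @return Data frame with `metric`, `attribute`, `rho`, `p_value`,
#'   `significant`, `n`, `note` (`"constant input"` where undefined).
#' @export
watershed_correlations <- function(metrics, sites, alpha = 0.05,
                                   adjust = FALSE) {
  validate_sites(sites)
  attr_cols <- setdiff(names(sites)[vapply(sites, is.numeric, TRUE)], "toc_percent")
  met_cols <- setdiff(names(metrics), "site_id")
  rows <- list()
  for (mc in met_cols) {
    x <- metrics[[mc]][match(sites$site_id, metrics$site_id)]
    for (ac in attr_cols) {
      y <- sites[[ac]]
      keep <- !is.na(x) & !is.na(y)
      n <- sum(keep)
      if (n < 3) {
        rows[[length(rows) + 1L]] <- data.frame(
          metric = mc, attribute = ac, rho = NA_real_, p_value = NA_real_,
          significant = NA, n = n, note = "fewer than 3 pairs",
          stringsAsFactors = FALSE)
        next
      }
      if (length(unique(x[keep])) == 1L || length(unique(y[keep])) == 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          metric = mc, attribute = ac, rho = NA_real_, p_value = NA_real_,
          significant = NA, n = n, note = "constant input",
          stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(cor.test(x[keep], y[keep], method = "spearman",
                                      exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mc, attribute = ac, rho = unname(ct$estimate),
        p_value = ct$p.value, significant = NA, n = n, note = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  p <- out$p_value
  if (adjust) p <- p.adjust(p, method = "BH")
  out$significant <- !is.na(p) & p < alpha
  out$significant[is.na(out$p_value)] <- NA
  rownames(out) <- NULL
  out
}
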