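# Orchestration: run every line of evidence and fold the results into one
# classed object.

#' Screening thresholds and constants
#'
#' All tunable constants of the screening pipeline in one place. Defaults
#' are the conventional values: an EAR_Max screening threshold of 0.001; an
#' endpoint-mixture retention rule of EAR_Endpoint > 0.1 at at least 20% of
#' sites with members contributing at least 0.001 (10% of the 0.01
#' benchmark) and major contributors at 0.01; TEC/PEC of 1610/22800 µg/kg
#' for the 16-PAH sum; an alkylphenol guideline of 1400 µg/kg at 1% organic
#' carbon; and Spearman screening at alpha = 0.05 without multiplicity
#' adjustment.
#'
#' @param ear_threshold Per-chemical EAR_Max screening threshold.
#' @param endpoint_site_threshold EAR_Endpoint retention threshold.
#' @param prevalence Site-prevalence fraction for endpoint retention
#'   (`>=` count rule) and chemical priority (strict `>` rule).
#' @param member_threshold,major_threshold Endpoint-mixture membership and
#'   major-contributor thresholds (both compared with `>=`).
#' @param tec,pec PAH effect concentrations, µg/kg.
#' @param isqg Alkylphenol guideline, µg/kg at 1% organic carbon.
#' @param alpha Significance level for watershed correlations.
#' @param adjust_correlations Benjamini-Hochberg switch for the
#'   correlations.
#' @param ladder Chemical-priority threshold ladder.
#' @return List of class `screen_control`.
#' @export
screen_control <- function(ear_threshold = 0.001,
                           endpoint_site_threshold = 0.1,
                           prevalence = 0.2,
                           member_threshold = 0.001,
                           major_threshold = 0.01,
                           tec = 1610, pec = 22800, isqg = 1400,
                           alpha = 0.05, adjust_correlations = FALSE,
                           ladder = priority_ladder()) {
  structure(list(ear_threshold = ear_threshold,
                 endpoint_site_threshold = endpoint_site_threshold,
                 prevalence = prevalence,
                 member_threshold = member_threshold,
                 major_threshold = major_threshold,
                 tec = tec, pec = pec, isqg = isqg, alpha = alpha,
                 adjust_correlations = adjust_correlations, ladder = ladder),
            class = "screen_control")
}

#' Run the full sediment screening analysis
#'
#' Executes every line of evidence on one study: porewater estimation,
#' sediment and porewater toxicity quotients with their class/sample
#' aggregates, exposure-activity ratios with endpoint mixtures and
#' gene/AOP annotation, the three mixture scores, chemical priority levels,
#' per-site priority scores with ranking, and watershed correlations.
#'
#' @param measurements Normalized measurement table (see
#'   [normalize_measurements()]).
#' @param registry Validated chemical registry.
#' @param sites Site table.
#' @param benchmarks Benchmark table.
#' @param acc ACC table, or `NULL` when no bioactivity data exist (the EAR
#'   methods are then marked unavailable).
#' @param aop_map Optional endpoint-gene-AOP mapping for annotation.
#' @param control A [screen_control()] object.
#' @return Object of class `sed_screen`; see Details.
#' @details The returned list contains `porewater`, `tq` (`long`, `tq_max`,
#'   `aggregates`, `exceedances`), `ear` (`table`, `aggregates`, `flags`,
#'   `priority_endpoints`), `mixtures` (`pah`, `esb`, `alkylphenol`),
#'   `chemical_priority`, `site_priority` (ranked), `correlations`, and the
#'   `control` used. Components unavailable for lack of data are `NULL`.
#' @export
#' @examples
#' study <- generate_study(synth_config(n_sites = 12, seed = 7))
#' scr <- screen_sediment(study$measurements, study$registry, study$sites,
#'                        study$benchmarks, study$acc, study$aop_map)
#' scr
screen_sediment <- function(measurements, registry, sites, benchmarks,
                            acc = NULL, aop_map = NULL,
                            control = screen_control()) {
  validate_registry(registry)
  validate_sites(sites)
  validate_benchmarks(benchmarks)
  site_ids <- sort(unique(sites$site_id))
  n_sites <- length(site_ids)

  pw <- porewater_table(measurements, registry, sites)

  sed <- tq_table(measurements, benchmarks, "sediment")
  pwq <- tq_table(measurements, benchmarks, "porewater", pw = pw)
  tqmax <- rbind(sed$tq_max, pwq$tq_max)
  tq_agg <- aggregate_tq(tqmax, registry)
  tq_exc <- count_exceedances(tqmax, 1)

  have_ear <- !is.null(acc) && nrow(acc) > 0
  ear_tbl <- ear_agg <- flags <- pe <- NULL
  if (have_ear) {
    acc_prep <- prepare_acc(acc, registry)
    ear_tbl <- compute_ear(pw, acc_prep, registry)
    have_ear <- nrow(ear_tbl) > 0
  }
  if (have_ear) {
    ear_agg <- aggregate_ear(ear_tbl, registry)
    flags <- flag_chemicals(ear_agg$ear_max, control$ear_threshold)
    pe <- priority_endpoints(ear_tbl, n_sites,
                             site_threshold = control$endpoint_site_threshold,
                             prevalence = control$prevalence,
                             member_threshold = control$member_threshold,
                             major_threshold = control$major_threshold)
    if (!is.null(aop_map)) pe <- annotate_endpoints(pe, aop_map)
  }

  pah <- pah_mixtures(measurements, registry, control$tec, control$pec)
  esb <- esbtu(measurements, sites, registry)
  ap <- alkylphenol_mixtures(measurements, sites, registry, control$isqg)

  empty_earmax <- data.frame(site_id = character(), chemical_id = character(),
                             ear_max = numeric())
  chem_pri <- chemical_priority(tqmax,
                                if (have_ear) ear_agg$ear_max else empty_earmax,
                                measurements, registry, n_sites,
                                prevalence = control$prevalence,
                                ladder = control$ladder)

  ear_site_counts <- if (have_ear)
    flag_chemicals(ear_agg$ear_max, 0.01)$per_site
  else data.frame(site_id = character(), n_chemicals = integer())
  sp <- site_priority(site_ids, tq_exc$per_site, ear_site_counts,
                      tq_agg$by_sample,
                      if (have_ear) ear_agg$by_sample
                      else data.frame(site_id = character(), ear_sample = numeric()),
                      pah, esb$by_site, ap, have_ear = have_ear)
  sp <- rank_sites(sp)

  metrics <- data.frame(site_id = sp$site_id,
                        sediment_tq_sample = sp$sediment_tq_sample_value,
                        porewater_tq_sample = sp$porewater_tq_sample_value,
                        stringsAsFactors = FALSE)
  if (have_ear) metrics$ear_sample <- sp$ear_sample_value
  attr_cols <- setdiff(names(sites)[vapply(sites, is.numeric, TRUE)], "toc_percent")
  correlations <- if (length(attr_cols))
    watershed_correlations(metrics, sites, alpha = control$alpha,
                           adjust = control$adjust_correlations)
  else NULL

  structure(list(porewater = pw,
                 tq = list(long = rbind(sed$long, pwq$long), tq_max = tqmax,
                           aggregates = tq_agg, exceedances = tq_exc),
                 ear = if (have_ear) list(table = ear_tbl, aggregates = ear_agg,
                                          flags = flags,
                                          priority_endpoints = pe) else NULL,
                 mixtures = list(pah = pah, esb = esb, alkylphenol = ap),
                 chemical_priority = chem_pri,
                 site_priority = sp,
                 correlations = correlations,
                 n_sites = n_sites, control = control),
            class = "sed_screen")
}

#' @export
print.sed_screen <- function(x, ...) {
  cat("Sediment chemical screening\n")
  cat(sprintf("  %d sites, %d chemicals\n", x$n_sites,
              nrow(x$chemical_priority)))
  lv <- table(factor(x$chemical_priority$level,
                     levels = c("P1", "P2", "P3", "uncategorized",
                                "no_benchmarks", "low")))
  cat("  chemical priority levels: ",
      paste(sprintf("%s=%d", names(lv), lv), collapse = ", "), "\n", sep = "")
  top <- utils::head(x$site_priority, 5)
  cat("  top sites (overall score, lower = higher priority):\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %d. %s (%.2f)\n", top$rank[i], top$site_id[i],
                top$overall_score[i]))
  invisible(x)
}

#' @export
summary.sed_screen <- function(object, ...) {
  exc <- object$tq$exceedances$per_chemical
  n_sed <- sum(exc$medium == "sediment")
  n_pw <- sum(exc$medium == "porewater")
  n_ear <- if (!is.null(object$ear)) nrow(object$ear$flags$per_chemical) else NA_integer_
  pah_cat <- table(factor(object$mixtures$pah$category,
                          levels = c("unlikely", "possible", "likely")))
  out <- list(n_sites = object$n_sites,
              n_chemicals = nrow(object$chemical_priority),
              n_exceed_sediment = n_sed,
              n_exceed_porewater = n_pw,
              n_exceed_ear = n_ear,
              n_esbtu_exceed = sum(object$mixtures$esb$by_site$esbtu_sum > 1,
                                   na.rm = TRUE),
              n_tq_ap_exceed = sum(object$mixtures$alkylphenol$tq_ap > 1,
                                   na.rm = TRUE),
              pah_categories = pah_cat,
              priority_levels = table(object$chemical_priority$level),
              n_priority_endpoints = if (!is.null(object$ear))
                nrow(object$ear$priority_endpoints$endpoints) else NA_integer_,
              top_sites = utils::head(object$site_priority[
                , c("rank", "site_id", "overall_score", "n_methods_available")], 10))
  class(out) <- "summary.sed_screen"
  out
}

#' @export
print.summary.sed_screen <- function(x, ...) {
  cat("Sediment chemical screening summary\n")
  cat(sprintf("  sites: %d, chemicals: %d\n", x$n_sites, x$n_chemicals))
  cat(sprintf("  chemicals exceeding benchmarks: sediment TQ_Max > 1: %d; porewater TQ_Max > 1: %d; EAR_Max > 0.001: %s\n",
              x$n_exceed_sediment, x$n_exceed_porewater,
              ifelse(is.na(x$n_exceed_ear), "n/a", x$n_exceed_ear)))
  cat("  PAH mixture categories: ",
      paste(sprintf("%s=%d", names(x$pah_categories), x$pah_categories),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  sites with toxic-unit sum > 1: %d; alkylphenol quotient > 1: %d\n",
              x$n_esbtu_exceed, x$n_tq_ap_exceed))
  if (!is.na(x$n_priority_endpoints))
    cat(sprintf("  priority endpoint mixtures retained: %d\n",
                x$n_priority_endpoints))
  cat("  top-ranked sites:\n")
  print(x$top_sites, row.names = FALSE)
  invisible(x)
}

#' Plot method for screening results
#'
#' Dot plot of per-site overall priority scores in rank order (lower score =
#' higher priority), with the per-site count of available methods in the
#' axis annotation.
#'
#' @param x A `sed_screen` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sed_screen <- function(x, ...) {
  sp <- x$site_priority
  graphics::plot(sp$rank, sp$overall_score, xlab = "site rank",
                 ylab = "overall priority score (1 = highest priority)",
                 ylim = c(1, 4), pch = 19, ...)
  graphics::axis(3, at = utils::head(sp$rank, 5),
                 labels = utils::head(sp$site_id, 5), las = 2, cex.axis = 0.7)
  invisible(x)
}
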