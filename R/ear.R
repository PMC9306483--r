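# Exposure-activity ratios against high-throughput bioactivity cutoffs.
#
# An exposure-activity ratio (EAR) divides the estimated dissolved porewater
# concentration by an assay endpoint's activity concentration at cutoff
# (ACC), the concentration at which measured bioactivity first exceeds
# baseline. EARs are a relative bioactivity-potential ranking, not a risk
# estimate. Within a sample, EAR_Max is the maximum over a chemical's
# endpoints; EAR_Class and EAR_Sample sum EAR_Max over classes and over all
# chemicals; EAR_Endpoint sums EARs of all chemicals acting on one shared
# endpoint, under a concentration-addition assumption.

#' Convert ACC values to µg/L
#'
#' Canonical ACC storage is µg/L so porewater concentrations (µg/L) can be
#' divided by them directly. Micromolar entries convert via the molecular
#' weight: 1 µM of a compound of MW m g/mol is m µg/L. Entries already in
#' µg/L pass through.
#'
#' @param acc_value Positive ACC values.
#' @param acc_unit `"micromolar"` or `"ug_L"` (recycled).
#' @param mw Molecular weight, g/mol; required for micromolar rows.
#' @return ACC in µg/L; `NA` for micromolar rows with missing MW.
#' @export
#' @examples
#' acc_to_ug_per_L(1, "micromolar", 228.29) # 228.29 µg/L
acc_to_ug_per_L <- function(acc_value, acc_unit, mw) {
  if (any(!is.finite(acc_value) | acc_value <= 0))
    stop("acc_value must be positive", call. = FALSE)
  out <- ifelse(acc_unit == "ug_L", acc_value, acc_value * mw)
  as.numeric(out)
}

#' Prepare an ACC table for screening
#'
#' Adds an `acc_ugL` column. Micromolar rows whose chemical has no molecular
#' weight in the registry cannot be converted and are dropped with a warning.
#'
#' @param acc Validated ACC table.
#' @param registry Validated chemical registry (supplies `mw`).
#' @return The ACC table with an `acc_ugL` column, unconvertible rows
#'   removed.
#' @export
prepare_acc <- function(acc, registry) {
  validate_acc(acc)
  validate_registry(registry)
  mw <- registry$mw[match(acc$chemical_id, registry$chemical_id)]
  drop <- acc$acc_unit == "micromolar" & is.na(mw)
  if (any(drop)) {
    warning(sum(drop), " micromolar ACC row(s) dropped: no molecular weight for ",
            paste(unique(acc$chemical_id[drop]), collapse = ", "))
    acc <- acc[!drop, , drop = FALSE]
    mw <- mw[!drop]
  }
  acc$acc_ugL <- acc_to_ug_per_L(acc$acc_value, acc$acc_unit, mw)
  rownames(acc) <- NULL
  acc
}

#' Compute exposure-activity ratios
#'
#' One row per (site, chemical, non-excluded endpoint) for chemicals whose
#' porewater status is `ok` or `censored`; censored chemicals yield an EAR of
#' zero. Excluded ACC rows (quality flags, poor dose-response curves) never
#' contribute.
#'
#' @param pw Porewater table from [porewater_table()].
#' @param acc ACC table; passed through [prepare_acc()] if `acc_ugL` is
#'   absent.
#' @param registry Validated chemical registry.
#' @return Data frame with `site_id`, `chemical_id`, `endpoint_id`, `ear`.
#' @export
compute_ear <- function(pw, acc, registry) {
  if (!"acc_ugL" %in% names(acc)) acc <- prepare_acc(acc, registry)
  acc <- acc[!acc$excluded, , drop = FALSE]
  use <- pw$status %in% c("ok", "censored")
  conc <- pw[use, c("site_id", "chemical_id", "c_pw")]
  out <- merge(conc, acc[, c("chemical_id", "endpoint_id", "acc_ugL")],
               by = "chemical_id")
  out$ear <- if (nrow(out)) out$c_pw / out$acc_ugL else numeric(0)
  out <- out[order(out$site_id, out$chemical_id, out$endpoint_id),
             c("site_id", "chemical_id", "endpoint_id", "ear")]
  rownames(out) <- NULL
  out
}

#' EAR aggregates
#'
#' Computes the four summary statistics: `ear_max` per (site, chemical) over
#' that chemical's endpoints; `ear_class` per (site, class), the sum of
#' EAR_Max over class members; `ear_sample` per site, the sum over all
#' chemicals; and `ear_endpoint` per (site, endpoint), the additive sum over
#' chemicals acting on a shared endpoint.
#'
#' @param ear EAR table from [compute_ear()].
#' @param registry Validated chemical registry.
#' @return List with `ear_max`, `by_class`, `by_sample`, `by_endpoint` data
#'   frames.
#' @export
aggregate_ear <- function(ear, registry) {
  validate_registry(registry)
  empty <- list(
    ear_max = data.frame(site_id = character(), chemical_id = character(),
                         ear_max = numeric()),
    by_class = data.frame(site_id = character(), chem_class = character(),
                          ear_class = numeric()),
    by_sample = data.frame(site_id = character(), ear_sample = numeric()),
    by_endpoint = data.frame(site_id = character(), endpoint_id = character(),
                             ear_endpoint = numeric()))
  if (!nrow(ear)) return(empty)
  ear_max <- aggregate(list(ear_max = ear$ear),
                       by = list(site_id = ear$site_id,
                                 chemical_id = ear$chemical_id), FUN = max)
  cls <- registry$chem_class[match(ear_max$chemical_id, registry$chemical_id)]
  by_class <- aggregate(list(ear_class = ear_max$ear_max),
                        by = list(site_id = ear_max$site_id, chem_class = cls),
                        FUN = sum)
  by_sample <- aggregate(list(ear_sample = by_class$ear_class),
                         by = list(site_id = by_class$site_id), FUN = sum)
  by_endpoint <- aggregate(list(ear_endpoint = ear$ear),
                           by = list(site_id = ear$site_id,
                                     endpoint_id = ear$endpoint_id), FUN = sum)
  list(ear_max = ear_max[order(ear_max$site_id, ear_max$chemical_id), ],
       by_class = by_class[order(by_class$site_id, by_class$chem_class), ],
       by_sample = by_sample[order(by_sample$site_id), ],
       by_endpoint = by_endpoint[order(by_endpoint$site_id,
                                       by_endpoint$endpoint_id), ])
}

#' Flag chemicals by EAR_Max exceedance
#'
#' Strict `>` comparison of per-site EAR_Max values against the screening
#' threshold (default 0.001, a level of potential concern relative to
#' established water quality benchmarks).
#'
#' @param ear_max `ear_max` data frame from [aggregate_ear()].
#' @param threshold Positive threshold; default `0.001`.
#' @return List with `per_chemical` (`chemical_id`, `n_sites`, and the site
#'   ids as a list column `sites`) and `per_site` (`site_id`,
#'   `n_chemicals`).
#' @export
flag_chemicals <- function(ear_max, threshold = 0.001) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive", call. = FALSE)
  ex <- ear_max[ear_max$ear_max > threshold, , drop = FALSE]
  if (!nrow(ex)) {
    return(list(per_chemical = data.frame(chemical_id = character(),
                                          n_sites = integer()),
                per_site = data.frame(site_id = character(),
                                      n_chemicals = integer())))
  }
  per_chem <- aggregate(list(n_sites = rep(1L, nrow(ex))),
                        by = list(chemical_id = ex$chemical_id), FUN = sum)
  per_chem$sites <- lapply(per_chem$chemical_id,
                           function(ch) sort(ex$site_id[ex$chemical_id == ch]))
  per_site <- aggregate(list(n_chemicals = rep(1L, nrow(ex))),
                        by = list(site_id = ex$site_id), FUN = sum)
  list(per_chemical = per_chem, per_site = per_site)
}

#' Priority endpoint mixtures
#'
#' Identifies assay endpoints whose additive EAR_Endpoint exceeds
#' `site_threshold` (strict `>`) at a sufficient number of sites: at least
#' `max(1, floor(prevalence * n_sites))` sites (so 20% of 71 sites requires
#' 14). For each retained endpoint and site, the member chemicals of the
#' mixture are those contributing an EAR of at least `member_threshold`
#' (10% of the 0.01 screening benchmark, i.e. 0.001, compared with `>=`).
#' Chemicals contributing an EAR of at least `major_threshold` (0.01) at the
#' prevalence number of sites or more are additionally flagged as major
#' contributors.
#'
#' @param ear EAR table from [compute_ear()].
#' @param n_sites Total number of sites in the study.
#' @param site_threshold EAR_Endpoint retention threshold (default 0.1).
#' @param prevalence Required fraction of sites, in (0, 1] (default 0.2).
#' @param member_threshold Per-chemical mixture-membership threshold
#'   (default 0.001).
#' @param major_threshold Major-contributor threshold (default 0.01).
#' @return Object of class `priority_endpoints`: list with `endpoints`
#'   (`endpoint_id`, `n_sites_exceeding`), `members` (`endpoint_id`,
#'   `site_id`, `chemical_id`, `ear`), `major_contributors` (`endpoint_id`,
#'   `chemical_id`, `n_sites`), `required_sites`, and the thresholds used.
#' @export
priority_endpoints <- function(ear, n_sites, site_threshold = 0.1,
                               prevalence = 0.2, member_threshold = 0.001,
                               major_threshold = 0.01) {
  if (!(prevalence > 0 && prevalence <= 1))
    stop("prevalence must be in (0, 1]", call. = FALSE)
  required <- max(1L, floor(prevalence * n_sites))

  by_endpoint <- aggregate(list(ear_endpoint = ear$ear),
                           by = list(site_id = ear$site_id,
                                     endpoint_id = ear$endpoint_id), FUN = sum)
  ex <- by_endpoint[by_endpoint$ear_endpoint > site_threshold, , drop = FALSE]
  counts <- if (nrow(ex))
    aggregate(list(n_sites_exceeding = rep(1L, nrow(ex))),
              by = list(endpoint_id = ex$endpoint_id), FUN = sum)
  else data.frame(endpoint_id = character(), n_sites_exceeding = integer())
  kept <- counts[counts$n_sites_exceeding >= required, , drop = FALSE]
  kept <- kept[order(-kept$n_sites_exceeding, kept$endpoint_id), ]
  rownames(kept) <- NULL

  mem <- ear[ear$endpoint_id %in% kept$endpoint_id &
               ear$ear >= member_threshold, , drop = FALSE]
  members <- mem[order(mem$endpoint_id, mem$site_id, -mem$ear),
                 c("endpoint_id", "site_id", "chemical_id", "ear")]
  rownames(members) <- NULL

  maj <- ear[ear$endpoint_id %in% kept$endpoint_id &
               ear$ear >= major_threshold, , drop = FALSE]
  major <- if (nrow(maj))
    aggregate(list(n_sites = rep(1L, nrow(maj))),
              by = list(endpoint_id = maj$endpoint_id,
                        chemical_id = maj$chemical_id), FUN = sum)
  else data.frame(endpoint_id = character(), chemical_id = character(),
                  n_sites = integer())
  major <- major[major$n_sites >= required, , drop = FALSE]
  major <- major[order(major$endpoint_id, major$chemical_id), ]
  rownames(major) <- NULL

  structure(list(endpoints = kept, members = members,
                 major_contributors = major, required_sites = required,
                 n_sites = n_sites, site_threshold = site_threshold,
                 prevalence = prevalence, member_threshold = member_threshold,
                 major_threshold = major_threshold),
            class = "priority_endpoints")
}

#' @export
print.priority_endpoints <- function(x, ...) {
  cat("Priority endpoint mixtures\n")
  cat(sprintf("  retention: EAR_Endpoint > %g at >= %d of %d sites\n",
              x$site_threshold, x$required_sites, x$n_sites))
  cat(sprintf("  %d endpoint(s) retained, %d major contributor pair(s)\n",
              nrow(x$endpoints), nrow(x$major_contributors)))
  if (nrow(x$endpoints)) print(x$endpoints, ...)
  invisible(x)
}

#' Annotate priority endpoints with gene targets and adverse outcome pathways
#'
#' Left-joins the retained endpoints against an endpoint-to-gene-to-AOP
#' mapping table. Endpoints absent from the map are kept with empty
#' annotation; they are never dropped.
#'
#' @param report A `priority_endpoints` object.
#' @param map Validated AOP map.
#' @return The report with its `endpoints` table gaining `gene_symbol`,
#'   `aop_ids`, `annotation` columns (semicolon-joined when an endpoint maps
#'   to several genes).
#' @export
annotate_endpoints <- function(report, map) {
  stopifnot(inherits(report, "priority_endpoints"))
  validate_aop_map(map)
  ep <- report$endpoints
  join1 <- function(id, col) {
    v <- map[[col]][map$endpoint_id == id]
    v <- v[!is.na(v) & nzchar(v)]
    if (!length(v)) "" else paste(unique(v), collapse = ";")
  }
  ep$gene_symbol <- vapply(ep$endpoint_id, join1, "", col = "gene_symbol")
  ep$aop_ids <- vapply(ep$endpoint_id, join1, "", col = "aop_ids")
  ep$annotation <- if ("annotation" %in% names(map))
    vapply(ep$endpoint_id, join1, "", col = "annotation") else ""
  report$endpoints <- ep
  report
}
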