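# Toxicity quotients against compiled quality benchmarks.
#
# A toxicity quotient (TQ) is concentration / benchmark in matching units;
# TQ > 1 flags potential adverse effects. Chemicals often have several
# benchmarks per medium (spanning up to an order of magnitude); the TQ
# against the most sensitive (lowest) benchmark is the chemical's TQ_Max at
# that site. TQ_Max values are summed within chemical classes (TQ_Class) and
# across the whole sample (TQ_Sample). The sediment and porewater pipelines
# are parallel structures distinguished only by the medium tag; no sum ever
# mixes media.

#' Toxicity quotient
#'
#' @param conc Concentration (>= 0), same units as `benchmark`.
#' @param benchmark Benchmark value (> 0).
#' @return `conc / benchmark`, dimensionless. Vectorized.
#' @export
#' @examples
#' tq(51600, 1400) # 36.86, a more than 10-fold exceedance
tq <- function(conc, benchmark) {
  if (any(!is.finite(benchmark) | benchmark <= 0))
    stop("benchmark must be positive", call. = FALSE)
  if (any(conc < 0)) stop("concentration must be non-negative", call. = FALSE)
  conc / benchmark
}

#' Maximum toxicity quotient over a chemical's benchmarks
#'
#' The TQ against the most sensitive (lowest) benchmark, which equals the
#' maximum over per-benchmark TQs. Value ties between benchmarks are broken
#' by first occurrence, so the reported `benchmark_used` is deterministic.
#'
#' @param conc Single concentration (>= 0).
#' @param benchmarks Numeric vector of benchmark values (> 0). An empty
#'   vector means the chemical is unscreenable in this medium: the result is
#'   absent (`NA`), not zero.
#' @return List with `tq_max` and `benchmark_used`.
#' @export
#' @examples
#' tq_max(100, c(50, 200, 500)) # tq_max 2.0 against benchmark 50
tq_max <- function(conc, benchmarks) {
  if (length(benchmarks) == 0L)
    return(list(tq_max = NA_real_, benchmark_used = NA_real_))
  i <- which.min(benchmarks) # first occurrence wins ties
  list(tq_max = tq(conc, benchmarks[i]), benchmark_used = benchmarks[i])
}

#' Long TQ table and per-chemical TQ_Max for one medium
#'
#' Joins concentrations with every available benchmark in the requested
#' medium. For sediment the measured concentration is used directly (censored
#' rows contribute a TQ of 0); for porewater only rows with porewater status
#' `ok` or `censored` are screenable.
#'
#' @param m Normalized measurement table.
#' @param pw Porewater table from [porewater_table()]; required when
#'   `medium = "porewater"`.
#' @param benchmarks Validated benchmark table.
#' @param medium `"sediment"` or `"porewater"`.
#' @return List with `long` (one row per site x chemical x benchmark:
#'   `site_id`, `chemical_id`, `medium`, `benchmark_value`,
#'   `benchmark_source`, `tq`) and `tq_max` (one row per site x chemical:
#'   `site_id`, `chemical_id`, `medium`, `tq_max`, `benchmark_used`,
#'   `censored`).
#' @export
tq_table <- function(m, benchmarks, medium = c("sediment", "porewater"),
                     pw = NULL) {
  medium <- match.arg(medium)
  validate_benchmarks(benchmarks)
  bm <- benchmarks[benchmarks$medium == medium, , drop = FALSE]
  bm$.order <- seq_len(nrow(bm))

  if (medium == "sediment") {
    conc <- data.frame(site_id = m$site_id, chemical_id = m$chemical_id,
                       conc = m$c_sed, censored = m$censored,
                       stringsAsFactors = FALSE)
  } else {
    if (is.null(pw)) stop("porewater table required for medium = 'porewater'",
                          call. = FALSE)
    use <- pw$status %in% c("ok", "censored")
    conc <- data.frame(site_id = pw$site_id[use], chemical_id = pw$chemical_id[use],
                       conc = pw$c_pw[use], censored = pw$status[use] == "censored",
                       stringsAsFactors = FALSE)
  }

  long <- merge(conc, bm, by = "chemical_id")
  if (nrow(long)) {
    long <- long[order(long$site_id, long$chemical_id, long$.order), ]
    long$tq <- tq(long$conc, long$value)
  } else long$tq <- numeric(0)

  # per (site, chemical): min benchmark, ties by file order
  if (nrow(long)) {
    key <- paste(long$site_id, long$chemical_id, sep = "\r")
    # order by value then original file order; first row per key is the
    # most sensitive benchmark with deterministic tie-breaking
    o <- order(key, long$value, long$.order)
    first <- !duplicated(key[o])
    sel <- long[o, ][first, ]
    tqmax <- data.frame(site_id = sel$site_id, chemical_id = sel$chemical_id,
                        medium = medium, tq_max = tq(sel$conc, sel$value),
                        benchmark_used = sel$value, censored = sel$censored,
                        stringsAsFactors = FALSE)
    tqmax <- tqmax[order(tqmax$site_id, tqmax$chemical_id), ]
    rownames(tqmax) <- NULL
  } else {
    tqmax <- data.frame(site_id = character(), chemical_id = character(),
                        medium = character(), tq_max = numeric(),
                        benchmark_used = numeric(), censored = logical(),
                        stringsAsFactors = FALSE)
  }

  long_out <- data.frame(site_id = long$site_id, chemical_id = long$chemical_id,
                         medium = medium, benchmark_value = long$value,
                         benchmark_source = if ("source" %in% names(long))
                           long$source else NA_character_,
                         tq = long$tq, stringsAsFactors = FALSE)
  rownames(long_out) <- NULL
  list(long = long_out, tq_max = tqmax)
}

#' Class and sample TQ aggregates
#'
#' Sums TQ_Max values within each chemical class (TQ_Class) and across all
#' chemicals (TQ_Sample) per site and medium. Chemicals without a benchmark
#' in a medium contribute nothing (they are absent from the input); censored
#' chemicals contribute zero. By construction TQ_Sample equals the sum of
#' the TQ_Class values at each site.
#'
#' @param tqmax Per-chemical TQ_Max table (from [tq_table()]), any mix of
#'   media.
#' @param registry Validated chemical registry (supplies classes).
#' @return List with `by_class` (`site_id`, `medium`, `chem_class`,
#'   `tq_class`) and `by_sample` (`site_id`, `medium`, `tq_sample`).
#' @export
aggregate_tq <- function(tqmax, registry) {
  validate_registry(registry)
  if (!nrow(tqmax)) {
    return(list(by_class = data.frame(site_id = character(), medium = character(),
                                      chem_class = character(), tq_class = numeric()),
                by_sample = data.frame(site_id = character(), medium = character(),
                                       tq_sample = numeric())))
  }
  cls <- registry$chem_class[match(tqmax$chemical_id, registry$chemical_id)]
  by_class <- aggregate(list(tq_class = tqmax$tq_max),
                        by = list(site_id = tqmax$site_id, medium = tqmax$medium,
                                  chem_class = cls), FUN = sum)
  by_sample <- aggregate(list(tq_sample = by_class$tq_class),
                         by = list(site_id = by_class$site_id,
                                   medium = by_class$medium), FUN = sum)
  list(by_class = by_class[order(by_class$medium, by_class$site_id,
                                 by_class$chem_class), ],
       by_sample = by_sample[order(by_sample$medium, by_sample$site_id), ])
}

#' Count TQ_Max exceedances
#'
#' Strict-inequality counts of chemicals (per site) and sites (per chemical)
#' with `tq_max > threshold`. Censored chemicals have TQ_Max 0 and are never
#' counted.
#'
#' @param tqmax Per-chemical TQ_Max table.
#' @param threshold Positive exceedance threshold (default 1).
#' @return List with `per_site` (`site_id`, `medium`, `n_chemicals`) and
#'   `per_chemical` (`chemical_id`, `medium`, `n_sites`).
#' @export
count_exceedances <- function(tqmax, threshold = 1) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive", call. = FALSE)
  ex <- tqmax[!is.na(tqmax$tq_max) & tqmax$tq_max > threshold, , drop = FALSE]
  agg <- function(df, by) {
    if (!nrow(df)) return(data.frame())
    aggregate(list(n = rep(1L, nrow(df))), by = by, FUN = sum)
  }
  per_site <- agg(ex, list(site_id = ex$site_id, medium = ex$medium))
  if (nrow(per_site)) names(per_site)[names(per_site) == "n"] <- "n_chemicals"
  else per_site <- data.frame(site_id = character(), medium = character(),
                              n_chemicals = integer())
  per_chem <- agg(ex, list(chemical_id = ex$chemical_id, medium = ex$medium))
  if (nrow(per_chem)) names(per_chem)[names(per_chem) == "n"] <- "n_sites"
  else per_chem <- data.frame(chemical_id = character(), medium = character(),
                              n_sites = integer())
  list(per_site = per_site, per_chemical = per_chem)
}
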