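# Input tables: reading, validation, normalization, and descriptive QC.
#
# Canonical in-memory schemas are plain data frames with fixed column names.
# CSV files use the column names documented in each reader; units are µg/kg
# dry weight for sediment concentrations, µg/L for porewater, percent for TOC.

#' The fourteen chemical classes
#'
#' Class labels used to aggregate chemicals for class-level summations and
#' reporting. Registries may use any subset, but labels outside this set are
#' rejected during validation.
#'
#' @return Character vector of the 14 recognized class labels.
#' @export
#' @examples
#' chem_classes()
chem_classes <- function() {
  c("antimicrobial disinfectants", "antioxidants", "detergent metabolites",
    "dyes and pigments", "fire retardants", "flavors and fragrances",
    "fuels", "herbicides", "insecticides", "nonprescription drugs",
    "PAHs", "plasticizers", "solvents", "sterols")
}

# required columns per canonical table (in-memory names)
.registry_cols <- c("chemical_id", "name", "chem_class", "koc", "mw",
                    "reporting_limit", "tef", "fcv",
                    "is_pah16", "is_esb_pah", "is_alkylphenol")

.stop_rows <- function(msg, rows) {
  stop(msg, ": ", paste(utils::head(rows, 5L), collapse = ", "),
       if (length(rows) > 5L) sprintf(" (and %d more)", length(rows) - 5L),
       call. = FALSE)
}

#' Validate a chemical registry
#'
#' Checks uniqueness of `chemical_id`, recognized class labels, positivity of
#' the physical constants where present, the range of toxic equivalency
#' factors, and consistency of the 16-PAH membership flag with the PAH class.
#'
#' @param reg Data frame with columns `chemical_id`, `name`, `chem_class`,
#'   `koc` (L/kg), `mw` (g/mol), `reporting_limit` (µg/kg dry wt), `tef`
#'   (dimensionless, relative to nonylphenol), `fcv` (µg/g organic carbon),
#'   and logical flags `is_pah16`, `is_esb_pah`, `is_alkylphenol`.
#'   Optional constants are `NA` where unknown, never zero.
#' @return `reg`, invisibly, if valid; otherwise an error.
#' @export
validate_registry <- function(reg) {
  stopifnot(is.data.frame(reg))
  miss <- setdiff(.registry_cols, names(reg))
  if (length(miss)) .stop_rows("registry is missing required columns", miss)
  dup <- reg$chemical_id[duplicated(reg$chemical_id)]
  if (length(dup)) .stop_rows("duplicate chemical_id in registry", unique(dup))
  bad <- !reg$chem_class %in% chem_classes()
  if (any(bad)) .stop_rows("unknown chem_class label for", reg$chemical_id[bad])
  for (col in c("koc", "mw", "reporting_limit", "fcv")) {
    v <- reg[[col]]
    if (!is.numeric(v)) stop("registry column '", col, "' must be numeric", call. = FALSE)
    if (any(!is.na(v) & v <= 0))
      .stop_rows(paste0("non-positive ", col, " for"), reg$chemical_id[!is.na(v) & v <= 0])
  }
  if (any(!is.na(reg$tef) & (reg$tef <= 0 | reg$tef > 1)))
    .stop_rows("tef outside (0, 1] for",
               reg$chemical_id[!is.na(reg$tef) & (reg$tef <= 0 | reg$tef > 1)])
  inconsistent <- reg$is_pah16 & reg$chem_class != "PAHs"
  if (any(inconsistent))
    .stop_rows("is_pah16 chemicals must have chem_class 'PAHs'",
               reg$chemical_id[inconsistent])
  invisible(reg)
}

#' Read a chemical registry from CSV
#'
#' Expected columns: `chemical_id`, `name`, `chem_class`, `koc_L_kg`,
#' `mw_g_mol`, `reporting_limit_ug_kg`, `tef`, `fcv_ug_gOC`, `is_pah16`,
#' `is_esb_pah`, `is_alkylphenol`. Empty cells in the constant columns become
#' `NA` (missing), never zero.
#'
#' @param path Path to a UTF-8, comma-separated CSV file with a header row.
#' @return A validated registry data frame (canonical column names).
#' @export
read_registry <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  want <- c(chemical_id = "chemical_id", name = "name", chem_class = "chem_class",
            koc = "koc_L_kg", mw = "mw_g_mol", reporting_limit = "reporting_limit_ug_kg",
            tef = "tef", fcv = "fcv_ug_gOC", is_pah16 = "is_pah16",
            is_esb_pah = "is_esb_pah", is_alkylphenol = "is_alkylphenol")
  miss <- setdiff(unname(want), names(raw))
  if (length(miss)) .stop_rows("registry CSV is missing columns", miss)
  reg <- data.frame(chemical_id = as.character(raw$chemical_id),
                    name = as.character(raw$name),
                    chem_class = as.character(raw$chem_class),
                    stringsAsFactors = FALSE)
  for (col in c("koc", "mw", "reporting_limit", "tef", "fcv")) {
    v <- raw[[want[[col]]]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    vn <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & is.na(vn)))
      .stop_rows(paste0("non-numeric ", col, " for"), reg$chemical_id[!is.na(v) & is.na(vn)])
    reg[[col]] <- vn
  }
  for (col in c("is_pah16", "is_esb_pah", "is_alkylphenol"))
    reg[[col]] <- .as_flag(raw[[want[[col]]]], col)
  validate_registry(reg)
  reg
}

.as_flag <- function(v, what) {
  if (is.logical(v)) return(ifelse(is.na(v), FALSE, v))
  if (is.numeric(v)) return(ifelse(is.na(v), FALSE, v != 0))
  v <- tolower(trimws(as.character(v)))
  out <- v %in% c("true", "t", "1", "yes")
  bad <- !v %in% c("true", "t", "1", "yes", "false", "f", "0", "no", "", "na")
  if (any(bad)) stop("unparseable logical values in '", what, "'", call. = FALSE)
  out
}

#' Normalize raw measurement rows
#'
#' Applies the non-detect convention: concentrations reported below the
#' laboratory reporting limit are stored as zero with `censored = TRUE`, so
#' they contribute nothing to any summation. Detected values pass through
#' unchanged. A tolerant reader converts `"<x"` strings to censored rows.
#' Missing (site, chemical) pairs stay absent, which is distinct from
#' censored: absent means not reported at all.
#'
#' @param raw Data frame with columns `site_id`, `chemical_id`, `c_sed`
#'   (numeric µg/kg dry wt, or character possibly `"<"`-prefixed) and
#'   optionally `censored` (logical).
#' @param registry Validated chemical registry; rows with unknown
#'   `chemical_id` are a hard error.
#' @return Data frame with columns `site_id`, `chemical_id`, `c_sed`,
#'   `censored`; censored rows have `c_sed = 0`.
#' @export
#' @examples
#' reg <- data.frame(chemical_id = "naphthalene", name = "naphthalene",
#'                   chem_class = "PAHs", koc = 1300, mw = 128.2,
#'                   reporting_limit = 5, tef = NA, fcv = 385,
#'                   is_pah16 = TRUE, is_esb_pah = TRUE, is_alkylphenol = FALSE)
#' raw <- data.frame(site_id = c("A", "B"), chemical_id = "naphthalene",
#'                   c_sed = c("12.0", "<5"))
#' normalize_measurements(raw, reg)
normalize_measurements <- function(raw, registry) {
  stopifnot(all(c("site_id", "chemical_id", "c_sed") %in% names(raw)))
  validate_registry(registry)
  unknown <- setdiff(unique(raw$chemical_id), registry$chemical_id)
  if (length(unknown)) .stop_rows("measurements reference unregistered chemicals", unknown)

  cens <- if ("censored" %in% names(raw)) .as_flag(raw$censored, "censored") else
    rep(FALSE, nrow(raw))
  v <- raw$c_sed
  if (is.character(v)) {
    v <- trimws(v)
    lt <- startsWith(v, "<")
    cens <- cens | lt
    v[lt] <- "0"
    v <- suppressWarnings(as.numeric(v))
    if (anyNA(v)) stop("unparseable concentration values in measurements", call. = FALSE)
  }
  if (any(is.na(v))) stop("missing concentration values in measurements", call. = FALSE)
  if (any(v < 0)) stop("negative sediment concentrations are not allowed", call. = FALSE)

  out <- data.frame(site_id = as.character(raw$site_id),
                    chemical_id = as.character(raw$chemical_id),
                    c_sed = as.numeric(v),
                    censored = cens,
                    stringsAsFactors = FALSE)
  out$c_sed[out$censored] <- 0
  key <- paste(out$site_id, out$chemical_id, sep = "\r")
  if (anyDuplicated(key))
    .stop_rows("duplicate (site_id, chemical_id) measurement rows",
               unique(key[duplicated(key)]))
  rownames(out) <- NULL
  out
}

#' Read measurements from CSV
#'
#' Expected columns: `site_id`, `chemical_id`, `c_sed_ug_kg`, `censored`.
#' The concentration column may contain `"<x"` strings, which are converted
#' to censored rows.
#'
#' @param path CSV path.
#' @param registry Validated chemical registry.
#' @return Normalized measurement table (see [normalize_measurements()]).
#' @export
read_measurements <- function(path, registry) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(c_sed_ug_kg = "character"))
  if (!"c_sed_ug_kg" %in% names(raw))
    stop("measurements CSV must have a 'c_sed_ug_kg' column", call. = FALSE)
  names(raw)[names(raw) == "c_sed_ug_kg"] <- "c_sed"
  normalize_measurements(raw, registry)
}

#' Read the site table from CSV
#'
#' Expected columns: `site_id`, `toc_percent`, plus any number of numeric
#' watershed-attribute columns (population density, percent impervious, ...).
#'
#' @param path CSV path.
#' @return Data frame with `site_id`, `toc_percent`, and attribute columns.
#' @export
read_sites <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_sites(df)
  df$site_id <- as.character(df$site_id)
  df
}

#' Validate a site table
#'
#' @param sites Data frame with `site_id` (unique), `toc_percent` in (0, 100]
#'   (NA allowed: such sites are skipped by porewater and TOC-normalized
#'   metrics), and numeric attribute columns.
#' @return `sites`, invisibly.
#' @export
validate_sites <- function(sites) {
  stopifnot(is.data.frame(sites), all(c("site_id", "toc_percent") %in% names(sites)))
  dup <- sites$site_id[duplicated(sites$site_id)]
  if (length(dup)) .stop_rows("duplicate site_id", unique(dup))
  toc <- sites$toc_percent
  if (any(!is.na(toc) & toc > 100))
    .stop_rows("toc_percent above 100 for", sites$site_id[!is.na(toc) & toc > 100])
  invisible(sites)
}

#' Read benchmark table from CSV
#'
#' Expected columns: `chemical_id`, `medium` (`"sediment"` or `"porewater"`),
#' `value` (µg/kg dry wt for sediment, µg/L for porewater), `source`,
#' `effect_label`. A chemical may have zero, one, or many benchmarks per
#' medium; row order is preserved (used to break value ties).
#'
#' @param path CSV path.
#' @return Validated benchmark data frame.
#' @export
read_benchmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_benchmarks(df)
  df
}

#' Validate a benchmark table
#' @param bm Data frame with `chemical_id`, `medium`, `value` (> 0), `source`,
#'   `effect_label`.
#' @return `bm`, invisibly.
#' @export
validate_benchmarks <- function(bm) {
  stopifnot(is.data.frame(bm),
            all(c("chemical_id", "medium", "value") %in% names(bm)))
  if (!all(bm$medium %in% c("sediment", "porewater")))
    stop("benchmark medium must be 'sediment' or 'porewater'", call. = FALSE)
  if (any(!is.finite(bm$value) | bm$value <= 0))
    stop("benchmark values must be positive", call. = FALSE)
  invisible(bm)
}

#' Read the bioactivity (ACC) table from CSV
#'
#' Expected columns: `chemical_id`, `endpoint_id`, `acc_value`, `acc_unit`
#' (`"micromolar"` or `"ug_L"`), `gene_symbol`, `excluded`,
#' `exclusion_reason`. Rows flagged `excluded` are retained in the table but
#' never contribute to any exposure-activity ratio.
#'
#' @param path CSV path.
#' @return Validated ACC data frame.
#' @export
read_acc <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"gene_symbol" %in% names(df)) df$gene_symbol <- NA_character_
  if (!"exclusion_reason" %in% names(df)) df$exclusion_reason <- NA_character_
  df$excluded <- .as_flag(df$excluded, "excluded")
  validate_acc(df)
  df
}

#' Validate an ACC table
#' @param acc Data frame with `chemical_id`, `endpoint_id`, `acc_value` (> 0),
#'   `acc_unit` in `micromolar`/`ug_L`, logical `excluded`; the pair
#'   (`chemical_id`, `endpoint_id`) must be unique.
#' @return `acc`, invisibly.
#' @export
validate_acc <- function(acc) {
  stopifnot(is.data.frame(acc),
            all(c("chemical_id", "endpoint_id", "acc_value", "acc_unit",
                  "excluded") %in% names(acc)))
  if (any(!is.finite(acc$acc_value) | acc$acc_value <= 0))
    stop("ACC values must be positive", call. = FALSE)
  if (!all(acc$acc_unit %in% c("micromolar", "ug_L")))
    stop("acc_unit must be 'micromolar' or 'ug_L'", call. = FALSE)
  key <- paste(acc$chemical_id, acc$endpoint_id, sep = "\r")
  if (anyDuplicated(key))
    .stop_rows("duplicate (chemical_id, endpoint_id) ACC rows",
               unique(key[duplicated(key)]))
  invisible(acc)
}

#' Read the endpoint-to-gene-to-AOP mapping table from CSV
#'
#' Expected columns: `endpoint_id`, `gene_symbol`, `aop_ids`
#' (semicolon-joined identifiers), `annotation`.
#'
#' @param path CSV path.
#' @return Validated AOP map data frame.
#' @export
read_aop_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_aop_map(df)
  df
}

#' Validate an AOP map
#' @param map Data frame with `endpoint_id`, `gene_symbol`, `aop_ids`,
#'   `annotation`; (`endpoint_id`, `gene_symbol`) unique.
#' @return `map`, invisibly.
#' @export
validate_aop_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("endpoint_id", "gene_symbol", "aop_ids") %in% names(map)))
  key <- paste(map$endpoint_id, map$gene_symbol, sep = "\r")
  if (anyDuplicated(key))
    .stop_rows("duplicate (endpoint_id, gene_symbol) AOP map rows",
               unique(key[duplicated(key)]))
  invisible(map)
}

#' Per-chemical detection frequency
#'
#' Fraction of sites at which a chemical was detected (reported above the
#' reporting limit). Sites with no measurement row for a chemical count as
#' non-detections: the full analyte list is assumed to have been measured at
#' every site.
#'
#' @param m Normalized measurement table.
#' @param n_sites Number of sites in the study (>= 1).
#' @return Data frame with `chemical_id`, `n_detected`, `detection_frequency`.
#' @export
#' @examples
#' # a chemical detected at 66 of 71 sites has detection frequency 0.93
detection_frequency <- function(m, n_sites) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1)
    stop("n_sites must be a single count >= 1", call. = FALSE)
  det <- m[!m$censored & m$c_sed > 0, ]
  n_det <- table(factor(det$chemical_id, levels = sort(unique(m$chemical_id))))
  data.frame(chemical_id = names(n_det),
             n_detected = as.integer(n_det),
             detection_frequency = as.numeric(n_det) / n_sites,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Relative percent difference between duplicate measurements
#'
#' The standard QC statistic for field duplicates:
#' `|a - b| / ((a + b) / 2) * 100`. Undefined when both values are zero;
#' returns `NA` with a warning in that case.
#'
#' @param a,b Non-negative duplicate concentrations (vectorized).
#' @return RPD in percent, in `[0, 200]`.
#' @export
#' @examples
#' relative_percent_difference(100, 50) # 66.67
#' relative_percent_difference(0, 10)   # 200
relative_percent_difference <- function(a, b) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    stop("duplicate concentrations must be non-negative", call. = FALSE)
  both_zero <- (a + b) == 0
  if (any(both_zero, na.rm = TRUE))
    warning("RPD undefined when both duplicates are zero; returning NA")
  out <- abs(a - b) / ((a + b) / 2) * 100
  out[both_zero] <- NA_real_
  out
}

#' Per-site chemical-class and total concentration sums
#'
#' Sums detected concentrations (censored values contribute zero) within each
#' chemical class and across the whole sample. Because the classes partition
#' the registry, the class sums at a site add up exactly to the site total.
#'
#' @param m Normalized measurement table.
#' @param registry Validated chemical registry.
#' @return List with `by_class` (`site_id`, `chem_class`, `class_total`) and
#'   `by_site` (`site_id`, `site_total`), concentrations in µg/kg dry wt.
#' @export
class_concentration_totals <- function(m, registry) {
  validate_registry(registry)
  unknown <- setdiff(unique(m$chemical_id), registry$chemical_id)
  if (length(unknown)) .stop_rows("unregistered chemicals in measurements", unknown)
  cls <- registry$chem_class[match(m$chemical_id, registry$chemical_id)]
  by_class <- aggregate(list(class_total = m$c_sed),
                        by = list(site_id = m$site_id, chem_class = cls), FUN = sum)
  by_site <- aggregate(list(site_total = by_class$class_total),
                       by = list(site_id = by_class$site_id), FUN = sum)
  by_class <- by_class[order(by_class$site_id, by_class$chem_class), ]
  rownames(by_class) <- rownames(by_site) <- NULL
  list(by_class = by_class, by_site = by_site)
}
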