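# Small in-code fixtures shared across test files.

# registry builder with sensible defaults; override any column by name
make_registry <- function(ids, classes, koc = 1000, mw = 200,
                          reporting_limit = 5, tef = NA_real_,
                          fcv = NA_real_, is_pah16 = FALSE,
                          is_esb_pah = FALSE, is_alkylphenol = FALSE) {
  n <- length(ids)
  data.frame(chemical_id = ids, name = ids,
             chem_class = rep_len(classes, n),
             koc = rep_len(koc, n), mw = rep_len(mw, n),
             reporting_limit = rep_len(reporting_limit, n),
             tef = rep_len(tef, n), fcv = rep_len(fcv, n),
             is_pah16 = rep_len(is_pah16, n),
             is_esb_pah = rep_len(is_esb_pah, n),
             is_alkylphenol = rep_len(is_alkylphenol, n),
             stringsAsFactors = FALSE)
}

make_measurements <- function(site_id, chemical_id, c_sed,
                              censored = FALSE) {
  data.frame(site_id = site_id, chemical_id = chemical_id,
             c_sed = c_sed, censored = rep_len(censored, length(site_id)),
             stringsAsFactors = FALSE)
}

make_sites <- function(site_id, toc_percent = 2, ...) {
  data.frame(site_id = site_id,
             toc_percent = rep_len(toc_percent, length(site_id)), ...,
             stringsAsFactors = FALSE)
}

make_benchmarks <- function(chemical_id, medium, value,
                            source = "test", effect_label = "chronic") {
  data.frame(chemical_id = chemical_id, medium = medium, value = value,
             source = rep_len(source, length(chemical_id)),
             effect_label = rep_len(effect_label, length(chemical_id)),
             stringsAsFactors = FALSE)
}

make_acc <- function(chemical_id, endpoint_id, acc_value,
                     acc_unit = "ug_L", gene_symbol = NA_character_,
                     excluded = FALSE) {
  data.frame(chemical_id = chemical_id, endpoint_id = endpoint_id,
             acc_value = acc_value,
             acc_unit = rep_len(acc_unit, length(chemical_id)),
             gene_symbol = rep_len(gene_symbol, length(chemical_id)),
             excluded = rep_len(excluded, length(chemical_id)),
             exclusion_reason = NA_character_, stringsAsFactors = FALSE)
}

# independent brute-force oracle for the endpoint-mixture rule: loops over
# every endpoint, site, and chemical without any aggregation shortcuts
brute_priority_endpoints <- function(ear, n_sites, site_threshold = 0.1,
                                     prevalence = 0.2,
                                     member_threshold = 0.001,
                                     major_threshold = 0.01) {
  required <- max(1, floor(prevalence * n_sites))
  endpoints <- sort(unique(ear$endpoint_id))
  kept <- character(0); kept_n <- integer(0)
  members <- list(); majors <- list()
  for (ep in endpoints) {
    sub <- ear[ear$endpoint_id == ep, ]
    n_exc <- 0L
    for (s in unique(sub$site_id)) {
      if (sum(sub$ear[sub$site_id == s]) > site_threshold) n_exc <- n_exc + 1L
    }
    if (n_exc < required) next
    kept <- c(kept, ep); kept_n <- c(kept_n, n_exc)
    for (s in unique(sub$site_id)) for (ch in unique(sub$chemical_id)) {
      v <- sub$ear[sub$site_id == s & sub$chemical_id == ch]
      if (length(v) && v >= member_threshold)
        members[[length(members) + 1L]] <-
          data.frame(endpoint_id = ep, site_id = s, chemical_id = ch,
                     ear = v, stringsAsFactors = FALSE)
    }
    for (ch in unique(sub$chemical_id)) {
      n_maj <- sum(vapply(unique(sub$site_id), function(s) {
        v <- sub$ear[sub$site_id == s & sub$chemical_id == ch]
        length(v) > 0 && v >= major_threshold
      }, logical(1)))
      if (n_maj >= required)
        majors[[length(majors) + 1L]] <-
          data.frame(endpoint_id = ep, chemical_id = ch, n_sites = n_maj,
                     stringsAsFactors = FALSE)
    }
  }
  list(endpoints = data.frame(endpoint_id = kept, n_sites_exceeding = kept_n,
                              stringsAsFactors = FALSE),
       members = if (length(members)) do.call(rbind, members) else NULL,
       major_contributors = if (length(majors)) do.call(rbind, majors) else NULL)
}
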