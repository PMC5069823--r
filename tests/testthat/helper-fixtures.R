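# Shared helpers: quick call-table construction and a minimal two-met case.

mk_calls <- function(specimen_id, gene, hgvs_p, af,
                     consequence = "missense", population_af = NA_real_,
                     depth = NA_integer_, alt_reads = NA_integer_) {
  as_variant_calls(data.frame(
    specimen_id = specimen_id, gene = gene, hgvs_p = hgvs_p,
    consequence = consequence, af_percent = af,
    population_af = population_af, depth = depth, alt_reads = alt_reads,
    stringsAsFactors = FALSE))
}

# A single valid case: normal + primary + two liver mets.
mk_case <- function(case_id = "k1", primary_date = "2010-01",
                    met_dates = c("2010-03", "2011-06")) {
  sp <- rbind(
    specimen(paste0(case_id, "_no"), case_id, "normal"),
    specimen(paste0(case_id, "_pt"), case_id, "primary", primary_date),
    specimen(paste0(case_id, "_m1"), case_id, "liver_met", met_dates[1]),
    specimen(paste0(case_id, "_m2"), case_id, "liver_met", met_dates[2]))
  cohort(sp, attributes = stats::setNames(
    list(list(location = "colon_left")), case_id))
}

# Random call table over a fixed small variant universe (keyed by
# gene|hgvs), used by the set-algebra oracle tests.
random_calls <- function(specimens, n_variants = 12, p = 0.5) {
  universe <- data.frame(
    gene = sample(panel_genes(), n_variants, replace = TRUE),
    hgvs_p = paste0("p.A", seq_len(n_variants), "T"))
  rows <- do.call(rbind, lapply(specimens, function(s) {
    pick <- which(stats::runif(n_variants) < p)
    if (!length(pick)) return(NULL)
    data.frame(specimen_id = s, gene = universe$gene[pick],
               hgvs_p = universe$hgvs_p[pick], consequence = "missense",
               af_percent = round(stats::runif(length(pick), 1, 90), 2))
  }))
  if (is.null(rows)) return(empty_calls())
  as_variant_calls(rows)
}
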