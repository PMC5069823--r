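agg_bundle <- local({
  coh <- assign_timing(crc_fixture_manifest())
  calls <- crc_fixture_calls()
  fc <- filter_config()
  som <- somatic_sets(coh, calls, fc)
  list(coh = coh, calls = calls, fc = fc, som = som)
})

test_that("gene-case summary reproduces the printed cohort counts", {
  gs <- gene_case_summary(agg_bundle$coh, agg_bundle$som)
  counts <- stats::setNames(gs$gene_counts$n_cases, gs$gene_counts$gene)
  expect_equal(counts[["TP53"]], 10L)
  expect_equal(counts[["KRAS"]], 8L)
  expect_equal(counts[["SMAD4"]], 2L)
  expect_equal(counts[["FGFR3"]], 1L)
  expect_equal(counts[["NRAS"]], 1L)
  # exact-variant rule: FGFR3 p.P718H occurs once in case 10, only p.P718S
  # qualifies
  c10 <- gs$rows[gs$rows$case_id == "c10" & gs$rows$gene == "FGFR3", ]
  expect_equal(c10$hgvs_p, "p.P718S")
  expect_equal(c10$n_specimens, 2L)
})

test_that("gene-case summary: degenerate and reordering cases", {
  # single tumour specimen per case: nothing occurs twice
  sp <- rbind(specimen("d_no", "d", "normal"),
              specimen("d_pt", "d", "primary", "2010-01"))
  coh1 <- cohort(sp, strict = FALSE)
  som1 <- list(d_pt = mk_calls("d_pt", "TP53", "p.R175H", 40))
  expect_equal(nrow(gene_case_summary(coh1, som1)$rows), 0L)
  # invariant under specimen reordering within a case
  b <- agg_bundle
  coh2 <- b$coh
  set.seed(2)
  coh2$specimens <- coh2$specimens[sample(nrow(coh2$specimens)), ]
  gs1 <- gene_case_summary(b$coh, b$som)
  gs2 <- gene_case_summary(coh2, b$som)
  expect_equal(gs1$gene_counts, gs2$gene_counts)
  expect_equal(gs1$rows[, c("case_id", "gene", "hgvs_p", "n_specimens")],
               gs2$rows[, c("case_id", "gene", "hgvs_p", "n_specimens")])
})

test_that("site-mixed tally: derivable printed row, RAS/blacklist excluded", {
  st <- site_mixed_tally(agg_bundle$coh, agg_bundle$som, agg_bundle$fc)
  r876 <- st[st$gene == "APC" & st$hgvs_p == "p.R876*", ]
  expect_equal(r876[["PT-Colon"]], 2L)     # cases 3 and 13
  expect_equal(r876[["metM[PUL]"]], 3L)    # case 3's three lung lesions
  expect_equal(r876[["synM[HEP]"]], 0L)
  expect_false(any(st$gene %in% c("KRAS", "NRAS")))
  expect_true(all(st$gene != "KIT" | st$hgvs_p != "p.M541L"))
  # every kept row has some site-class count >= 2
  cls <- c("PT-Colon", "PT-Rectum", "synM[HEP]", "synM[PUL]",
           "metM[HEP]", "metM[PUL]")
  expect_true(all(apply(as.matrix(st[, cls]), 1, max) >= 2))
})

test_that("site-mixed tally equals brute-force group-by (oracle)", {
  set.seed(13)
  sim <- simulate_cohort(sim_params(n_cases = 4, seed = 13))
  coh <- sim$cohort
  som <- somatic_sets(coh, sim$calls)
  st <- site_mixed_tally(coh, som)
  # brute force: count specimens per class per key over all somatic sets
  sp <- coh$specimens[coh$specimens$tissue != "normal", ]
  long <- do.call(rbind, lapply(sp$specimen_id, function(sid) {
    s <- som[[sid]]
    if (!nrow(s)) return(NULL)
    data.frame(key = unique(s$key),
               cls = crctrace:::site_class(coh, sp[sp$specimen_id == sid, ]))
  }))
  tab <- table(long$key, long$cls)
  keep <- rownames(tab)[apply(tab, 1, max) >= 2]
  lk <- do.call(rbind, lapply(som, function(s) s[, c("key", "gene")]))
  keep <- keep[!(lk$gene[match(keep, lk$key)] %in% c("KRAS", "NRAS"))]
  expect_setequal(st$key, keep)
  for (k in st$key)
    for (cl in intersect(colnames(tab), names(st)))
      expect_equal(st[st$key == k, cl], unname(tab[k, cl]))
  # sum over classes never exceeds total carriers
  for (k in st$key)
    expect_lte(sum(st[st$key == k, c("PT-Colon", "PT-Rectum", "synM[HEP]",
                                     "synM[PUL]", "metM[HEP]",
                                     "metM[PUL]")]),
               sum(vapply(som, function(s) k %in% s$key, TRUE)))
})

test_that("tally is empty when every variant occurs once per site", {
  coh <- mk_case()
  som <- list(
    k1_pt = mk_calls("k1_pt", "TP53", "p.R175H", 40),
    k1_m1 = mk_calls("k1_m1", "APC", "p.Q1338*", 40),
    k1_m2 = mk_calls("k1_m2", "SMO", "p.A1T", 40))
  expect_equal(nrow(site_mixed_tally(assign_timing(coh), som)), 0L)
})

test_that("de novo frequency counts cases, not lesions", {
  coh <- assign_timing(cohort(rbind(
    specimen("e_no", "e", "normal"),
    specimen("e_pt", "e", "primary", "2010-01"),
    specimen("e_l1", "e", "lung_met", "2011-06"),
    specimen("e_l2", "e", "lung_met", "2011-08"))))
  som <- list(
    e_l1 = mk_calls("e_l1", "FBXW7", "p.R465C", 30),
    e_l2 = mk_calls("e_l2", "FBXW7", "p.R465C", 25))
  dn <- list(e_l1 = "FBXW7|p.R465C", e_l2 = "FBXW7|p.R465C")
  freq <- de_novo_frequency(coh, dn, som)
  # both lesions are metachronous lung: one case counted once
  expect_equal(freq[freq$gene == "FBXW7", "metM[PUL]"], 1L)
  expect_equal(sum(freq[, c("synM[HEP]", "synM[PUL]", "metM[HEP]")]), 0L)
  # no de novo variants anywhere: all-zero table
  freq0 <- de_novo_frequency(coh, list(), som, genes = panel_genes())
  expect_equal(nrow(freq0), 48L)
  expect_true(all(freq0[, -1] == 0L))
})

test_that("de novo frequency recovers simulator-planted class structure", {
  sim <- simulate_cohort(sim_params(n_cases = 6, seed = 41,
                                    purity_range = c(0.5, 0.9)))
  coh <- sim$cohort
  som <- somatic_sets(coh, sim$calls)
  dn <- list()
  for (cid in case_ids(coh)) {
    prim <- som[[primary_specimen(coh, cid)$specimen_id]]
    tsp <- tumour_specimens(coh, cid)
    for (sid in tsp$specimen_id[tsp$tissue != "primary"])
      dn[[sid]] <- derive_de_novo(som[[sid]], prim)
  }
  freq <- de_novo_frequency(coh, dn, som, genes = panel_genes())
  # truth: per gene x class, cases with >= 1 planted private variant
  # (purity >= 0.5 means expected AF >= 25 %, all observable)
  expect_truth <- new.env()
  for (cid in case_ids(coh)) {
    for (sid in names(sim$truth[[cid]]$private)) {
      row <- coh$specimens[coh$specimens$specimen_id == sid, ]
      if (!row$tissue %in% c("liver_met", "lung_met")) next
      cls <- crctrace:::site_class(coh, row)
      pv <- sim$truth[[cid]]$private[[sid]]
      for (g in unique(pv$gene)) {
        slot <- paste(g, cls)
        expect_truth[[slot]] <- union(expect_truth[[slot]], cid)
      }
    }
  }
  for (slot in ls(expect_truth)) {
    g <- sub(" .*", "", slot); cls <- sub("^[^ ]+ ", "", slot)
    expect_equal(freq[freq$gene == g, cls], length(expect_truth[[slot]]),
                 info = slot)
  }
})

test_that("treatment report: one row per lung-met case, empty list rendered", {
  b <- agg_bundle
  dn <- list()
  for (cid in case_ids(b$coh)) {
    prim <- b$som[[primary_specimen(b$coh, cid)$specimen_id]]
    tsp <- tumour_specimens(b$coh, cid)
    for (sid in tsp$specimen_id[tsp$tissue != "primary"])
      dn[[sid]] <- derive_de_novo(b$som[[sid]], prim)
  }
  tr <- treatment_report(b$coh, dn, b$som)
  # every fixture case has at least one lung metastasis
  expect_equal(nrow(tr), 14L)
  r4 <- tr[tr$case_id == "c04", ]
  expect_equal(r4$de_novo_genes, "no de novo mutations")
  expect_equal(r4$regimens, "FOLFOX, 5-FU/Mitomycin, FOLFIRI")
  r6 <- tr[tr$case_id == "c06", ]
  expect_equal(r6$de_novo_genes, "SMO")
  expect_equal(r6$classes, "met")
  # case without recorded treatments: empty regimen field
  expect_equal(tr$regimens[tr$case_id == "c02"], "")
})

test_that("cohort summary: fixture statistics and empty cohort", {
  b <- agg_bundle
  traj <- lapply(case_ids(b$coh), function(cid)
    track_ras(b$coh, cid, b$calls, b$fc))
  s <- cohort_summary(b$coh, traj)
  expect_equal(s$n_specimens, 70L)
  expect_equal(s$ras_mutated, 9L)
  expect_equal(s$ras_wildtype, 5L)
  # percentages recompute from numerator/denominator
  expect_equal(s$kras_pct, as.integer(round(100 * s$kras_mutated / s$n_cases)))
  expect_equal(s$maintained_pct,
               as.integer(round(100 * s$maintained / s$ras_mutated)))
  s0 <- cohort_summary(cohort(NULL), list())
  expect_equal(s0$n_cases, 0L)
  expect_equal(s0$ras_mutated, 0L)
  expect_true(is.na(s0$maintained_pct))
})

test_that("cohort summary matches simulator-planted RAS truth", {
  sim <- simulate_cohort(sim_params(n_cases = 8, seed = 77,
                                    purity_range = c(0.4, 0.9)))
  coh <- sim$cohort
  traj <- lapply(case_ids(coh), function(cid)
    track_ras(coh, cid, sim$calls))
  s <- cohort_summary(coh, traj)
  truth_mut <- sum(vapply(sim$truth, function(t)
    t$ras$status == "mutated", TRUE))
  expect_equal(s$ras_mutated, truth_mut)
  expect_equal(s$ras_wildtype, 8L - truth_mut)
})
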