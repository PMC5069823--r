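fixture_bundle <- local({
  coh <- assign_timing(crc_fixture_manifest())
  calls <- crc_fixture_calls()
  fc <- filter_config()
  list(coh = coh, calls = calls, fc = fc,
       som = somatic_sets(coh, calls, fc))
})

test_that("germline subtraction removes matched-normal keys only", {
  tum <- mk_calls("t", c("KRAS", "TP53", "APC"),
                  c("p.G12D", "p.R175H", "p.Q1338*"), c(40, 30, 20))
  expect_equal(nrow(subtract_germline(tum, tum)), 0L)   # self-subtraction
  germ <- mk_calls("n", c("TP53", "ATM"), c("p.R175H", "p.A1T"), c(50, 48))
  out <- subtract_germline(tum, germ)
  expect_setequal(out$key, c("KRAS|p.G12D", "APC|p.Q1338*"))
  # a normal-side call below the evidence floor is not germline evidence
  germ_lo <- mk_calls("n", "TP53", "p.R175H", 0.5)
  expect_equal(nrow(subtract_germline(tum, germ_lo)), 3L)
  # cross-case guard
  coh <- fixture_bundle$coh
  t1 <- mk_calls("c01_pt", "KRAS", "p.G12D", 40)
  n2 <- mk_calls("c02_no", "KRAS", "p.G12D", 50)
  expect_error(subtract_germline(t1, n2, cohort = coh), "different cases")
})

test_that("simulator-planted germline SNPs are removed, somatic kept", {
  # 5 germline + 3 somatic planted by hand
  germ <- mk_calls("n", paste0("G", 1:5), paste0("p.A", 1:5, "T"),
                   rep(50, 5))
  som <- mk_calls("t", c("KRAS", "TP53", "APC"),
                  c("p.G12D", "p.R175H", "p.Q1338*"), c(40, 30, 20))
  tum <- rbind(som, transform(germ, specimen_id = "t", af_percent = 25))
  tum <- as_variant_calls(tum[, setdiff(names(tum), "key")])
  out <- subtract_germline(tum, germ)
  expect_setequal(out$key, som$key)
})

test_that("metastasis timing classification", {
  expect_equal(classify_metastasis("2004-05", "2004-03"), "synchronous")
  expect_equal(classify_metastasis("2004-03", "2004-03"), "synchronous")
  expect_equal(classify_metastasis("2004-09", "2004-03"), "synchronous")
  expect_equal(classify_metastasis("2004-10", "2004-03"), "metachronous")
  expect_equal(classify_metastasis("2006-02", "2005-04"), "metachronous")
  prim <- specimen("p", "c", "primary", "2004-03")
  expect_error(classify_metastasis(prim, "2004-03"), "metastatic")
})

test_that("assign_timing derives labels and respects manifest labels", {
  coh <- mk_case(met_dates = c("2010-03", "2011-06"))
  coh <- assign_timing(coh)
  sp <- coh$specimens
  expect_equal(sp$timing[sp$specimen_id == "k1_m1"], "synchronous")
  expect_equal(sp$timing[sp$specimen_id == "k1_m2"], "metachronous")
  # fixture case 5's second lung lesion keeps its printed label even though
  # the dates put it 7 months post primary
  fsp <- fixture_bundle$coh$specimens
  expect_equal(fsp$timing[fsp$specimen_id == "c05_pul_s2"], "synchronous")
})

test_that("partition: truncal trio of the all-shared case", {
  p14 <- partition_shared("c14", fixture_bundle$som[
    tumour_specimens(fixture_bundle$coh, "c14")$specimen_id],
    cohort = fixture_bundle$coh)
  expect_equal(length(p14$truncal), 3L)
  expect_setequal(p14$truncal, c("APC|p.T1430Pfs*", "NRAS|p.Q61R",
                                 "TP53|p.R175H"))
  expect_equal(sum(lengths(p14$private)), 0L)
})

test_that("partition: variant shared by some but not all is other_shared", {
  p1 <- partition_shared("c01", fixture_bundle$som[
    tumour_specimens(fixture_bundle$coh, "c01")$specimen_id],
    cohort = fixture_bundle$coh)
  expect_true("TP53|p.R342*" %in% names(p1$other_shared))
  expect_false("TP53|p.R342*" %in% p1$truncal)
  expect_setequal(p1$other_shared[["TP53|p.R342*"]],
                  c("c01_pt", "c01_pul_m1"))
  expect_error(partition_shared("c01", fixture_bundle$som["c01_pt"],
                                cohort = fixture_bundle$coh),
               "missing somatic set")
})

test_that("partition equals brute-force subset enumeration (oracle)", {
  set.seed(17)
  for (rep in 1:20) {
    ids <- paste0("s", 1:4)
    calls <- random_calls(ids, n_variants = 10, p = 0.5)
    sets <- lapply(ids, function(s) unique(calls$key[calls$specimen_id == s]))
    names(sets) <- ids
    p <- partition_shared("x", sets)
    for (k in unique(unlist(sets))) {
      supp <- ids[vapply(sets, function(s) k %in% s, TRUE)]
      comp <- if (length(supp) == 4) "truncal"
      else if (length(supp) == 1) "private" else "other"
      expect_equal(k %in% p$truncal, comp == "truncal")
      expect_equal(k %in% unlist(p$private), comp == "private")
      expect_equal(k %in% names(p$other_shared), comp == "other")
      if (comp == "other")
        expect_setequal(p$other_shared[[k]], supp)
    }
    # compartments disjoint, union preserved
    expect_equal(sort(c(p$truncal, unlist(p$private, use.names = FALSE),
                        names(p$other_shared))),
                 sort(unique(unlist(sets))))
  }
})

test_that("de novo derivation: set subtraction against the primary", {
  prim <- mk_calls("p", c("KRAS", "TP53"), c("p.G12D", "p.R175H"), c(40, 30))
  expect_equal(derive_de_novo(prim, prim), character(0))   # identical
  met <- rbind(prim, mk_calls("m", c("SMO", "FBXW7", "STK11", "PTEN"),
                              paste0("p.A", 1:4, "T"), rep(25, 4)))
  expect_setequal(derive_de_novo(met, prim),
                  c("SMO|p.A1T", "FBXW7|p.A2T", "STK11|p.A3T", "PTEN|p.A4T"))
  # strict mode also consults the primary's rescue-level set
  resc <- mk_calls("p", "SMO", "p.A1T", 2)
  strict <- derive_de_novo(met, prim, primary_rescue = resc, strict = TRUE)
  expect_false("SMO|p.A1T" %in% strict)
  expect_true(all(strict %in% derive_de_novo(met, prim)))
})

test_that("fixture case 6: SMO is de novo in the metachronous lung", {
  b <- fixture_bundle
  dn <- derive_de_novo(b$som[["c06_pul_m1"]], b$som[["c06_pt"]],
                       cohort = b$coh)
  expect_true("SMO|p.?" %in% dn)
  expect_equal(dn, "SMO|p.?")  # everything else is shared with the primary
})

test_that("de novo / intersection decomposition holds on simulated data", {
  sim <- simulate_cohort(sim_params(n_cases = 3, seed = 23))
  coh <- sim$cohort
  som <- somatic_sets(coh, sim$calls)
  for (cid in case_ids(coh)) {
    prim <- som[[primary_specimen(coh, cid)$specimen_id]]
    tsp <- tumour_specimens(coh, cid)
    for (sid in tsp$specimen_id[tsp$tissue != "primary"]) {
      met <- som[[sid]]
      dn <- derive_de_novo(met, prim)
      both <- intersect(met$key, prim$key)
      expect_equal(length(intersect(dn, prim$key)), 0L)
      expect_setequal(c(dn, both), met$key)
      expect_equal(length(intersect(dn, both)), 0L)
    }
  }
})

test_that("RAS trajectory: maintained case with printed allele fractions", {
  b <- fixture_bundle
  t1 <- track_ras(b$coh, "c01", b$calls, b$fc)
  expect_equal(t1$primary_status, "mutated")
  expect_equal(t1$primary_variants, "KRAS|p.G12D")
  expect_true(t1$maintained[["KRAS|p.G12D"]])
  expect_true(t1$status_maintained)
  expect_equal(sort(t1$table$af_percent), sort(c(55.59, 97.28, 16.77)))
  expect_true(all(t1$table$detection == "detected"))
})

test_that("RAS trajectory: sub-threshold rescue in low-content lesion", {
  b <- fixture_bundle
  t5 <- track_ras(b$coh, "c05", b$calls, b$fc)
  expect_true(t5$status_maintained)
  expect_true(t5$maintained[["KRAS|p.G12A"]])
  hep <- t5$table[t5$table$specimen_id == "c05_hep_s1", ]
  expect_equal(hep$detection, "detected_below_threshold")
  expect_equal(hep$af_percent, 9.7)
  expect_true(t5$subthreshold)
})

test_that("RAS trajectory: lost allele and codon switch", {
  b <- fixture_bundle
  # cases 3 and 6: allele absent from one lesion even at rescue level
  t3 <- track_ras(b$coh, "c03", b$calls, b$fc)
  expect_false(t3$status_maintained)
  expect_false(t3$maintained[["KRAS|p.G12V"]])
  expect_equal(
    t3$table$detection[t3$table$specimen_id == "c03_pul_m1"], "not_detected")
  t6 <- track_ras(b$coh, "c06", b$calls, b$fc)
  expect_false(t6$status_maintained)
  # case 13: primary carries G12D, metastases G12V; the exact primary
  # variant is not maintained but the case-level RAS status is
  t13 <- track_ras(b$coh, "c13", b$calls, b$fc)
  expect_equal(t13$primary_variants, "KRAS|p.G12D")
  expect_false(t13$maintained[["KRAS|p.G12D"]])
  expect_true(t13$status_maintained)
  expect_true(t13$subthreshold)  # the 5.62 % lung lesion
})

test_that("RAS trajectory: wildtype case has no rows", {
  b <- fixture_bundle
  t4 <- track_ras(b$coh, "c04", b$calls, b$fc)
  expect_equal(t4$primary_status, "wildtype")
  expect_equal(nrow(t4$table), 0L)
  expect_true(is.na(t4$status_maintained))
})

test_that("maintained is insensitive to AF fluctuation above rescue", {
  coh <- mk_case()
  set.seed(8)
  for (rep in 1:10) {
    afs <- runif(3, 1, 100)  # any fractions at/above rescue
    calls <- mk_calls(c("k1_pt", "k1_m1", "k1_m2"), "KRAS", "p.G12D",
                      c(max(afs[1], 10), afs[2], afs[3]))
    tr <- track_ras(coh, "k1", calls)
    expect_true(tr$status_maintained)
    expect_true(all(tr$maintained))
  }
})

test_that("non-hotspot RAS variants are reported separately", {
  coh <- mk_case()
  calls <- rbind(mk_calls("k1_pt", "KRAS", "p.A146T", 40),
                 mk_calls("k1_pt", "KRAS", "p.L19F", 40),
                 mk_calls("k1_m1", "KRAS", "p.A146T", 30),
                 mk_calls("k1_m2", "KRAS", "p.A146T", 30))
  tr <- track_ras(coh, "k1", calls)
  expect_equal(tr$primary_variants, "KRAS|p.A146T")  # codon 146 is hotspot
  expect_equal(tr$other_ras, "KRAS|p.L19F")
})

test_that("co-resected lesion concordance", {
  b <- fixture_bundle
  conc <- compare_colocated_lesions(b$som[["c14_hep_s1"]],
                                    b$som[["c14_hep_s2"]], cohort = b$coh)
  expect_equal(length(conc$exclusive_a), 0L)
  expect_equal(length(conc$exclusive_b), 0L)
  expect_setequal(conc$shared, c("APC|p.T1430Pfs*", "NRAS|p.Q61R",
                                 "TP53|p.R175H"))
  # toy disjoint sets
  toy <- compare_colocated_lesions(c("a", "b"), "c")
  expect_equal(toy$shared, character(0))
  expect_setequal(toy$exclusive_a, c("a", "b"))
  expect_equal(toy$exclusive_b, "c")
  # mismatched dates are rejected
  expect_error(
    compare_colocated_lesions(b$som[["c03_pul_m1"]], b$som[["c03_pul_m3"]],
                              cohort = b$coh), "tissue or resection date")
})

test_that("concordance equals brute-force set ops with consistent counts", {
  set.seed(31)
  for (rep in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    r <- compare_colocated_lesions(a, b)
    expect_setequal(r$shared, intersect(a, b))
    expect_setequal(r$exclusive_a, setdiff(a, b))
    expect_equal(r$counts[["shared"]] + r$counts[["exclusive_a"]],
                 r$counts[["a"]])
    expect_equal(r$counts[["shared"]] + r$counts[["exclusive_b"]],
                 r$counts[["b"]])
  }
})
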