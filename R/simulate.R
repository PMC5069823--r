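# Seeded clonal-evolution cohort simulator with ground truth.
#
# Generative model (documented in the methods vignette): per case a set of
# germline polymorphisms (present in every specimen, AF ~ 50 % het / 100 %
# hom, not purity-scaled) and 1-3 truncal somatic variants shared by all
# tumour specimens; per metastatic lesion class-dependent private (de novo)
# variants. Expected somatic AF = purity * clonal_fraction / 2 (heterozygous
# diploid, no copy-number model). Observed AF: p ~ Beta(mean, precision =
# af_noise), alt_reads ~ Binomial(depth, p), depth ~ Poisson(depth_mean).

#' The 48-gene amplicon cancer panel
#'
#' Gene symbols of the 48-gene hotspot amplicon panel (225 amplicons) the
#' cohort was profiled with; the simulator draws variants from it.
#'
#' @return Character vector of 48 HGNC symbols.
#' @export
panel_genes <- function() c(
  "ABL1", "AKT1", "ALK", "APC", "ATM", "BRAF", "CDH1", "CDKN2A", "CSF1R",
  "CTNNB1", "EGFR", "ERBB2", "ERBB4", "FBXW7", "FGFR1", "FGFR2", "FGFR3",
  "FLT3", "GNA11", "GNAQ", "GNAS", "HNF1A", "HRAS", "IDH1", "JAK2", "JAK3",
  "KDR", "KIT", "KRAS", "MET", "MLH1", "MPL", "NOTCH1", "NPM1", "NRAS",
  "PDGFRA", "PIK3CA", "PTEN", "PTPN11", "RB1", "RET", "SMAD4", "SMARCB1",
  "SMO", "SRC", "STK11", "TP53", "VHL")

.met_classes <- c("synM[HEP]", "synM[PUL]", "metM[HEP]", "metM[PUL]")

.default_de_novo_rate <- function() list(
  # Illustrative per-gene expected counts per lesion, echoing the class
  # patterns seen in the cohort; not biological estimates.
  "synM[HEP]" = c(FBXW7 = 0.3, FGFR3 = 0.3, GNAQ = 0.2, PTEN = 0.2),
  "synM[PUL]" = c(ATM = 0.5, KIT = 0.5, PIK3CA = 0.5, SMAD4 = 0.5),
  "metM[HEP]" = c(FGFR3 = 0.3, TP53 = 0.3),
  "metM[PUL]" = c(FBXW7 = 0.4, SMO = 0.3, STK11 = 0.3, CDKN2A = 0.1,
                  FGFR2 = 0.1, GNAS = 0.1, JAK3 = 0.1, SRC = 0.1))

#' Simulation parameters
#'
#' Defaults state the cohort being emulated: 14 cases with 2-4 metastases
#' each, class mix proportional to the study's 12/8/6/16 lesion counts,
#' 1-3 truncal variants, purity 0.10-0.95 (so low-purity lesions produce
#' sub-10 % alleles by construction), mean depth 5000x.
#'
#' @param n_cases Number of cases.
#' @param met_range Integer range of metastatic lesions per case (>= 2).
#' @param class_mix Named probabilities over the four metastasis classes.
#' @param truncal_range Integer range of truncal somatic variants per case.
#' @param germline_range Integer range of germline polymorphisms per case.
#' @param de_novo_rate Named list class -> named numeric (gene -> expected
#'   de novo count per lesion, Poisson).
#' @param purity_range Tumour purity range (uniform draw per specimen).
#' @param depth_mean Mean sequencing depth (Poisson).
#' @param af_noise Beta precision of the allele-fraction noise law (larger =
#'   tighter around the expected AF); overdispersion beyond binomial
#'   counting noise.
#' @param germline_hom_rate Fraction of germline polymorphisms simulated
#'   homozygous (expected AF 100 %).
#' @param ras_mut_prob Probability that a case's trunk carries a RAS hotspot
#'   mutation (study: 9/14).
#' @param syn_rate Expected synonymous passenger calls per specimen.
#' @param blacklist_prob Probability that a case carries the KIT p.M541L
#'   common polymorphism (exercises the blacklist filter).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_cases = 14, met_range = 2:4,
                       class_mix = c("synM[HEP]" = 12, "synM[PUL]" = 8,
                                     "metM[HEP]" = 6, "metM[PUL]" = 16) / 42,
                       truncal_range = 1:3, germline_range = 3:8,
                       de_novo_rate = .default_de_novo_rate(),
                       purity_range = c(0.10, 0.95), depth_mean = 5000,
                       af_noise = 2000, germline_hom_rate = 0.2,
                       ras_mut_prob = 9 / 14, syn_rate = 0.5,
                       blacklist_prob = 0.3, seed = 1L) {
  if (n_cases < 0) stop("n_cases must be >= 0", call. = FALSE)
  if (length(met_range) < 1L || any(met_range < 2L))
    stop("met_range must contain integers >= 2 (inclusion rule)",
         call. = FALSE)
  if (!setequal(names(class_mix), .met_classes) ||
      abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix must be probabilities over the four metastasis classes ",
         "summing to 1", call. = FALSE)
  if (length(truncal_range) < 1L || any(truncal_range < 0L))
    stop("truncal_range must be non-negative", call. = FALSE)
  if (purity_range[1] < 0.05 || purity_range[2] > 0.95 ||
      purity_range[1] > purity_range[2])
    stop("purity_range must lie within [0.05, 0.95]", call. = FALSE)
  if (depth_mean <= 0 || af_noise <= 0)
    stop("depth_mean and af_noise must be positive", call. = FALSE)
  structure(list(n_cases = as.integer(n_cases), met_range = met_range,
                 class_mix = class_mix[.met_classes],
                 truncal_range = truncal_range,
                 germline_range = germline_range,
                 de_novo_rate = de_novo_rate, purity_range = purity_range,
                 depth_mean = depth_mean, af_noise = af_noise,
                 germline_hom_rate = germline_hom_rate,
                 ras_mut_prob = ras_mut_prob, syn_rate = syn_rate,
                 blacklist_prob = blacklist_prob, seed = as.integer(seed)),
            class = "sim_params")
}

.aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")
.bases <- c("A", "C", "G", "T")

# Draws a fresh variant with a unique genomic quadruple. `state` is an
# environment carrying the position counter so keys never collide.
.new_variant <- function(state, gene, consequence, hgvs_p = NULL,
                         population_af = NA_real_) {
  state$pos <- state$pos + sample(1:997, 1L)
  ref <- sample(.bases, 1L)
  alt <- sample(setdiff(.bases, ref), 1L)
  if (is.null(hgvs_p)) {
    codon <- sample(200:1500, 1L)  # clear of the RAS hotspot codons
    hgvs_p <- switch(consequence,
      nonsense = paste0("p.", sample(.aa, 1L), codon, "*"),
      frameshift = paste0("p.", sample(.aa, 1L), codon,
                          sample(.aa, 1L), "fs*"),
      paste0("p.", sample(.aa, 1L), codon, sample(setdiff(.aa, "X"), 1L)))
  }
  data.frame(gene = gene,
             chrom = paste0("chr", 1 + (abs(sum(utf8ToInt(gene))) %% 22)),
             pos = state$pos, ref = ref, alt = alt, hgvs_p = hgvs_p,
             consequence = consequence, population_af = population_af,
             stringsAsFactors = FALSE)
}

# Observed-call row for one variant in one specimen under the noise law.
.observe <- function(v, specimen_id, expected_af, params) {
  m <- expected_af / 100
  p <- if (m <= 0) 0 else if (m >= 1) 1 else
    stats::rbeta(1L, m * params$af_noise, (1 - m) * params$af_noise)
  depth <- max(1L, stats::rpois(1L, params$depth_mean))
  alt <- stats::rbinom(1L, depth, p)
  if (alt == 0L) return(NULL)  # below the caller's detection floor
  cbind(data.frame(specimen_id = specimen_id), v,
        data.frame(af_percent = 100 * alt / depth, depth = depth,
                   alt_reads = alt))
}

.ras_hotspot_pool <- function() data.frame(
  gene = c("KRAS", "KRAS", "KRAS", "KRAS", "KRAS", "NRAS"),
  hgvs_p = c("p.G12D", "p.G12V", "p.G12A", "p.G13D", "p.Q61H", "p.Q61R"),
  stringsAsFactors = FALSE)

#' Simulate a cohort with ground truth
#'
#' Generates a case-matched cohort (manifest, per-specimen raw variant
#' calls, truth record) under the model described in [sim_params()]. Fixed
#' seed implies identical output.
#'
#' @param params A [sim_params()] object.
#' @return List with `cohort` (a `crc_cohort`), `calls` (raw variant-call
#'   table over all specimens), `truth` (per-case germline/truncal keys,
#'   per-specimen private keys with expected AFs, purities, RAS status) and
#'   `params`.
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  state <- new.env(); state$pos <- 10000L
  sp_rows <- list(); call_rows <- list()
  truth <- list(); treatments <- list(); attributes <- list()
  regimen_pool <- c("FOLFOX", "FOLFIRI", "FOLFOXIRI/Bevacizumab", "Xeloda",
                    "FOLFIRI/Bevacizumab", "RCTx", "5-FU/Mitomycin")

  for (ci in seq_len(params$n_cases)) {
    cid <- sprintf("sim%02d", ci)
    attributes[[cid]] <- list(
      location = sample(c("colon_left", "colon_right", "rectum"), 1L,
                        prob = c(6, 3, 5) / 14),
      gender = sample(c("m", "f"), 1L), age = sample(35:75, 1L))
    treatments[[cid]] <- sample(regimen_pool,
                                sample(1:3, 1L), replace = FALSE)
    p_year <- sample(2004:2014, 1L); p_month <- sample(1:12, 1L)
    p_idx <- p_year * 12L + p_month - 1L
    fmt_ym <- function(idx) sprintf("%d-%02d", idx %/% 12L,
                                    idx %% 12L + 1L)
    p_date <- fmt_ym(p_idx)

    n_met <- if (length(params$met_range) == 1L) params$met_range else
      sample(params$met_range, 1L)
    classes <- sample(.met_classes, n_met, replace = TRUE,
                      prob = params$class_mix)
    specs <- rbind(
      specimen(paste0(cid, "_no"), cid, "normal"),
      specimen(paste0(cid, "_pt"), cid, "primary", p_date,
               lesion_label = "PT",
               tumour_cell_content = 100 * stats::runif(
                 1, params$purity_range[1], params$purity_range[2])))
    for (mi in seq_len(n_met)) {
      cls <- classes[mi]
      offset <- if (grepl("^metM", cls)) sample(7:60, 1L) else
        sample(0:6, 1L)
      specs <- rbind(specs, specimen(
        sprintf("%s_m%02d", cid, mi), cid,
        if (grepl("HEP", cls)) "liver_met" else "lung_met",
        fmt_ym(p_idx + offset),
        lesion_label = sprintf("%s %d", cls, mi),
        tumour_cell_content = 100 * stats::runif(
          1, params$purity_range[1], params$purity_range[2]),
        timing = if (grepl("^metM", cls)) "metachronous" else "synchronous"))
    }
    tumour_ids <- specs$specimen_id[specs$tissue != "normal"]
    purity <- stats::setNames(specs$tumour_cell_content / 100,
                              specs$specimen_id)

    # germline polymorphisms: in every specimen, not purity-scaled
    n_germ <- if (length(params$germline_range) == 1L)
      params$germline_range else sample(params$germline_range, 1L)
    germ <- lapply(seq_len(n_germ), function(i)
      .new_variant(state, sample(panel_genes(), 1L), "missense",
                   population_af = if (stats::runif(1) < 0.5)
                     stats::runif(1, 0.051, 0.5) else NA_real_))
    germ_af <- ifelse(stats::runif(n_germ) < params$germline_hom_rate,
                      100, 50)
    if (stats::runif(1) < params$blacklist_prob) {
      germ <- c(germ, list(.new_variant(state, "KIT", "missense",
                                        hgvs_p = "p.M541L",
                                        population_af = 0.3)))
      germ_af <- c(germ_af, 50)
    }

    # truncal somatic variants; optional RAS hotspot on the trunk
    n_trunk <- if (length(params$truncal_range) == 1L)
      params$truncal_range else sample(params$truncal_range, 1L)
    trunk <- lapply(seq_len(n_trunk), function(i)
      .new_variant(state, sample(panel_genes(), 1L),
                   sample(c("missense", "nonsense", "frameshift"), 1L,
                          prob = c(0.6, 0.25, 0.15))))
    ras_status <- "wildtype"; ras_key <- NA_character_
    if (stats::runif(1) < params$ras_mut_prob) {
      hs <- .ras_hotspot_pool()[sample(6, 1L), ]
      rv <- .new_variant(state, hs$gene, "missense", hgvs_p = hs$hgvs_p)
      trunk <- c(trunk, list(rv))
      ras_status <- "mutated"
      ras_key <- variant_key(rv)
    }

    private <- list()  # specimen -> data.frame(key, gene, expected_af)
    for (sid in tumour_ids) {
      row <- specs[specs$specimen_id == sid, ]
      pv <- list()
      if (row$tissue != "primary") {
        cls <- sub(" .*", "", row$lesion_label)
        rates <- params$de_novo_rate[[cls]] %||% numeric(0)
        for (g in names(rates)) {
          for (r in seq_len(stats::rpois(1L, rates[[g]])))
            pv <- c(pv, list(.new_variant(
              state, g, sample(c("missense", "nonsense"), 1L,
                               prob = c(0.7, 0.3)))))
        }
      }
      # occasional synonymous passengers (exercise the consequence filter)
      for (r in seq_len(stats::rpois(1L, params$syn_rate)))
        pv <- c(pv, list(.new_variant(state, sample(panel_genes(), 1L),
                                      "synonymous")))
      private[[sid]] <- pv
    }

    # observations
    for (si in seq_len(nrow(specs))) {
      sid <- specs$specimen_id[si]
      for (gi in seq_along(germ))
        call_rows[[length(call_rows) + 1L]] <-
          .observe(germ[[gi]], sid, germ_af[gi], params)
      if (specs$tissue[si] == "normal") next
      for (tv in trunk)
        call_rows[[length(call_rows) + 1L]] <-
          .observe(tv, sid, 100 * purity[[sid]] / 2, params)
      for (pv in private[[sid]])
        call_rows[[length(call_rows) + 1L]] <-
          .observe(pv, sid, 100 * purity[[sid]] / 2, params)
    }

    somatic_priv <- lapply(private, function(pv) {
      pv <- Filter(function(v) v$consequence != "synonymous", pv)
      if (!length(pv)) return(data.frame(key = character(0),
                                         gene = character(0),
                                         expected_af = numeric(0)))
      data.frame(key = vapply(pv, variant_key, ""),
                 gene = vapply(pv, function(v) v$gene, ""),
                 expected_af = NA_real_)
    })
    for (sid in names(somatic_priv))
      if (nrow(somatic_priv[[sid]]))
        somatic_priv[[sid]]$expected_af <- 100 * purity[[sid]] / 2

    truth[[cid]] <- list(
      germline = vapply(germ, variant_key, ""),
      truncal = vapply(trunk, variant_key, ""),
      truncal_expected_af = stats::setNames(
        lapply(tumour_ids, function(s) 100 * purity[[s]] / 2), tumour_ids),
      private = somatic_priv,
      purity = as.list(purity[tumour_ids]),
      ras = list(status = ras_status, key = ras_key))
    sp_rows[[length(sp_rows) + 1L]] <- specs
  }

  specimens <- if (length(sp_rows)) do.call(rbind, sp_rows) else NULL
  calls <- call_rows[!vapply(call_rows, is.null, TRUE)]
  calls <- if (length(calls)) as_variant_calls(do.call(rbind, calls)) else
    empty_calls()
  list(cohort = cohort(specimens, treatments = treatments,
                       attributes = attributes,
                       provenance = sprintf("crctrace simulation seed=%d",
                                            params$seed)),
       calls = calls, truth = truth, params = params)
}

# ---- file emission --------------------------------------------------------

.vcf_header <- function(specimen_id) c(
  "##fileformat=VCFv4.2",
  "##source=crctrace-simulator",
  "##INFO=<ID=GENE,Number=1,Type=String,Description=\"HGNC gene symbol\">",
  "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"Protein change\">",
  "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
  "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"Population allele frequency\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
  "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
  paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
         specimen_id))

write_specimen_vcf <- function(calls, specimen_id, path) {
  df <- calls[calls$specimen_id == specimen_id, , drop = FALSE]
  df <- df[order(df$chrom, df$pos, df$alt), , drop = FALSE]
  info <- paste0("GENE=", df$gene, ";HGVSP=", df$hgvs_p, ";CSQ=",
                 df$consequence,
                 ifelse(is.na(df$population_af), "",
                        sprintf(";POPAF=%.6g", df$population_af)))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tDP:AD\t%d:%d,%d",
                  df$chrom, df$pos, df$ref, df$alt, info, df$depth,
                  df$depth - df$alt_reads, df$alt_reads)
  writeLines(c(.vcf_header(specimen_id), body), path)
  invisible(path)
}

#' Emit a simulated cohort as files
#'
#' Writes one VCF per specimen, the cohort manifest (JSON) and the truth
#' record (JSON) into a directory. Reading the VCFs back with [read_vcf()]
#' recovers the generated call set exactly.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Writable output directory (created if needed).
#' @return Named list of file paths (`manifest`, `truth`, `vcf` vector).
#' @export
emit_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(dir, "manifest.json")
  write_manifest(sim$cohort, manifest)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null",
                       na = "null")
  vcfs <- character(0)
  for (sid in sim$cohort$specimens$specimen_id) {
    p <- file.path(dir, paste0(sid, ".vcf"))
    write_specimen_vcf(sim$calls, sid, p)
    vcfs[sid] <- p
  }
  list(manifest = manifest, truth = truth_path, vcf = vcfs)
}
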