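# Case-matched set algebra: germline subtraction, truncal/private
# partitioning, de novo derivation, metastasis timing, RAS trajectory,
# co-resected lesion concordance. Somatic sets are variant-call tables with
# unique identity keys; most operations accept either a call table or a bare
# character vector of keys.

keys_of <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x)) {
    if (is.null(x$key)) stop("call table lacks a key column; pass it ",
                             "through as_variant_calls()", call. = FALSE)
    return(x$key)
  }
  stop("expected a call table or key vector", call. = FALSE)
}

.case_of <- function(cohort, specimen_id) {
  i <- match(specimen_id, cohort$specimens$specimen_id)
  if (is.na(i)) stop("unknown specimen: ", specimen_id, call. = FALSE)
  cohort$specimens$case_id[i]
}

.check_same_case <- function(cohort, a_ids, b_ids) {
  if (is.null(cohort)) return(invisible(NULL))
  cases <- unique(vapply(unique(c(a_ids, b_ids)), function(s)
    .case_of(cohort, s), ""))
  if (length(cases) > 1L)
    stop("specimens belong to different cases: ",
         paste(cases, collapse = " vs "), call. = FALSE)
  invisible(NULL)
}

#' Subtract matched-normal (germline) calls
#'
#' Removes from a tumour call set every variant whose identity key occurs in
#' the case-matched normal-epithelium call set, yielding somatic calls only.
#' Matching ignores allele fraction, but normal-side calls must clear a low
#' evidence floor (`rescue_af`) to count as germline evidence, so noise-level
#' normal observations do not delete true somatic variants.
#'
#' @param tumour Filtered tumour call table.
#' @param normal Raw call table of the matched normal specimen.
#' @param config A [filter_config()]; supplies the evidence floor.
#' @param cohort Optional `crc_cohort` used to verify both call sets belong
#'   to the same case (mismatch is an error).
#' @return The somatic subset of `tumour`, order preserved, with any
#'   duplicate identity keys collapsed (first occurrence kept).
#' @export
subtract_germline <- function(tumour, normal, config = filter_config(),
                              cohort = NULL) {
  .check_same_case(cohort, unique(tumour$specimen_id),
                   unique(normal$specimen_id))
  germ <- if (is.data.frame(normal))
    normal$key[normal$af_percent >= config$rescue_af]
  else keys_of(normal)
  out <- tumour[!(tumour$key %in% germ), , drop = FALSE]
  out[!duplicated(out$key), , drop = FALSE]
}

#' Classify metastasis timing
#'
#' A metastasis is metachronous when resected strictly more than 6 whole
#' calendar months after the primary tumour, else synchronous.
#'
#' @param specimen One-row specimen data frame (tissue must be a metastasis),
#'   or a `"YYYY-MM"` resection date.
#' @param primary_date Primary-tumour resection date `"YYYY-MM"`.
#' @return `"synchronous"` or `"metachronous"`.
#' @export
classify_metastasis <- function(specimen, primary_date) {
  if (is.data.frame(specimen)) {
    if (!specimen$tissue %in% c("liver_met", "lung_met"))
      stop("timing classification applies to metastatic specimens only",
           call. = FALSE)
    date <- specimen$resection_date
  } else date <- specimen
  if (month_diff(date, primary_date) > 6L) "metachronous" else "synchronous"
}

#' Assign timing labels across a cohort
#'
#' Fills the `timing` column for every metastatic specimen. A label already
#' present in the manifest (the clinic's designation) takes precedence;
#' otherwise the label is derived from resection dates via
#' [classify_metastasis()].
#'
#' @param x A `crc_cohort`.
#' @return The cohort with `timing` complete for all metastases.
#' @export
assign_timing <- function(x) {
  sp <- x$specimens
  for (i in seq_len(nrow(sp))) {
    if (!sp$tissue[i] %in% c("liver_met", "lung_met")) next
    if (!is.na(sp$timing[i])) next
    pd <- primary_specimen(x, sp$case_id[i])$resection_date
    sp$timing[i] <- classify_metastasis(sp$resection_date[i], pd)
  }
  x$specimens <- sp
  x
}

# Site class of a tumour specimen: PT split by primary organ, metastases by
# timing x organ, mirroring the case-mixed summary columns.
site_class <- function(cohort, sp_row) {
  if (sp_row$tissue == "primary") {
    loc <- tolower(cohort$attributes[[sp_row$case_id]]$location %||% "")
    if (grepl("rect", loc)) return("PT-Rectum")
    if (grepl("colon", loc)) return("PT-Colon")
    return(NA_character_)
  }
  organ <- if (sp_row$tissue == "liver_met") "HEP" else "PUL"
  pre <- if (identical(sp_row$timing, "metachronous")) "metM" else "synM"
  paste0(pre, "[", organ, "]")
}

#' Partition somatic variants into truncal, private and other-shared
#'
#' Over all tumour specimens of one case, each somatic variant key falls in
#' exactly one compartment: `truncal` (present in every tumour specimen),
#' `private` (exactly one specimen), or `other_shared` (at least two but not
#' all). The three compartments are disjoint and their union is the union of
#' all specimens' somatic keys — the per-case Venn diagram of the study.
#'
#' @param case_id Case identifier.
#' @param somatic Named list (specimen_id -> somatic call table or key
#'   vector) covering every tumour specimen of the case.
#' @param cohort Optional `crc_cohort`; when given, a missing tumour
#'   specimen in `somatic` is an error naming it.
#' @return A `crc_partition` list with `truncal`, `private` (named list),
#'   `other_shared` (named list key -> supporting specimens), `n_specimens`.
#' @export
partition_shared <- function(case_id, somatic, cohort = NULL) {
  if (!is.null(cohort)) {
    need <- tumour_specimens(cohort, case_id)$specimen_id
    miss <- setdiff(need, names(somatic))
    if (length(miss))
      stop("case ", case_id, ": missing somatic set for specimen(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    somatic <- somatic[need]
  }
  sets <- lapply(somatic, function(s) unique(keys_of(s)))
  n_spec <- length(sets)
  support <- table(unlist(sets, use.names = FALSE))
  all_keys <- names(support)
  truncal <- all_keys[support == n_spec & n_spec > 0L]
  private_keys <- all_keys[support == 1L & n_spec > 1L]
  if (n_spec == 1L) { truncal <- character(0); private_keys <- all_keys }
  other_keys <- setdiff(all_keys, c(truncal, private_keys))
  private <- lapply(sets, function(s) intersect(s, private_keys))
  other_shared <- lapply(other_keys, function(k)
    names(sets)[vapply(sets, function(s) k %in% s, TRUE)])
  names(other_shared) <- other_keys
  structure(list(case_id = case_id, truncal = truncal, private = private,
                 other_shared = other_shared, n_specimens = n_spec,
                 union = all_keys),
            class = "crc_partition")
}

#' @export
print.crc_partition <- function(x, ...) {
  cat("crc_partition [", x$case_id, "]: ", length(x$truncal), " truncal, ",
      sum(lengths(x$private)), " private, ", length(x$other_shared),
      " other-shared over ", x$n_specimens, " specimens\n", sep = "")
  invisible(x)
}

#' Derive de novo variants of a metastasis
#'
#' The de novo set of a metastasis is its somatic variant keys absent from
#' the case-matched primary tumour's somatic set (plain set subtraction).
#' In strict mode a key also present in the primary at the rescue threshold
#' (`primary_rescue`) is not counted as de novo.
#'
#' @param met Somatic call table or key vector of the metastasis.
#' @param primary Somatic call table or key vector of the primary tumour.
#' @param primary_rescue Optional rescue-threshold somatic keys of the
#'   primary, consulted only when `strict = TRUE`.
#' @param strict Strict mode flag; see [filter_config()]'s `strict_de_novo`.
#' @param cohort Optional `crc_cohort` for the cross-case guard.
#' @return Character vector of de novo variant keys.
#' @export
derive_de_novo <- function(met, primary, primary_rescue = NULL,
                           strict = FALSE, cohort = NULL) {
  if (!is.null(cohort) && is.data.frame(met) && is.data.frame(primary))
    .check_same_case(cohort, unique(met$specimen_id),
                     unique(primary$specimen_id))
  out <- setdiff(unique(keys_of(met)), keys_of(primary))
  if (strict && !is.null(primary_rescue))
    out <- setdiff(out, keys_of(primary_rescue))
  out
}

# ---- RAS hotspot machinery ------------------------------------------------

.ras_genes <- c("KRAS", "NRAS")
.ras_hotspot_codons <- c(12L, 13L, 59L, 61L, 117L, 146L)

# First integer in a protein-level HGVS string, e.g. "p.G12D" -> 12.
hgvs_codon <- function(hgvs_p) {
  hgvs_p <- as.character(hgvs_p)
  pos <- regexpr("[0-9]+", hgvs_p)
  out <- rep(NA_integer_, length(hgvs_p))
  has <- !is.na(hgvs_p) & pos > 0L
  out[has] <- as.integer(regmatches(hgvs_p, pos))
  out
}

is_ras_hotspot <- function(gene, hgvs_p) {
  gene %in% .ras_genes & hgvs_codon(hgvs_p) %in% .ras_hotspot_codons
}

#' Track RAS hotspot status through the disease course
#'
#' Examines the unfiltered calls of every tumour specimen of a case for
#' KRAS/NRAS hotspot variants (codons 12, 13, 59, 61, 117, 146 — extended
#' RAS testing, exons 2-4). Each distinct hotspot variant is tracked
#' independently across specimens with a three-level detection status:
#' `detected` (AF at or above the reporting cutoff),
#' `detected_below_threshold` (AF in the rescue window, i.e. at or above
#' `rescue_af` but below the cutoff — the sub-threshold rescue scan), and
#' `not_detected` (absent or below the rescue threshold).
#'
#' `primary_status` is called from the primary specimen at the standard
#' cutoff. `maintained` (per primary hotspot variant) is `TRUE` when that
#' exact variant is at least rescue-detectable in every tumour specimen.
#' `status_maintained` is the case-level notion used in cohort summaries:
#' every tumour lesion shows *some* RAS hotspot variant at rescue level or
#' above (this accommodates a case whose metastases carry a different codon
#' allele than the primary).
#'
#' @param cohort A `crc_cohort`.
#' @param case_id Case identifier (must have a primary specimen).
#' @param raw_calls Unfiltered call table covering the case's tumour
#'   specimens (pre-AF-filter so the rescue scan can see sub-10 % alleles).
#' @param config A [filter_config()].
#' @return A `ras_trajectory` list: `case_id`, `primary_status`,
#'   `primary_variants`, `table` (one row per hotspot variant x tumour
#'   specimen), `maintained` (named logical), `status_maintained`,
#'   `subthreshold` (any rescue-window detection), `other_ras` (non-hotspot
#'   RAS variant keys, reported separately).
#' @export
track_ras <- function(cohort, case_id, raw_calls, config = filter_config()) {
  tsp <- tumour_specimens(cohort, case_id)
  if (!nrow(tsp)) stop("case ", case_id, ": no tumour specimens",
                       call. = FALSE)
  psp <- primary_specimen(cohort, case_id)
  if (!nrow(psp)) stop("case ", case_id, ": no primary specimen",
                       call. = FALSE)
  calls <- raw_calls[raw_calls$specimen_id %in% tsp$specimen_id, ,
                     drop = FALSE]
  ras <- calls[calls$gene %in% .ras_genes, , drop = FALSE]
  hot <- ras[is_ras_hotspot(ras$gene, ras$hgvs_p), , drop = FALSE]
  other_ras <- unique(ras$key[!is_ras_hotspot(ras$gene, ras$hgvs_p) &
                                ras$af_percent >= config$rescue_af])

  variants <- unique(hot[, c("key", "gene", "hgvs_p")])
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    for (j in seq_len(nrow(tsp))) {
      hit <- hot[hot$key == variants$key[i] &
                   hot$specimen_id == tsp$specimen_id[j], , drop = FALSE]
      af <- if (nrow(hit)) max(hit$af_percent) else 0
      detection <- if (af >= config$af_cutoff) "detected"
      else if (af >= config$rescue_af) "detected_below_threshold"
      else "not_detected"
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = case_id, key = variants$key[i], gene = variants$gene[i],
        hgvs_p = variants$hgvs_p[i], specimen_id = tsp$specimen_id[j],
        tissue = tsp$tissue[j], timing = tsp$timing[j],
        af_percent = af, detection = detection)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(0), key = character(0),
               gene = character(0), hgvs_p = character(0),
               specimen_id = character(0), tissue = character(0),
               timing = character(0), af_percent = numeric(0),
               detection = character(0))

  prim_tab <- tab[tab$specimen_id == psp$specimen_id, , drop = FALSE]
  primary_variants <- prim_tab$key[prim_tab$detection == "detected"]
  primary_status <- if (length(primary_variants)) "mutated" else "wildtype"

  maintained <- vapply(primary_variants, function(k) {
    all(tab$detection[tab$key == k] != "not_detected")
  }, TRUE)

  status_maintained <- if (primary_status == "wildtype") NA else
    all(vapply(tsp$specimen_id, function(s) {
      any(tab$specimen_id == s & tab$detection != "not_detected")
    }, TRUE))

  subthreshold <- any(tab$detection == "detected_below_threshold")

  structure(list(case_id = case_id, primary_status = primary_status,
                 primary_variants = primary_variants, table = tab,
                 maintained = maintained,
                 status_maintained = status_maintained,
                 subthreshold = subthreshold, other_ras = other_ras),
            class = "ras_trajectory")
}

#' @export
print.ras_trajectory <- function(x, ...) {
  cat("ras_trajectory [", x$case_id, "]: primary ", x$primary_status,
      if (!is.na(x$status_maintained))
        paste0(", status ", if (x$status_maintained) "maintained"
               else "not maintained"),
      "\n", sep = "")
  if (nrow(x$table)) print(x$table[, c("gene", "hgvs_p", "specimen_id",
                                       "af_percent", "detection")])
  invisible(x)
}

#' Concordance of two co-resected lesions
#'
#' Compares the somatic sets of two topographically separate lesions of the
#' same organ resected at the same date: shared keys (intersection) and each
#' lesion's exclusive keys (set differences). Counts satisfy
#' `|shared| + |exclusive_a| = |A|`.
#'
#' @param a,b Somatic call tables or key vectors of the two lesions.
#' @param cohort Optional `crc_cohort`; when given with call tables, the two
#'   specimens must share case, tissue and resection date (else an error).
#' @return A list with `shared`, `exclusive_a`, `exclusive_b` and `counts`.
#' @export
compare_colocated_lesions <- function(a, b, cohort = NULL) {
  if (!is.null(cohort) && is.data.frame(a) && is.data.frame(b)) {
    sa <- unique(a$specimen_id); sb <- unique(b$specimen_id)
    .check_same_case(cohort, sa, sb)
    ra <- cohort$specimens[cohort$specimens$specimen_id == sa, ]
    rb <- cohort$specimens[cohort$specimens$specimen_id == sb, ]
    if (nrow(ra) && nrow(rb) &&
        (!identical(ra$tissue, rb$tissue) ||
         !identical(ra$resection_date, rb$resection_date)))
      stop("lesions differ in tissue or resection date: ", sa, " vs ", sb,
           call. = FALSE)
  }
  ka <- unique(keys_of(a)); kb <- unique(keys_of(b))
  shared <- intersect(ka, kb)
  list(shared = shared,
       exclusive_a = setdiff(ka, kb), exclusive_b = setdiff(kb, ka),
       counts = c(shared = length(shared),
                  exclusive_a = length(setdiff(ka, kb)),
                  exclusive_b = length(setdiff(kb, ka)),
                  a = length(ka), b = length(kb)))
}

#' Compute per-specimen somatic sets for a whole cohort
#'
#' The standard preprocessing chain: for each case, tumour-specimen calls are
#' passed through [filter_calls()] at the given cutoff and the matched
#' normal's calls are subtracted ([subtract_germline()]).
#'
#' @param cohort A `crc_cohort`.
#' @param calls Raw call table for all specimens.
#' @param config A [filter_config()].
#' @param af_cutoff Cutoff used for the tumour-side filter (defaults to the
#'   standard cutoff; pass `config$rescue_af` for rescue-level sets).
#' @return Named list specimen_id -> somatic call table, covering every
#'   tumour specimen.
#' @export
somatic_sets <- function(cohort, calls, config = filter_config(),
                         af_cutoff = config$af_cutoff) {
  out <- list()
  for (cid in case_ids(cohort)) {
    nsp <- normal_specimen(cohort, cid)$specimen_id
    normal <- calls[calls$specimen_id == nsp, , drop = FALSE]
    for (sid in tumour_specimens(cohort, cid)$specimen_id) {
      tum <- calls[calls$specimen_id == sid, , drop = FALSE]
      tum <- filter_calls(tum, config, af_cutoff = af_cutoff)
      out[[sid]] <- subtract_germline(tum, normal, config)
    }
  }
  out
}
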