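# File formats: JSON cohort manifest (human-editable, mirrors the
# clinico-pathological summary table), TSV variant-call tables (1-based
# coordinates, af_percent 0-100, population_af 0-1), VCF 4.x input via
# VariantAnnotation, TSV report output with a provenance header comment.

#' Load a cohort manifest
#'
#' The manifest is a JSON document:
#' \preformatted{
#' {"provenance": "...",
#'  "cases": [
#'    {"case_id": "c01",
#'     "attributes": {"location": "colon_right", "TNM": "pT3pN1", ...},
#'     "treatments": ["Ardalan"],
#'     "specimens": [
#'       {"specimen_id": "c01_no", "tissue": "normal"},
#'       {"specimen_id": "c01_pt", "tissue": "primary",
#'        "resection_date": "2004-03"},
#'       {"specimen_id": "c01_hep_s1", "tissue": "liver_met",
#'        "resection_date": "2004-05", "timing": "synchronous",
#'        "lesion_label": "synM[HEP] 1"}, ...]}]}
#' }
#' Metastasis timing labels are optional; when absent they are derived from
#' resection dates by [assign_timing()].
#'
#' @param path Manifest file path.
#' @param strict Enforce the two-metastases inclusion rule. Default `TRUE`.
#' @return A validated `crc_cohort`.
#' @export
load_manifest <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cases <- doc$cases %||% list()
  sp_rows <- list(); treatments <- list(); attributes <- list()
  for (cs in cases) {
    cid <- cs$case_id
    if (is.null(cid)) stop("manifest case without case_id", call. = FALSE)
    treatments[[cid]] <- vapply(cs$treatments %||% list(), as.character, "")
    attributes[[cid]] <- cs$attributes %||% list()
    for (sp in cs$specimens %||% list()) {
      if (!is.null(sp$case_id) && !identical(sp$case_id, cid))
        stop("specimen ", sp$specimen_id, " references unknown case ",
             sp$case_id, call. = FALSE)
      sp_rows[[length(sp_rows) + 1L]] <- specimen(
        specimen_id = sp$specimen_id, case_id = cid, tissue = sp$tissue,
        resection_date = sp$resection_date %||% NA_character_,
        lesion_label = sp$lesion_label %||% NA_character_,
        tumour_cell_content = sp$tumour_cell_content %||% NA_real_,
        timing = sp$timing %||% NA_character_)
    }
  }
  specimens <- if (length(sp_rows)) do.call(rbind, sp_rows) else NULL
  cohort(specimens, treatments = treatments, attributes = attributes,
         provenance = doc$provenance %||% "", strict = strict)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort manifest
#'
#' Inverse of [load_manifest()]; emits the documented JSON schema with cases
#' and specimens in table order.
#'
#' @param x A `crc_cohort`.
#' @param path Output path.
#' @export
write_manifest <- function(x, path) {
  cases <- lapply(case_ids(x), function(cid) {
    cs <- case_specimens(x, cid)
    specs <- lapply(seq_len(nrow(cs)), function(i) {
      row <- as.list(cs[i, setdiff(names(cs), "case_id")])
      Filter(function(v) !is.na(v), row)
    })
    list(case_id = cid,
         attributes = x$attributes[[cid]] %||% list(),
         treatments = as.list(x$treatments[[cid]] %||% character(0)),
         specimens = specs)
  })
  jsonlite::write_json(list(provenance = x$provenance, cases = cases),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a tabular variant-call file
#'
#' TSV dialect with header columns `specimen_id`, `gene`, `chrom`, `pos`,
#' `ref`, `alt`, `hgvs_p`, `consequence`, `af_percent`, `population_af`,
#' `depth`, `alt_reads`; coordinate and annotation columns are optional per
#' the variant identity rules. Coordinates are 1-based; `af_percent` is 0-100
#' and `population_af` 0-1. Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return A validated variant-call table (see [as_variant_calls()]).
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("variant table not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty_calls())
  as_variant_calls(df)
}

#' @rdname read_variant_table
#' @param calls A variant-call table.
#' @export
write_variant_table <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# crctrace variant table; coordinates 1-based;",
               "# af_percent in [0,100], population_af in [0,1]"), con)
  utils::write.table(calls[, .call_cols, drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read variant calls from a VCF file
#'
#' Backed by \pkg{VariantAnnotation}: multi-allelic records are split into
#' one call per alternate allele; allele fraction is taken from the FORMAT
#' `AF` field when present, otherwise computed as `AD[alt] / DP` (percent).
#' Annotation is read from the INFO keys `GENE`, `HGVSP`, `CSQ` (consequence
#' vocabulary) and `POPAF` when present. Records with no usable allele
#' fraction are skipped; the number skipped is attached as attribute
#' `n_skipped`.
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @param specimen_id Specimen identifier to stamp on each call; defaults to
#'   the single sample name in the VCF.
#' @return A variant-call table with attribute `n_skipped`.
#' @export
read_vcf <- function(path, specimen_id = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path, call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)  # one row per alt allele
  n <- length(vcf)
  if (is.null(specimen_id)) {
    smp <- colnames(vcf)
    specimen_id <- if (length(smp) == 1L) smp else
      stop("specimen_id required for multi-sample VCF", call. = FALSE)
  }
  if (n == 0L) {
    out <- empty_calls(); attr(out, "n_skipped") <- 0L; return(out)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  geno <- VariantAnnotation::geno(vcf)
  info <- VariantAnnotation::info(vcf)

  af <- rep(NA_real_, n)
  depth <- rep(NA_integer_, n); alt_reads <- rep(NA_integer_, n)
  if ("DP" %in% names(geno)) depth <- as.integer(geno$DP[, 1L])
  if ("AD" %in% names(geno)) {
    ad <- geno$AD
    # after expand(): AD holds (ref, this alt) per expanded row
    alt_reads <- as.integer(vapply(seq_len(n), function(i) {
      x <- if (is.list(ad)) ad[[i]] else ad[i, 1L, ]
      if (length(x) >= 2L) x[[2L]] else NA_integer_
    }, integer(1)))
    if (!("DP" %in% names(geno)))
      depth <- as.integer(vapply(seq_len(n), function(i) {
        x <- if (is.list(ad)) ad[[i]] else ad[i, 1L, ]
        if (all(!is.na(x))) sum(x) else NA_integer_
      }, integer(1)))
  }
  if ("AF" %in% names(geno)) {
    raw <- geno$AF
    af <- as.numeric(vapply(seq_len(n), function(i) {
      x <- if (is.list(raw)) raw[[i]] else raw[i, 1L, drop = TRUE]
      if (length(x) && !is.na(x[[1L]])) as.numeric(x[[1L]]) else NA_real_
    }, numeric(1))) * 100
  }
  need <- is.na(af) & !is.na(alt_reads) & !is.na(depth) & depth > 0L
  af[need] <- 100 * alt_reads[need] / depth[need]

  grab <- function(key) {
    if (key %in% names(info)) as.character(info[[key]]) else
      rep(NA_character_, n)
  }
  df <- data.frame(
    specimen_id = specimen_id,
    gene = grab("GENE"),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    hgvs_p = grab("HGVSP"),
    consequence = grab("CSQ"),
    af_percent = af,
    population_af = if ("POPAF" %in% names(info))
      as.numeric(info$POPAF) else NA_real_,
    depth = depth, alt_reads = alt_reads,
    stringsAsFactors = FALSE)
  df$consequence[is.na(df$consequence)] <- "other"
  keep <- !is.na(df$af_percent)
  n_skipped <- sum(!keep)
  if (n_skipped)
    warning(n_skipped, " VCF record(s) without usable AF or AD+DP skipped",
            call. = FALSE)
  out <- as_variant_calls(df[keep, , drop = FALSE])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a report table as TSV
#'
#' Emits a rectangular report with a header comment naming the package
#' version and the filter configuration, then the tab-separated table.
#' `read_report` parses it back (the round trip is the identity).
#'
#' @param table Data frame produced by the aggregation functions.
#' @param path Output path.
#' @param config Optional `filter_config` recorded in the header.
#' @export
write_report <- function(table, path, config = NULL) {
  stopifnot(is.data.frame(table))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot write report: ", path, call. = FALSE)
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("crctrace"))
  writeLines(paste0("# crctrace ", ver), con)
  if (!is.null(config))
    writeLines(sprintf(
      "# filter: af_cutoff=%g pop_af_cutoff=%g exclude_synonymous=%s rescue_af=%g",
      config$af_cutoff, config$pop_af_cutoff, config$exclude_synonymous,
      config$rescue_af), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE)
}
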