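# Canonical column set for a variant-call table. Coordinates and read support
# are optional per the identity rules; af_percent is 0-100, population_af 0-1.
.call_cols <- c("specimen_id", "gene", "chrom", "pos", "ref", "alt",
                "hgvs_p", "consequence", "af_percent", "population_af",
                "depth", "alt_reads")

.consequences <- c("missense", "nonsense", "frameshift", "synonymous",
                   "splice", "inframe", "other")

#' Construct a variant
#'
#' A variant is an allele identity: either a complete genomic quadruple
#' (chrom, pos, ref, alt) or a gene plus protein-level HGVS change. At least
#' one of the two must be complete; the quadruple dominates for identity.
#'
#' @param gene HGNC symbol, or `NA`.
#' @param hgvs_p Protein-level change such as `"p.G12D"`, or `NA`.
#' @param chrom,pos,ref,alt Genomic quadruple; all four or none.
#' @param consequence One of `missense`, `nonsense`, `frameshift`,
#'   `synonymous`, `splice`, `inframe`, `other`.
#' @param population_af Population allele frequency in `[0, 1]`, or `NA`.
#' @return A `crc_variant` list.
#' @examples
#' v <- variant(gene = "KRAS", hgvs_p = "p.G12D")
#' variant_key(v)
#' @export
variant <- function(gene = NA_character_, hgvs_p = NA_character_,
                    chrom = NA_character_, pos = NA_integer_,
                    ref = NA_character_, alt = NA_character_,
                    consequence = "other", population_af = NA_real_) {
  consequence <- match.arg(consequence, .consequences)
  v <- structure(list(gene = as.character(gene), hgvs_p = as.character(hgvs_p),
                      chrom = as.character(chrom), pos = as.integer(pos),
                      ref = as.character(ref), alt = as.character(alt),
                      consequence = consequence,
                      population_af = as.numeric(population_af)),
                 class = "crc_variant")
  validate_variant(v)
  v
}

.has <- function(x) !is.na(x) & nzchar(as.character(x))

validate_variant <- function(v) {
  quad <- .has(v$chrom) && !is.na(v$pos) && .has(v$ref) && .has(v$alt)
  pair <- .has(v$gene) && .has(v$hgvs_p)
  if (!quad && !pair)
    stop("malformed variant: need a complete (chrom,pos,ref,alt) quadruple ",
         "or a (gene, hgvs_p) pair", call. = FALSE)
  if (!is.na(v$pos) && v$pos < 1L)
    stop("malformed variant: pos must be >= 1", call. = FALSE)
  if (.has(v$ref) && .has(v$alt) && identical(v$ref, v$alt))
    stop("malformed variant: ref equals alt", call. = FALSE)
  if (!is.na(v$population_af) &&
      (v$population_af < 0 || v$population_af > 1))
    stop("malformed variant: population_af outside [0,1]", call. = FALSE)
  invisible(v)
}

#' Deterministic variant identity key
#'
#' Returns the genomic-quadruple key `"chrom:pos:ref>alt"` when the quadruple
#' is complete, otherwise the protein-level key `"gene|hgvs_p"`. Two variants
#' are the same allele iff their keys are equal. Vectorised over equal-length
#' field vectors so it applies directly to a call table.
#'
#' @param v A `crc_variant`, or a data frame carrying the variant columns.
#' @return Character key(s).
#' @export
variant_key <- function(v) {
  if (inherits(v, "crc_variant"))
    return(variant_key_fields(v$gene, v$hgvs_p, v$chrom, v$pos, v$ref, v$alt))
  if (is.data.frame(v))
    return(variant_key_fields(v$gene, v$hgvs_p, v$chrom, v$pos, v$ref, v$alt))
  stop("variant_key expects a crc_variant or a call table", call. = FALSE)
}

variant_key_fields <- function(gene, hgvs_p, chrom = NA, pos = NA,
                               ref = NA, alt = NA) {
  gene <- gene %||% NA; hgvs_p <- hgvs_p %||% NA; chrom <- chrom %||% NA
  pos <- pos %||% NA; ref <- ref %||% NA; alt <- alt %||% NA
  n <- max(length(gene), length(hgvs_p), length(chrom))
  gene <- rep_len(as.character(gene), n); hgvs_p <- rep_len(as.character(hgvs_p), n)
  chrom <- rep_len(as.character(chrom), n); pos <- rep_len(pos, n)
  ref <- rep_len(as.character(ref), n); alt <- rep_len(as.character(alt), n)
  quad <- .has(chrom) & !is.na(pos) & .has(ref) & .has(alt)
  pair <- .has(gene) & .has(hgvs_p)
  if (any(!quad & !pair))
    stop("malformed variant at position(s) ",
         paste(which(!quad & !pair), collapse = ", "),
         ": no identity key constructible", call. = FALSE)
  ifelse(quad, paste0(chrom, ":", pos, ":", ref, ">", alt),
         paste0(gene, "|", hgvs_p))
}

#' Validate and normalise a variant-call table
#'
#' A call table is the package's working container: one row per variant
#' observation in one specimen. Missing optional columns are added as `NA`;
#' a `key` column with the variant identity is appended.
#'
#' @param df Data frame with at least `specimen_id`, `af_percent`, and either
#'   the genomic quadruple or `gene` + `hgvs_p`.
#' @return The validated data frame with all canonical columns plus `key`.
#' @export
as_variant_calls <- function(df) {
  stopifnot(is.data.frame(df))
  missing_mand <- setdiff(c("specimen_id", "af_percent"), names(df))
  if (length(missing_mand))
    stop("variant table missing mandatory column(s): ",
         paste(missing_mand, collapse = ", "), call. = FALSE)
  for (col in .call_cols)
    if (is.null(df[[col]]))
      df[[col]] <- if (col %in% c("pos", "depth", "alt_reads")) NA_integer_
                   else if (col %in% c("af_percent", "population_af")) NA_real_
                   else NA_character_
  df <- df[, .call_cols, drop = FALSE]
  df$pos <- as.integer(df$pos)
  df$depth <- as.integer(df$depth); df$alt_reads <- as.integer(df$alt_reads)
  df$af_percent <- as.numeric(df$af_percent)
  df$population_af <- as.numeric(df$population_af)

  bad <- which(is.na(df$af_percent) | df$af_percent < 0 | df$af_percent > 100)
  if (length(bad))
    stop("allele_fraction outside [0,100] at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!is.na(df$alt_reads) & !is.na(df$depth) &
                 df$alt_reads > df$depth)
  if (length(bad))
    stop("alt_reads > depth at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(df$pos) & df$pos < 1L)
  if (length(bad))
    stop("pos < 1 at row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(.has(df$ref) & .has(df$alt) & df$ref == df$alt)
  if (length(bad))
    stop("ref equals alt at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  df$key <- tryCatch(variant_key(df), error = function(e)
    stop("variant identity failure: ", conditionMessage(e), call. = FALSE))
  rownames(df) <- NULL
  df
}

empty_calls <- function() {
  df <- as.data.frame(stats::setNames(
    lapply(.call_cols, function(col)
      if (col %in% c("pos", "depth", "alt_reads")) integer(0)
      else if (col %in% c("af_percent", "population_af")) numeric(0)
      else character(0)),
    .call_cols))
  df$key <- character(0)
  df
}

#' Variant-filter configuration
#'
#' Bundles the thresholds of the reporting filter stack used throughout the
#' pipeline: the allele-fraction cutoff (percent, calls at or above are
#' retained), the population-frequency cutoff (fraction, calls strictly above
#' are removed), synonymous exclusion, the named common-variant blacklist,
#' and the rescue threshold for the sub-threshold scan.
#'
#' @param af_cutoff Allele-fraction reporting cutoff in percent. Default 10.
#' @param pop_af_cutoff Population-frequency exclusion cutoff as a fraction.
#'   Default 0.05; calls with population frequency above it are removed.
#' @param exclude_synonymous Drop synonymous calls. Default `TRUE`.
#' @param blacklist Data frame with columns `gene`, `hgvs_p` of common
#'   polymorphisms never reported. Default: KDR p.Q472H, KIT p.M541L,
#'   TP53 p.P72R.
#' @param rescue_af Lowered cutoff (percent) for the sub-threshold rescue
#'   scan. Default 1.
#' @param strict_de_novo If `TRUE`, a metastasis variant counts as de novo
#'   only when absent from the primary even at the rescue threshold.
#' @return A `filter_config` list.
#' @export
filter_config <- function(af_cutoff = 10, pop_af_cutoff = 0.05,
                          exclude_synonymous = TRUE,
                          blacklist = default_blacklist(),
                          rescue_af = 1, strict_de_novo = FALSE) {
  stopifnot(is.numeric(af_cutoff), is.numeric(pop_af_cutoff),
            is.numeric(rescue_af), is.logical(exclude_synonymous))
  if (!(rescue_af > 0 && rescue_af < af_cutoff && af_cutoff <= 100))
    stop("require 0 < rescue_af < af_cutoff <= 100", call. = FALSE)
  if (pop_af_cutoff < 0 || pop_af_cutoff > 1)
    stop("pop_af_cutoff must lie in [0,1]", call. = FALSE)
  if (!is.data.frame(blacklist) ||
      !all(c("gene", "hgvs_p") %in% names(blacklist)))
    stop("blacklist must be a data frame with gene and hgvs_p", call. = FALSE)
  structure(list(af_cutoff = af_cutoff, pop_af_cutoff = pop_af_cutoff,
                 exclude_synonymous = exclude_synonymous,
                 blacklist = blacklist, rescue_af = rescue_af,
                 strict_de_novo = strict_de_novo),
            class = "filter_config")
}

#' @rdname filter_config
#' @export
default_blacklist <- function() {
  data.frame(gene = c("KDR", "KIT", "TP53"),
             hgvs_p = c("p.Q472H", "p.M541L", "p.P72R"))
}
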