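# Cohort-level summary tables. All tables are plain data frames with a
# deterministic row order so written reports are byte-stable.

.lookup_variants <- function(somatic) {
  tabs <- Filter(is.data.frame, somatic)
  if (!length(tabs)) return(data.frame(key = character(0),
                                       gene = character(0),
                                       hgvs_p = character(0)))
  lk <- do.call(rbind, lapply(tabs, function(s)
    s[, c("key", "gene", "hgvs_p")]))
  lk[!duplicated(lk$key), , drop = FALSE]
}

#' Per-case summary of recurrently present variants
#'
#' For each case, lists the exact somatic variants present in at least two
#' of its tumour specimens (the case-matched "shared in 2 or more tumour
#' sites" view), with per-specimen presence. Cohort counts roll rows up to
#' gene level: the count for gene g is the number of cases with at least one
#' qualifying row for g.
#'
#' @param cohort A `crc_cohort`.
#' @param somatic Named list specimen_id -> somatic call table
#'   (see [somatic_sets()]).
#' @return List with `rows` (case_id, gene, hgvs_p, key, n_specimens,
#'   specimens) and `gene_counts` (gene, n_cases), both sorted.
#' @export
gene_case_summary <- function(cohort, somatic) {
  rows <- list()
  for (cid in case_ids(cohort)) {
    tsp <- tumour_specimens(cohort, cid)$specimen_id
    sets <- lapply(somatic[tsp], function(s)
      if (is.null(s)) character(0) else unique(keys_of(s)))
    support <- table(unlist(sets, use.names = FALSE))
    shared <- names(support)[support >= 2L]
    if (!length(shared)) next
    lk <- .lookup_variants(somatic[tsp])
    for (k in shared) {
      who <- tsp[vapply(sets, function(s) k %in% s, TRUE)]
      i <- match(k, lk$key)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = cid, gene = lk$gene[i], hgvs_p = lk$hgvs_p[i], key = k,
        n_specimens = length(who),
        specimens = paste(who, collapse = ","))
    }
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(0), gene = character(0),
               hgvs_p = character(0), key = character(0),
               n_specimens = integer(0), specimens = character(0))
  rows <- rows[order(rows$case_id, rows$gene, rows$hgvs_p), , drop = FALSE]
  rownames(rows) <- NULL
  gc <- if (nrow(rows))
    stats::aggregate(case_id ~ gene, rows,
                     function(x) length(unique(x)))
  else data.frame(gene = character(0), case_id = integer(0))
  names(gc) <- c("gene", "n_cases")
  gc <- gc[order(-gc$n_cases, gc$gene), , drop = FALSE]
  rownames(gc) <- NULL
  list(rows = rows, gene_counts = gc)
}

#' Case-mixed tally of variants by tumour-site class
#'
#' Pools specimens across cases by site class (primary split by organ:
#' PT-Colon / PT-Rectum; metastases by timing x organ) and counts, for every
#' exact variant, the specimens per class carrying it. Rows are kept only
#' when some class count reaches 2; KRAS/NRAS (reported via the RAS tracker)
#' and blacklisted polymorphisms are excluded.
#'
#' @param cohort A `crc_cohort` with timing assigned.
#' @param somatic Named list specimen_id -> somatic call table.
#' @param config A [filter_config()] (supplies the blacklist).
#' @return Data frame (gene, hgvs_p, key, one column per site class),
#'   ordered by gene then variant.
#' @export
site_mixed_tally <- function(cohort, somatic, config = filter_config()) {
  classes <- c("PT-Colon", "PT-Rectum", "synM[HEP]", "synM[PUL]",
               "metM[HEP]", "metM[PUL]")
  sp <- cohort$specimens[cohort$specimens$tissue != "normal", , drop = FALSE]
  counts <- list()
  lk <- .lookup_variants(somatic)
  for (i in seq_len(nrow(sp))) {
    cls <- site_class(cohort, sp[i, ])
    if (is.na(cls)) {
      warning("case ", sp$case_id[i],
              ": unknown primary location; excluded from PT columns",
              call. = FALSE)
      next
    }
    s <- somatic[[sp$specimen_id[i]]]
    if (is.null(s)) next
    for (k in unique(keys_of(s))) {
      if (is.null(counts[[k]]))
        counts[[k]] <- stats::setNames(integer(length(classes)), classes)
      counts[[k]][cls] <- counts[[k]][cls] + 1L
    }
  }
  keep <- names(counts)[vapply(counts, function(x) any(x >= 2L), TRUE)]
  lk <- lk[match(keep, lk$key), , drop = FALSE]
  bl <- paste0(config$blacklist$gene, "|", config$blacklist$hgvs_p)
  ok <- !(lk$gene %in% c("KRAS", "NRAS")) &
    !(paste0(lk$gene, "|", lk$hgvs_p) %in% bl)
  keep <- keep[ok]; lk <- lk[ok, , drop = FALSE]
  out <- data.frame(gene = lk$gene, hgvs_p = lk$hgvs_p, key = keep,
                    stringsAsFactors = FALSE)
  for (cls in classes)
    out[[cls]] <- vapply(keep, function(k) counts[[k]][[cls]], integer(1))
  out <- out[order(out$gene, out$hgvs_p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene de novo case counts by metastasis class
#'
#' For each gene and metastasis class (synchronous/metachronous x
#' liver/lung), the number of cases with at least one de novo variant of
#' that gene in a lesion of that class. A case with several lesions of one
#' class counts once.
#'
#' @param cohort A `crc_cohort` with timing assigned.
#' @param de_novo Named list specimen_id -> de novo key vector (metastatic
#'   specimens).
#' @param somatic Named list used to resolve keys to genes.
#' @param genes Gene universe for the table rows; defaults to the genes
#'   observed. Pass [panel_genes()] for the full-panel view.
#' @return Data frame (gene, `synM[HEP]`, `synM[PUL]`, `metM[HEP]`,
#'   `metM[PUL]`) of case counts.
#' @export
de_novo_frequency <- function(cohort, de_novo, somatic, genes = NULL) {
  classes <- c("synM[HEP]", "synM[PUL]", "metM[HEP]", "metM[PUL]")
  lk <- .lookup_variants(somatic)
  hits <- list()  # gene -> class -> set of cases
  sp <- cohort$specimens
  for (sid in names(de_novo)) {
    row <- sp[sp$specimen_id == sid, , drop = FALSE]
    if (!nrow(row) || !row$tissue %in% c("liver_met", "lung_met")) next
    cls <- site_class(cohort, row[1, ])
    gs <- unique(lk$gene[match(de_novo[[sid]], lk$key)])
    gs <- gs[!is.na(gs)]
    for (g in gs)
      hits[[g]][[cls]] <- union(hits[[g]][[cls]], row$case_id)
  }
  if (is.null(genes)) genes <- sort(names(hits))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (cls in classes)
    out[[cls]] <- vapply(genes, function(g)
      length(hits[[g]][[cls]]), integer(1))
  rownames(out) <- NULL
  out
}

#' Treatment-context report of lung-metastasis de novo mutations
#'
#' One row per case with at least one lung metastasis: timing classes seen,
#' years post primary resection (whole years, rounded up), recorded
#' treatment regimens, and the sorted union of de novo genes over the
#' case's lung lesions ("no de novo mutations" when empty).
#'
#' @inheritParams de_novo_frequency
#' @return Data frame (case_id, classes, years_post_primary, regimens,
#'   de_novo_genes).
#' @export
treatment_report <- function(cohort, de_novo, somatic) {
  lk <- .lookup_variants(somatic)
  rows <- list()
  for (cid in case_ids(cohort)) {
    lungs <- cohort$specimens[cohort$specimens$case_id == cid &
                                cohort$specimens$tissue == "lung_met", ,
                              drop = FALSE]
    if (!nrow(lungs)) next
    pd <- primary_specimen(cohort, cid)$resection_date
    cls <- unique(ifelse(lungs$timing == "metachronous", "met", "syn"))
    yrs <- sort(unique(ceiling(pmax(
      month_diff(lungs$resection_date, pd), 0) / 12)))
    genes <- sort(unique(stats::na.omit(
      lk$gene[match(unlist(de_novo[lungs$specimen_id]), lk$key)])))
    rows[[length(rows) + 1L]] <- data.frame(
      case_id = cid,
      classes = paste(cls, collapse = ","),
      years_post_primary = paste(yrs, collapse = ","),
      regimens = paste(cohort$treatments[[cid]] %||% character(0),
                       collapse = ", "),
      de_novo_genes = if (length(genes)) paste(genes, collapse = ", ")
      else "no de novo mutations")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(0), classes = character(0),
               years_post_primary = character(0), regimens = character(0),
               de_novo_genes = character(0))
  rownames(out) <- NULL
  out
}

#' Cohort-level RAS and size summary
#'
#' Counts and percentages over the cohort: specimens, cases, RAS
#' wildtype/mutant primaries with the KRAS/NRAS split, the fraction of
#' mutant cases whose RAS status is maintained in every lesion, and the
#' number of cases with sub-threshold (rescue-window) hotspot detections.
#' Percentages are recomputed from their numerator/denominator and rounded
#' to the nearest integer.
#'
#' @param cohort A `crc_cohort`.
#' @param trajectories List of `ras_trajectory` objects, one per case.
#' @return Named list of counts and integer percentages.
#' @export
cohort_summary <- function(cohort, trajectories) {
  n_cases <- length(case_ids(cohort))
  n_specimens <- nrow(cohort$specimens)
  status <- vapply(trajectories, function(t) t$primary_status, "")
  mutated <- sum(status == "mutated")
  wildtype <- sum(status == "wildtype")
  prim_gene <- vapply(trajectories, function(t) {
    if (t$primary_status != "mutated") return(NA_character_)
    gs <- unique(t$table$gene[t$table$key %in% t$primary_variants])
    paste(sort(gs), collapse = "+")
  }, "")
  kras <- sum(prim_gene == "KRAS", na.rm = TRUE)
  nras <- sum(prim_gene == "NRAS", na.rm = TRUE)
  maint <- vapply(trajectories, function(t)
    isTRUE(t$status_maintained), TRUE)
  maintained <- sum(maint & status == "mutated")
  subthr <- sum(vapply(trajectories, function(t) isTRUE(t$subthreshold),
                       TRUE))
  pct <- function(num, den) if (den > 0) as.integer(round(100 * num / den))
  else NA_integer_
  list(n_cases = n_cases, n_specimens = n_specimens,
       ras_mutated = mutated, ras_wildtype = wildtype,
       kras_mutated = kras, nras_mutated = nras,
       kras_pct = pct(kras, n_cases), nras_pct = pct(nras, n_cases),
       maintained = maintained, maintained_denominator = mutated,
       maintained_pct = pct(maintained, mutated),
       subthreshold_cases = subthr)
}
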