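# Resection dates have month precision; internally a month index
# (year * 12 + month - 1) so date arithmetic is plain integer subtraction.

#' Month-precision date helpers
#'
#' Dates throughout the package carry month precision ("YYYY-MM").
#' `ym_index` converts to an absolute month count; `month_diff` is the signed
#' whole-month difference `a - b`.
#'
#' @param x,a,b Character dates `"YYYY-MM"` (also accepts `"MM/YY"`,
#'   interpreted in 1950-2049).
#' @return Integer month index / difference.
#' @export
ym_index <- function(x) {
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  iso <- grepl("^\\d{4}-\\d{1,2}$", x)
  out[iso] <- as.integer(sub("-.*", "", x[iso])) * 12L +
    as.integer(sub(".*-", "", x[iso])) - 1L
  mmyy <- grepl("^\\d{1,2}/\\d{2}$", x)
  if (any(mmyy)) {
    yy <- as.integer(sub(".*/", "", x[mmyy]))
    yr <- ifelse(yy < 50L, 2000L + yy, 1900L + yy)
    out[mmyy] <- yr * 12L + as.integer(sub("/.*", "", x[mmyy])) - 1L
  }
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop("unparseable month date(s): ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  out
}

#' @rdname ym_index
#' @export
month_diff <- function(a, b) ym_index(a) - ym_index(b)

.tissues <- c("normal", "primary", "liver_met", "lung_met")

#' Construct a specimen record
#'
#' @param specimen_id,case_id Identifiers.
#' @param tissue One of `normal`, `primary`, `liver_met`, `lung_met`.
#' @param resection_date `"YYYY-MM"`; required for tumour specimens.
#' @param lesion_label Free-text lesion description (e.g. "segment 7").
#' @param tumour_cell_content Percent of tumour nuclei, or `NA`.
#' @param timing Optional clinic-assigned timing label (`synchronous` /
#'   `metachronous`) that overrides the date-derived classification.
#' @return A one-row data frame.
#' @export
specimen <- function(specimen_id, case_id, tissue,
                     resection_date = NA_character_,
                     lesion_label = NA_character_,
                     tumour_cell_content = NA_real_,
                     timing = NA_character_) {
  tissue <- match.arg(tissue, .tissues)
  if (tissue != "normal" && is.na(resection_date))
    stop("specimen ", specimen_id,
         ": resection_date required for tumour specimens", call. = FALSE)
  if (!is.na(timing))
    timing <- match.arg(timing, c("synchronous", "metachronous"))
  if (tissue == "normal") timing <- NA_character_
  if (!is.na(tumour_cell_content) &&
      (tumour_cell_content < 0 || tumour_cell_content > 100))
    stop("tumour_cell_content outside [0,100]", call. = FALSE)
  data.frame(specimen_id = as.character(specimen_id),
             case_id = as.character(case_id), tissue = tissue,
             lesion_label = as.character(lesion_label),
             resection_date = as.character(resection_date),
             tumour_cell_content = as.numeric(tumour_cell_content),
             timing = as.character(timing))
}

#' Assemble a cohort from specimen and case tables
#'
#' A `crc_cohort` bundles a specimen table, per-case treatments and
#' clinico-pathological attributes. Case invariants are enforced: exactly one
#' primary and one normal specimen per case and at least two metastatic
#' lesions (the study-inclusion rule), unless `strict = FALSE`.
#'
#' @param specimens Data frame of specimen rows (see [specimen()]).
#' @param treatments Named list: case_id -> character vector of regimens.
#' @param attributes Named list: case_id -> named list of clinico-pathological
#'   keys (location, histotype, grade, TNM, MSI, CIMP, ...).
#' @param provenance Free-text metadata.
#' @param strict Enforce the metastasis-count inclusion rule. Default `TRUE`.
#' @return A `crc_cohort` object.
#' @export
cohort <- function(specimens, treatments = list(), attributes = list(),
                   provenance = "", strict = TRUE) {
  if (is.null(specimens) || nrow(specimens) == 0L) {
    specimens <- specimen("x", "x", "normal")[0, ]
  }
  dup <- specimens$specimen_id[duplicated(specimens$specimen_id)]
  if (length(dup))
    stop("duplicate specimen_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  obj <- structure(list(specimens = specimens,
                        treatments = treatments, attributes = attributes,
                        provenance = provenance),
                   class = "crc_cohort")
  validate_cohort(obj, strict = strict)
  obj
}

#' @rdname cohort
#' @export
validate_cohort <- function(x, strict = TRUE) {
  sp <- x$specimens
  extra <- setdiff(names(x$treatments), sp$case_id)
  if (length(extra))
    stop("treatments reference unknown case(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  for (cid in unique(sp$case_id)) {
    cs <- sp[sp$case_id == cid, ]
    if (sum(cs$tissue == "primary") != 1L)
      stop("case ", cid, ": exactly one primary specimen required",
           call. = FALSE)
    if (sum(cs$tissue == "normal") != 1L)
      stop("case ", cid, ": exactly one normal specimen required",
           call. = FALSE)
    if (strict && sum(cs$tissue %in% c("liver_met", "lung_met")) < 2L)
      stop("case ", cid, ": at least two metastatic specimens required",
           call. = FALSE)
    miss <- cs$tissue != "normal" & (is.na(cs$resection_date))
    if (any(miss))
      stop("case ", cid, ": tumour specimen(s) missing resection_date: ",
           paste(cs$specimen_id[miss], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.crc_cohort <- function(x, ...) {
  cat("crc_cohort:", length(case_ids(x)), "cases,", nrow(x$specimens),
      "specimens\n")
  tab <- table(x$specimens$tissue)
  cat(paste0("  ", names(tab), ": ", tab, collapse = "\n"), "\n")
  invisible(x)
}

#' Cohort accessors
#'
#' @param x A `crc_cohort`.
#' @param case_id Case identifier.
#' @return `case_ids`: character vector of case ids in first-seen order.
#'   `case_specimens`: the specimen table subset of one case.
#'   `primary_specimen` / `normal_specimen`: the single primary / normal row.
#'   `tumour_specimens`: primary + metastatic rows of one case.
#' @export
case_ids <- function(x) unique(x$specimens$case_id)

#' @rdname case_ids
#' @export
case_specimens <- function(x, case_id) {
  cs <- x$specimens[x$specimens$case_id == case_id, , drop = FALSE]
  if (!nrow(cs)) stop("unknown case: ", case_id, call. = FALSE)
  cs
}

#' @rdname case_ids
#' @export
primary_specimen <- function(x, case_id) {
  cs <- case_specimens(x, case_id)
  cs[cs$tissue == "primary", , drop = FALSE]
}

#' @rdname case_ids
#' @export
normal_specimen <- function(x, case_id) {
  cs <- case_specimens(x, case_id)
  cs[cs$tissue == "normal", , drop = FALSE]
}

#' @rdname case_ids
#' @export
tumour_specimens <- function(x, case_id) {
  cs <- case_specimens(x, case_id)
  cs[cs$tissue != "normal", , drop = FALSE]
}
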