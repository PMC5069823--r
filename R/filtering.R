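# The reporting filter stack and the FFPE DNA QC metric.
#
# Boundary conventions (the source wording never tests a boundary, so they
# are fixed here and documented): the AF cutoff is inclusive (af >= cutoff
# retained), the population cutoff exclusive (pop_af > cutoff removed).

#' FFPE DNA quality-control value
#'
#' qPCR-based QC for FFPE-derived DNA: the sample and a positive control are
#' each measured in triplicate and the QC value is the mean cycle-threshold
#' difference `mean(sample) - mean(control)` (delta-Ct). Values below 2
#' cycles indicate DNA suitable for amplicon library preparation.
#'
#' @param sample_cts Three Ct values of the sample.
#' @param control_cts Three Ct values of the positive control.
#' @param specimen_id Optional identifier carried into the record.
#' @return A one-row data frame with `specimen_id`, `qc_value`, `valid`.
#' @examples
#' compute_qc_value(c(30, 30, 30), c(27, 27, 27))  # 3 cycles, invalid
#' @export
compute_qc_value <- function(sample_cts, control_cts,
                             specimen_id = NA_character_) {
  if (length(sample_cts) != 3L || length(control_cts) != 3L)
    stop("QC requires triplicate Ct values for sample and control",
         call. = FALSE)
  if (!all(is.finite(sample_cts)) || !all(is.finite(control_cts)) ||
      any(sample_cts <= 0) || any(control_cts <= 0))
    stop("Ct values must be finite and positive", call. = FALSE)
  qc <- mean(sample_cts) - mean(control_cts)
  data.frame(specimen_id = specimen_id, qc_value = qc, valid = qc < 2)
}

#' Apply the variant reporting filter
#'
#' Retains exactly the calls with allele fraction at or above the cutoff,
#' non-synonymous consequence (when synonymous exclusion is on), population
#' frequency absent or at most the population cutoff, and protein change not
#' on the common-variant blacklist. Input order is preserved and the input
#' is not modified; filtering is idempotent.
#'
#' @param calls A variant-call table.
#' @param config A [filter_config()].
#' @param af_cutoff Override of the allele-fraction cutoff, e.g. the rescue
#'   threshold for a sub-threshold scan.
#' @return The retained subset of `calls`.
#' @export
filter_calls <- function(calls, config = filter_config(),
                         af_cutoff = config$af_cutoff) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(calls) == 0L) return(calls)
  keep <- calls$af_percent >= af_cutoff
  if (config$exclude_synonymous)
    keep <- keep & !(calls$consequence %in% "synonymous")
  keep <- keep & (is.na(calls$population_af) |
                    calls$population_af <= config$pop_af_cutoff)
  bl <- paste0(config$blacklist$gene, "|", config$blacklist$hgvs_p)
  keep <- keep & !(paste0(calls$gene, "|", calls$hgvs_p) %in% bl)
  calls[keep, , drop = FALSE]
}
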