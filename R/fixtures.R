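#' Bundled disease-course cohort fixture
#'
#' Accessors for the hand-transcribed study fixture shipped with the
#' package: the 14-case / 70-specimen cohort manifest and the case-matched
#' variant calls (recurrently shared variants plus the RAS hotspot allele
#' fractions). Absent ("WT"/0) table cells are absent rows; allele
#' fractions the source tables do not print are a nominal 30 %.
#'
#' @return `crc_fixture_manifest()`: a `crc_cohort`;
#'   `crc_fixture_calls()`: a variant-call table.
#' @export
crc_fixture_manifest <- function() {
  load_manifest(system.file("extdata", "cohort_manifest.json",
                            package = "crctrace", mustWork = TRUE))
}

#' @rdname crc_fixture_manifest
#' @export
crc_fixture_calls <- function() {
  read_variant_table(system.file("extdata", "variant_calls.tsv",
                                 package = "crctrace", mustWork = TRUE))
}
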