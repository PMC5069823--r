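---
title: "Case-matched mutation profiling of colorectal cancer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-matched mutation profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crctrace)
```

## The analysis model

crctrace analyses targeted-panel variant calls from case-matched tissue
specimens collected across the disease course of colorectal cancer
patients: one normal colonic epithelium sample, one primary tumour, and at
least two distant (liver and/or lung) metastases per case. All reasoning
is within-case; case-mixed pooling is provided only as the explicitly
labelled `site_mixed_tally()` view.

The pipeline is a chain of set operations on variant *identities*:

1. **Reporting filter** (`filter_calls()`): retain calls with allele
   fraction (AF) ≥ `af_cutoff`, non-synonymous consequence, population
   frequency ≤ `pop_af_cutoff` (or unannotated), and not on the named
   common-polymorphism blacklist.
2. **Germline subtraction** (`subtract_germline()`): remove every variant
   whose identity occurs among the matched normal's calls, yielding the
   specimen's *somatic set*.
3. **Timing** (`classify_metastasis()`): metachronous iff resected more
   than 6 whole calendar months after the primary.
4. **Partition** (`partition_shared()`): truncal / lesion-private /
   other-shared compartments over a case's tumour specimens.
5. **De novo derivation** (`derive_de_novo()`): metastasis somatic set
   minus primary somatic set.
6. **RAS trajectory** (`track_ras()`): KRAS/NRAS hotspot variants (codons
   12, 13, 59, 61, 117, 146) tracked per lesion on *unfiltered* calls with
   a three-level detection status, so the sub-threshold rescue scan can
   see alleles between `rescue_af` and `af_cutoff`.
7. **Aggregation**: per-case recurrence summary, case-mixed site tally,
   per-gene de novo case counts by metastasis class, treatment-context
   report, cohort summary.

### Variant identity

Matching must work for two input dialects: VCF with genomic coordinates,
and protein-level tables as published. Identity is therefore the genomic
quadruple `chrom:pos:ref>alt` when complete, else the `(gene, hgvs_p)`
pair; the quadruple dominates when both are available. Distinct alleles at
one codon (e.g. KRAS p.G12D vs p.G12V) are distinct variants and are
tracked independently — this matters for the one cohort case whose primary
and metastases carry different codon-12 alleles.

## Tunable parameters

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| `af_cutoff` | percent | 10 | standard reporting cutoff of the assay; inclusive (≥ 10 retained) |
| `rescue_af` | percent | 1 | sub-threshold rescue scan level; inclusive (≥ 1 counts as detectable) |
| `pop_af_cutoff` | fraction | 0.05 | common-polymorphism exclusion; exclusive (> 0.05 removed) |
| `exclude_synonymous` | flag | TRUE | synonymous calls carry no reporting value here |
| `blacklist` | set | KDR p.Q472H, KIT p.M541L, TP53 p.P72R | named common variants never reported |
| `strict_de_novo` | flag | FALSE | strict mode also requires absence from the primary at rescue level |

Boundary conventions deserve a note: the sources the thresholds come from
never test a boundary value, so the conventions are fixed here and
documented rather than inferred — AF cutoffs inclusive, population cutoff
exclusive. Calls with *absent* population frequency are retained, because
annotation absence must not silently delete somatic candidates.

The germline subtraction ignores allele fraction on the normal side except
for a low evidence floor (`rescue_af`): any normal-specimen observation at
or above it counts as germline evidence. A 10 % normal-side threshold
would leak germline polymorphisms whenever the normal sample is shallow or
impure; a floor of zero would let single-read noise delete true somatic
variants.

## Design decisions that were genuinely open

**Two notions of "maintained".** Per hotspot variant, `maintained` means
the primary's exact allele is at least rescue-detectable in every tumour
specimen. But the clinically relevant quantity is the *status*: does every
lesion carry some RAS hotspot mutation? The cohort summary therefore uses
the case-level `status_maintained`. The distinction is visible in the
bundled fixture: one case's primary carries p.G12D while its metastases
carry p.G12V — exact-allele maintenance fails, status maintenance holds,
and the cohort statistic (7/9 maintained) counts it as maintained. Both
flags are reported so neither view is lost.

**Timing label precedence.** `classify_metastasis()` is the pure
date rule. Manifests may also carry the clinic's printed timing label,
which `assign_timing()` treats as authoritative when present: resection
dates have month precision, and a lesion detected synchronously may be
resected a few weeks past the 6-month line (the fixture contains exactly
one such lesion, 7 months post primary but designated synchronous).

**Years post primary** in the treatment report are whole years rounded up
from the month difference. The published treatment table's year column is
not consistent with any simple rounding of the published dates, so the
convention is fixed and documented rather than reverse-engineered.

**Manifest format.** A nested, human-editable JSON schema (cases →
specimens), because the cohort table must be hand-transcribable; jsonlite
ships with the dependency stack, so no extra parser is needed.

**Case-mixed site classes** split primaries by organ (colon vs rectum,
left/right colon pooled) and metastases by timing × organ — exactly the
six columns of the published case-mixed table.

## The synthetic-data generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, with ground truth recorded exactly:

- per case: 3–8 germline polymorphisms present in *every* specimen at
  ~50 % AF (100 % for the homozygous fraction, default 20 %), not purity
  scaled; 1–3 truncal somatic variants; a RAS hotspot truncal variant with
  probability 9/14;
- per metastatic lesion: class-dependent private (de novo) variants with
  per-gene Poisson rates (defaults are *illustrative*, echoing the
  qualitative class patterns — no per-gene rates are published);
- expected somatic AF = purity × clonal fraction / 2 (heterozygous
  diploid, clonal fraction 1, no copy-number model — the simplest model
  that yields sub-10 % alleles in low-purity lesions);
- observed AF: p ~ Beta(mean = expected, precision = `af_noise`),
  alt reads ~ Binomial(depth, p), depth ~ Poisson(`depth_mean` = 5000,
  matching the assay's mean amplicon coverage); calls with zero alt reads
  are not emitted.

Cohort-shape defaults (14 cases, 2–4 metastases, class mix 12:8:6:16 over
synchronous/metachronous liver/lung, purity 0.10–0.95) restate the study
cohort. `af_noise = 2000` encodes overdispersion beyond binomial counting
noise; it is chosen once so that the stated recovery property holds by
construction — at purity ≥ 0.25 a truncal variant's expected AF is
≥ 12.5 %, more than three noise standard deviations above the 10 % cutoff,
hence truncal precision and recall of 1.0 are a property of the stated
world, not of a tuned test.

What a green simulator test does **not** establish: correctness on real
FFPE data with C>T deamination artifacts, copy-number-driven AF shifts,
subclonal structure, multi-nucleotide or splice variants, or caller-specific
quirks — none of which the generator models (read-level simulation is out
of scope by design).

## Numerical and degenerate-input conventions

- Dates carry month precision; month arithmetic is integer subtraction of
  month indices. The two-digit-year form `MM/YY` is accepted (1950–2049).
- Percentages in summaries are recomputed from numerator/denominator and
  rounded to the nearest integer; nothing is stored pre-rounded.
- A case with a single tumour specimen has no truncal compartment (all
  keys private); an empty somatic set in any specimen empties the truncal
  compartment, by definition of intersection.
- Empty cohorts, empty call tables, header-only files and zero-case
  simulations are legal everywhere and produce empty outputs, not errors.
- Duplicate variant keys within one specimen are collapsed (first
  occurrence) when forming somatic sets.
- Report writing is deterministic (fixed column order, sorted rows);
  re-running the pipeline on identical input is byte-identical.

## Known limitations

- Two gene-level cohort counts printed in the source study's text (APC
  8/14, PIK3CA 1/14) disagree with recounting its own per-case table
  (9/14 and 2/14 by the stated "≥ 2 tumour sites per case" rule); the
  package reports the recomputed values and these two genes are excluded
  from acceptance checks.
- The case-mixed site tally and per-gene de novo frequencies of the full
  cohort require the complete per-sample variant lists, which were never
  deposited; those outputs are validated against brute-force oracles on
  simulated cohorts instead, and the bundled fixture reproduces only the
  rows derivable from the published per-case tables.
- HGVS strings are treated as opaque identity tokens (no transcript-aware
  normalization); multi-allelic VCF records are split at ingest but no
  further normalization (left-alignment, MNV decomposition) is applied.
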