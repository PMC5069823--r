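# End-to-end pipeline and command-line entry points. Per-stage counts are
# logged to stderr as machine-parsable "STAGE <name> key=value ..." lines.

log_stage <- function(stage, ...) {
  kv <- list(...)
  message("STAGE ", stage, " ",
          paste(names(kv), unlist(kv), sep = "=", collapse = " "))
}

#' Pipeline configuration
#'
#' A [filter_config()] plus input/output paths and mode flags.
#'
#' @param manifest Path to the cohort manifest (JSON).
#' @param calls Path to a TSV variant table, or a directory of per-specimen
#'   VCFs named `<specimen_id>.vcf`.
#' @param out_dir Report output directory.
#' @param filter A [filter_config()].
#' @param seed Seed recorded in reports (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(manifest, calls, out_dir = ".",
                            filter = filter_config(), seed = 1L) {
  stopifnot(inherits(filter, "filter_config"))
  structure(list(manifest = manifest, calls = calls, out_dir = out_dir,
                 filter = filter, seed = as.integer(seed)),
            class = "pipeline_config")
}

load_calls_input <- function(path, cohort) {
  if (dir.exists(path)) {
    parts <- lapply(cohort$specimens$specimen_id, function(sid) {
      f <- file.path(path, paste0(sid, ".vcf"))
      if (!file.exists(f)) empty_calls() else read_vcf(f, sid)
    })
    df <- do.call(rbind, lapply(parts, function(p) {
      attr(p, "n_skipped") <- NULL; p
    }))
    rownames(df) <- NULL
    return(df)
  }
  read_variant_table(path)
}

#' Run the full case-matched analysis pipeline
#'
#' Executes filter, germline subtraction, metastasis-timing classification,
#' truncal/private partitioning, de novo derivation, RAS trajectory tracking
#' and all cohort-level reports; writes the report TSVs when `out_dir` is
#' set and returns everything in memory. Re-running on identical inputs and
#' configuration yields byte-identical reports.
#'
#' @param config A [pipeline_config()], or a `crc_cohort` plus `calls` table
#'   for in-memory use.
#' @param calls Optional in-memory call table (when `config` is a cohort).
#' @param write Write report files. Default `TRUE` when paths are given.
#' @return A report bundle: `cohort`, `somatic`, `partitions`, `de_novo`,
#'   `trajectories`, `gene_summary`, `site_tally`, `dn_frequency`,
#'   `treatment`, `summary`, `venn_counts`.
#' @export
run_pipeline <- function(config, calls = NULL, write = NULL) {
  if (inherits(config, "crc_cohort")) {
    coh <- config
    fc <- filter_config()
    out_dir <- NULL
    if (is.null(write)) write <- FALSE
  } else {
    stopifnot(inherits(config, "pipeline_config"))
    fc <- config$filter
    coh <- load_manifest(config$manifest)
    calls <- load_calls_input(config$calls, coh)
    out_dir <- config$out_dir
    if (is.null(write)) write <- TRUE
  }
  stopifnot(is.data.frame(calls))
  coh <- assign_timing(coh)
  log_stage("load", cases = length(case_ids(coh)),
            specimens = nrow(coh$specimens), calls = nrow(calls))

  # filter + germline subtraction, with per-specimen count conservation
  for (sid in coh$specimens$specimen_id) {
    n_in <- sum(calls$specimen_id == sid)
    n_kept <- nrow(filter_calls(calls[calls$specimen_id == sid, ], fc))
    log_stage("filter", specimen = sid, input = n_in, kept = n_kept,
              removed = n_in - n_kept)
  }
  somatic <- somatic_sets(coh, calls, fc)
  somatic_rescue <- somatic_sets(coh, calls, fc,
                                 af_cutoff = fc$rescue_af)
  log_stage("somatic", specimens = length(somatic),
            keys = sum(vapply(somatic, nrow, 0L)))

  partitions <- list(); de_novo <- list(); trajectories <- list()
  for (cid in case_ids(coh)) {
    tsp <- tumour_specimens(coh, cid)
    partitions[[cid]] <- partition_shared(cid, somatic[tsp$specimen_id],
                                          cohort = coh)
    prim_id <- primary_specimen(coh, cid)$specimen_id
    for (sid in tsp$specimen_id[tsp$tissue != "primary"]) {
      de_novo[[sid]] <- derive_de_novo(
        somatic[[sid]], somatic[[prim_id]],
        primary_rescue = somatic_rescue[[prim_id]],
        strict = fc$strict_de_novo)
    }
    trajectories[[cid]] <- track_ras(coh, cid, calls, fc)
  }
  log_stage("casematch", partitions = length(partitions),
            de_novo_lesions = length(de_novo))

  gene_summary <- gene_case_summary(coh, somatic)
  site_tally <- site_mixed_tally(coh, somatic, fc)
  dn_frequency <- de_novo_frequency(coh, de_novo, somatic,
                                    genes = panel_genes())
  treatment <- treatment_report(coh, de_novo, somatic)
  summary <- cohort_summary(coh, trajectories)
  venn_counts <- do.call(rbind, c(list(
    data.frame(case_id = character(0), truncal = integer(0),
               private = integer(0), other_shared = integer(0),
               total = integer(0))),
    lapply(partitions, function(p) data.frame(
      case_id = p$case_id, truncal = length(p$truncal),
      private = sum(lengths(p$private)),
      other_shared = length(p$other_shared),
      total = length(p$union)))))
  rownames(venn_counts) <- NULL

  ras_report <- do.call(rbind, c(list(
    data.frame(case_id = character(0), key = character(0),
               gene = character(0), hgvs_p = character(0),
               specimen_id = character(0), tissue = character(0),
               timing = character(0), af_percent = numeric(0),
               detection = character(0))),
    lapply(trajectories, function(t) t$table)))
  rownames(ras_report) <- NULL

  bundle <- list(cohort = coh, somatic = somatic, partitions = partitions,
                 de_novo = de_novo, trajectories = trajectories,
                 gene_summary = gene_summary, site_tally = site_tally,
                 dn_frequency = dn_frequency, treatment = treatment,
                 summary = summary, venn_counts = venn_counts,
                 ras_report = ras_report, filter = fc)
  if (isTRUE(write) && !is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(gene_summary$rows,
                 file.path(out_dir, "gene_case_summary.tsv"), fc)
    write_report(gene_summary$gene_counts,
                 file.path(out_dir, "gene_counts.tsv"), fc)
    write_report(site_tally, file.path(out_dir, "site_mixed_tally.tsv"), fc)
    write_report(dn_frequency,
                 file.path(out_dir, "de_novo_frequency.tsv"), fc)
    write_report(treatment, file.path(out_dir, "treatment_report.tsv"), fc)
    write_report(ras_report, file.path(out_dir, "ras_trajectory.tsv"), fc)
    write_report(venn_counts, file.path(out_dir, "venn_counts.tsv"), fc)
    write_report(data.frame(metric = names(summary),
                            value = unlist(summary)),
                 file.path(out_dir, "cohort_summary.tsv"), fc)
  }
  log_stage("done", reports = 8L)
  bundle
}

# ---- command-line interface ----------------------------------------------

.cli_usage <- "usage: crctrace <command> [options]

commands:
  simulate   --out DIR [--seed N] [--cases N]
  filter     --calls FILE --out FILE [--af-cutoff X] [--pop-af-cutoff X]
             [--keep-synonymous] [--rescue-af X]
  somatic    --manifest FILE --calls PATH --out FILE [filter options]
  denovo     --manifest FILE --calls PATH --out FILE [--strict]
  ras-status --manifest FILE --calls PATH --out FILE [filter options]
  summarize  --manifest FILE --calls PATH --out DIR [filter options]
  run        --manifest FILE --calls PATH --out DIR [filter options]
"

.cli_opt <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  if (i[1] == length(args)) stop("missing value for ", flag, call. = FALSE)
  args[i[1] + 1L]
}

.cli_filter <- function(args) {
  filter_config(
    af_cutoff = as.numeric(.cli_opt(args, "--af-cutoff", 10)),
    pop_af_cutoff = as.numeric(.cli_opt(args, "--pop-af-cutoff", 0.05)),
    exclude_synonymous = !("--keep-synonymous" %in% args),
    rescue_af = as.numeric(.cli_opt(args, "--rescue-af", 1)),
    strict_de_novo = "--strict" %in% args)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `filter`, `somatic`, `denovo`,
#' `ras-status`, `summarize` and `run`; see `inst/cli/crctrace`. Filter
#' flags mirror the [filter_config()] field names.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { cat(.cli_usage); return(invisible(1L)) }
  cmd <- args[1L]; rest <- args[-1L]
  known <- c("simulate", "filter", "somatic", "denovo", "ras-status",
             "summarize", "run")
  if (!cmd %in% known) { cat(.cli_usage); return(invisible(1L)) }
  fc <- .cli_filter(rest)
  out <- .cli_opt(rest, "--out")
  if (is.null(out)) stop("--out is required", call. = FALSE)
  run_bundle <- function() {
    cfg <- pipeline_config(.cli_opt(rest, "--manifest"),
                           .cli_opt(rest, "--calls"),
                           out_dir = out, filter = fc)
    run_pipeline(cfg, write = cmd %in% c("run", "summarize"))
  }
  switch(cmd,
    simulate = {
      sim <- simulate_cohort(sim_params(
        n_cases = as.integer(.cli_opt(rest, "--cases", 14)),
        seed = as.integer(.cli_opt(rest, "--seed", 1))))
      emit_files(sim, out)
    },
    filter = {
      calls <- read_variant_table(.cli_opt(rest, "--calls"))
      kept <- filter_calls(calls, fc)
      log_stage("filter", input = nrow(calls), kept = nrow(kept),
                removed = nrow(calls) - nrow(kept))
      write_variant_table(kept, out)
    },
    somatic = {
      b <- run_bundle()
      write_report(do.call(rbind, lapply(names(b$somatic), function(s) {
        df <- b$somatic[[s]]
        if (nrow(df)) df[, c("specimen_id", "gene", "hgvs_p", "key",
                             "af_percent")] else NULL
      })), out, fc)
    },
    denovo = {
      b <- run_bundle()
      rows <- do.call(rbind, lapply(names(b$de_novo), function(s)
        if (length(b$de_novo[[s]]))
          data.frame(specimen_id = s, key = b$de_novo[[s]]) else NULL))
      write_report(rows %||% data.frame(specimen_id = character(0),
                                        key = character(0)), out, fc)
    },
    `ras-status` = {
      b <- run_bundle()
      write_report(b$ras_report, out, fc)
    },
    summarize = invisible(run_bundle()),
    run = invisible(run_bundle()),
    { cat(.cli_usage); return(invisible(1L)) })
  invisible(0L)
}
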