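#' Read a pipeline configuration file
#'
#' YAML file with paths and parameters for the staged pipeline. Recognised
#' keys: `genome`, `vcf`, `variants_tsv`, `gtf`, `expression`, `copy_number`,
#' `dependency`, `score_table`, `breakpoints`, `output_dir`, `sample_id`,
#' `scoring_mode` (`table_import` or `builtin`), `max_mismatches`, `weights`
#' (named list overriding [ranking_weights()] arguments), `thresholds`
#' (overriding [report_thresholds()]), `seed`. Unknown keys are rejected so
#' typos fail loudly.
#'
#' @param path YAML config path.
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("genome", "vcf", "variants_tsv", "gtf", "expression",
             "copy_number", "dependency", "score_table", "breakpoints",
             "output_dir", "sample_id", "scoring_mode", "max_mismatches",
             "weights", "thresholds", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0L) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg$output_dir <- cfg$output_dir %||% "."
  cfg$scoring_mode <- cfg$scoring_mode %||% "table_import"
  cfg$sample_id <- cfg$sample_id %||% "sample"
  structure(cfg, class = "pipeline_config")
}

require_path <- function(cfg, key) {
  p <- cfg[[key]]
  if (is.null(p)) stop("config is missing required path: ", key)
  if (!file.exists(p)) stop("missing input file for '", key, "': ", p)
  p
}

cfg_weights <- function(cfg) do.call(ranking_weights, as.list(cfg$weights %||% list()))
cfg_thresholds <- function(cfg) do.call(report_thresholds, as.list(cfg$thresholds %||% list()))

load_cfg_variants <- function(cfg, genome) {
  if (!is.null(cfg$vcf)) {
    load_somatic_variants(require_path(cfg, "vcf"), cfg$sample_id, genome)
  } else {
    load_variants_tsv(require_path(cfg, "variants_tsv"), genome)
  }
}

#' Pipeline stages
#'
#' Each stage reads its inputs (the genome plus either primary input files or
#' the previous stage's TSV in `output_dir`), writes its own headered TSV and
#' returns the result invisibly. `run_all()` chains
#' discover -> annotate -> rank (and breakpoints when configured).
#'
#' @param config a `pipeline_config` from [read_pipeline_config()].
#' @return the stage's table (invisibly for the file-writing stages).
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
run_discover <- function(config) {
  genome <- load_reference(require_path(config, "genome"))
  genes <- if (!is.null(config$gtf)) load_gene_models(require_path(config, "gtf"), genome)
  variants <- load_cfg_variants(config, genome)
  cand <- discover_sample(variants, genome, genes)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cand, file.path(config$output_dir, "candidates.tsv"))
  cnt <- attr(cand, "counters")
  message(sprintf("discover: %d variants -> %d candidates (%d variants yielding)",
                  cnt[["n_variants"]], cnt[["n_candidates"]], cnt[["n_yielding"]]))
  invisible(cand)
}

#' @rdname pipeline_stages
#' @export
run_annotate <- function(config) {
  cand_path <- file.path(config$output_dir, "candidates.tsv")
  if (!file.exists(cand_path)) stop("missing input file: ", cand_path,
                                    " (run the discover stage first)")
  cand <- utils::read.delim(cand_path, stringsAsFactors = FALSE)
  genome <- load_reference(require_path(config, "genome"))
  genes <- if (!is.null(config$gtf)) load_gene_models(require_path(config, "gtf"), genome)
  expr <- if (!is.null(config$expression)) {
    load_feature_table(require_path(config, "expression"), "expression")
  }
  cn <- if (!is.null(config$copy_number)) {
    load_feature_table(require_path(config, "copy_number"), "copy_number")
  }
  dep <- if (!is.null(config$dependency)) {
    load_feature_table(require_path(config, "dependency"), "dependency")
  }
  st <- NULL
  if (identical(config$scoring_mode, "table_import")) {
    st <- load_score_table(require_path(config, "score_table"))
    genome_for_scores <- NULL
  } else {
    genome_for_scores <- genome
  }
  ann <- annotate_candidates(cand, genes, expr, cn, dep,
                             score_table = st, genome = genome_for_scores)
  write_tsv(ann, file.path(config$output_dir, "annotated.tsv"))
  invisible(ann)
}

#' @rdname pipeline_stages
#' @export
run_rank <- function(config) {
  ann_path <- file.path(config$output_dir, "annotated.tsv")
  if (!file.exists(ann_path)) stop("missing input file: ", ann_path,
                                   " (run the annotate stage first)")
  ann <- utils::read.delim(ann_path, stringsAsFactors = FALSE)
  if (nrow(ann) == 0L) stop("no candidates")
  ranked <- rank_candidates(ann, cfg_weights(config))
  write_tsv(ranked, file.path(config$output_dir, "ranked.tsv"))
  report <- flag_sample(ranked, cfg_thresholds(config))
  utils::capture.output(print(report),
                        file = file.path(config$output_dir, "sample_report.txt"))
  invisible(ranked)
}

#' @rdname pipeline_stages
#' @export
run_breakpoints <- function(config) {
  genome <- load_reference(require_path(config, "genome"))
  bkps <- read_breakpoints(require_path(config, "breakpoints"))
  res <- analyze_cohort_breakpoints(bkps, genome)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(res$candidates, file.path(config$output_dir, "junction_candidates.tsv"))
  write_tsv(res$per_sample, file.path(config$output_dir, "junction_per_sample.tsv"))
  invisible(res)
}

#' @rdname pipeline_stages
#' @param candidate_tables named list (sample -> candidate data.frame) when
#'   running recurrence in memory; by default the stage reads
#'   `candidates.tsv` and splits it by `sample_id`.
#' @export
run_recur <- function(config, candidate_tables = NULL) {
  if (is.null(candidate_tables)) {
    cand_path <- file.path(config$output_dir, "candidates.tsv")
    if (!file.exists(cand_path)) stop("missing input file: ", cand_path)
    cand <- utils::read.delim(cand_path, stringsAsFactors = FALSE)
    candidate_tables <- split(cand, cand$sample_id)
  }
  keys <- lapply(candidate_tables, site_key)
  summary <- recurrence(keys)
  hist_df <- data.frame(patients_per_site = names(summary$histogram),
                        n_sites = unname(summary$histogram))
  write_tsv(hist_df, file.path(config$output_dir, "recurrence_histogram.tsv"))
  invisible(summary)
}

#' @rdname pipeline_stages
#' @param spec a [fixture_spec()].
#' @param dir output directory for the synthetic bundle.
#' @export
run_simulate <- function(spec = fixture_spec(), dir = "fixture") {
  generate_fixture(spec, dir)
}

#' @rdname pipeline_stages
#' @export
run_all <- function(config) {
  run_discover(config)
  run_annotate(config)
  ranked <- run_rank(config)
  if (!is.null(config$breakpoints)) run_breakpoints(config)
  invisible(ranked)
}
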