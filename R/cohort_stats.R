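#' Canonical identity of a candidate site across samples
#'
#' Variant-derived PAM candidates are keyed genomically by
#' `(contig, gg_start, strand)`; breakpoint-derived candidates are keyed by
#' `(motif, gRNA sequence)` because junction coordinates differ across
#' patients for what is biologically the same target. Identical sites in
#' different samples therefore produce equal keys.
#'
#' @param candidates candidate data.frame; variant candidates need columns
#'   `contig`, `gg_start`, `strand`; breakpoint candidates need `motif`,
#'   `grna`.
#' @return character vector of keys, one per row.
#' @export
site_key <- function(candidates) {
  if (all(c("motif", "grna") %in% names(candidates))) {
    paste(candidates$motif, candidates$grna, sep = "|")
  } else if (all(c("contig", "gg_start", "strand") %in% names(candidates))) {
    paste(candidates$contig, candidates$gg_start, candidates$strand, sep = "|")
  } else {
    stop("candidates lack both genomic and sequence key columns")
  }
}

#' Per-sample discovery yield
#'
#' Variant count, candidate count, and the fraction of variants that yielded
#' at least one novel PAM (missing when the sample has no variants).
#'
#' @param variants variant data.frame for one sample.
#' @param candidates candidate data.frame from [discover_sample()] for the
#'   same sample (its `counters` attribute supplies the yielding-variant
#'   count).
#' @return one-row data.frame with `n_variants`, `n_yielding`,
#'   `n_candidates`, `fraction_yielding`.
#' @export
sample_yield <- function(variants, candidates) {
  n_var <- nrow(variants)
  cnt <- attr(candidates, "counters")
  n_yield <- if (!is.null(cnt)) unname(cnt[["n_yielding"]]) else NA_integer_
  data.frame(
    n_variants = n_var,
    n_yielding = n_yield,
    n_candidates = nrow(candidates),
    fraction_yielding = if (n_var > 0L) n_yield / n_var else NA_real_)
}

#' Cohort-level yield summary
#'
#' @param yields data.frame of per-sample rows from [sample_yield()].
#' @return list with medians of variant counts, candidate counts and
#'   yield fractions across samples.
#' @export
cohort_yield <- function(yields) {
  list(median_variants = stats::median(yields$n_variants),
       median_candidates = stats::median(yields$n_candidates),
       median_fraction = stats::median(yields$fraction_yielding, na.rm = TRUE))
}

#' Cross-patient recurrence of candidate sites
#'
#' Counts, for every canonical site, the number of distinct samples carrying
#' it (its multiplicity). A site-occurrence is one (site, sample) pair; the
#' recurrence rate is the fraction of occurrences belonging to sites seen in
#' two or more samples.
#'
#' @param per_sample_sites named list: one character vector of site keys per
#'   sample (duplicates within a sample are collapsed).
#' @return object of class `recurrence_summary`: list with
#'   `total_occurrences`, `histogram` (multiplicity -> number of sites),
#'   `recurrent_occurrences`, `recurrence_rate`.
#' @export
recurrence <- function(per_sample_sites) {
  if (length(per_sample_sites) < 2L) {
    stop("recurrence needs at least two samples")
  }
  sets <- lapply(per_sample_sites, unique)
  occ <- table(unlist(sets, use.names = FALSE))
  histogram <- table(as.integer(occ))
  recurrence_from_histogram(
    setNames(as.integer(histogram), names(histogram)))
}

#' Recurrence summary from a multiplicity histogram
#'
#' Builds the summary directly from a `multiplicity -> site count` histogram
#' (e.g. 50 sites in two patients, 4 in three, 2 in four), optionally with a
#' separately known total occurrence count when the histogram omits
#' singletons.
#'
#' @param histogram named integer vector: names are multiplicities (patients
#'   per site), values are site counts.
#' @param total_occurrences total (site, sample) occurrences in the cohort;
#'   by default computed from the histogram itself.
#' @return a `recurrence_summary`.
#' @export
recurrence_from_histogram <- function(histogram, total_occurrences = NULL) {
  mult <- as.integer(names(histogram))
  cnt <- as.integer(histogram)
  if (any(is.na(mult)) || any(mult < 1L) || any(cnt < 0L)) {
    stop("histogram names must be multiplicities >= 1, values counts >= 0")
  }
  if (is.null(total_occurrences)) total_occurrences <- sum(mult * cnt)
  rec <- sum(mult[mult >= 2L] * cnt[mult >= 2L])
  if (rec > total_occurrences) {
    stop("recurrent occurrences exceed the stated total")
  }
  structure(list(total_occurrences = as.integer(total_occurrences),
                 histogram = setNames(cnt, mult),
                 recurrent_occurrences = as.integer(rec),
                 recurrence_rate = if (total_occurrences > 0L) {
                   rec / total_occurrences
                 } else NA_real_),
            class = "recurrence_summary")
}

#' @export
print.recurrence_summary <- function(x, ...) {
  cat("Cohort recurrence summary\n")
  cat(sprintf("  site-occurrences: %d\n", x$total_occurrences))
  for (m in names(x$histogram)) {
    if (x$histogram[[m]] > 0L && as.integer(m) >= 2L) {
      cat(sprintf("  sites in %s patients: %d\n", m, x$histogram[[m]]))
    }
  }
  cat(sprintf("  recurrent occurrences: %d\n", x$recurrent_occurrences))
  cat(sprintf("  recurrence rate: %.1f%%\n", 100 * x$recurrence_rate))
  invisible(x)
}
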