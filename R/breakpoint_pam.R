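#' Junction coordinate helpers
#'
#' A junction window covers positions -30..-1 (left flank) and +1..+30 (right
#' flank) relative to the breakpoint, which lies between -1 and +1; there is
#' no position 0. These helpers convert between junction positions and
#' 1-based indices into the joined 60-mer, and are mutually inverse.
#'
#' @param k junction position(s) in -30..-1 or +1..+30.
#' @param i 1-based index (indices) into the joined 60-nt sequence.
#' @return converted integer position(s).
#' @export
jpos_to_index <- function(k) {
  stopifnot(all(k != 0L), all(k >= -30L), all(k <= 30L))
  ifelse(k < 0L, k + 31L, k + 30L)
}

#' @rdname jpos_to_index
#' @export
index_to_jpos <- function(i) {
  stopifnot(all(i >= 1L), all(i <= 60L))
  ifelse(i <= 30L, i - 31L, i - 30L)
}

# fetch a plus-strand slice, N-padding anything outside the contig
fetch_padded <- function(genome, contig, start, end) {
  len <- contig_length(genome, contig)
  s <- max(0L, start); e <- min(len, end)
  core <- if (e > s) fetch_seq(genome, contig, s, e) else ""
  paste0(strrep("N", s - start), core, strrep("N", end - e))
}

#' Build the 60-nt window across a rearrangement junction
#'
#' Extracts the 30 nt of retained sequence adjacent to the junction on each
#' side, strand-corrected according to the reported breakpoint orientation so
#' that the joined 60-mer reads 5' to 3' across the junction as it does on
#' the derivative chromosome. Orientation semantics: for the left side,
#' `"+"` retains the reference-upstream segment ending at `pos1` (1-based,
#' last retained base) and `"-"` retains the downstream segment starting at
#' `pos1`, reverse-complemented; for the right side, `"+"` retains the
#' downstream segment starting at `pos2` and `"-"` retains the upstream
#' segment ending at `pos2`, reverse-complemented. Flanks running off a
#' contig end are N-padded with a warning. The native reference continuation
#' past each flank (the base that follows the left flank, and the base that
#' precedes the right flank, in the unrearranged genome, junction-oriented)
#' is recorded for the novelty check.
#'
#' @param genome a `ref_genome`.
#' @param contig1,pos1,strand1 left anchor (1-based position).
#' @param contig2,pos2,strand2 right anchor (1-based position).
#' @return object of class `junction_window`: list with `left`, `right`
#'   (30-nt strings), `joined` (60 nt), `native_after_left`,
#'   `native_before_right` (single bases, `"N"` when off-contig).
#' @export
build_junction_window <- function(genome, contig1, pos1, strand1,
                                  contig2, pos2, strand2) {
  flank <- 30L
  if (strand1 == "+") {
    p <- as.integer(pos1)                       # 1-based last retained base
    left <- fetch_padded(genome, contig1, p - flank, p)
    after <- fetch_padded(genome, contig1, p, p + 1L)
  } else {
    p0 <- as.integer(pos1) - 1L                 # 1-based first retained base
    left <- revcomp(fetch_padded(genome, contig1, p0, p0 + flank))
    after <- revcomp(fetch_padded(genome, contig1, p0 - 1L, p0))
  }
  if (strand2 == "+") {
    p0 <- as.integer(pos2) - 1L                 # 1-based first retained base
    right <- fetch_padded(genome, contig2, p0, p0 + flank)
    before <- fetch_padded(genome, contig2, p0 - 1L, p0)
  } else {
    p <- as.integer(pos2)                       # 1-based last retained base
    right <- revcomp(fetch_padded(genome, contig2, p - flank, p))
    before <- revcomp(fetch_padded(genome, contig2, p, p + 1L))
  }
  if (grepl("N", left, fixed = TRUE) || grepl("N", right, fixed = TRUE)) {
    warning("junction window N-padded near a contig end")
  }
  structure(list(left = left, right = right, joined = paste0(left, right),
                 native_after_left = after, native_before_right = before),
            class = "junction_window")
}

#' @export
print.junction_window <- function(x, ...) {
  cat("junction window (-30..-1 | +1..+30):\n  ", x$left, " | ", x$right,
      "\n  native continuation after left flank: ", x$native_after_left,
      "; native base before right flank: ", x$native_before_right, "\n",
      sep = "")
  invisible(x)
}

bkp_candidate_frame <- function() {
  data.frame(candidate_class = character(), motif = character(),
             grna = character(), n_jpos = integer(),
             left_overlap = integer(), right_overlap = integer(),
             is_novel = logical(), stringsAsFactors = FALSE)
}

#' Is a junction-created PAM novel?
#'
#' A GG (or CC) straddling the junction is novel only if juxtaposition
#' created it: the partner base must be absent at the same offset in both
#' wild-type contexts, i.e. the reference base that natively follows the left
#' flank and the one that natively precedes the right flank are both not G
#' (for GG; symmetric with C for CC).
#'
#' @param window a `junction_window`.
#' @param motif `"NGG"` or `"CCN"`.
#' @return logical scalar.
#' @export
is_junction_pam_novel <- function(window, motif) {
  b <- if (motif == "NGG") "G" else "C"
  window$native_after_left != b && window$native_before_right != b
}

#' Detect a PAM created at the junction itself
#'
#' Inspects the bases at positions -1 and +1: GG there is an NGG PAM whose
#' guide is the 20 nt at -22..-3 (the PAM's N sits at -2); CC there is the
#' reverse-complement CCN motif whose guide is the reverse complement of
#' +3..+22. Only candidates passing [is_junction_pam_novel()] are emitted;
#' windows with N at the junction, or guides containing N, yield nothing.
#'
#' @param window a `junction_window`.
#' @return data.frame of junction-created candidates (0 or 1 row per motif).
#' @export
detect_junction_pam <- function(window) {
  j <- window$joined
  b1 <- substr(j, 30L, 30L); b2 <- substr(j, 31L, 31L)
  out <- list()
  if (b1 == "G" && b2 == "G" && is_junction_pam_novel(window, "NGG")) {
    grna <- substr(j, jpos_to_index(-22L), jpos_to_index(-3L))
    if (!grepl("N", grna, fixed = TRUE)) {
      out[[length(out) + 1L]] <- data.frame(
        candidate_class = "junction_pam", motif = "NGG", grna = grna,
        n_jpos = -2L, left_overlap = 20L, right_overlap = 0L,
        is_novel = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (b1 == "C" && b2 == "C" && is_junction_pam_novel(window, "CCN")) {
    grna <- revcomp(substr(j, jpos_to_index(3L), jpos_to_index(22L)))
    if (!grepl("N", grna, fixed = TRUE)) {
      out[[length(out) + 1L]] <- data.frame(
        candidate_class = "junction_pam", motif = "CCN", grna = grna,
        n_jpos = 2L, left_overlap = 0L, right_overlap = 20L,
        is_novel = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else bkp_candidate_frame()
}

#' Detect guides spanning the junction
#'
#' Scans the joined 60-mer for NGG motifs whose N sits at junction position
#' +6..+16 and CCN motifs whose first C sits at -18..-8; the guide is the
#' 20 nt 5' of the PAM on the respective strand. Every emitted guide overlaps
#' both sides of the junction by at least 4 nt (breakpoint specificity is
#' carried by the dual-side overlap). Guides containing N are dropped.
#'
#' @param window a `junction_window`.
#' @param min_overlap minimum nt of guide on each side of the junction
#'   (default 4).
#' @return data.frame of spanning-guide candidates.
#' @export
detect_spanning_guides <- function(window, min_overlap = 4L) {
  j <- window$joined
  out <- list()
  for (k in 6:16) {                      # NGG, N at +k
    i <- jpos_to_index(k)
    if (i + 2L > 60L) next
    if (substr(j, i + 1L, i + 2L) != "GG") next
    grna <- substr(j, i - 20L, i - 1L)
    lo <- 21L - k; ro <- k - 1L
    if (lo < min_overlap || ro < min_overlap) next
    if (grepl("N", grna, fixed = TRUE) ||
        substr(j, i, i) == "N") next
    out[[length(out) + 1L]] <- data.frame(
      candidate_class = "spanning_grna", motif = "NGG", grna = grna,
      n_jpos = k, left_overlap = lo, right_overlap = ro,
      is_novel = TRUE, stringsAsFactors = FALSE)
  }
  for (k in -18:-8) {                    # CCN, first C at +k
    i <- jpos_to_index(k)
    if (substr(j, i, i + 1L) != "CC") next
    grna <- revcomp(substr(j, i + 3L, i + 22L))
    lo <- 28L - i; ro <- 20L - lo
    if (lo < min_overlap || ro < min_overlap) next
    if (grepl("N", grna, fixed = TRUE) ||
        substr(j, i + 2L, i + 2L) == "N") next
    out[[length(out) + 1L]] <- data.frame(
      candidate_class = "spanning_grna", motif = "CCN", grna = grna,
      n_jpos = k, left_overlap = lo, right_overlap = ro,
      is_novel = TRUE, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else bkp_candidate_frame()
}

#' All novel candidates at one junction
#'
#' Junction-created PAMs plus spanning guides, with spanning guides that
#' duplicate a junction-created candidate (same motif and guide sequence)
#' removed.
#'
#' @param window a `junction_window`.
#' @return combined candidate data.frame.
#' @export
scan_junction <- function(window) {
  jp <- detect_junction_pam(window)
  sp <- detect_spanning_guides(window)
  if (nrow(jp) > 0L && nrow(sp) > 0L) {
    dup <- paste(sp$motif, sp$grna) %in% paste(jp$motif, jp$grna)
    sp <- sp[!dup, , drop = FALSE]
  }
  out <- rbind(jp, sp)
  rownames(out) <- NULL
  out
}

#' Read a breakpoint list
#'
#' Headered TSV with columns `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`,
#' `strand2`, `class` (source class: ecDNA, deletion, insertion, inversion,
#' tandem_duplication, translocation), `sample` (or `sample_id`). Positions
#' are 1-based; orientation semantics as in [build_junction_window()].
#'
#' @param path TSV path.
#' @return data.frame of breakpoints.
#' @export
read_breakpoints <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("sample" %in% names(tab) && !"sample_id" %in% names(tab)) {
    names(tab)[names(tab) == "sample"] <- "sample_id"
  }
  need <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2",
            "class", "sample_id")
  if (!all(need %in% names(tab))) {
    stop("breakpoint TSV must have columns: ", paste(need, collapse = ", "))
  }
  tab$pos1 <- as.integer(tab$pos1); tab$pos2 <- as.integer(tab$pos2)
  tab
}

#' Scan a cohort's breakpoints for novel junction targets
#'
#' Builds the junction window of every breakpoint, collects junction-created
#' PAMs and spanning guides, and tabulates per-sample and per-source-class
#' counts with cohort medians.
#'
#' @param breakpoints data.frame from [read_breakpoints()].
#' @param genome a `ref_genome`.
#' @return list with `candidates` (full annotated table), `per_sample`
#'   (candidate and breakpoint counts by sample), `per_class` (counts by
#'   source class), `median_candidates_per_sample`,
#'   `median_breakpoints_per_sample`.
#' @export
analyze_cohort_breakpoints <- function(breakpoints, genome) {
  rows <- list()
  for (i in seq_len(nrow(breakpoints))) {
    b <- breakpoints[i, ]
    w <- suppressWarnings(build_junction_window(
      genome, b$chrom1, b$pos1, b$strand1, b$chrom2, b$pos2, b$strand2))
    cand <- scan_junction(w)
    if (nrow(cand) == 0L) next
    meta <- data.frame(
      sample_id = b$sample_id, source_class = b$class,
      chrom1 = b$chrom1, pos1 = b$pos1, strand1 = b$strand1,
      chrom2 = b$chrom2, pos2 = b$pos2, strand2 = b$strand2,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- cbind(meta[rep(1L, nrow(cand)), , drop = FALSE],
                                       cand)
  }
  cands <- if (length(rows)) do.call(rbind, rows) else {
    cbind(data.frame(sample_id = character(), source_class = character(),
                     chrom1 = character(), pos1 = integer(),
                     strand1 = character(), chrom2 = character(),
                     pos2 = integer(), strand2 = character(),
                     stringsAsFactors = FALSE),
          bkp_candidate_frame())
  }
  rownames(cands) <- NULL
  samples <- unique(breakpoints$sample_id)
  per_sample <- data.frame(
    sample_id = samples,
    n_breakpoints = vapply(samples, function(s) {
      sum(breakpoints$sample_id == s)
    }, integer(1)),
    n_candidates = vapply(samples, function(s) {
      sum(cands$sample_id == s)
    }, integer(1)),
    stringsAsFactors = FALSE)
  per_class <- if (nrow(cands) > 0L) {
    as.data.frame(table(source_class = cands$source_class,
                        candidate_class = cands$candidate_class),
                  responseName = "n", stringsAsFactors = FALSE)
  } else {
    data.frame(source_class = character(), candidate_class = character(),
               n = integer(), stringsAsFactors = FALSE)
  }
  list(candidates = cands, per_sample = per_sample, per_class = per_class,
       median_candidates_per_sample = stats::median(per_sample$n_candidates),
       median_breakpoints_per_sample = stats::median(per_sample$n_breakpoints))
}
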