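#' Is a dinucleotide a novel PAM anchor?
#'
#' A plus-strand candidate is novel when the reference dinucleotide at the GG
#' interval is not already GG; a minus-strand candidate when it is not already
#' CC. Every emitted candidate re-verifies novelty through this check.
#'
#' @param genome a `ref_genome`.
#' @param contig contig name.
#' @param gg_start 0-based start of the 2-bp dinucleotide interval.
#' @param strand `"+"` (NGG read on plus) or `"-"` (CC on plus, NGG on minus).
#' @return logical scalar.
#' @export
is_novel_pam <- function(genome, contig, gg_start, strand) {
  din <- fetch_seq(genome, contig, gg_start, gg_start + 2L)
  if (strand == "+") din != "GG" else din != "CC"
}

# empty candidate table with the canonical column set
candidate_frame <- function() {
  data.frame(sample_id = character(), contig = character(),
             variant_pos = integer(), ref = character(), alt = character(),
             strand = character(), gg_start = integer(), n_pos = integer(),
             pam_3mer = character(), protospacer = character(),
             gene_id = character(), indel_derived = logical(),
             is_novel = logical(), stringsAsFactors = FALSE)
}

# assemble one candidate row; returns NULL if the protospacer window does not
# fit inside the contig (callers count these drops)
make_snv_candidate <- function(variant, genome, strand, gg_start) {
  ctg <- variant$contig
  len <- contig_length(genome, ctg)
  p0 <- vcf_to_internal(variant$pos)
  if (strand == "+") {
    # NGG on plus: N immediately 5' of the GG; protospacer 20 nt 5' of the N
    n_pos <- gg_start - 1L
    if (n_pos - 20L < 0L || gg_start + 2L > len) return(NULL)
    proto <- fetch_seq(genome, ctg, n_pos - 20L, n_pos)
    pam <- paste0(fetch_seq(genome, ctg, n_pos, n_pos + 1L),
                  apply_snv(fetch_seq(genome, ctg, gg_start, gg_start + 2L),
                            gg_start, p0, variant$alt))
  } else {
    # CC on plus read as NGG on minus: N at plus position gg_start + 2
    n_pos <- gg_start + 2L
    if (n_pos + 21L > len || gg_start < 0L) return(NULL)
    proto <- fetch_seq(genome, ctg, n_pos + 1L, n_pos + 21L, strand = "-")
    plus3 <- apply_snv(fetch_seq(genome, ctg, gg_start, gg_start + 3L),
                       gg_start, p0, variant$alt)
    pam <- revcomp(plus3)
  }
  data.frame(sample_id = variant$sample_id, contig = ctg,
             variant_pos = variant$pos, ref = variant$ref, alt = variant$alt,
             strand = strand, gg_start = gg_start, n_pos = n_pos,
             pam_3mer = pam, protospacer = proto,
             gene_id = NA_character_, indel_derived = FALSE, is_novel = TRUE,
             stringsAsFactors = FALSE)
}

# substitute the alt base into a plus-strand window fetched at `win_start`
apply_snv <- function(win, win_start, p0, alt) {
  off <- p0 - win_start
  if (off >= 0 && off < nchar(win)) substr(win, off + 1L, off + 1L) <- alt
  win
}

#' Scan one SNV for novel PAM creation
#'
#' Implements the adjacency rule at the heart of the pipeline: an SNV creates
#' a novel plus-strand PAM when its alternate allele is G and the reference
#' carries a G immediately 5' or 3' of it (a new GG dinucleotide), and a novel
#' minus-strand PAM when the alternate allele is C next to an existing C (a
#' new CC, read as NGG on the minus strand). Each qualifying dinucleotide
#' yields one candidate, so a G landing between two reference Gs emits two.
#' The created base always sits inside the PAM, never inside the protospacer,
#' so SNV-derived protospacers are pure reference sequence.
#'
#' @param variant one-row data.frame (or list) with fields `contig`, `pos`
#'   (1-based), `ref`, `alt`, `vtype = "SNV"`, `sample_id`.
#' @param genome a `ref_genome`.
#' @return data.frame of candidates (possibly empty) in the canonical
#'   candidate-table layout; drops for insufficient flank are recorded in the
#'   `n_dropped_flank` attribute.
#' @export
scan_snv_for_novel_pams <- function(variant, genome) {
  if (variant$vtype != "SNV") stop("scan_snv_for_novel_pams requires an SNV")
  ctg <- variant$contig
  len <- contig_length(genome, ctg)
  p0 <- vcf_to_internal(variant$pos)
  alt <- variant$alt
  out <- list(); dropped <- 0L

  neighbours <- function(base) {
    hits <- integer(0)
    if (p0 - 1L >= 0L &&
        fetch_seq(genome, ctg, p0 - 1L, p0) == base) hits <- c(hits, p0 - 1L)
    if (p0 + 1L < len &&
        fetch_seq(genome, ctg, p0 + 1L, p0 + 2L) == base) hits <- c(hits, p0)
    hits  # each value = gg_start of a dinucleotide containing the new base
  }

  gg_starts <- character(0)
  if (alt == "G") {
    for (g in neighbours("G")) {
      if (!is_novel_pam(genome, ctg, g, "+")) next  # cannot occur: ref != alt
      cand <- make_snv_candidate(variant, genome, "+", g)
      if (is.null(cand)) dropped <- dropped + 1L else out[[length(out) + 1L]] <- cand
    }
  } else if (alt == "C") {
    for (g in neighbours("C")) {
      if (!is_novel_pam(genome, ctg, g, "-")) next
      cand <- make_snv_candidate(variant, genome, "-", g)
      if (is.null(cand)) dropped <- dropped + 1L else out[[length(out) + 1L]] <- cand
    }
  }
  res <- if (length(out)) do.call(rbind, out) else candidate_frame()
  attr(res, "n_dropped_flank") <- dropped
  res
}

# map an alt-haplotype window coordinate back to the reference coordinate:
# positions left of the edited region are unchanged, positions right of it are
# shifted by the length difference; inside the edit there is no reference
# image (NA).
map_alt_to_ref <- function(alt_pos, edit_start, edit_end_alt, delta) {
  ifelse(alt_pos < edit_start, alt_pos,
         ifelse(alt_pos >= edit_end_alt, alt_pos - delta, NA_integer_))
}

#' Scan one small indel for novel PAM creation
#'
#' Rebuilds the tumour (alt) haplotype over a window around the edit and
#' rescans it: every GG (plus strand) or CC (minus strand) dinucleotide in the
#' alt window that touches edited bases and is absent from the
#' reference-aligned position is emitted as a candidate, flagged
#' `indel_derived`. Protospacers are read from the alt haplotype.
#'
#' @param variant one-row data.frame with `vtype` INS or DEL (VCF-style
#'   anchored alleles, length change < 300).
#' @param genome a `ref_genome`.
#' @param window_halfwidth half-width of the rescanned window (default 25).
#' @return candidate data.frame; `gg_start`/`n_pos` hold the reference-aligned
#'   coordinate of the leftmost dinucleotide base when one exists (junction
#'   dinucleotides map to the last unshifted base).
#' @export
scan_indel_for_novel_pams <- function(variant, genome, window_halfwidth = 25L) {
  if (!variant$vtype %in% c("INS", "DEL")) {
    stop("scan_indel_for_novel_pams requires an INS or DEL variant")
  }
  ctg <- variant$contig
  len <- contig_length(genome, ctg)
  p0 <- vcf_to_internal(variant$pos)       # anchor base (shared ref/alt)
  ref_a <- variant$ref; alt_a <- variant$alt
  ref_len <- nchar(ref_a); alt_len <- nchar(alt_a)
  delta <- alt_len - ref_len

  win_start <- max(0L, p0 - window_halfwidth)
  win_end <- min(len, p0 + ref_len + window_halfwidth)
  left <- fetch_seq(genome, ctg, win_start, p0)
  right <- fetch_seq(genome, ctg, p0 + ref_len, win_end)
  alt_win <- paste0(left, alt_a, right)
  ref_win <- paste0(left, ref_a, right)

  # edited region within the alt window (0-based, window-local)
  edit_start <- p0 - win_start + 1L        # first base after the anchor
  edit_end_alt <- edit_start + max(alt_len - 1L, 0L)  # half-open, alt coords
  if (variant$vtype == "DEL") edit_end_alt <- edit_start  # deletion: zero alt width

  out <- list()
  n_alt <- nchar(alt_win)
  for (i in 0:(n_alt - 2L)) {
    din <- substr(alt_win, i + 1L, i + 2L)
    if (din != "GG" && din != "CC") next
    # must touch (overlap or be adjacent to) the edited region
    if ((i + 2L) < (edit_start - 1L) || i > edit_end_alt) next
    # reference-aligned position of the dinucleotide start
    r1 <- map_alt_to_ref(i, edit_start, edit_end_alt, delta)
    r2 <- map_alt_to_ref(i + 1L, edit_start, edit_end_alt, delta)
    ref_has <- FALSE
    if (!is.na(r1)) {
      g_ref <- win_start + r1
      if (g_ref + 2L <= len) {
        ref_has <- fetch_seq(genome, ctg, g_ref, g_ref + 2L) == din
      }
    }
    if (ref_has) next
    strand <- if (din == "GG") "+" else "-"
    if (strand == "+") {
      if (i - 21L < 0L) next                     # flank for N + protospacer
      proto <- substr(alt_win, i - 20L, i - 1L)
      pam <- substr(alt_win, i, i + 2L)          # N,G,G (1-based i..i+2)
      n_loc <- i - 1L
    } else {
      if (i + 2L + 21L > n_alt) next
      proto <- revcomp(substr(alt_win, i + 4L, i + 23L))
      pam <- revcomp(substr(alt_win, i + 1L, i + 3L))
      n_loc <- i + 2L
    }
    if (grepl("N", proto, fixed = TRUE)) next
    g_map <- if (!is.na(r1)) r1 else r2 - 1L     # junction GG: last unshifted base
    n_map <- map_alt_to_ref(n_loc, edit_start, edit_end_alt, delta)
    out[[length(out) + 1L]] <- data.frame(
      sample_id = variant$sample_id, contig = ctg,
      variant_pos = variant$pos, ref = ref_a, alt = alt_a,
      strand = strand, gg_start = win_start + g_map,
      n_pos = if (is.na(n_map)) NA_integer_ else win_start + n_map,
      pam_3mer = pam, protospacer = proto,
      gene_id = NA_character_, indel_derived = TRUE, is_novel = TRUE,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else candidate_frame()
  attr(res, "truncated") <- (win_start == 0L || win_end == len) &&
    (p0 - window_halfwidth < 0L || p0 + ref_len + window_halfwidth > len)
  res
}

#' Derive the 20-nt protospacer for a PAM candidate
#'
#' Always the 20 nt immediately 5' of the NGG on the PAM strand: plus-strand
#' candidates read plus-strand bases `[n-20, n)`; minus-strand candidates read
#' the reverse complement of plus-strand bases `(c+2, c+22]` where `c` is the
#' left base of the CC dinucleotide. SNV alternate alleles never overlap the
#' protospacer (the created base is inside the PAM), so the reference and
#' tumour reads are identical for SNV candidates.
#'
#' @param genome a `ref_genome`.
#' @param contig contig name.
#' @param gg_start 0-based start of the GG (plus) / CC (minus) dinucleotide.
#' @param strand `"+"` or `"-"`.
#' @return 20-nt character scalar, or `NA` when the flank does not fit.
#' @export
derive_protospacer <- function(genome, contig, gg_start, strand) {
  len <- contig_length(genome, contig)
  if (strand == "+") {
    n_pos <- gg_start - 1L
    if (n_pos - 20L < 0L) return(NA_character_)
    fetch_seq(genome, contig, n_pos - 20L, n_pos)
  } else {
    if (gg_start + 23L > len) return(NA_character_)
    fetch_seq(genome, contig, gg_start + 3L, gg_start + 23L, strand = "-")
  }
}

#' Discover all novel PAM candidates for one sample
#'
#' Runs the SNV adjacency scan (and the indel rescan when indels are present)
#' over every variant, deduplicates candidates sharing the same PAM
#' dinucleotide `(contig, gg_start, strand)`, and tags each candidate with the
#' gene whose span contains its dinucleotide.
#'
#' @param variants variant data.frame as returned by
#'   [load_somatic_variants()].
#' @param genome a `ref_genome`.
#' @param genes optional gene-model data.frame from [load_gene_models()].
#' @param include_indels scan INS/DEL variants too (default TRUE).
#' @return candidate data.frame; summary counters (total variants, variants
#'   yielding at least one PAM, total candidates, flank drops) in
#'   `attr(, "counters")`; variants sharing a deduplicated site are listed in
#'   `attr(, "provenance")`.
#' @export
discover_sample <- function(variants, genome, genes = NULL, include_indels = TRUE) {
  res <- list(); dropped <- 0L; yielding <- 0L
  if (nrow(variants) > 0L) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      cand <- if (v$vtype == "SNV") {
        scan_snv_for_novel_pams(v, genome)
      } else if (include_indels) {
        scan_indel_for_novel_pams(v, genome)
      } else {
        candidate_frame()
      }
      dropped <- dropped + (attr(cand, "n_dropped_flank") %||% 0L)
      if (nrow(cand) > 0L) {
        yielding <- yielding + 1L
        res[[length(res) + 1L]] <- cand
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else candidate_frame()
  provenance <- NULL
  if (nrow(out) > 0L) {
    key <- paste(out$contig, out$gg_start, out$strand, sep = ":")
    provenance <- stats::aggregate(
      list(variant_pos = out$variant_pos), by = list(site = key),
      FUN = function(p) paste(sort(unique(p)), collapse = ","))
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
    if (!is.null(genes) && nrow(genes) > 0L) {
      out$gene_id <- assign_gene(out, genes)
    }
  }
  attr(out, "counters") <- c(
    n_variants = nrow(variants), n_yielding = yielding,
    n_candidates = nrow(out), n_dropped_flank = dropped)
  attr(out, "provenance") <- provenance
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# gene containing the GG dinucleotide; ties resolved later by annotate_gene
assign_gene <- function(candidates, genes) {
  vapply(seq_len(nrow(candidates)), function(i) {
    g <- candidates$gg_start[i]
    hit <- genes$contig == candidates$contig[i] & genes$start <= g & genes$end >= g + 2L
    if (!any(hit)) NA_character_ else genes$gene_id[which(hit)[1]]
  }, character(1))
}
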