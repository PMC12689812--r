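#' Mismatch penalty models for specificity scoring
#'
#' A penalty model holds (i) a per-mismatch penalty lookup keyed by protospacer
#' position (1-20, PAM-proximal = 20), guide base and off-target base, and
#' (ii) per-PAM-class factors. `load_penalty_model()` reads a published table
#' from TSV (columns `position`, `ref_base`, `obs_base`, `penalty`);
#' `uniform_penalty_model()` builds the flat model used for testing and as the
#' default when no published table is supplied: every mismatch costs
#' `penalty`, a canonical NGG PAM costs nothing and any other PAM halves the
#' hit score.
#'
#' @param path TSV file with columns `position`, `ref_base`, `obs_base`,
#'   `penalty` (all penalties in `[0,1]`).
#' @param pam_penalties named numeric vector of PAM-class factors; names are
#'   PAM patterns such as `"NGG"`, `"NAG"`.
#' @return an object of class `penalty_model`.
#' @export
load_penalty_model <- function(path, pam_penalties = c(NGG = 1, NAG = 0.25)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "ref_base", "obs_base", "penalty")
  if (!all(need %in% names(tab))) {
    stop("penalty model TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$penalty < 0 | tab$penalty > 1)) stop("penalties must lie in [0,1]")
  key <- paste(tab$position, toupper(tab$ref_base), toupper(tab$obs_base), sep = ":")
  structure(list(lookup = setNames(tab$penalty, key),
                 pam_penalties = pam_penalties, uniform = NA_real_),
            class = "penalty_model")
}

#' @rdname load_penalty_model
#' @param penalty the flat per-mismatch penalty (default 0.5).
#' @export
uniform_penalty_model <- function(penalty = 0.5,
                                  pam_penalties = c(NGG = 1, NAG = 0.5)) {
  stopifnot(penalty >= 0, penalty <= 1)
  structure(list(lookup = NULL, pam_penalties = pam_penalties,
                 uniform = penalty),
            class = "penalty_model")
}

#' MIT position weights
#'
#' The published 20-element position-weight vector used by the
#' Hsu-2013-style specificity score, shipped with the package
#' (position 1 = PAM-distal, 20 = PAM-proximal).
#'
#' @return numeric vector of length 20.
#' @export
mit_weights <- function() {
  path <- system.file("extdata", "mit_position_weights.tsv", package = "pamscan")
  tab <- utils::read.delim(path)
  w <- tab$weight[order(tab$position)]
  stopifnot(length(w) == 20L)
  w
}

# penalty lookup for one mismatch
penalty_for <- function(model, position, guide_base, ot_base) {
  if (!is.na(model$uniform)) return(model$uniform)
  key <- paste(position, guide_base, ot_base, sep = ":")
  p <- model$lookup[key]
  if (is.na(p)) stop("no penalty for key (position:guide:off-target) ", key)
  unname(p)
}

# does a 3-mer PAM match a pattern with N wildcards; returns the factor
pam_factor <- function(model, pam) {
  pats <- names(model$pam_penalties)
  for (p in pats) {
    rx <- paste0("^", gsub("N", "[ACGT]", p), "$")
    if (grepl(rx, pam)) return(unname(model$pam_penalties[[p]]))
  }
  0  # a PAM outside every configured class cannot be cleaved
}

# mismatch positions (1..20, PAM-proximal = 20) between guide and site
mismatch_positions <- function(protospacer, site) {
  which(strsplit(protospacer, "")[[1]] != strsplit(site, "")[[1]])
}

#' Per-hit CFD-style similarity score
#'
#' Product of position/identity-dependent penalties over all mismatches,
#' times the PAM-class factor; 1 for a perfect match with canonical PAM.
#'
#' @param protospacer 20-nt guide sequence (5' to 3', PAM-proximal last).
#' @param site 20-nt off-target protospacer-aligned sequence.
#' @param pam the off-target's 3-nt PAM.
#' @param model a `penalty_model`.
#' @return similarity in `[0,1]`.
#' @export
cfd_hit_score <- function(protospacer, site, pam, model = uniform_penalty_model()) {
  mm <- mismatch_positions(protospacer, site)
  s <- pam_factor(model, pam)
  if (length(mm) > 0L) {
    gb <- strsplit(protospacer, "")[[1]][mm]
    ob <- strsplit(site, "")[[1]][mm]
    for (k in seq_along(mm)) s <- s * penalty_for(model, mm[k], gb[k], ob[k])
  }
  s
}

#' Per-hit MIT-style similarity score
#'
#' The Hsu-2013 convention: the product over mismatches of `1 - W[pos]`,
#' times a mean-pairwise-distance term `1 / (((19 - d) / 19) * 4 + 1)` (1 when
#' fewer than two mismatches) and a count term `1 / m^2`.
#'
#' @inheritParams cfd_hit_score
#' @param weights 20-element position-weight vector (default: the shipped
#'   published weights).
#' @return similarity in `[0,1]`.
#' @export
mit_hit_score <- function(protospacer, site, weights = mit_weights()) {
  mm <- mismatch_positions(protospacer, site)
  m <- length(mm)
  if (m == 0L) return(1)
  s1 <- prod(1 - weights[mm])
  s2 <- if (m < 2L) 1 else {
    d <- mean(diff(mm))
    1 / (((19 - d) / 19) * 4 + 1)
  }
  s1 * s2 / m^2
}

#' Aggregate per-hit similarities into a 0-100 specificity score
#'
#' `100 / (1 + sum(s))` over all off-target similarities (the on-target site
#' excluded): 100 means no off-target burden at all, and every added hit
#' strictly lowers the score.
#'
#' @param s numeric vector of per-hit similarities in `[0,1]`.
#' @return specificity score in `(0, 100]`.
#' @export
aggregate_specificity <- function(s) {
  if (length(s) > 0 && (any(s < 0) || any(s > 1))) {
    stop("per-hit similarities must lie in [0,1]")
  }
  100 / (1 + sum(s))
}

#' Enumerate genomic off-target sites of a protospacer
#'
#' Brute-force search over both strands of every contig for 20-nt windows
#' within `max_mismatches` of the protospacer whose 3' flank matches one of
#' the PAM patterns (N = wildcard). The on-target site (if present in the
#' genome) is returned too, flagged by zero mismatches.
#'
#' @param protospacer 20-nt guide sequence.
#' @param genome a `ref_genome`.
#' @param max_mismatches maximum Hamming distance (default 4).
#' @param pam_patterns character vector of 3-nt PAM patterns (default
#'   `c("NGG", "NAG")`).
#' @return data.frame with columns `contig`, `start` (0-based, plus-strand
#'   coordinates of the 20-nt site), `strand`, `site`, `pam`, `mismatches`,
#'   sorted by position.
#' @export
enumerate_offtargets <- function(protospacer, genome, max_mismatches = 4L,
                                 pam_patterns = c("NGG", "NAG")) {
  stopifnot(nchar(protospacer) == 20L)
  pat <- Biostrings::DNAString(protospacer)
  rcpat <- Biostrings::reverseComplement(pat)
  pam_rx <- paste0("^(", paste(gsub("N", "[ACGT]", pam_patterns), collapse = "|"), ")$")
  hits <- list()
  for (ctg in contig_names(genome)) {
    subject <- Biostrings::DNAString(genome$seqs[[ctg]])
    len <- genome$lengths[[ctg]]
    # plus strand: site [s, s+20), PAM [s+20, s+23)
    m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mismatches)
    for (s1 in Biostrings::start(m)) {
      s0 <- s1 - 1L
      if (s0 + 23L > len) next
      pam <- fetch_seq(genome, ctg, s0 + 20L, s0 + 23L)
      if (!grepl(pam_rx, pam)) next
      site <- fetch_seq(genome, ctg, s0, s0 + 20L)
      if (grepl("N", site, fixed = TRUE)) next
      hits[[length(hits) + 1L]] <- data.frame(
        contig = ctg, start = s0, strand = "+", site = site, pam = pam,
        mismatches = length(mismatch_positions(protospacer, site)),
        stringsAsFactors = FALSE)
    }
    # minus strand: plus-strand window [s, s+20) carries revcomp(site);
    # the PAM lies at plus [s-3, s) and reads as NGG on the minus strand
    m <- Biostrings::matchPattern(rcpat, subject, max.mismatch = max_mismatches)
    for (s1 in Biostrings::start(m)) {
      s0 <- s1 - 1L
      if (s0 - 3L < 0L) next
      pam <- fetch_seq(genome, ctg, s0 - 3L, s0, strand = "-")
      if (!grepl(pam_rx, pam)) next
      site <- fetch_seq(genome, ctg, s0, s0 + 20L, strand = "-")
      if (grepl("N", site, fixed = TRUE)) next
      hits[[length(hits) + 1L]] <- data.frame(
        contig = ctg, start = s0, strand = "-", site = site, pam = pam,
        mismatches = length(mismatch_positions(protospacer, site)),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else {
    data.frame(contig = character(), start = integer(), strand = character(),
               site = character(), pam = character(), mismatches = integer(),
               stringsAsFactors = FALSE)
  }
  out <- out[out$mismatches <= max_mismatches, , drop = FALSE]
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-wide CFD and MIT specificity of a guide
#'
#' Enumerates off-targets, scores every hit under both models, removes one
#' on-target occurrence (the first perfect canonical-PAM hit; the intended
#' locus when `on_target` gives its `(contig, start, strand)`), and
#' aggregates to the 0-100 scale.
#'
#' @inheritParams enumerate_offtargets
#' @param cfd_model a `penalty_model` for the CFD-style score.
#' @param mit_w MIT position weights.
#' @param on_target optional list/row with `contig`, `start`, `strand`
#'   identifying the intended site.
#' @return named numeric vector `c(cfd_spec, mit_spec)`, both in `(0, 100]`.
#' @export
specificity_scores <- function(protospacer, genome, max_mismatches = 4L,
                               pam_patterns = c("NGG", "NAG"),
                               cfd_model = uniform_penalty_model(),
                               mit_w = mit_weights(), on_target = NULL) {
  hits <- enumerate_offtargets(protospacer, genome, max_mismatches, pam_patterns)
  if (nrow(hits) > 0L) {
    drop <- if (!is.null(on_target)) {
      which(hits$contig == on_target$contig & hits$start == on_target$start &
              hits$strand == on_target$strand)
    } else {
      which(hits$mismatches == 0L & substr(hits$pam, 2, 3) == "GG")
    }
    if (length(drop) > 0L) hits <- hits[-drop[1], , drop = FALSE]
  }
  if (nrow(hits) == 0L) return(c(cfd_spec = 100, mit_spec = 100))
  s_cfd <- vapply(seq_len(nrow(hits)), function(i) {
    cfd_hit_score(protospacer, hits$site[i], hits$pam[i], cfd_model)
  }, numeric(1))
  s_mit <- vapply(seq_len(nrow(hits)), function(i) {
    mit_hit_score(protospacer, hits$site[i], mit_w)
  }, numeric(1))
  c(cfd_spec = aggregate_specificity(s_cfd),
    mit_spec = aggregate_specificity(s_mit))
}

#' Load a precomputed guide-score table
#'
#' Reads a CRISPOR-style TSV keyed by guide sequence with columns
#' `protospacer`, `cfd_spec`, `mit_spec`, `doench`, `moreno` (all scores
#' 0-100; missing entries allowed). This is the fidelity pathway: scores
#' computed by an external platform are imported rather than recomputed.
#'
#' @param path TSV path.
#' @return data.frame keyed by `protospacer`.
#' @export
load_score_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protospacer", "cfd_spec", "mit_spec", "doench", "moreno")
  if (!all(need %in% names(tab))) {
    stop("score table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$protospacer)) stop("duplicate protospacer in score table")
  for (cc in need[-1]) tab[[cc]] <- suppressWarnings(as.numeric(tab[[cc]]))
  tab
}

#' On-target efficiency scores for a guide
#'
#' `mode = "table_import"` looks the guide up in a precomputed score table
#' (guides absent from the table get missing scores, which the ranking later
#' assigns the lowest rank). `mode = "builtin_surrogate"` computes a
#' deterministic sequence heuristic — a weighted combination of GC content,
#' PAM-proximal GC, guanine enrichment and adenine depletion mapped to 0-100.
#' The surrogate is a documented stand-in so that synthetic pipelines run end
#' to end; it is not a published predictor and is not validation-grade.
#'
#' @param protospacer 20-nt guide sequence.
#' @param mode `"table_import"` or `"builtin_surrogate"`.
#' @param score_table table from [load_score_table()] (table mode).
#' @return named numeric vector `c(doench, moreno)`, each in `[0,100]` or
#'   `NA`.
#' @export
efficiency_scores <- function(protospacer,
                              mode = c("table_import", "builtin_surrogate"),
                              score_table = NULL) {
  mode <- match.arg(mode)
  if (mode == "table_import") {
    if (is.null(score_table)) stop("table_import mode needs a score_table")
    i <- match(protospacer, score_table$protospacer)
    if (is.na(i)) return(c(doench = NA_real_, moreno = NA_real_))
    return(c(doench = score_table$doench[i], moreno = score_table$moreno[i]))
  }
  b <- strsplit(protospacer, "")[[1]]
  gc <- mean(b %in% c("G", "C"))
  gc_prox <- mean(b[11:20] %in% c("G", "C"))
  g_frac <- mean(b == "G")
  a_frac <- mean(b == "A")
  # bell-shaped preference for mid-range GC, bonus for PAM-proximal GC and
  # guanine enrichment, penalty for adenine-rich guides
  doench <- 100 * max(0, min(1, 1 - 2 * abs(gc - 0.55) + 0.2 * (gc_prox - 0.5)))
  moreno <- 100 * max(0, min(1, 0.5 + 0.8 * (g_frac - a_frac) + 0.5 * (gc - 0.5)))
  c(doench = doench, moreno = moreno)
}
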