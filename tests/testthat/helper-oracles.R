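# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: they work by
# regex-scanning mutated windows, exhaustive substring comparison, and naive
# O(n^2) rank counting.

# reverse complement without using the package's helper
oracle_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# all 0-based start positions of a dinucleotide in a string (overlapping)
oracle_din_starts <- function(s, din) {
  m <- gregexpr(paste0("(?=", din, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

# Novel-PAM oracle for one SNV: diff GG/CC dinucleotide start positions
# between the reference window and the mutated window (+-25 bp), then apply
# the same protospacer-flank feasibility rule as the pipeline. Returns a
# character vector of "ggstart:strand" keys.
oracle_snv_keys <- function(contig_seq, contig, pos1, alt) {
  len <- nchar(contig_seq)
  p0 <- pos1 - 1L
  w_s <- max(0L, p0 - 25L); w_e <- min(len, p0 + 26L)
  refw <- substr(contig_seq, w_s + 1L, w_e)
  altw <- refw
  substr(altw, p0 - w_s + 1L, p0 - w_s + 1L) <- alt
  keys <- character(0)
  for (din in c("GG", "CC")) {
    strand <- if (din == "GG") "+" else "-"
    new <- setdiff(oracle_din_starts(altw, din), oracle_din_starts(refw, din))
    for (d in new) {
      g <- w_s + d
      # the created dinucleotide must contain the variant base
      if (p0 < g || p0 > g + 1L) next
      ok <- if (strand == "+") g >= 21L && g + 2L <= len else g + 23L <= len
      if (ok) keys <- c(keys, paste0(g, ":", strand))
    }
  }
  sort(keys)
}

# exhaustive off-target oracle: every 23-mer window on both strands, PAM
# checked by regex, spacer compared base-by-base
oracle_offtargets <- function(protospacer, contig_seq, contig, max_mm = 4L,
                              pams = c("NGG", "NAG")) {
  len <- nchar(contig_seq)
  pam_rx <- paste0("^(", paste(gsub("N", "[ACGT]", pams), collapse = "|"), ")$")
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  rows <- list()
  for (s0 in 0:(len - 23L)) {
    win <- substr(contig_seq, s0 + 1L, s0 + 23L)
    # plus strand: spacer then PAM
    sp <- substr(win, 1L, 20L); pam <- substr(win, 21L, 23L)
    if (grepl(pam_rx, pam) && !grepl("N", sp, fixed = TRUE)) {
      mm <- hamming(sp, protospacer)
      if (mm <= max_mm) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig = contig, start = s0, strand = "+", site = sp, pam = pam,
          mismatches = mm, stringsAsFactors = FALSE)
      }
    }
    # minus strand: PAM then revcomp(spacer) on the plus strand
    rcwin <- oracle_rc(win)
    sp <- substr(rcwin, 1L, 20L); pam <- substr(rcwin, 21L, 23L)
    if (grepl(pam_rx, pam) && !grepl("N", sp, fixed = TRUE)) {
      mm <- hamming(sp, protospacer)
      if (mm <= max_mm) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig = contig, start = s0 + 3L, strand = "-", site = sp, pam = pam,
          mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(contig = character(), start = integer(), strand = character(),
               site = character(), pam = character(), mismatches = integer(),
               stringsAsFactors = FALSE)
  }
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

# naive O(n^2) rank with average ties, missing -> shared rank 1
oracle_rank_feature <- function(v) {
  n <- length(v)
  out <- numeric(n)
  miss <- is.na(v)
  out[miss] <- 1
  nm <- sum(miss)
  for (i in which(!miss)) {
    less <- sum(v[!miss] < v[i])
    eq <- sum(v[!miss] == v[i])
    out[i] <- nm + less + (eq + 1) / 2
  }
  out
}

# full naive ranking pipeline on an annotated table
oracle_rank_table <- function(df, w = c(2, 1, 0.5, 1, 1, 1)) {
  r_cfd <- oracle_rank_feature(df$cfd_spec)
  r_mit <- oracle_rank_feature(df$mit_spec)
  r_do <- oracle_rank_feature(df$doench)
  r_mo <- oracle_rank_feature(df$moreno)
  r_dep <- oracle_rank_feature(df$dependency)
  r_tpm <- oracle_rank_feature(df$expression_tpm)
  r_cn <- oracle_rank_feature(df$copy_number)
  raw <- w[1] * r_cfd + w[2] * r_mit + w[3] * (r_do + r_mo) +
    w[4] * r_dep + w[5] * r_tpm + w[6] * r_cn
  rng <- range(raw)
  norm <- if (diff(rng) == 0) rep(100, length(raw)) else {
    (raw - rng[1]) / diff(rng) * 100
  }
  fr <- vapply(norm, function(x) 1L + sum(norm > x), integer(1))
  list(raw = raw, norm = norm, final_rank = fr)
}

# junction oracle: scan the joined 60-mer for all NGG/CCN, apply the
# positional filters independently of the package's index arithmetic
oracle_spanning <- function(joined) {
  stopifnot(nchar(joined) == 60L)
  jp <- function(i) if (i <= 30L) i - 31L else i - 30L  # index -> junction pos
  rows <- list()
  for (i in 1:58) {
    tri <- substr(joined, i, i + 2L)
    if (substr(tri, 2, 3) == "GG" && jp(i) >= 6L && jp(i) <= 16L) {
      if (i - 20L >= 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif = "NGG", grna = substr(joined, i - 20L, i - 1L),
          n_jpos = jp(i), stringsAsFactors = FALSE)
      }
    }
    if (substr(tri, 1, 2) == "CC" && jp(i) >= -18L && jp(i) <= -8L) {
      if (i + 22L <= 60L) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif = "CCN", grna = oracle_rc(substr(joined, i + 3L, i + 22L)),
          n_jpos = jp(i), stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(motif = character(), grna = character(), n_jpos = integer(),
               stringsAsFactors = FALSE)
  }
  out[!grepl("N", out$grna, fixed = TRUE), , drop = FALSE]
}

# "ggstart:strand" keys for a candidate table (safe for zero rows, where
# paste0 would otherwise recycle to a single ":")
cand_keys <- function(df) {
  if (nrow(df) == 0L) character(0) else sort(paste0(df$gg_start, ":", df$strand))
}

# uniform random genome string
random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
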