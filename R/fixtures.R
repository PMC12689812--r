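#' Specification for a synthetic test dataset
#'
#' Describes a deterministic synthetic dataset: a random genome, somatic
#' variants with planted PAM-creating events and verified-neutral background
#' variants, rearrangement breakpoints with planted junction-GG events,
#' gene models, per-gene feature tables and a precomputed guide-score table.
#' The same spec (including seed) always regenerates byte-identical files.
#'
#' @param seed integer seed driving every random draw.
#' @param contig_length length of each contig in bp.
#' @param n_contigs number of contigs.
#' @param gc GC fraction of the random genome.
#' @param n_planted_snv_plus,n_planted_snv_minus planted SNVs creating one
#'   novel plus-/minus-strand PAM each.
#' @param n_neutral_snv background SNVs rejection-sampled to create no PAM.
#' @param n_planted_indel planted single-base insertions creating one novel
#'   junction GG each.
#' @param n_planted_junction planted deletion-type breakpoints whose junction
#'   creates one novel GG PAM.
#' @param n_neutral_junction background breakpoints rejection-sampled to
#'   create no junction PAM.
#' @param n_genes gene models tiled over the genome.
#' @param sample_id sample identifier used in the variant files.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, contig_length = 20000L, n_contigs = 1L,
                         gc = 0.41, n_planted_snv_plus = 5L,
                         n_planted_snv_minus = 5L, n_neutral_snv = 90L,
                         n_planted_indel = 3L, n_planted_junction = 5L,
                         n_neutral_junction = 5L, n_genes = 20L,
                         sample_id = "S1") {
  structure(list(seed = as.integer(seed), contig_length = as.integer(contig_length),
                 n_contigs = as.integer(n_contigs), gc = gc,
                 n_planted_snv_plus = as.integer(n_planted_snv_plus),
                 n_planted_snv_minus = as.integer(n_planted_snv_minus),
                 n_neutral_snv = as.integer(n_neutral_snv),
                 n_planted_indel = as.integer(n_planted_indel),
                 n_planted_junction = as.integer(n_planted_junction),
                 n_neutral_junction = as.integer(n_neutral_junction),
                 n_genes = as.integer(n_genes), sample_id = sample_id),
            class = "fixture_spec")
}

# random genome as a list of per-contig character vectors
random_genome_chars <- function(spec) {
  p <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2, G = spec$gc / 2,
         T = (1 - spec$gc) / 2)
  lapply(seq_len(spec$n_contigs), function(i) {
    sample(names(p), spec$contig_length, replace = TRUE, prob = p)
  })
}

# draw a position keeping a margin from contig ends and a minimum distance
# from already-claimed positions
claim_position <- function(claimed, len, margin, min_dist = 60L) {
  for (try in 1:10000) {
    pos <- sample.int(len - 2L * margin, 1L) + margin  # 0-based
    if (all(abs(claimed - pos) >= min_dist)) return(pos)
  }
  stop("could not place event: genome too crowded for the requested counts")
}

#' Generate a synthetic dataset with known ground truth
#'
#' Writes FASTA, VCF, a 5-column variant TSV, GTF, three feature TSVs, a
#' guide-score TSV, a breakpoint TSV and a ground-truth TSV into `dir`.
#' Planting is verified at plant time: each planted SNV/indel is rescanned
#' and must yield exactly its intended candidate, each planted breakpoint
#' must yield exactly one junction-created PAM, and every neutral event is
#' rejection-sampled against the corresponding detector until it yields
#' nothing. Ground truth is therefore exact by construction.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list with `paths` (named file paths), `genome` (the
#'   `ref_genome`), `ground_truth` (data.frame of planted events) and
#'   `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  set.seed(spec$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chars <- random_genome_chars(spec)
  names(chars) <- paste0("ctg", seq_len(spec$n_contigs))
  margin <- 60L
  claimed <- lapply(chars, function(x) integer(0))

  truth <- list(); var_rows <- list(); bkp_rows <- list()
  pick_contig <- function() sample(names(chars), 1L)
  non_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

  # --- planted PAM-creating SNVs -------------------------------------------
  plant_snv <- function(strand) {
    ctg <- pick_contig()
    p0 <- claim_position(claimed[[ctg]], spec$contig_length, margin)
    claimed[[ctg]] <<- c(claimed[[ctg]], p0)
    base <- if (strand == "+") "G" else "C"
    # alt base lands at p0 next to an existing partner at p0+1; the base
    # before p0 must not be a partner (exactly one new dinucleotide)
    chars[[ctg]][p0 + 1L] <<- "A"            # ref base (!= alt)
    chars[[ctg]][p0 + 2L] <<- base           # existing partner 3' of the SNV
    if (chars[[ctg]][p0] == base) chars[[ctg]][p0] <<- "T"
    list(contig = ctg, pos = p0 + 1L, ref = "A", alt = base,
         strand = strand, gg_start = p0)
  }
  for (s in c(rep("+", spec$n_planted_snv_plus),
              rep("-", spec$n_planted_snv_minus))) {
    ev <- plant_snv(s)
    var_rows[[length(var_rows) + 1L]] <- data.frame(
      contig = ev$contig, pos = ev$pos, ref = ev$ref, alt = ev$alt,
      vtype = "SNV", sample_id = spec$sample_id, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      type = "snv_pam", contig = ev$contig, variant_pos = ev$pos,
      strand = ev$strand, gg_start = ev$gg_start, grna = NA_character_,
      stringsAsFactors = FALSE)
  }

  # --- planted PAM-creating insertions (junction GG) -----------------------
  for (i in seq_len(spec$n_planted_indel)) {
    ctg <- pick_contig()
    p0 <- claim_position(claimed[[ctg]], spec$contig_length, margin)
    claimed[[ctg]] <- c(claimed[[ctg]], p0)
    chars[[ctg]][p0 + 1L] <- "G"             # anchor base
    chars[[ctg]][p0 + 2L] <- "T"             # next base must not be G (novelty)
    if (chars[[ctg]][p0] == "G") chars[[ctg]][p0] <- "A"  # no pre-existing GG
    var_rows[[length(var_rows) + 1L]] <- data.frame(
      contig = ctg, pos = p0 + 1L, ref = "G", alt = "GG", vtype = "INS",
      sample_id = spec$sample_id, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      type = "indel_pam", contig = ctg, variant_pos = p0 + 1L, strand = "+",
      gg_start = p0, grna = NA_character_, stringsAsFactors = FALSE)
  }

  # --- planted junction-GG breakpoints (deletion-type joins) ---------------
  for (i in seq_len(spec$n_planted_junction)) {
    ctg <- pick_contig()
    repeat {                                 # both anchors must clear claims
      a0 <- claim_position(claimed[[ctg]], spec$contig_length, margin + 200L)
      b0 <- a0 + 100L + sample.int(50L, 1L)  # deleted span >= 100 bp
      if (all(abs(claimed[[ctg]] - b0) >= 60L)) break
    }
    claimed[[ctg]] <- c(claimed[[ctg]], a0, b0)
    chars[[ctg]][a0 + 1L] <- "G"             # last retained base, left side
    chars[[ctg]][a0 + 2L] <- "T"             # native continuation != G
    chars[[ctg]][b0 + 1L] <- "G"             # first retained base, right side
    chars[[ctg]][b0] <- "T"                  # native predecessor != G
    bkp_rows[[length(bkp_rows) + 1L]] <- data.frame(
      chrom1 = ctg, pos1 = a0 + 1L, strand1 = "+",
      chrom2 = ctg, pos2 = b0 + 1L, strand2 = "+",
      class = if (i %% 2L == 0L) "ecDNA" else "deletion",
      sample_id = spec$sample_id, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      type = "junction_pam", contig = ctg, variant_pos = a0 + 1L,
      strand = "+", gg_start = NA_integer_, grna = NA_character_,
      stringsAsFactors = FALSE)
  }

  genome <- ref_genome(vapply(chars, paste, character(1), collapse = ""))

  # verify planted events and fill in derived ground-truth fields
  truth_df <- do.call(rbind, truth)
  vars_df <- do.call(rbind, var_rows)
  k <- 0L
  for (i in seq_len(nrow(truth_df))) {
    if (truth_df$type[i] == "snv_pam") {
      k <- k + 1L
      cand <- scan_snv_for_novel_pams(vars_df[k, ], genome)
      if (nrow(cand) != 1L || cand$gg_start != truth_df$gg_start[i]) {
        stop("internal: planted SNV did not verify")
      }
      truth_df$grna[i] <- cand$protospacer
    } else if (truth_df$type[i] == "indel_pam") {
      k <- k + 1L
      cand <- scan_indel_for_novel_pams(vars_df[k, ], genome)
      if (nrow(cand) != 1L || cand$gg_start != truth_df$gg_start[i]) {
        stop("internal: planted indel did not verify")
      }
      truth_df$grna[i] <- cand$protospacer
    }
  }
  bkps_df <- if (length(bkp_rows)) do.call(rbind, bkp_rows) else NULL
  jt <- which(truth_df$type == "junction_pam")
  for (j in seq_along(jt)) {
    b <- bkps_df[j, ]
    w <- build_junction_window(genome, b$chrom1, b$pos1, b$strand1,
                               b$chrom2, b$pos2, b$strand2)
    jp <- detect_junction_pam(w)
    if (nrow(jp) != 1L || jp$motif != "NGG") {
      stop("internal: planted junction PAM did not verify")
    }
    truth_df$grna[jt[j]] <- jp$grna
  }

  # --- neutral SNVs: rejection-sampled to create no PAM --------------------
  for (i in seq_len(spec$n_neutral_snv)) {
    repeat {
      ctg <- pick_contig()
      p0 <- claim_position(claimed[[ctg]], spec$contig_length, margin, min_dist = 3L)
      ref <- chars[[ctg]][p0 + 1L]
      v <- data.frame(contig = ctg, pos = p0 + 1L, ref = ref,
                      alt = non_base(ref), vtype = "SNV",
                      sample_id = spec$sample_id, stringsAsFactors = FALSE)
      if (p0 %in% claimed[[ctg]]) next
      if (nrow(scan_snv_for_novel_pams(v, genome)) == 0L) {
        claimed[[ctg]] <- c(claimed[[ctg]], p0)
        var_rows[[length(var_rows) + 1L]] <- v
        break
      }
    }
  }

  # --- neutral breakpoints: junctions creating no PAM ----------------------
  for (i in seq_len(spec$n_neutral_junction)) {
    repeat {
      ctg <- pick_contig()
      a0 <- claim_position(claimed[[ctg]], spec$contig_length, margin + 200L,
                           min_dist = 3L)
      b0 <- a0 + 100L + sample.int(50L, 1L)
      w <- build_junction_window(genome, ctg, a0 + 1L, "+", ctg, b0 + 1L, "+")
      if (nrow(detect_junction_pam(w)) == 0L) {
        bkp_rows[[length(bkp_rows) + 1L]] <- data.frame(
          chrom1 = ctg, pos1 = a0 + 1L, strand1 = "+",
          chrom2 = ctg, pos2 = b0 + 1L, strand2 = "+",
          class = "deletion", sample_id = spec$sample_id,
          stringsAsFactors = FALSE)
        break
      }
    }
  }

  vars_df <- do.call(rbind, var_rows)
  bkps_df <- do.call(rbind, bkp_rows)

  # --- gene models tiled across contig 1 -----------------------------------
  glen <- spec$contig_length %/% (spec$n_genes + 1L)
  genes_df <- data.frame(
    gene_id = sprintf("GENE%03d", seq_len(spec$n_genes)),
    contig = names(chars)[1],
    start1 = (seq_len(spec$n_genes) - 1L) * glen + 1L,
    end1 = seq_len(spec$n_genes) * glen - 10L,
    strand = rep(c("+", "-"), length.out = spec$n_genes),
    stringsAsFactors = FALSE)

  # --- feature tables and guide-score table --------------------------------
  tpm <- round(stats::rlnorm(spec$n_genes, meanlog = 2, sdlog = 1.5), 2)
  cn <- sample(0:8, spec$n_genes, replace = TRUE,
               prob = c(1, 2, 8, 4, 3, 2, 1, 1, 1))
  dep <- round(stats::runif(spec$n_genes, -2, 0.5), 3)
  guides <- unique(stats::na.omit(truth_df$grna))
  scores_df <- data.frame(
    protospacer = guides,
    cfd_spec = round(stats::runif(length(guides), 60, 100), 1),
    mit_spec = round(stats::runif(length(guides), 50, 100), 1),
    doench = round(stats::runif(length(guides), 20, 90), 1),
    moreno = round(stats::runif(length(guides), 20, 90), 1),
    stringsAsFactors = FALSE)

  # --- write everything ----------------------------------------------------
  paths <- list(
    fasta = file.path(dir, "genome.fa"), vcf = file.path(dir, "variants.vcf"),
    variants_tsv = file.path(dir, "variants.tsv"),
    gtf = file.path(dir, "genes.gtf"),
    expression = file.path(dir, "expression.tsv"),
    copy_number = file.path(dir, "copy_number.tsv"),
    dependency = file.path(dir, "dependency.tsv"),
    scores = file.path(dir, "scores.tsv"),
    breakpoints = file.path(dir, "breakpoints.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv"))

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(genome$seqs, names(genome$seqs))),
    paths$fasta)
  write_fixture_vcf(vars_df, genome, paths$vcf)
  write_tsv(vars_df[, c("contig", "pos", "ref", "alt", "sample_id")],
            paths$variants_tsv)
  gtf <- c(
    sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
            genes_df$contig, genes_df$start1, genes_df$end1, genes_df$strand,
            genes_df$gene_id, genes_df$gene_id),
    sprintf("%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
            genes_df$contig, genes_df$start1, genes_df$end1, genes_df$strand,
            genes_df$gene_id, genes_df$gene_id))
  writeLines(gtf, paths$gtf)
  write_tsv(data.frame(gene_id = genes_df$gene_id, tpm = tpm), paths$expression)
  write_tsv(data.frame(gene_id = genes_df$gene_id, copy_number = cn),
            paths$copy_number)
  write_tsv(data.frame(gene_id = genes_df$gene_id, dependency = dep),
            paths$dependency)
  write_tsv(scores_df, paths$scores)
  write_tsv(bkps_df, paths$breakpoints)
  write_tsv(truth_df, paths$ground_truth)

  list(paths = paths, genome = genome, ground_truth = truth_df, spec = spec)
}

# minimal VCF 4.2 writer for the synthetic variant set
write_fixture_vcf <- function(vars, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig_names(genome),
                   unname(contig_length(genome))),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                  vars$contig, vars$pos, vars$ref, vars$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}
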