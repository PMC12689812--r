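#' Reverse complement of a DNA string
#'
#' Vectorised over its argument; operates on plain character strings over the
#' alphabet ACGTN (case-insensitive, returned upper case).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Construct an in-memory reference genome
#'
#' Builds the genome container used throughout the package from a named
#' character vector of contig sequences. Sequences are upper-cased and any
#' character outside ACGTN is replaced by N.
#'
#' @param seqs named character vector, one element per contig.
#' @return an object of class `ref_genome`.
#' @examples
#' g <- ref_genome(c(chr1 = "acgtACGT"))
#' fetch_seq(g, "chr1", 0, 4)
#' @export
ref_genome <- function(seqs) {
  if (length(seqs) == 0L) stop("empty genome: no contigs")
  nm <- names(seqs)
  if (is.null(nm) || any(nm == "")) stop("all contigs must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate contig names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
  names(seqs) <- nm
  structure(list(seqs = seqs, lengths = setNames(nchar(seqs), nm)),
            class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("ref_genome with", length(x$seqs), "contig(s),",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  n <- min(length(x$seqs), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  %s  %s bp\n", names(x$seqs)[i],
                format(x$lengths[i], big.mark = ",")))
  }
  if (length(x$seqs) > n) cat("  ...\n")
  invisible(x)
}

#' Contig names and lengths of a reference genome
#' @param genome a `ref_genome`.
#' @return `contig_names`: character vector; `contig_length`: named integer vector
#'   (or a single length when `contig` is given).
#' @export
contig_names <- function(genome) names(genome$seqs)

#' @rdname contig_names
#' @param contig optional single contig name.
#' @export
contig_length <- function(genome, contig = NULL) {
  if (is.null(contig)) return(genome$lengths)
  if (!contig %in% names(genome$lengths)) stop("unknown contig: ", contig)
  unname(genome$lengths[[contig]])
}

#' Load a reference genome from FASTA
#'
#' Reads every contig into memory (desk-scale genomes assumed), upper-cases
#' soft-masked sequence and maps non-ACGTN characters to N.
#'
#' @param path path to a FASTA file.
#' @return a `ref_genome`.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty genome: no contigs in ", path)
  # FASTA headers may carry descriptions after the first token
  nm <- sub("\\s.*$", "", names(ss))
  ref_genome(setNames(as.character(ss), nm))
}

#' Fetch genomic sequence
#'
#' Coordinates are 0-based half-open (`[start, end)`), the package-internal
#' convention. A minus-strand fetch returns the reverse complement of the
#' plus-strand sequence over the same interval.
#'
#' @param genome a `ref_genome`.
#' @param contig contig name.
#' @param start,end 0-based half-open interval; must satisfy
#'   `0 <= start <= end <= contig length`.
#' @param strand `"+"` or `"-"`.
#' @return a character scalar.
#' @export
fetch_seq <- function(genome, contig, start, end, strand = "+") {
  if (!contig %in% names(genome$seqs)) stop("unknown contig: ", contig)
  len <- genome$lengths[[contig]]
  if (start < 0 || end < start || end > len) {
    stop(sprintf("interval [%d,%d) out of bounds for contig %s (length %d)",
                 start, end, contig, len))
  }
  s <- substr(genome$seqs[[contig]], start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

#' Convert between VCF/GTF 1-based and internal 0-based coordinates
#'
#' The package stores all positions 0-based half-open; VCF and GTF use 1-based
#' coordinates. These helpers make the conversion explicit and self-inverse.
#'
#' @param pos1 1-based position(s).
#' @param pos0 0-based position(s).
#' @return converted integer position(s).
#' @export
vcf_to_internal <- function(pos1) as.integer(pos1) - 1L

#' @rdname vcf_to_internal
#' @export
internal_to_vcf <- function(pos0) as.integer(pos0) + 1L

# classify a biallelic ref/alt pair
variant_type <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
         ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
}

#' Load somatic variants from a VCF file
#'
#' Keeps PASS (or unfiltered, `.`) records, splits multi-allelic records into
#' one biallelic variant per alternate allele, classifies each as SNV, INS or
#' DEL, and drops indels whose length change is at or above `max_indel` (small
#' indels only are considered by the discovery rule). When a genome is
#' supplied, records whose REF allele disagrees with the loaded reference are
#' skipped with a warning.
#'
#' @param path path to a VCF (4.x) file.
#' @param sample_id sample identifier attached to every variant.
#' @param genome optional `ref_genome` for REF-allele verification.
#' @param max_indel indels with `abs(nchar(ref) - nchar(alt)) >= max_indel`
#'   are dropped (default 300).
#' @return a data.frame with columns `contig`, `pos` (1-based, VCF
#'   convention), `ref`, `alt`, `vtype`, `sample_id`, and a `counters`
#'   attribute recording how many records were dropped and why.
#' @export
load_somatic_variants <- function(path, sample_id, genome = NULL, max_indel = 300L) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- variant_frame()
    attr(out, "counters") <- c(n_records = 0L, n_filtered = 0L,
                               n_large_indel = 0L, n_ref_mismatch = 0L)
    return(out)
  }
  keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  n_filtered <- sum(!keep)
  fix <- fix[keep, , drop = FALSE]

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alts <- alts[alts != "" & alts != "."]
    if (length(alts) == 0L) next
    rows[[i]] <- data.frame(
      contig = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = toupper(fix$REF[i]), alt = toupper(alts),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- variant_frame()[, c("contig", "pos", "ref", "alt")]

  out$vtype <- variant_type(out$ref, out$alt)
  large <- abs(nchar(out$ref) - nchar(out$alt)) >= max_indel
  n_large <- sum(large)
  out <- out[!large, , drop = FALSE]

  n_mismatch <- 0L
  if (!is.null(genome) && nrow(out) > 0L) {
    ok <- vapply(seq_len(nrow(out)), function(i) {
      ctg <- out$contig[i]
      if (!ctg %in% contig_names(genome)) return(FALSE)
      p0 <- vcf_to_internal(out$pos[i])
      end <- p0 + nchar(out$ref[i])
      end <= contig_length(genome, ctg) &&
        fetch_seq(genome, ctg, p0, end) == out$ref[i]
    }, logical(1))
    n_mismatch <- sum(!ok)
    if (n_mismatch > 0L) {
      warning(n_mismatch, " variant(s) skipped: REF allele does not match the loaded genome")
    }
    out <- out[ok, , drop = FALSE]
  }
  out$sample_id <- sample_id
  rownames(out) <- NULL
  attr(out, "counters") <- c(n_records = nrow(fix), n_filtered = n_filtered,
                             n_large_indel = n_large, n_ref_mismatch = n_mismatch)
  out
}

variant_frame <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), vtype = character(), sample_id = character(),
             stringsAsFactors = FALSE)
}

#' Load somatic variants from a minimal 5-column TSV
#'
#' Fixture-friendly alternative carrier: a headered TSV with columns
#' `contig`, `pos` (1-based), `ref`, `alt`, `sample` (or `sample_id`).
#' Applies the same type classification and indel size cap as the VCF loader.
#'
#' @inheritParams load_somatic_variants
#' @return same shape as [load_somatic_variants()].
#' @export
load_variants_tsv <- function(path, genome = NULL, max_indel = 300L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("sample" %in% names(tab) && !"sample_id" %in% names(tab)) {
    names(tab)[names(tab) == "sample"] <- "sample_id"
  }
  need <- c("contig", "pos", "ref", "alt", "sample_id")
  if (!all(need %in% names(tab))) {
    stop("variant TSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- tab[, need]
  out$pos <- as.integer(out$pos)
  out$ref <- toupper(out$ref); out$alt <- toupper(out$alt)
  out$vtype <- variant_type(out$ref, out$alt)
  large <- abs(nchar(out$ref) - nchar(out$alt)) >= max_indel
  out <- out[!large, c("contig", "pos", "ref", "alt", "vtype", "sample_id")]
  rownames(out) <- NULL
  attr(out, "counters") <- c(n_records = nrow(tab), n_filtered = 0L,
                             n_large_indel = sum(large), n_ref_mismatch = 0L)
  out
}

#' Load gene models from GTF/GFF3
#'
#' One record per `gene` feature; 1-based annotation coordinates are converted
#' to the internal 0-based half-open convention. Exon intervals are attached
#' as an attribute for callers that need sub-gene structure.
#'
#' @param path path to a GTF or GFF3 file.
#' @param genome optional `ref_genome`; genes on contigs absent from it
#'   trigger a warning.
#' @return data.frame with columns `gene_id`, `symbol`, `contig`, `start`
#'   (0-based), `end` (half-open), `strand`; exons in `attr(, "exons")`.
#' @export
load_gene_models <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!"type" %in% names(df)) df$type <- "gene"
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) {
    warning("no gene features found in ", path)
    return(gene_frame())
  }
  gid <- if ("gene_id" %in% names(genes)) genes$gene_id else as.character(seq_len(nrow(genes)))
  sym <- if ("gene_name" %in% names(genes)) genes$gene_name else gid
  sym[is.na(sym)] <- gid[is.na(sym)]
  out <- data.frame(
    gene_id = as.character(gid), symbol = as.character(sym),
    contig = as.character(genes$seqnames),
    start = as.integer(genes$start) - 1L,  # to 0-based half-open
    end = as.integer(genes$end),
    strand = as.character(genes$strand),
    stringsAsFactors = FALSE)
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  if (!is.null(genome)) {
    bad <- setdiff(unique(out$contig), contig_names(genome))
    if (length(bad) > 0L) {
      warning("gene models on contig(s) absent from the reference: ",
              paste(bad, collapse = ", "))
    }
  }
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) > 0L) {
    exons <- data.frame(
      gene_id = as.character(if ("gene_id" %in% names(ex)) ex$gene_id else NA),
      contig = as.character(ex$seqnames),
      start = as.integer(ex$start) - 1L, end = as.integer(ex$end),
      stringsAsFactors = FALSE)
    attr(out, "exons") <- exons[order(exons$gene_id, exons$start), ]
  } else {
    attr(out, "exons") <- NULL
  }
  out
}

gene_frame <- function() {
  data.frame(gene_id = character(), symbol = character(), contig = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Load a per-gene feature table
#'
#' Reads a headered TSV mapping gene identifiers to one numeric feature
#' (expression in TPM, copy number, or gene dependency). Non-numeric values
#' become missing; duplicate gene identifiers are an error.
#'
#' @param path path to a TSV with a `gene_id` column and one or more value
#'   columns.
#' @param feature_kind one of `"expression"`, `"copy_number"`, `"dependency"`;
#'   recorded on the result for downstream sanity checks.
#' @param value_col which value column to use (default: the first non-id
#'   column).
#' @return named numeric vector (names = gene_id) with attribute
#'   `feature_kind`.
#' @export
load_feature_table <- function(path, feature_kind = c("expression", "copy_number", "dependency"),
                               value_col = NULL) {
  feature_kind <- match.arg(feature_kind)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab)) stop("feature table must have a gene_id column")
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene_id in feature table: ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  }
  if (is.null(value_col)) value_col <- setdiff(names(tab), "gene_id")[1]
  if (is.na(value_col) || !value_col %in% names(tab)) {
    stop("feature table has no value column")
  }
  vals <- suppressWarnings(as.numeric(tab[[value_col]]))
  structure(setNames(vals, tab$gene_id), feature_kind = feature_kind)
}

#' Write a candidate (or any) table as headered TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
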