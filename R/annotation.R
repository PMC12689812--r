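#' Assign the containing gene to a PAM candidate
#'
#' The gene whose span contains the candidate's PAM dinucleotide (gene-span
#' assignment, not exon-only: intronic PAMs still carry gene-level features).
#' When several genes overlap the site, the most highly expressed wins
#' (ties broken lexicographically by gene_id) and the alternates are recorded.
#'
#' @param candidate one-row candidate data.frame.
#' @param genes gene-model data.frame from [load_gene_models()].
#' @param expression named numeric vector (TPM by gene_id) used for the tie
#'   rule; optional.
#' @return list with `gene_id`, `symbol` (either may be `NA`) and
#'   `alternates` (character vector, possibly empty).
#' @export
annotate_gene <- function(candidate, genes, expression = NULL) {
  g <- candidate$gg_start
  hit <- which(genes$contig == candidate$contig &
                 genes$start <= g & genes$end >= g + 2L)
  if (length(hit) == 0L) {
    return(list(gene_id = NA_character_, symbol = NA_character_,
                alternates = character(0)))
  }
  ids <- genes$gene_id[hit]
  if (length(ids) > 1L) {
    tpm <- if (is.null(expression)) rep(NA_real_, length(ids)) else unname(expression[ids])
    tpm[is.na(tpm)] <- -Inf
    ord <- order(-tpm, ids)
    ids <- ids[ord]; hit <- hit[ord]
  }
  list(gene_id = ids[1], symbol = genes$symbol[hit[1]], alternates = ids[-1])
}

#' Classify a gene-dependency score
#'
#' DepMap-style semantics: around 0 means non-essential, at or below -0.5
#' means depletion in most contexts, at or below -1 strong lethality on
#' knockout.
#'
#' @param dependency numeric vector of dependency scores (NA allowed).
#' @return character vector of labels.
#' @export
dependency_class <- function(dependency) {
  ifelse(is.na(dependency), NA_character_,
         ifelse(dependency <= -1, "strong_lethality",
                ifelse(dependency <= -0.5, "depletion", "non_essential")))
}

#' Annotate discovered candidates with gene context, features and scores
#'
#' Attaches gene assignment, the three per-gene biological features
#' (expression TPM, copy number, dependency) and the four guide scores to
#' every candidate. Candidates outside any gene get all gene-keyed features
#' missing; genes absent from a table get that feature missing (the ranking
#' assigns missing values the lowest rank). Guide scores come either from a
#' precomputed table keyed by protospacer or from the built-in computation
#' against the genome.
#'
#' @param candidates candidate data.frame from [discover_sample()].
#' @param genes gene-model data.frame.
#' @param expression,copy_number,dependency named numeric vectors by gene_id
#'   (from [load_feature_table()]); any may be `NULL`.
#' @param score_table precomputed guide scores from [load_score_table()];
#'   when `NULL` and `genome` is given, specificity is computed with
#'   [specificity_scores()] and efficiency with the built-in surrogate.
#' @param genome `ref_genome`, required for built-in scoring.
#' @param cfd_model,mit_w penalty models for built-in specificity.
#' @return annotated data.frame (candidate columns plus `symbol`,
#'   `expression_tpm`, `copy_number`, `dependency`, `dependency_class`,
#'   `cfd_spec`, `mit_spec`, `doench`, `moreno`).
#' @export
annotate_candidates <- function(candidates, genes = NULL, expression = NULL,
                                copy_number = NULL, dependency = NULL,
                                score_table = NULL, genome = NULL,
                                cfd_model = uniform_penalty_model(),
                                mit_w = mit_weights()) {
  out <- candidates
  n <- nrow(out)
  out$symbol <- NA_character_
  out$expression_tpm <- NA_real_
  out$copy_number <- NA_real_
  out$dependency <- NA_real_
  out$cfd_spec <- NA_real_; out$mit_spec <- NA_real_
  out$doench <- NA_real_; out$moreno <- NA_real_
  if (n == 0L) {
    out$dependency_class <- character(0)
    return(out)
  }
  for (i in seq_len(n)) {
    if (!is.null(genes) && nrow(genes) > 0L) {
      ga <- annotate_gene(out[i, ], genes, expression)
      out$gene_id[i] <- ga$gene_id
      out$symbol[i] <- ga$symbol
    }
    gid <- out$gene_id[i]
    if (!is.na(gid)) {
      if (!is.null(expression)) out$expression_tpm[i] <- unname(expression[gid])
      if (!is.null(copy_number)) out$copy_number[i] <- unname(copy_number[gid])
      if (!is.null(dependency)) out$dependency[i] <- unname(dependency[gid])
    }
    proto <- out$protospacer[i]
    if (!is.null(score_table)) {
      j <- match(proto, score_table$protospacer)
      if (!is.na(j)) {
        out$cfd_spec[i] <- score_table$cfd_spec[j]
        out$mit_spec[i] <- score_table$mit_spec[j]
        out$doench[i] <- score_table$doench[j]
        out$moreno[i] <- score_table$moreno[j]
      }
    } else if (!is.null(genome)) {
      sp <- specificity_scores(proto, genome, cfd_model = cfd_model, mit_w = mit_w)
      out$cfd_spec[i] <- sp[["cfd_spec"]]
      out$mit_spec[i] <- sp[["mit_spec"]]
      eff <- efficiency_scores(proto, mode = "builtin_surrogate")
      out$doench[i] <- eff[["doench"]]
      out$moreno[i] <- eff[["moreno"]]
    }
  }
  out$dependency_class <- dependency_class(out$dependency)
  out
}
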