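#' Ranking weights and report thresholds
#'
#' `ranking_weights()` holds the weights of the composite score
#' `w_cfd * rank(CFD) + w_mit * rank(MIT) + w_eff * (rank(Doench) +
#' rank(Moreno)) + w_dependency * rank(dependency) + w_expression *
#' rank(TPM) + w_copy_number * rank(CN)`. The defaults double-weight the CFD
#' specificity rank (safety) and half-weight each efficiency rank (their two
#' ranks together count once).
#'
#' @param w_cfd,w_mit,w_eff,w_dependency,w_expression,w_copy_number
#'   non-negative weights.
#' @return named numeric vector of class `ranking_weights`.
#' @export
ranking_weights <- function(w_cfd = 2, w_mit = 1, w_eff = 0.5,
                            w_dependency = 1, w_expression = 1,
                            w_copy_number = 1) {
  w <- c(w_cfd = w_cfd, w_mit = w_mit, w_eff = w_eff,
         w_dependency = w_dependency, w_expression = w_expression,
         w_copy_number = w_copy_number)
  if (any(w < 0)) stop("ranking weights must be non-negative")
  structure(w, class = "ranking_weights")
}

#' @rdname ranking_weights
#' @param min_pam_count minimum per-sample novel-PAM count for the
#'   feasibility flag (default 86).
#' @param cfd_cut,mit_cut specificity cuts applied to the top-3 candidates
#'   (defaults 90 and 80; the flags require strictly greater values).
#' @export
report_thresholds <- function(min_pam_count = 86, cfd_cut = 90, mit_cut = 80) {
  t <- c(min_pam_count = min_pam_count, cfd_cut = cfd_cut, mit_cut = mit_cut)
  if (any(t < 0)) stop("thresholds must be non-negative")
  structure(t, class = "report_thresholds")
}

#' Rank one feature across a candidate set
#'
#' Ranks run from 1 (worst) to n (best); all seven features are oriented so
#' that a higher value is better (for dependency, a higher — less negative —
#' score means less essential, hence safer). Tied values share the average of
#' the spanned ranks. Missing values all receive (and share) rank 1, the
#' lowest rank; the non-missing values then occupy the ranks above them.
#'
#' @param values numeric vector, NA = missing.
#' @return numeric vector of ranks, same length.
#' @export
rank_feature <- function(values) {
  n <- length(values)
  if (n == 0L) stop("rank_feature: empty input")
  out <- numeric(n)
  miss <- is.na(values)
  out[miss] <- 1
  if (any(!miss)) {
    out[!miss] <- rank(values[!miss], ties.method = "average") + sum(miss)
  }
  out
}

#' Composite weighted rank-sum score
#'
#' @param ranks named list/vector with elements `cfd`, `mit`, `doench`,
#'   `moreno`, `dependency`, `expression`, `copy_number` (per-feature ranks).
#' @param weights a [ranking_weights()] object.
#' @return numeric raw composite score.
#' @export
composite_score <- function(ranks, weights = ranking_weights()) {
  weights[["w_cfd"]] * ranks[["cfd"]] +
    weights[["w_mit"]] * ranks[["mit"]] +
    weights[["w_eff"]] * (ranks[["doench"]] + ranks[["moreno"]]) +
    weights[["w_dependency"]] * ranks[["dependency"]] +
    weights[["w_expression"]] * ranks[["expression"]] +
    weights[["w_copy_number"]] * ranks[["copy_number"]]
}

#' Rank and prioritise annotated candidates
#'
#' Per-feature ranks (see [rank_feature()]) are combined by the weighted
#' rank-sum, the raw composite is min-max normalised within the candidate set
#' to 0-100 (100 = most promising; a single candidate, or an all-tied set, is
#' defined as 100), and candidates are sorted by descending normalised score.
#' Final ranks start at 1 for the best candidate; exact ties share the same
#' (minimum) rank.
#'
#' @param annotated annotated candidate data.frame from
#'   [annotate_candidates()].
#' @param weights a [ranking_weights()] object.
#' @return the input with added columns `rank_cfd`, `rank_mit`,
#'   `rank_doench`, `rank_moreno`, `rank_dependency`, `rank_expression`,
#'   `rank_copy_number`, `raw_score`, `normalized_score`, `final_rank`,
#'   sorted best-first.
#' @export
rank_candidates <- function(annotated, weights = ranking_weights()) {
  if (nrow(annotated) == 0L) stop("no candidates to rank")
  r <- data.frame(
    cfd = rank_feature(annotated$cfd_spec),
    mit = rank_feature(annotated$mit_spec),
    doench = rank_feature(annotated$doench),
    moreno = rank_feature(annotated$moreno),
    dependency = rank_feature(annotated$dependency),
    expression = rank_feature(annotated$expression_tpm),
    copy_number = rank_feature(annotated$copy_number))
  raw <- vapply(seq_len(nrow(r)), function(i) {
    composite_score(as.list(r[i, ]), weights)
  }, numeric(1))
  rng <- range(raw)
  norm <- if (diff(rng) == 0) rep(100, length(raw)) else {
    (raw - rng[1]) / diff(rng) * 100
  }
  out <- annotated
  out$rank_cfd <- r$cfd; out$rank_mit <- r$mit
  out$rank_doench <- r$doench; out$rank_moreno <- r$moreno
  out$rank_dependency <- r$dependency; out$rank_expression <- r$expression
  out$rank_copy_number <- r$copy_number
  out$raw_score <- raw
  out$normalized_score <- norm
  out <- out[order(-norm), , drop = FALSE]
  # competition ranking: 1 = best, exact score ties share the rank
  out$final_rank <- rank(-out$normalized_score, ties.method = "min")
  rownames(out) <- NULL
  out
}

#' Per-sample feasibility and safety report
#'
#' Summarises one ranked candidate set against the report thresholds: the
#' total novel-PAM count versus the minimum feasibility count, and whether
#' each of the top three ranked candidates clears the CFD and MIT specificity
#' cuts.
#'
#' @param ranked output of [rank_candidates()].
#' @param thresholds a [report_thresholds()] object.
#' @return object of class `sample_report`: a list with `n_candidates`,
#'   `pass_min_pam_count`, `top3` (data.frame with per-candidate flag
#'   columns `cfd_pass`, `mit_pass`) and the thresholds used.
#' @export
flag_sample <- function(ranked, thresholds = report_thresholds()) {
  n <- nrow(ranked)
  top3 <- utils::head(ranked, 3L)
  rep <- list(
    n_candidates = n,
    pass_min_pam_count = n >= thresholds[["min_pam_count"]],
    top3 = data.frame(
      final_rank = top3$final_rank,
      protospacer = top3$protospacer,
      cfd_spec = top3$cfd_spec, mit_spec = top3$mit_spec,
      cfd_pass = !is.na(top3$cfd_spec) & top3$cfd_spec > thresholds[["cfd_cut"]],
      mit_pass = !is.na(top3$mit_spec) & top3$mit_spec > thresholds[["mit_cut"]],
      stringsAsFactors = FALSE),
    thresholds = thresholds)
  class(rep) <- "sample_report"
  rep
}

#' @export
print.sample_report <- function(x, ...) {
  cat("Sample target-site report\n")
  cat(sprintf("  novel PAM sites: %d (feasibility >= %g: %s)\n",
              x$n_candidates, x$thresholds[["min_pam_count"]],
              if (x$pass_min_pam_count) "PASS" else "FAIL"))
  cat(sprintf("  top-3 specificity (CFD > %g, MIT > %g):\n",
              x$thresholds[["cfd_cut"]], x$thresholds[["mit_cut"]]))
  for (i in seq_len(nrow(x$top3))) {
    cat(sprintf("    #%d %s  CFD %.1f [%s]  MIT %.1f [%s]\n",
                x$top3$final_rank[i], x$top3$protospacer[i],
                x$top3$cfd_spec[i], if (x$top3$cfd_pass[i]) "ok" else "below",
                x$top3$mit_spec[i], if (x$top3$mit_pass[i]) "ok" else "below"))
  }
  invisible(x)
}
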