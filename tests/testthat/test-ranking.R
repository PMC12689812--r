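ann_row <- function(cfd, mit, doench, moreno, dep, tpm, cn, id = "x") {
  data.frame(protospacer = id, cfd_spec = cfd, mit_spec = mit, doench = doench,
             moreno = moreno, dependency = dep, expression_tpm = tpm,
             copy_number = cn, stringsAsFactors = FALSE)
}

worked_example <- function() {
  rbind(ann_row(95, 85, 60, 50, -0.1, 50, 2, "X"),
        ann_row(80, 90, 70, 40, -1.2, 10, 4, "Y"),
        ann_row(95, 70, NA, NA, 0.0, 100, 2, "Z"))
}

test_that("feature ranking: ties share the average, missing shares rank 1", {
  expect_equal(rank_feature(c(80, 95, 95)), c(1, 2.5, 2.5))
  expect_equal(rank_feature(c(NA, 10, 20)), c(1, 2, 3))
  expect_equal(rank_feature(c(NA, NA, 10, 20)), c(1, 1, 3, 4))
  expect_equal(rank_feature(42), 1)
  expect_error(rank_feature(numeric(0)), "empty")
})

test_that("composite score follows the weighted rank-sum formula", {
  ones <- list(cfd = 1, mit = 1, doench = 1, moreno = 1,
               dependency = 1, expression = 1, copy_number = 1)
  expect_equal(composite_score(ones), 7)            # 2+1+0.5*2+1+1+1
  # doubling the CFD weight doubles only the CFD term
  r <- list(cfd = 3, mit = 2, doench = 1, moreno = 2,
            dependency = 1, expression = 2, copy_number = 1)
  base <- composite_score(r)
  doubled <- composite_score(r, ranking_weights(w_cfd = 4))
  expect_equal(doubled - base, 2 * r$cfd)
  expect_error(ranking_weights(w_cfd = -1), "non-negative")
})

test_that("the three-candidate worked example reproduces scores and ranks", {
  ranked <- rank_candidates(worked_example())
  expect_equal(ranked$raw_score[match(c("X", "Y", "Z"), ranked$protospacer)],
               c(15.0, 12.5, 14.5))
  expect_equal(ranked$normalized_score[match(c("X", "Y", "Z"), ranked$protospacer)],
               c(100, 0, 80))
  expect_equal(ranked$final_rank[match(c("X", "Y", "Z"), ranked$protospacer)],
               c(1L, 3L, 2L))
  # independently recomputed by the naive oracle
  o <- oracle_rank_table(worked_example())
  expect_equal(sort(ranked$raw_score), sort(o$raw))
})

test_that("degenerate candidate sets normalise to 100", {
  one <- rank_candidates(ann_row(95, 85, 60, 50, -0.1, 50, 2))
  expect_equal(one$normalized_score, 100)
  expect_equal(one$final_rank, 1L)
  two <- rank_candidates(rbind(ann_row(95, 85, 60, 50, -0.1, 50, 2, "a"),
                               ann_row(95, 85, 60, 50, -0.1, 50, 2, "b")))
  expect_equal(two$normalized_score, c(100, 100))
  expect_equal(two$final_rank, c(1L, 1L))
  expect_error(rank_candidates(worked_example()[0, ]), "no candidates")
})

test_that("ranking is invariant to candidate input order", {
  set.seed(31)
  df <- do.call(rbind, lapply(1:25, function(i) {
    ann_row(runif(1, 0, 100), runif(1, 0, 100), runif(1, 0, 100),
            runif(1, 0, 100), runif(1, -2, 0.5), rlnorm(1, 2), sample(0:8, 1),
            paste0("g", i))
  }))
  a <- rank_candidates(df)
  b <- rank_candidates(df[sample(nrow(df)), ])
  a <- a[order(a$protospacer), ]; b <- b[order(b$protospacer), ]
  expect_equal(a$raw_score, b$raw_score)
  expect_equal(a$normalized_score, b$normalized_score)
  expect_equal(a$final_rank, b$final_rank)
})

test_that("improving any single feature never lowers a composite score", {
  set.seed(32)
  for (rep in 1:20) {
    df <- do.call(rbind, lapply(1:10, function(i) {
      ann_row(runif(1, 0, 100), runif(1, 0, 100),
              if (runif(1) < 0.2) NA else runif(1, 0, 100),
              runif(1, 0, 100), runif(1, -2, 0.5), rlnorm(1, 2),
              sample(0:8, 1), paste0("g", i))
    }))
    before <- rank_candidates(df)
    feat <- sample(c("cfd_spec", "mit_spec", "doench", "moreno",
                     "dependency", "expression_tpm", "copy_number"), 1)
    i <- sample(nrow(df), 1)
    df2 <- df
    df2[[feat]][i] <- if (is.na(df2[[feat]][i])) 1e6 else df2[[feat]][i] + 1e6
    after <- rank_candidates(df2)
    id <- df$protospacer[i]
    expect_gte(after$raw_score[after$protospacer == id],
               before$raw_score[before$protospacer == id])
  }
})

test_that("ranking matches the naive O(n^2) oracle on random tables", {
  set.seed(33)
  for (rep in 1:30) {
    n <- 50
    df <- data.frame(
      protospacer = paste0("g", 1:n),
      cfd_spec = ifelse(runif(n) < 0.1, NA, round(runif(n, 0, 100), 1)),
      mit_spec = ifelse(runif(n) < 0.1, NA, round(runif(n, 0, 100), 1)),
      doench = ifelse(runif(n) < 0.2, NA, sample(0:100, n, TRUE)),  # many ties
      moreno = ifelse(runif(n) < 0.2, NA, sample(0:100, n, TRUE)),
      dependency = ifelse(runif(n) < 0.15, NA, round(runif(n, -2, 0.5), 2)),
      expression_tpm = ifelse(runif(n) < 0.1, NA, round(rlnorm(n, 2), 1)),
      copy_number = ifelse(runif(n) < 0.1, NA, sample(0:8, n, TRUE)),
      stringsAsFactors = FALSE)
    ranked <- rank_candidates(df)
    o <- oracle_rank_table(df)
    ord <- match(ranked$protospacer, df$protospacer)
    expect_equal(ranked$raw_score, o$raw[ord])
    expect_equal(ranked$normalized_score, o$norm[ord])
    expect_equal(ranked$final_rank, o$final_rank[ord])
  }
})

test_that("normalisation stays in [0,100] and attains 100", {
  set.seed(34)
  for (rep in 1:10) {
    n <- sample(2:40, 1)
    df <- data.frame(
      protospacer = paste0("g", 1:n),
      cfd_spec = runif(n, 0, 100), mit_spec = runif(n, 0, 100),
      doench = runif(n, 0, 100), moreno = runif(n, 0, 100),
      dependency = runif(n, -2, 0.5), expression_tpm = rlnorm(n, 2),
      copy_number = sample(0:8, n, TRUE), stringsAsFactors = FALSE)
    ranked <- rank_candidates(df)
    expect_true(all(ranked$normalized_score >= 0 & ranked$normalized_score <= 100))
    expect_equal(max(ranked$normalized_score), 100)
    expect_equal(ranked$final_rank[1], 1L)
  }
})

test_that("sample flags compare counts and top-3 specificity to thresholds", {
  set.seed(35)
  mk_ranked <- function(n, cfd3, mit3) {
    # a ranked table, best-first, whose top three carry the given scores
    data.frame(
      protospacer = paste0("g", 1:n),
      cfd_spec = c(cfd3, runif(n - 3, 0, 80)),
      mit_spec = c(mit3, runif(n - 3, 0, 70)),
      normalized_score = seq(100, 0, length.out = n),
      final_rank = seq_len(n), stringsAsFactors = FALSE)
  }
  r <- mk_ranked(100, c(95, 93, 91), c(85, 84, 81))
  rep1 <- flag_sample(r)
  expect_true(rep1$pass_min_pam_count)
  expect_true(all(rep1$top3$cfd_pass))
  expect_true(all(rep1$top3$mit_pass))
  rep2 <- flag_sample(mk_ranked(50, c(95, 93, 91), c(85, 84, 81)))
  expect_false(rep2$pass_min_pam_count)
  # a top-3 CFD of 88 fails the safety flag for that candidate
  rep3 <- flag_sample(mk_ranked(100, c(95, 93, 88), c(85, 84, 81)))
  expect_equal(rep3$top3$cfd_pass, c(TRUE, TRUE, FALSE))
  # a boundary value does not pass a strict threshold
  expect_false(flag_sample(r, report_thresholds(cfd_cut = 95))$top3$cfd_pass[1])
})
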