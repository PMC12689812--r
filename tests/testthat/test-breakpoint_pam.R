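# a genome whose two halves are distinguishable; helpers to compose junction
# windows directly from sequence strings
window_from_strings <- function(left, right, after = "T", before = "T") {
  stopifnot(nchar(left) == 30, nchar(right) == 30)
  structure(list(left = left, right = right, joined = paste0(left, right),
                 native_after_left = after, native_before_right = before),
            class = "junction_window")
}

test_that("junction position <-> index mapping round-trips, skipping zero", {
  ks <- c(-30:-1, 1:30)
  expect_identical(index_to_jpos(jpos_to_index(ks)), ks)
  expect_identical(jpos_to_index(index_to_jpos(1:60)), 1:60)
  expect_error(jpos_to_index(0L))
})

test_that("deletion-type windows read the retained reference flanks", {
  set.seed(41)
  seq1 <- random_seq(3000)
  g <- ref_genome(c(c1 = seq1))
  w <- build_junction_window(g, "c1", 1000, "+", "c1", 2001, "+")
  expect_equal(w$left, substr(seq1, 971, 1000))
  expect_equal(w$right, substr(seq1, 2001, 2030))
  expect_equal(w$joined, paste0(w$left, w$right))
  expect_equal(w$native_after_left, substr(seq1, 1001, 1001))
  expect_equal(w$native_before_right, substr(seq1, 2000, 2000))
})

test_that("inverted sides are reverse-complemented into junction orientation", {
  set.seed(42)
  seq1 <- random_seq(3000)
  g <- ref_genome(c(c1 = seq1))
  # right side retained-upstream, inverted
  w <- build_junction_window(g, "c1", 1000, "+", "c1", 2000, "-")
  expect_equal(w$right, oracle_rc(substr(seq1, 1971, 2000)))
  expect_equal(w$native_before_right, oracle_rc(substr(seq1, 2001, 2001)))
  # left side retained-downstream, inverted
  w2 <- build_junction_window(g, "c1", 500, "-", "c1", 2001, "+")
  expect_equal(w2$left, oracle_rc(substr(seq1, 500, 529)))
  expect_equal(w2$native_after_left, oracle_rc(substr(seq1, 499, 499)))
})

test_that("anchors near contig ends produce N-padded flanks with a warning", {
  g <- ref_genome(c(c1 = strrep("A", 3000)))
  expect_warning(w <- build_junction_window(g, "c1", 10, "+", "c1", 2001, "+"),
                 "N-padded")
  expect_equal(w$left, paste0(strrep("N", 20), strrep("A", 10)))
})

test_that("a GG straddling the junction is called as a novel NGG PAM", {
  left <- paste0(strrep("T", 27), "AAG")            # ends ...A A G
  right <- paste0("GTT", strrep("T", 27))           # begins G T T...
  w <- window_from_strings(left, right, after = "T", before = "C")
  cand <- detect_junction_pam(w)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$motif, "NGG")
  expect_equal(cand$candidate_class, "junction_pam")
  expect_equal(cand$n_jpos, -2L)                    # the A before the G
  expect_equal(cand$grna, substr(paste0(left, right), 9, 28))
  expect_equal(cand$left_overlap, 20L)
})

test_that("a CC straddling the junction is called with a revcomp guide", {
  left <- paste0(strrep("T", 29), "C")
  right <- paste0("C", strrep("A", 29))
  w <- window_from_strings(left, right, after = "A", before = "G")
  cand <- detect_junction_pam(w)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$motif, "CCN")
  # gRNA = revcomp of joined +3..+22 (indices 33..52)
  expect_equal(cand$grna, oracle_rc(substr(paste0(left, right), 33, 52)))
  expect_equal(cand$right_overlap, 20L)
})

test_that("junction bases other than GG/CC yield no junction PAM", {
  w <- window_from_strings(paste0(strrep("T", 29), "A"),
                           paste0("T", strrep("T", 29)))
  expect_equal(nrow(detect_junction_pam(w)), 0L)
})

test_that("pre-existing partner bases in the wild type veto novelty", {
  left <- paste0(strrep("T", 29), "G")
  right <- paste0("G", strrep("T", 29))
  # native continuation after the left flank is G: GG pre-exists on the left
  expect_false(is_junction_pam_novel(
    window_from_strings(left, right, after = "G", before = "T"), "NGG"))
  expect_false(is_junction_pam_novel(
    window_from_strings(left, right, after = "T", before = "G"), "NGG"))
  expect_false(is_junction_pam_novel(
    window_from_strings(left, right, after = "G", before = "G"), "NGG"))
  expect_true(is_junction_pam_novel(
    window_from_strings(left, right, after = "T", before = "C"), "NGG"))
  expect_equal(nrow(detect_junction_pam(
    window_from_strings(left, right, after = "G", before = "T"))), 0L)
})

test_that("spanning guides obey the positional windows and overlap rule", {
  # NGG with N at +6: plant GG at +7,+8 in an otherwise G/C-free window
  left <- strrep("T", 30)
  right <- paste0("TTTTA", "GG", strrep("T", 23))   # N at +5? no: A at +5, GG at +6,+7
  # place N exactly at +6: bases +7 and +8 are G
  right <- paste0(strrep("T", 5), "A", "GG", strrep("T", 22))
  w <- window_from_strings(left, right)
  cand <- detect_spanning_guides(w)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$n_jpos, 6L)
  expect_equal(cand$left_overlap, 15L)
  expect_equal(cand$right_overlap, 5L)
  expect_equal(nchar(cand$grna), 20L)
  # N at +16 mirrors the overlaps
  right2 <- paste0(strrep("T", 15), "A", "GG", strrep("T", 12))
  cand2 <- detect_spanning_guides(window_from_strings(left, right2))
  expect_equal(cand2$left_overlap, 5L)
  expect_equal(cand2$right_overlap, 15L)
  # no G or C anywhere: nothing to find
  expect_equal(nrow(detect_spanning_guides(
    window_from_strings(strrep("T", 30), strrep("T", 30)))), 0L)
})

test_that("spanning-guide detection agrees with the 60-mer brute-force scan", {
  set.seed(44)
  for (i in 1:200) {
    joined <- random_seq(60, gc = 0.5)
    w <- window_from_strings(substr(joined, 1, 30), substr(joined, 31, 60))
    got <- detect_spanning_guides(w)
    want <- oracle_spanning(joined)
    got_keys <- sort(paste(got$motif, got$n_jpos, got$grna))
    want_keys <- sort(paste(want$motif, want$n_jpos, want$grna))
    expect_identical(got_keys, want_keys, info = joined)
  }
})

test_that("every spanning guide is 20 nt with at least 4 nt on each side", {
  set.seed(45)
  for (i in 1:100) {
    joined <- random_seq(60, gc = 0.6)
    w <- window_from_strings(substr(joined, 1, 30), substr(joined, 31, 60))
    cand <- detect_spanning_guides(w)
    if (nrow(cand) == 0L) next
    expect_true(all(nchar(cand$grna) == 20L))
    expect_true(all(cand$left_overlap >= 4L & cand$right_overlap >= 4L))
    expect_true(all(cand$left_overlap + cand$right_overlap == 20L))
  }
})

test_that("reverse-complementing the window maps NGG and CCN candidates 1:1", {
  set.seed(46)
  for (i in 1:100) {
    joined <- random_seq(60, gc = 0.5)
    w <- window_from_strings(substr(joined, 1, 30), substr(joined, 31, 60),
                             after = "T", before = "T")
    rcj <- oracle_rc(joined)
    w_rc <- window_from_strings(substr(rcj, 1, 30), substr(rcj, 31, 60),
                                after = "A", before = "A")
    a <- detect_spanning_guides(w)
    b <- detect_spanning_guides(w_rc)
    expect_equal(nrow(a), nrow(b))
    # guides are preserved as sequences; motif classes swap
    expect_setequal(a$grna, b$grna)
    expect_equal(sum(a$motif == "NGG"), sum(b$motif == "CCN"))
    # junction-created PAMs mirror the same way
    ja <- detect_junction_pam(w)
    jb <- detect_junction_pam(w_rc)
    expect_equal(nrow(ja), nrow(jb))
  }
})

test_that("cohort scan recovers planted junction PAMs and counts by class", {
  fx <- generate_fixture(fixture_spec(seed = 97, n_planted_junction = 5L,
                                      n_neutral_junction = 4L), tempfile())
  bkps <- read_breakpoints(fx$paths$breakpoints)
  res <- analyze_cohort_breakpoints(bkps, fx$genome)
  jp <- res$candidates[res$candidates$candidate_class == "junction_pam", ]
  truth <- fx$ground_truth[fx$ground_truth$type == "junction_pam", ]
  expect_equal(nrow(jp), nrow(truth))
  expect_setequal(jp$grna, truth$grna)
  expect_true(all(c("deletion", "ecDNA") %in% res$candidates$source_class))
  expect_equal(nrow(res$per_sample), 1L)
  expect_equal(res$per_sample$n_breakpoints, 9L)
  # empty breakpoint list -> empty table
  empty <- analyze_cohort_breakpoints(bkps[0, ], fx$genome)
  expect_equal(nrow(empty$candidates), 0L)
})
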