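snv <- function(contig, pos, ref, alt, sample = "s1") {
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
             vtype = "SNV", sample_id = sample, stringsAsFactors = FALSE)
}

test_that("an SNV creating G next to an existing G yields one plus-strand PAM", {
  g <- ref_genome(c(c1 = "CCCCCCCCCCCCCCCCCCCCTAGAA"))
  cand <- scan_snv_for_novel_pams(snv("c1", 22, "A", "G"), g)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$strand, "+")
  expect_equal(cand$gg_start, 21L)              # 1-based (22,23)
  expect_equal(cand$n_pos, 20L)                 # N base is the T at 1-based 21
  expect_equal(cand$pam_3mer, "TGG")
  expect_equal(cand$protospacer, strrep("C", 20))
  expect_true(cand$is_novel)
})

test_that("an SNV creating C next to an existing C yields one minus-strand PAM", {
  g <- ref_genome(c(c1 = paste0("TACT", strrep("A", 23))))
  cand <- scan_snv_for_novel_pams(snv("c1", 2, "A", "C"), g)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$strand, "-")
  expect_equal(cand$gg_start, 1L)               # CC at 1-based (2,3)
  expect_equal(cand$pam_3mer, "AGG")            # read 5'->3' on the minus strand
  expect_equal(cand$protospacer, strrep("T", 20))
})

test_that("a G landing between two reference Gs emits two candidates", {
  g <- ref_genome(c(c1 = paste0(strrep("C", 25), "GAG", strrep("T", 25))))
  cand <- scan_snv_for_novel_pams(snv("c1", 27, "A", "G"), g)
  expect_equal(nrow(cand), 2L)
  expect_setequal(cand$gg_start, c(25L, 26L))   # both overlapping GG pairs
  expect_true(all(cand$strand == "+"))
})

test_that("SNVs that create neither G-next-to-G nor C-next-to-C yield nothing", {
  g <- ref_genome(c(c1 = strrep("A", 60)))
  expect_equal(nrow(scan_snv_for_novel_pams(snv("c1", 30, "A", "T"), g)), 0L)
  # alt G with no neighbouring G
  expect_equal(nrow(scan_snv_for_novel_pams(snv("c1", 30, "A", "G"), g)), 0L)
})

test_that("candidates too close to a contig end are dropped and counted", {
  g <- ref_genome(c(c1 = paste0("AG", strrep("T", 30))))
  cand <- scan_snv_for_novel_pams(snv("c1", 1, "A", "G"), g)  # GG at start
  expect_equal(nrow(cand), 0L)
  expect_equal(attr(cand, "n_dropped_flank"), 1L)
})

test_that("novelty check reads the reference dinucleotide", {
  g <- ref_genome(c(c1 = "AAGGCCAA"))
  expect_true(is_novel_pam(g, "c1", 0, "+"))    # "AA" != GG
  expect_false(is_novel_pam(g, "c1", 2, "+"))   # "GG"
  expect_false(is_novel_pam(g, "c1", 4, "-"))   # "CC"
  expect_true(is_novel_pam(g, "c1", 4, "+"))    # "CC" is not GG
})

test_that("derive_protospacer reads 20 nt 5' of the PAM on the PAM strand", {
  g <- ref_genome(c(c1 = paste0(strrep("C", 20), "TGG", strrep("A", 30))))
  expect_equal(derive_protospacer(g, "c1", 21L, "+"), strrep("C", 20))
  g2 <- ref_genome(c(c1 = paste0("TCCT", strrep("A", 23))))
  expect_equal(derive_protospacer(g2, "c1", 1L, "-"), strrep("T", 20))
  # insufficient flank
  expect_true(is.na(derive_protospacer(g, "c1", 5L, "+")))
})

test_that("insertions can create a junction GG", {
  # reference ...G T..., insert G right after the G
  g <- ref_genome(c(c1 = paste0(strrep("A", 30), "GT", strrep("A", 30))))
  v <- data.frame(contig = "c1", pos = 31, ref = "G", alt = "GG",
                  vtype = "INS", sample_id = "s1", stringsAsFactors = FALSE)
  cand <- scan_indel_for_novel_pams(v, g)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$strand, "+")
  expect_true(cand$indel_derived)
  expect_equal(cand$gg_start, 30L)              # anchored at the reference G
  # protospacer comes from the alt haplotype ending right before the N
  expect_equal(cand$protospacer, strrep("A", 20))
})

test_that("deletions can juxtapose a GG across the removed segment", {
  # ...AG | deleted | GT... -> AG+GT joins G and G
  left <- paste0(strrep("T", 30), "AG")
  mid <- strrep("C", 10)
  right <- paste0("GT", strrep("T", 30))
  g <- ref_genome(c(c1 = paste0(left, mid, right)))
  v <- data.frame(contig = "c1", pos = 32, ref = paste0("G", mid), alt = "G",
                  vtype = "DEL", sample_id = "s1", stringsAsFactors = FALSE)
  cand <- scan_indel_for_novel_pams(v, g)
  expect_true(any(cand$strand == "+" & cand$indel_derived))
  gg <- cand[cand$strand == "+", ][1, ]
  expect_equal(gg$gg_start, 31L)                # the retained G left of the join
})

test_that("neutral insertions yield nothing", {
  g <- ref_genome(c(c1 = strrep("A", 80)))
  v <- data.frame(contig = "c1", pos = 40, ref = "A", alt = "ATTTT",
                  vtype = "INS", sample_id = "s1", stringsAsFactors = FALSE)
  expect_equal(nrow(scan_indel_for_novel_pams(v, g)), 0L)
})

test_that("discovery deduplicates shared dinucleotides and keeps provenance", {
  # two SNVs each creating the same GG at (30,31): C->G at 31 next to ref G
  # at 32, and C->G at 32 next to ref G at 31 cannot both exist; instead use
  # one SNV twice (same record duplicated)
  g <- ref_genome(c(c1 = paste0(strrep("T", 29), "AG", strrep("T", 30))))
  vars <- rbind(snv("c1", 30, "A", "G"), snv("c1", 30, "A", "G"))
  cand <- discover_sample(vars, g)
  expect_equal(nrow(cand), 1L)
  cnt <- attr(cand, "counters")
  expect_equal(unname(cnt[["n_variants"]]), 2L)
  expect_equal(unname(cnt[["n_yielding"]]), 2L)
  expect_equal(unname(cnt[["n_candidates"]]), 1L)
})

test_that("empty variant sets give empty output with zeroed counters", {
  g <- ref_genome(c(c1 = strrep("A", 100)))
  vars <- data.frame(contig = character(), pos = integer(), ref = character(),
                     alt = character(), vtype = character(),
                     sample_id = character(), stringsAsFactors = FALSE)
  cand <- discover_sample(vars, g)
  expect_equal(nrow(cand), 0L)
  expect_equal(unname(attr(cand, "counters")[["n_variants"]]), 0L)
})

test_that("SNV discovery matches the window-diff oracle on random genomes", {
  set.seed(101)
  seq1 <- random_seq(10000, gc = 0.45)
  g <- ref_genome(c(c1 = seq1))
  for (i in 1:300) {
    p <- sample(30:9970, 1)
    ref <- substr(seq1, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    cand <- scan_snv_for_novel_pams(snv("c1", p, ref, alt), g)
    expect_identical(cand_keys(cand), oracle_snv_keys(seq1, "c1", p, alt),
                     info = sprintf("pos %d %s>%s", p, ref, alt))
  }
})

test_that("discovery is strand-symmetric under genome reverse complement", {
  set.seed(202)
  n <- 4000
  seq1 <- random_seq(n, gc = 0.45)
  g_fwd <- ref_genome(c(c1 = seq1))
  g_rev <- ref_genome(c(c1 = oracle_rc(seq1)))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:100) {
    p <- sample(30:(n - 30), 1)
    ref <- substr(seq1, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    fwd <- scan_snv_for_novel_pams(snv("c1", p, ref, alt), g_fwd)
    # mirrored variant: position n-p+1, complemented alleles
    rev <- scan_snv_for_novel_pams(
      snv("c1", n - p + 1L, comp[[ref]], comp[[alt]]), g_rev)
    expect_equal(nrow(fwd), nrow(rev))
    if (nrow(fwd) > 0) {
      # a plus-strand GG at [g, g+2) mirrors to a minus-strand CC at n-g-2
      mirrored <- sort(paste0(n - fwd$gg_start - 2L, ":",
                              ifelse(fwd$strand == "+", "-", "+")))
      expect_identical(sort(paste0(rev$gg_start, ":", rev$strand)), mirrored)
    }
  }
})

test_that("SNV protospacers always occur verbatim in the reference genome", {
  set.seed(303)
  seq1 <- random_seq(8000, gc = 0.5)
  g <- ref_genome(c(c1 = seq1))
  found <- 0L
  for (i in 1:200) {
    p <- sample(30:7970, 1)
    ref <- substr(seq1, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    cand <- scan_snv_for_novel_pams(snv("c1", p, ref, alt), g)
    for (j in seq_len(nrow(cand))) {
      found <- found + 1L
      probe <- if (cand$strand[j] == "+") cand$protospacer[j] else oracle_rc(cand$protospacer[j])
      expect_true(grepl(probe, seq1, fixed = TRUE))
    }
  }
  expect_gt(found, 10L)  # the property was actually exercised
})
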