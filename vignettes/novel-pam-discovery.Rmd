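---
title: "Discovering and ranking tumour-specific CRISPR target sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and ranking tumour-specific CRISPR target sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamscan)
```

## The problem

SpCas9 only cleaves DNA immediately 5′ of an NGG protospacer adjacent
motif (PAM). A somatic mutation that *creates* an NGG absent from the
patient's germline therefore creates a cut site that exists exclusively in
tumour cells: a guide RNA programmed against it can direct knock-in of a
therapeutic payload with genetic, rather than pharmacological,
tumour selectivity. `pamscan` finds such sites in matched tumour/normal
sequencing data, attaches the biological and guide-level evidence needed to
choose among them, and ranks them.

## The detection rule

Since the N of NGG matches any base, a single-nucleotide variant can only
create a new PAM through the GG dinucleotide: a new G adjacent to an
existing reference G (plus strand), or — by symmetry — a new C adjacent to
an existing C, which reads as NGG on the minus strand. `scan_snv_for_novel_pams()`
implements exactly this adjacency rule. Three consequences follow:

* each qualifying dinucleotide is one candidate, so a G landing between two
  reference Gs (GAG → GGG) yields two overlapping docking sites;
* variants that only change the N base are never candidates;
* the created base always falls inside the PAM, never inside the
  protospacer, so SNV-derived protospacers are pure reference sequence —
  tumour specificity is carried by the PAM alone. This is asserted as a
  property test.

Novelty is guaranteed by construction (the reference dinucleotide contained
the reference allele, so it was not GG) and re-verified against the
reference via `is_novel_pam()`.

Small indels (<300 bp, the same cap applied to pipeline input) are handled
by rebuilding the alternate haplotype over a ±25 bp window and rescanning:
any GG/CC in the alternate window that touches edited bases and is absent
at its reference-aligned position (left of the edit unchanged, right of it
shifted by the length difference) is emitted, flagged `indel_derived` so
downstream users can filter it. Whether indel-created PAMs belong in the
candidate set at all is a judgement call — the adjacency rule is stated for
SNVs — so the flag preserves both choices.

Candidates whose 20-nt protospacer would run off the contig are dropped and
counted; candidates from different variants that share a dinucleotide are
deduplicated on (contig, dinucleotide start, strand), with provenance
retained.

## Guide scores

Four per-guide scores are annotated. The fidelity pathway is a precomputed
score table keyed by guide sequence (`load_score_table()`), mirroring how
such scores are normally obtained from an external scoring platform. The
package can also compute specificity itself:

* `enumerate_offtargets()` does a brute-force search of both strands for
  20-mers within 4 mismatches of the guide followed by an NGG or NAG PAM
  (the conventional search space; bulges are out of scope). It is verified
  against an exhaustive Hamming-distance oracle.
* Per-hit similarity: the CFD-style score multiplies position- and
  identity-dependent mismatch penalties with a PAM-class factor; the
  MIT-style score uses the published 20-position weight vector (shipped in
  `inst/extdata/`) with the mean-pairwise-distance and mismatch-count
  terms of that scheme.
* Aggregation to the 0–100 scale is `100 / (1 + Σ s)` over off-target
  similarities, excluding one on-target occurrence. An off-target-free
  guide scores exactly 100, and every added hit strictly lowers the score —
  both are property-tested.

The per-mismatch CFD penalty table is user-supplied
(`load_penalty_model()`, TSV of position/ref/obs/penalty); the package
deliberately ships no reconstruction of it. The default
`uniform_penalty_model()` (every mismatch 0.5, NGG factor 1, other PAMs
0.5) is a transparent flat model adequate for pipeline plumbing and tests;
for publication-grade specificity use the published table or the
score-table import path. On-target efficiency has no in-package
re-implementation of the published regressions either: `table_import` is
the fidelity mode, and `builtin_surrogate` is a documented deterministic
GC/composition heuristic that exists so synthetic pipelines run end to end.
It is clearly not validation-grade and is labelled as such.

## Ranking

Within one sample, every feature is ranked with 1 = worst and n = best:
specificity, efficiency, expression and copy number rank higher-is-better,
and dependency ranks higher (less negative, less essential) as better,
because knocking into an essential gene risks selecting against edited
cells. Missing values take the lowest rank (1), shared; tied values share
the average of the spanned ranks. The composite is the weighted rank sum

S = 2·r(CFD) + r(MIT) + 0.5·(r(Doench) + r(Moreno)) + r(dep) + r(TPM) + r(CN)

with the CFD rank double-weighted for safety and the two efficiency ranks
jointly counting once (their limited predictive accuracy argues against
more weight). S is min–max normalised to 0–100 within the sample and
candidates are sorted into final ranks, exact ties sharing the better rank.

Design choices that the rank-sum statement itself leaves open, decided
here once:

* **Tie method** — average (fractional) ranks, because they preserve the
  rank-sum total regardless of tie pattern, keeping composites comparable.
* **Degenerate normalisation** — one candidate, or an all-tied set,
  normalises to 100: a lone candidate is trivially the most promising.
* **Missing + present** — missing entries all share rank 1 and the present
  values stack above them (so `[NA, 10, 20]` ranks `[1, 2, 3]`).

The report thresholds (≥86 novel PAMs per sample; top-3 CFD > 90 and
MIT > 80, strict inequalities) follow the observed feasibility/safety
operating point for this kind of cohort; both are configurable in
`report_thresholds()`.

## Junction analysis

Rearrangement breakpoints (structural variants, ecDNA circularisation
junctions) juxtapose sequences that are never adjacent in the reference,
which can create PAMs and — more often — uniquely targetable spanning
sequence. For each breakpoint the package builds a 60-nt window: 30
retained bases per side, strand-corrected by the reported orientation so
the joined sequence reads 5′→3′ across the derivative junction. Positions
are numbered −30…−1 and +1…+30 with no zero; the index mapping is tested
to round-trip.

* **Junction-created PAMs**: GG (or CC) at positions (−1, +1). The guide is
  the 20 nt at −22…−3 for NGG, or the reverse complement of +3…+22 for
  CCN. The candidate is kept only when juxtaposition created it — the base
  natively following the left flank and the base natively preceding the
  right flank must both differ from the partner base, otherwise the
  wild-type context already contains the dinucleotide and the site is not
  tumour-specific.
* **Spanning guides**: NGG motifs whose N falls at +6…+16, and CCN motifs
  whose first C falls at −18…−8. These ranges are read as the position of
  the N (respectively the first C); this is the reading that makes the two
  ranges strand-symmetric, and it implies every emitted guide overlaps both
  sides of the junction by 5–15 nt, comfortably clearing the ≥4-nt
  dual-side overlap required for breakpoint specificity. The overlap rule
  is the operational novelty criterion for spanning guides (an optional
  off-target check through the scoring module can be added on top).

Junctions are modelled as clean joins; microhomology and non-templated
insertions at real breakpoints are not represented. Windows near contig
ends are N-padded and any candidate whose guide would include an N is
dropped.

## Cohort statistics

`recurrence()` asks how often the *same* target recurs across patients.
Variant-derived sites are keyed genomically (contig, dinucleotide start,
strand); junction-derived candidates are keyed by motif plus guide
sequence, since junction coordinates differ across patients for what is
functionally the same target. With multiplicity = number of distinct
patients carrying a site, the recurrence rate is the fraction of
site-occurrences belonging to sites with multiplicity ≥2. This definition
is the one under which both published worked examples come out right
(120/8750 → 1.4%, 102/1818 → 5.6%), and both are locked in as tests.

```{r recurrence}
recurrence_from_histogram(c("2" = 50, "3" = 4, "4" = 2), 8750)
```

## The synthetic-data generator

`generate_fixture()` emulates the *inputs* of a tumour/normal analysis at
desk scale: a uniform-random genome at 41% GC (a human-like base
composition), planted PAM-creating SNVs on both strands, planted
single-base insertions creating junction GGs, planted deletion-type
breakpoints whose junction creates a GG, verified-neutral background SNVs
and breakpoints, tiled gene models, and feature tables drawn from
field-plausible distributions (log-normal TPM, copy number 0–8 centred on
2, dependency uniform on [−2, 0.5]). Every planted event is re-detected at
plant time and every neutral event is rejection-sampled against the
detector, so ground truth is exact by construction and recovery tests are
meaningful (sensitivity 1, zero false positives).

What the generator does **not** emulate: mutational signatures, the
gene-dense clustering of real PAM distributions, correlated feature values,
sequencing noise, or germline variation. Passing its tests therefore
demonstrates correctness of the detection/ranking logic, not performance
on real cohorts — per-sample yields on synthetic data should not be read
as biological estimates.

Default sizes (20-kb contig, 10 planted + 90 neutral SNVs, 3 indels, 5 + 5
breakpoints, 20 genes) keep a full pipeline run under a second while still
exercising every code path; the oracle-equivalence suites run on larger
seeded genomes (100 kb, 1000 SNVs per seed, 20 seeds).

## Numerical and degenerate-input conventions

* Internal coordinates are 0-based half-open everywhere; VCF/GTF 1-based
  coordinates are converted on load (`vcf_to_internal()` /
  `internal_to_vcf()` are mutually inverse by test).
* Soft-masked (lowercase) reference sequence is treated as normal sequence;
  non-ACGTN characters become N, and candidates touching N are dropped.
* Variants whose REF allele contradicts the loaded genome are skipped with
  a warning (and counted), not fatal, so toy genomes and build mismatches
  fail visibly but not catastrophically.
* Multi-allelic VCF records are split; FILTER values other than PASS/"."
  are dropped; indels with |Δlen| ≥ 300 are dropped and counted.
* Overlapping-gene assignment prefers the higher-expressed gene, then the
  lexicographically smaller gene_id (deterministic), recording alternates.
* All randomness in the generator flows from the single spec seed; the same
  spec yields byte-identical files.

## Known limitations

Only NGG PAMs are scanned (SpCas9); nearby somatic variants are evaluated
independently, without phasing, so compound haplotype effects are missed;
germline variants are not consulted (a germline-aware mode would remove
candidates whose partner base is polymorphic); the off-target search is
desk-scale brute force, not an FM-index, and is not intended for
whole-genome-scale guide auditing; and the built-in efficiency surrogate is
a placeholder for table import, not a predictor.
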