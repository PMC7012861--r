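---
title: "Identifying and quantifying heat-inducible promoters with hseprom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and quantifying heat-inducible promoters with hseprom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hseprom)
```

## The biology and the model

Stress-inducible transcription of heat-shock protein (*Hsp*) genes is
driven by heat-shock factor (HSF) binding to heat-shock elements (HSEs):
arrays of the 5-bp unit nGAAn arranged as inverted repeats in the promoter.
A promoter rich in HSEs close to the gene is a good candidate for a
heat-switchable expression cassette, which is the practical motivation of
this package: given a draft genome and gene models, find promoters dense in
HSEs, pick a clonable fragment that retains most of them, and quantify the
resulting induction first at the mRNA level (RT-qPCR) and then with a
luciferase reporter.

`hseprom` models an HSE as one of three fixed-length, 15-bp degenerate
consensus geometries, distinguished by the relative orientation and spacing
of their nGAAn/nTTCn units:

| name | consensus |
|---|---|
| tail-tail | `NTTCNNGAANNNNNN` |
| head-head | `NGAANNTCCNNNNNN` |
| step/gap  | `NTTCNNNNNNNTTCN` |

`N` matches any nucleotide; the other letters must match exactly. This is
deliberately not a position-weight-matrix model: the consensus is a crisp
predicate, so a count of HSEs per promoter is exactly reproducible.

## Promoter extraction

The promoter is defined operationally as the fixed-length window
immediately 5' of the translation start: for a gene whose ATG `A` sits at
forward-strand position `p`, the `+`-strand window is `[p - w, p - 1]` and
the `-`-strand window is the reverse complement of `[p + 1, p + w]`, with
`w = 2000` nt by default. The ATG itself is excluded; in all downstream
coordinates the base immediately 5' of the ATG is offset `-1` and a match's
`start_offset` is the offset of its first base (always `<= -15`).

Draft contigs routinely clip upstream regions, so a window running off the
contig end is truncated and flagged (`truncated = TRUE`, with a warning)
rather than rejected. Internally coordinates are 0/1-based per each file
format's native convention: GFF3 and FASTA spans are 1-based inclusive,
BED is 0-based half-open, and `load_genes()` converts.

## Scanning conventions

Three choices pin down what "number of HSEs" means, and each is enforced by
tests:

* **Every (offset, pattern) hit counts.** Overlapping matches are all kept
  and a window matching two geometries (possible, e.g.
  `ATTCGGGAAGATTCA` is simultaneously tail-tail and step/gap) counts once
  per geometry. Any merging rule would introduce a free parameter; counting
  all hits is the one convention that is reproducible from the pattern
  definitions alone.
* **Sense strand by default.** The patterns are defined relative to the
  gene and already encode the inverted-repeat geometry, so the default scan
  reports a single per-promoter count. `both_strands = TRUE` additionally
  scans the reverse complement and reports hits at the mirrored sense
  offset.
* **Conservative ambiguity handling.** A sequence letter outside
  `{A,C,G,T}` (including `N`) matches a consensus `N` but never a fixed
  letter — an unknown base cannot be asserted to equal a specific one. A
  fully-`N` sequence therefore matches nothing. Only complete 15-nt windows
  are tested; there are no partial matches at promoter edges.

The production scanner is vectorised; `brute_force_oracle()` re-implements
the same contract as an explicit per-position, per-letter loop with no
shared code, and the test suite checks their equivalence on a thousand
random 2-kb sequences per run.

## Clusters, fragments, ranking

For construct design two summaries matter: where the HSEs sit, and how much
upstream sequence must be cloned to keep most of them.

* `cluster_matches()` chains matches whose start offsets are within
  `max_gap` of each other (single linkage). The default `max_gap = 50` nt
  separates visually distinct HSE groups at a 2-kb scale while keeping
  adjacent/overlapping hits together; it is a named, overridable parameter,
  not a biological claim.
* `select_fragment()` returns the smallest fragment `[-L, -1]` containing
  at least `ceiling(min_fraction * n)` of the gene's `n` matches. The
  default `min_fraction = 0.8` operationalises "most of the HSEs"; real
  construct endpoints are also constrained by primer practicality, which is
  out of scope, so the result is an explicit surrogate. A promoter with no
  HSEs returns the full promoter, flagged.
* `rank_promoters()` orders genes by total HSE count, ties broken by gene
  id, so the ranking is deterministic.

## qPCR fold induction

Relative quantification uses the Livak 2^-ddCt method with an assumed
amplification efficiency of 2 and no efficiency correction. Technical
replicates are averaged first (a dispersion flag marks cells whose
technical range exceeds 0.5 cycles); dCt references each target to the
reference gene within the same condition and biological replicate; ddCt is
computed per biological replicate between treatment and control, paired by
replicate index (an unpaired mode referencing the mean control dCt is
available); and fold induction is `2^-ddCt`, summarised by its arithmetic
mean and SD over replicates.

The significance test is a two-sided pooled-variance (Student)
independent-samples t-test applied to the dCt values, not to the folds:
dCt is approximately normal on the cycle scale while folds are log-normal.
Degenerate inputs are handled explicitly rather than silently: two
constant, equal groups raise an undefined-statistic error (surfaced as a
flag by the pipeline); constant groups with different means report an
infinite statistic with the p-value at the positive underflow limit,
flagged `zero_variance` — which is exactly what noiseless simulated data
produce.

## Reporter analysis

Each lysate is normalised to specific activity (RLU per µg protein) before
any averaging, so fold induction — `mean(heat-shock) / mean(control)` — is
invariant to rescaling either the luminometer or the protein assay. The
heat-shock and control conditions are paired within the same recovery
timepoint; the per-construct peak is the timepoint of maximum fold, ties
resolved to the earliest. Multi-construct comparisons use fixed-effects
one-way ANOVA on the raw specific activities (a `log_scale` option gives
the variance-stabilised alternative) followed by Tukey HSD on all pairs.

The compact letter display is computed from the maximal cliques of the
non-significance graph (enumerable exactly for the ≤ 15 groups a promoter
comparison involves), ordered from the highest group mean. This makes the
display *exact*: two groups share a letter if and only if their
Tukey-adjusted p-value is at least α — a property a greedy single-letter
assignment cannot guarantee when significance is non-transitive, and one
the test suite asserts on randomised fixtures.

## What the synthetic data emulate — and what they do not

`gen_promoter_set()` builds one contig per gene: a spacer-only upstream
region with built-in consensi planted at known offsets, followed by a short
gene body, alternating genes between the two contig strands. Its defining
trick is composition: spacers and all `N` positions are drawn only from
`{C, G}`, so the fixed core triplets (TTC/GAA/TCC) are the only source of
A/T. A spurious match would need a core at the right relative position, and
with planted motifs kept at least 30 nt apart start-to-start no 15-nt
window can span two motifs, so sense-strand scanning recovers exactly the
planted (offset, type) set. The 30-nt spacing is deliberate: at tighter
spacings two planted motifs can conspire to form an unplanned third
geometry (e.g. a step/gap's second TTC plus a downstream motif's TTC), so
the spacing is part of the exactness guarantee, and the oracle re-verifies
the guarantee on every generated set in the tests.

`gen_ct_dataset()` mirrors the standard design — three biological × three
technical replicates, one shared reference gene — with Gaussian Ct noise
per technical replicate (default SD 0.2 cycles) and the heat-shock shift
`-log2(true_fold)` applied to the target. `gen_reporter_dataset()` follows
the reporter time-course design (0, 1, 2, 4, 6, 12, 24 hr recovery, n = 5)
with a monotone log-linear ramp reaching the construct's induction ratio at
the 6-hr point and mean-one log-normal multiplicative noise (default CV
0.15); luminescence is generated as specific activity times a noisy protein
amount, so the normalisation path is genuinely exercised.

What the generators do *not* emulate: realistic genome composition (GC
skew, repeats, real promoters contain incidental near-HSE sequence),
amplification-efficiency differences between primer pairs, inter-plate and
batch effects, or saturation of the luciferase assay. Passing tests
demonstrate that the computations are correct and that parameter recovery
is unbiased at the stated noise levels — not that any particular biological
promoter will behave as predicted.

## Numerical choices and problem sizes

* Promoter records, matches and counts are plain data frames; sequences
  travel as `Biostrings::DNAStringSet` objects and all FASTA/GFF3/BED I/O
  goes through Biostrings/rtracklayer.
* All generators consume one explicit integer seed and restore the global
  RNG state (`withr::with_seed`), so fixtures are byte-reproducible.
* The test suite verifies scanner–oracle equivalence on 1,000 random
  2,000-nt sequences, exact recovery of planted counts on 100 synthetic
  genes with per-type counts up to 10, and ddCt parameter recovery over
  200 simulations at true folds {2, 32, 585} (geometric-mean estimate
  within 10% of truth at Ct noise SD 0.2, n = 3); these sizes make the
  whole suite run in well under a minute per property while keeping
  Monte-Carlo error small relative to the asserted tolerances.

## A worked example

```{r example}
# ground-truth genome: 5 genes, (2, 1, 1) HSEs planted per gene
g <- gen_promoter_set(5, c(2, 1, 1), seed = 42)
prom <- extract_promoters(g$genome, g$genes)
matches <- scan_promoters(prom)
rank_promoters(hse_count_table(matches, prom$gene_id))

# minimal fragment keeping >= 80% of gene g001's HSEs
select_fragment(prom[1, ], matches[matches$gene_id == "g001", ])

# qPCR: recover a 32-fold induction from noisy Ct data
ctt <- gen_ct_dataset(data.frame(gene = "target", true_fold = 32),
                      noise_sd = 0.2, seed = 7)
ddct_analysis(ctt, "28s_rrna")
```

## Known limitations

* The ATG is the only anchor: transcription start sites, 5' UTRs and
  spliced annotations are not modelled, so the "promoter" is a fixed
  operational window.
* The consensus predicate has no affinity model; two promoters with equal
  counts may differ greatly in HSF occupancy.
* Whether published per-promoter HSE counts deduplicate overlapping or
  multi-type windows is generally unstated; this package's convention
  (count every hit) is pinned by tests but other tools may differ.
* No multiple-testing correction is applied across genes in the qPCR
  module, matching common single-gene reporting practice; apply
  `p.adjust` downstream if many genes are screened.
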