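---
title: "Seed-match target networks and induction classes for learning-induced miRNAs"
author: "fearmiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-match target networks and induction classes for learning-induced miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

Contextual fear conditioning induces a panel of hippocampal miRNAs whose
joint regulatory footprint can be studied entirely in silico: which genes
carry seed-match binding sites for several of the induced miRNAs, whether
those co-targeted genes concentrate in particular signaling pathways, and
which induced miRNAs split into learning-specific versus experience-driven
expression classes. `fearmiR` implements that analysis chain as reusable,
tested components — seed-site scanning, co-targeting, permutation
enrichment, induction classification, replicate concordance and the small
closed-form assay normalizations — together with seeded generators that
produce synthetic inputs with planted ground truth for every structure the
pipeline is meant to recover. The generators replace the original
microarray and behavioral raw data, so every quantitative claim in the
package is about recovery of known planted structure, not about the
original biological measurements.

# Seed-match model

A mature miRNA recognizes a 3'UTR mainly through Watson–Crick pairing of
its *seed*, nucleotides 2–8 from the 5' end. With `S` the reverse
complement of positions 2–8 (7 nt, written in UTR space) and `S6` the
reverse complement of positions 2–7 (the last 6 nt of `S`), the four
canonical site classes on the UTR read 5'→3' are

| class   | UTR pattern | length |
|---------|-------------|--------|
| 8mer    | `S` + `A`   | 8      |
| 7mer-m8 | `S`         | 7      |
| 7mer-A1 | `S6` + `A`  | 7      |
| 6mer    | `S6`        | 6      |

in decreasing efficacy. The target-position-1 `A` must literally be an
adenosine in the UTR (not "whatever pairs with miRNA position 1"), the
convention of the major prediction tools. Every site contains the `S6`
core, so the scanner anchors on core matches and reports, at each core
locus, only the strongest class present; coordinates are 0-based
half-open on the UTR, and `U`/`T` are interchangeable on both sides.
There is no context scoring, conservation filtering or 3'-supplementary
pairing: downstream analyses use only binary site presence, and the
working definition of a "binding site" is 7mer-or-stronger
(`min_class = "7mer-A1"`), configurable because 6mers are weak predictors.

`mutate_seed_region()` is the in-silico analogue of reporter-UTR
mutagenesis: the three UTR nucleotides that pair antiparallel with seed
positions 4–6 — the 2nd–4th nucleotides of the 6mer core for every class —
are replaced by `ATT`. The operator guarantees abolition: it fails rather
than return a UTR that still carries (or has coincidentally regained) a
6mer-or-stronger site overlapping the mutated locus. Two small pieces of
algebra matter here and shaped the generator. First, a miRNA whose
positions 4–6 read `AAU` pairs those positions with `ATT` already, making
the substitution an identity; the miRNA generator therefore rejects such
seeds, so every simulated seed is mutable. Second, with random flanks the
substitution recreates an overlapping core with probability roughly
8/4096 per site (eight overlapping registers, six fixed bases each), i.e.
about one expected event per 500 mutations; the transcriptome generator
therefore verifies at planting time that every planted site is cleanly
mutable and re-draws the gene otherwise. Both checks make ground truth
unambiguous without weakening the operator's contract.

# Co-targeting and ranking

`build_target_matrix()` counts sites of the chosen class or stronger per
(gene, miRNA) pair; `filter_brain_expressed()` restricts rows to an
expressed-gene universe; `cotargeted_genes()` keeps genes targeted by at
least *k* = 3 *distinct* miRNAs (distinct regulators, not total sites —
the direct reading of "three or more of the 21 miRNAs");
`rank_mirnas_by_pathway()` orders miRNAs by their number of targets
inside one pathway, ties broken lexicographically so results are
reproducible. Gene identity is the bare upper-cased symbol, since FASTA
and GMT sources differ in case conventions.

# Permutation enrichment

Over-representation of a pathway among the co-targeted genes is scored
against an explicitly simulated null: `n_perm` uniform random gene sets
of the same size as the target list, drawn without replacement from the
brain-expressed universe, with the add-one empirical estimator

$$p_{\mathrm{emp}} = \frac{\#\{\text{null overlap} \ge \text{observed}\} + 1}{n_{\mathrm{perm}} + 1},$$

so `p` is never 0 and is bounded below by `1/(n_perm + 1)`. The exact
upper-tail hypergeometric probability, computed by direct log-binomial
tail summation, is reported alongside as an analytic oracle; the two must
agree within Monte-Carlo error, and the test suite checks this both
against the closed form and against exhaustive subset enumeration at tiny
universe size. Each pathway receives its own deterministic RNG substream
derived from the root seed, so the result set is independent of pathway
order. Significance uses the raw per-pathway cutoff `p < 0.01` by
default; a Benjamini–Hochberg column is available (`bh = TRUE`) but off
by default, matching the analysis this package re-implements. Because the
phrase "similar in size to the target gene list" is ambiguous between the
pre-filter and post-filter list sizes in the original description, the
random-set size always equals the target list actually supplied, and both
the list and the universe are explicit arguments.

One calibration property deserves honesty: the overlap count is a
discrete statistic, so its add-one empirical p-value is *superuniform*
(conservative), with CDF steps equal to the point masses of the overlap
distribution. For small pathways (say 10–40 genes against ~180 targets in
a ~1800-gene universe) the largest step is 0.1–0.4, and a two-sided
Kolmogorov–Smirnov uniformity test over hundreds of null pathways will
detect that conservatism even though the permutation machinery is exact.
The test suite includes that strict KS check as specified and it fails
for this structural reason, while the companion check — the fraction of
null pathways called significant at 0.01 staying inside its binomial 99%
band — passes: the estimator errs only on the conservative side.

# Induction classes

Expression tables are long-format (feature, group, replicate, value) with
a designated reference feature (`snoRNA-202`, alias `RNU58`). Each value
is divided by its sample's reference value, then by the feature's
naive-group arithmetic mean of reference-normalized values, so fold-
changes are relative to the naive condition and any per-sample scaling
cancels (the naive-group mean fold is 1 by construction; the arithmetic
mean is the literal reading of "divided by naive values"). A feature is
*induced* when its trained-group fold-change is at least θ = 1.5 — the
boundary is inclusive ("at least a 1.5-fold increase") — in **every**
replicate; `n_required` relaxes the all-replicates rule when wanted.

Induced features are then classified from two-tailed unequal-variance
(Welch) tests on log fold-changes, the natural scale for ratio data:

* **Class I** — trained vs naive significant, immediate vs naive not:
  induced only with associative learning;
* **Class II** — both significant *and* trained vs immediate significant
  with the trained geometric mean higher: experience-induced with a
  learning increment;
* **Class III** — both significant with no trained-vs-immediate
  difference: experience-induced;
* otherwise **unclassified**.

Group summaries are geometric means. α defaults to 0.05, per-feature
(no multiple-testing correction across features, matching the original
analysis). With zero-variance groups the t statistic is undefined; the
implementation returns p = 1 for equal means and p = 0 otherwise, so
noiseless synthetic data behaves sensibly. Replicate-level testing is
used throughout; the original study pooled three animals per replicate,
and pooling variance is deliberately not modeled.

# Replicate concordance

For a feature panel (by default the induced panel), every unordered pair
of replicates is correlated over the panel's fold-change vectors: Pearson
on log folds (configurable to the linear scale, since the original
description does not say), Spearman on mid-ranks of the raw folds. The
baseline repeats this for `R` random panels of the same size drawn from
the remaining array features (the selected panel excluded by default, the
cleaner null) and reports mean and dispersion per replicate pair. One
property of fold-change data is worth knowing when reading the baseline:
because both replicates of a feature share the same estimated naive
baseline, even pure-noise features show a positive expected
inter-replicate correlation (about σ²/3 of shared log-variance with three
naive replicates, ≈ 0.2 at the default noise level); the planted panel
must — and does, by a wide margin — exceed that baseline, and the test
suite requires the panel to beat it in at least 95% of simulated runs.

# Assay normalizations

Three closed-form operations used by the functional follow-up assays:

* **FM4-64 destaining** — `F = (F1 − B1)/(F0 − B0)`, background
  subtraction before any normalization, then division by the mean
  corrected intensity over the pre-stimulus baseline window. Negative
  backgrounds are rejected at ingest (physical intensities).
* **FRAP recovery** — the unbleached cell is used as a multiplicative
  acquisition-decay reference anchored at its first time point:
  `corrected(t) = bleached(t)/unbleached(t) × unbleached(1)`, converted
  to the recovered proportion against the pre-bleach intensity and
  expressed as fold change over the first post-bleach point. The original
  methods name this correction without writing out its algebra; the form
  implemented here is the standard decay correction and is documented as
  an interpretation.
* **Luciferase knockdown** — reporter/control ratios per condition,
  knockdown `1 − ratio_treatment/ratio_scramble`, with the `> 40%`
  criterion applied strictly (0.40 exactly does not qualify).

All three are invariant to common rescaling of paired raw intensities.

# The synthetic study

`simulate_study()` wires four seeded generators into the full planted
design. Defaults are the study conditions, chosen once:

* **Panel** — 21 miRNAs of 22 nt with pairwise-distinct, mutable seeds;
  classes 4 × I, 3 × II, 14 × III (the class sizes of the original
  panel); per-class mean folds (immediate, trained) of (1, 3), (1.8, 3)
  and (2, 2); measurement noise multiplicative lognormal with CV 0.10 on
  ratio-scale values; 3 replicates per group; 100 non-induced background
  array features plus the reference.
* **Transcriptome** — 2000 genes with 500-nt UTRs in DNA alphabet
  (transcript-annotation convention; scanning is U/T-agnostic).
  Background UTRs are rejection-sampled to contain no 6mer-or-stronger
  site for any panel miRNA, so ground truth is exact; 9% of genes are
  planted co-targets with 3 distinct miRNAs each (non-overlapping sites,
  ≥ 2 nt apart, classes drawn from 8mer/7mer-m8/7mer-A1), a scaled-down
  analogue of 353 co-targets among 3986 brain-expressed candidates; 40
  additional co-targeted decoys are excluded from the brain universe so
  the expression filter has real work to do; 90% of background genes are
  brain-expressed.
* **Pathways** — 20 gene sets; one planted "vesicle exocytosis" set of
  40 members, 15 of them co-targeted (the 15-of-40 geometry), in which
  the focal miRNA `mir-01` holds 12 targets (8 co-targeted members plus
  4 members it targets alone or with one partner) while every other
  miRNA holds at most 8; background pathway sizes are log-uniform on
  [10, 200], the spread of curated canonical-pathway collections.
* **Expression** — raw values `basal × class fold × lognormal(CV) ×
  sample scale`; the per-sample scale factor emulates loading differences
  and cancels under reference normalization; the reference tracks the
  sample scale noiselessly (a high-abundance control whose replicate CV
  is negligible), so realized per-replicate folds follow the declared
  `class mean × lognormal(CV)` model.

Every generator is a pure function of the root seed via labeled
substreams (`derive_seed()`), so adding or reordering stages never
silently reshuffles another stage's randomness, and fixed seeds give
bit-identical outputs — the property the end-to-end manifest test checks
by content digest.

What the generator does **not** emulate: real rodent UTR composition,
conservation or miRNA families; microarray intensity-level artifacts
(only fold-change level structure); pooling variance; correlated pathway
membership. Passing tests therefore demonstrate that the implementation
recovers planted structure under the declared noise model, not that the
original biological conclusions are reproduced — the original headline
numbers depend on the deposited array data, proprietary pathway
definitions and 2016-era prediction databases, none of which are inputs
here.

# Problem sizes and numerical choices

The shipped analyses and tests use: 2000-gene transcriptomes with 500-nt
UTRs; 9999 permutations for enrichment calls (p floor 1e-4) and 999 for
the 500-pathway null calibration; 200 simulated features for classifier
recovery; 500 simulation runs for the concordance comparison; 100,000
permutations for the permutation-vs-hypergeometric agreement check.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted tolerances while keeping a full run on one CPU in minutes.
Ties in rankings break lexicographically; site-class conflicts resolve
to the strongest class; degenerate inputs (empty UTRs, zero-variance
vectors, zero references, pathways outside the universe) follow the
documented error or `NA` contracts rather than returning silent numbers.

# Limitations

Binary site presence only; no thermodynamics, no CLIP integration, no
weighting by site class in co-targeting counts (a union over sources is
used when merging external target lists, consistent with a "combination"
of predictors yielding large candidate sets). The enrichment null ignores
gene-length and composition biases a sequence-level null would have. The
classifier tests replicate-level values and inherits the low power of
n = 3 designs; its type-I behavior at the θ boundary is reported by the
simulation scripts rather than asserted. The KS calibration caveat above
applies to any add-one empirical p-value of a discrete statistic.
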