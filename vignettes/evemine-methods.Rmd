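---
title: "Mining and dating endogenous herpesvirus-like elements: models and methods"
author: "evemine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and dating endogenous herpesvirus-like elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evemine)
```

## The problem

Herpesviruses occasionally integrate into host germline telomeres and are
then inherited like any other locus. Such endogenous viral elements (EVEs)
surface in draft whole-genome assemblies as contigs that look viral by
translated homology but carry the scars of long residence in the genome:
premature stop codons and frameshifts throughout their genes, a junction
where host chromosome runs into viral sequence through a telomeric repeat
(TMR) array, and — because telomeric hexamer repeats defeat short-read
assemblers — fragmented, truncated contigs. `evemine` implements the full
desk-side analysis of such candidates: discovery by six-frame translated
search, junction detection, molecular dating of the integration,
coding-degradation profiling, mate-pair-guided targeted scaffolding, and a
contig-composition PCA. A synthetic-genome generator with complete ground
truth makes every stage testable without touching archived sequencing
projects.

## The synthetic study system

`viral_genome_model()` builds a schematic roseolovirus-like genome: a
unique region of synthetic ORFs flanked by two direct-repeat (DR) blocks,
each containing an imperfect internal TMR array and a perfect terminal
(TAACCC)~n~ array. It is a layout, not a reconstruction of any real viral
genome: no exogenous ancestor of the element that motivated this package
is known, so the coding sequences are random sense codons and only the
architecture (ORFs, DRs, perfect/imperfect TMR pairs, telomeric termini)
is meaningful. `synthetic_host()` supplies a chromosome end: random flank
plus a (TTAGGG)~n~ telomere. `embed_viral_insertion()` splices the virus
into the telomere after evolving it neutrally for a chosen age, recording
full ground truth (junction coordinates, per-ORF disruption recomputed
from the mutated sequence, raw substitution counts).

Defaults are the study conditions: a 294 bp (49-copy) perfect terminal
array; integration age 75 My at the mammalian neutral rate
2.2×10^-9^ subs/site/yr (so the terminal repeat diverges by ~0.165
subs/site); 100 bp read pairs at 30× with truncated-normal insert sizes
(mean 300, sd 30, floor at twice the read length); error-free reads by
default. Spacers adjacent to TMR arrays are rejection-sampled free of
telomeric-family hexamers so that array boundaries, and hence junction
truth, are sharp by construction.

The mutation process is a per-site continuous-time Markov chain under a
user-supplied GTR model (`gtr_model()`), simulated event by event with
exponential waiting times; `rate * time` is therefore the expected number
of raw substitution events per site, multiple hits and reversions
included. The default equal-rates/uniform-frequency model reduces to
Jukes–Cantor, for which closed-form distances provide an independent
oracle in the tests. Indels are not simulated by default: the dating
stage assumes a positionally alignable repeat, and an indel channel would
change the estimand. What the generator does **not** emulate — platform
error profiles, real repeat landscapes (LINEs/SINEs/ERVs) in the flank,
biased composition, realistic assembler behaviour — bounds what passing
tests show: they validate the algorithms on their stated assumptions, not
performance on any particular archived assembly.

`fragment_assembly()` models the one assembler failure that matters here:
every run of ≥ `min_copies` telomeric-family hexamers becomes a break
window and loses a centred gap (default 60 bp). Contigs plus gaps tile the
genome exactly, which the tests assert by re-splicing.

## Translated homology discovery

Queries are per-cluster consensus sequences (`build_consensus()`:
plurality residue per column at a support threshold, `X` otherwise,
all-gap columns dropped). `six_frame_translate()` uses the standard code,
renders stops as `*` and N-containing codons as `X`, and drops trailing
partial codons.

`translated_search()` is exhaustive affine-gap Smith–Waterman (Rcpp)
against all six frames — deliberately *not* a re-implementation of BLAST
heuristics (seeding, two-hit extension, composition-based statistics are
out of scope). Per frame, non-overlapping locally optimal hits are
enumerated by masking the best hit's footprint and re-aligning, which is
deterministic and directly checkable against a quadratic-time oracle; the
test suite verifies score identity against an independent dynamic
programming implementation on hundreds of random instances including
reverse-strand plants. E-values follow Karlin–Altschul,
`E = K m n exp(-lambda S)`, with the published ungapped BLOSUM62
parameters (lambda = 0.3176, K = 0.134) and `n` the total translated
search-space length; this reproduces BLAST-like *ranking* at desk scale
without finite-size corrections, and the tests pin the exact property
that doubling the search space doubles every E-value.

The shortlist filter keeps hits ≥ 50 aa long with E ≤ 10^-10^. The source
phrasing of this filter is ambiguous as printed ("below 1E-10 …
discarded" would discard the *best* hits); `filter_policy()` defaults to
discarding non-significant hits and exposes the literal reading as an
option. `reciprocal_classify()` re-searches a candidate region against
viral and non-viral protein sets and compares best bit scores; exact ties
go to `ambiguous`, never silently to `viral`, because such cases were
hand-curated in the original analysis.

## TMR arrays and junction calling

A telomeric repeat family is the closure of a hexamer under rotation and
reverse complement — TTAGGG, ATTGGG and TAACCC all name the same family in
different phases and strands. `find_tmr_arrays()` canonicalizes to the
lexicographically smallest family member, counts maximal non-overlapping
intact copies, and merges occurrences spaced ≤ `max_gap` bp (default 6,
one motif unit) so single point mutations do not split an array. Purity
is intact copies over hexamer windows spanned, invariant to the rotation
chosen to name the motif. Orientation is defined per strand only.

`call_junction()` emits a call at every array that cleanly separates a
side with viral hits from a side with host evidence and no viral hits,
placing the coordinate at the array edge nearest the viral side — the
junction *is* the array, and the edge is where unique viral sequence
begins. Because internal DR arrays also separate cleanly, calls are
sorted by host proximity and the outermost call is the junction of
record. On simulated insertions at age 0 the junction coordinate is
recovered within one motif unit in ≥ 99% of replicates. Host evidence is
positional truth in simulation; on real contigs it is user-supplied
annotation, since repeat/gene annotation of flanks is out of scope.

`terminal_overlap()` aligns contig termini ends-free (Biostrings) in both
arrangements and orientations, reporting length, mismatches and gap count
— the report one needs to decide whether two contigs share a DR, without
asserting *which* DR, which cannot be known from overlap alone.

## Dating the integration

The dating logic rests on one observation: at integration, the terminal
TMR was a perfect hexamer repeat, so every deviation from perfection
accumulated *after* endogenisation at the host's neutral rate.

The pipeline (`date_integration()`) is: extract the window from the first
to the last intact motif copy (degraded internal copies retained;
`extract_anchored_window()` anchors on the family variant with most exact
occurrences, so the phase follows the observed repeat); tile a perfect
ancestor of the same length (`build_perfect_repeat()`); pair sites
positionally, or through a global affine alignment with gap columns
dropped when lengths differ (`pair_sites()`, refusing < 50 paired sites);
estimate divergence (`estimate_gtr_distance()`); and convert to age.

### The divergence estimator

This is an ancestor→descendant divergence, not a distance between two
contemporary sequences, and the estimator is built around that fact in
two ways.

First, the likelihood is the *conditional* paired-sites likelihood
`sum N[a,b] log P[a,b](d)` with the ancestral distribution fixed at its
empirical value. A stationary two-taxon GTR likelihood
(`sum N[a,b] log(pi[a] P[a,b])`) assumes the ancestor is a draw from the
model's stationary composition; a perfect TAACCC repeat — one third C on
one phase, no G at all — is nowhere near stationarity, and in recovery
simulations the stationary form overestimated divergence by roughly a
factor of two. Second, the generator is normalized to unit substitution
flux *under the ancestor composition*, so the branch length is reported
as expected substitutions per site actually experienced by this sequence
— the scale on which a per-year neutral rate applies.

At ~300 sites a full 9-parameter GTR fit is close to saturated and
inflates d by a Jensen-type bias (5–14% in our simulations). The
estimator therefore fits two nested parameterizations — equal
exchangeabilities (frequencies and d free) and the full six-exchangeability
model — and keeps the BIC-preferred one. Parameter economy at a few
hundred sites, not a change of model family: the equal-rates model *is*
GTR at an interior point. With this rule, median relative bias over
d_true ∈ {0.05, 0.165, 0.3} at 294 sites is within ±1.3%, and on exactly
JC-symmetric counts the estimate matches the closed form
`-(3/4) ln(1 - 4p/3)` to < 10^-3^.

Numerics: optimization by `nlminb` on log/softmax-transformed parameters
(d, 5 log exchangeabilities with GT fixed, 3 frequency logits), matrix
exponentials through the symmetrized eigensystem of the reversible
generator, non-finite likelihoods fenced. If ML fails, a log-det
(paralinear) estimate is returned tagged `logdet-fallback`; if that is
singular too the data are declared saturated and an error is raised
rather than a number invented. Zero off-diagonal counts short-circuit to
d = 0.

One caveat is inherent to the window definition: anchoring the window on
intact copies conditions ~12 bp at its ends to be unmutated, a small
downward bias on end-to-end estimates from single arrays (the
whole-pipeline recovery envelope is ±15% at 294 bp, versus ±5% for the
estimator alone on unanchored windows). The alternative — including
partially degraded edges — would make the window boundary arbitrary; the
motif-anchored definition follows the original analysis.

### Age conversion

`distance_to_age()` computes `t = d / r` and **never halves**: the
divergence spans one lineage from a known ancestral state, not two
lineages from a common ancestor. The no-halving semantics are encoded in
the result; a `pairwise` escape hatch exists but flips a `halved` flag so
misuse is visible downstream, and every estimate carries the standing
warning that repeat-array substitution may be non-neutral, which is
surfaced rather than modelled. Both conventional rates (2.2×10^-9^
mammalian, 3×10^-9^ small-prosimian) are reported side by side by
default; full precision is kept throughout, so 0.165/2.2e-9 prints as
75 My, with any difference from a rounded headline number attributable
to rounding of intermediates, not to the conversion.

Which array to date is a scientific choice the software cannot make: only
the terminal arrays were ancestrally perfect, and the original analysis
chose its substrate by inspection. `date_integration()` auto-selects the
array with the most intact copies × purity, and takes `array_index` when
the user — or the truth channel of a simulation — knows better.

## Coding degradation and provenance

`profile_orf_integrity()` mirrors how tBLASTn evidence presents on a
degraded contig: translated local alignments of the reference protein are
collected in all six frames, the majority strand (by summed score) is
kept, hits are chained greedily by score with non-redundant query
coverage, and each transition between chained segments in different
frames counts one frameshift. Premature stops are `*` inside aligned
segments (or same-frame gaps between them); a terminal stop beyond the
last reference-aligned residue is never premature. Frameshift counts are
invariant under reverse complement, which the tests assert.

`classify_provenance()` encodes the published evidence rules as a
deterministic table: disrupted-ORF fraction ≥ D (default 0.5, a package
choice — the source says only "nearly all genes") or a host junction ⇒
endogenous-like; zero disruptions, no junction, no transposable-element
flag ⇒ exogenous-like; anything else ambiguous. TE acquisition is an
external boolean input, since repeat annotation is out of scope.

## Targeted scaffolding

The original edge extension was manual, "tens of bases at a time", with
an eye-ball quality assessment; this module is that process automated
with explicit, conservative thresholds. Reads are indexed by k-mer
(k = 21) on both strands of both mates. Per iteration, reads anchored by
an exact edge k-mer are verified over ≥ 30 bp of overlap at ≤ 2%
mismatches, and the edge grows by the column-wise majority of overhanging
bases while ≥ 3 reads support every base. Extension stops
deterministically on ambiguity (a second base with sufficient support —
ties never resolved by chance), exhaustion, or a 500 bp cap
(`max_append`): targeted extension needs to reach a neighbouring contig
an insert-length away, and an uncapped walk at 30× would traverse the
whole template, making every contig pair mutually containing. No appended
base ever has support below the threshold, asserted across all
simulations.

Linking merges a contig whose extended sequence is wholly contained in
another's (a short contig overshot by its neighbour's extension) and
otherwise joins termini on near-exact suffix/prefix overlaps ≥ 30 bp.
Conflicting joins (one edge, two partners) are left unjoined and
reported; circular chains are reported, not constructed. An expected
gene-order hint demotes contradicting joins to "flagged" rather than
applying them. On error-free 30× pairs over a template split into three
contigs with 100 bp gaps, the composite reproduces the template exactly —
and, on the full synthetic chromosome, extension stops *ambiguous* inside
the perfect telomeric junction array, faithfully reproducing the
assembler failure the module exists to work around.

## Composition PCA

`contig_features()` computes 28 variables per contig: mean, median,
minimum and maximum per-base coverage depth; the 4 mononucleotide and 16
overlapping-window dinucleotide frequencies (N positions excluded); and
mean, median, minimum and maximum insert size over properly placed pairs.
The published enumeration of these variables lists 25 items under a count
of 28; the counts reconcile exactly if the four summary statistics apply
to coverage depth as well as insert size, which is the reading adopted
here. Contigs with no aligned pairs are null-flagged and excluded from
the PCA with a report.

`contig_pca()` standardizes by default (the features mix frequencies with
bp-scale inserts — the source does not state its scaling, so this is a
recorded package choice) and eigendecomposes via `prcomp`.
`outlier_assessment()` turns the qualitative "do the viral contigs sit
apart?" question into a seedable label-permutation test on the distance
between the flagged-group centroid and the overall centroid in PC1/2. It
is a diagnostic, labelled as such in reports: calibration simulations in
the test suite check its type-I behaviour, and a single flagged contig
degrades to a distance-only report.

## Problem sizes and reproducibility

The test and acceptance workloads are sized for a laptop: dating recovery
uses 500 replicates per divergence level at 294 sites; the search oracle
runs 200 random instances up to 200 aa × 1 kb; junction recovery uses 200
age-0 insertions; scaffolding benchmarks use ~3 kb templates at 30×; the
analysis scripts use a ~12 kb synthetic chromosome end. All randomness
flows through explicit seeds; every generator function is reproducible
given its `seed` argument, and the acceptance script derives everything
from a single `--seed`.

## Known limitations

* The viral model is schematic; nothing here reconstructs a real exogenous
  ancestor, and conclusions about any archived assembly require running
  the same functions on the archived contigs.
* Dating assumes positional alignability of the repeat and neutral,
  site-independent substitution; the non-neutrality caveat is surfaced on
  every estimate but not modelled, and no confidence intervals are
  attached (bootstrap machinery is out of scope).
* The homology stage is exhaustive rather than heuristic: fine at contig
  scale, not a tool for scanning large databases.
* Provenance classification is a rule table over explicit evidence; it
  does not attempt to distinguish exapted, still-active captured genes
  from drifting sequence.
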