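---
title: "Methods: comparative genomics and physiology of ViI-like phages"
author: "PhageCompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics and physiology of ViI-like phages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhageCompare)
```

PhageCompare implements the analysis chain used to characterize ViI-like
myoviruses — genome annotation, three-way proteome comparison, distance
phylogenetics, and one-step growth physiology — together with synthetic-data
generators that plant known ground truth for every stage. This vignette is
the package's methods account: the models and rules implemented, the
parameters that matter and why their defaults are what they are, the
numerical decisions taken where the underlying conventions are loose, and
what the synthetic benchmarks do and do not demonstrate about real data.

## Gene calling with a Shine–Dalgarno screen

A candidate gene is a stop-codon-bounded stretch of one of the six reading
frames that begins at an ATG, GTG, CTG or TTG start codon, runs for at least
`min_extra_codons` (default 30) further codons before its in-frame stop, and
— when `require_sd = TRUE` — carries an upstream sequence resembling the
Shine–Dalgarno ribosome-binding consensus `GGAGGT`. "Resembling" is
operationalized as the best ungapped placement of the hexamer within the
`sd_window_bp = 15` bases 5' of the start codon matching at
`sd_min_matches = 4` or more of its six positions. Both numbers are
parameters because the biological criterion is qualitative; 4/6 within 15 bp
is a common working rule that accepts the canonical variants (`AGGAGG`,
`GGAG`, `GAGG` cores) while rejecting most random sequence (a uniform-random
window passes with probability ≈ 0.25, which is exactly why gene calls on
random DNA are dominated by the length criterion, not the SD screen).

Within one stop-bounded frame segment the caller reports the upstream-most
start codon that satisfies all criteria — the longest open reading frame —
because start-codon choice among several candidates was historically a
manual curation step that an algorithm should not pretend to reproduce.
Overlapping calls on the same or opposite strands are all reported; no
greedy resolution is attempted. Reported coordinates are 1-based inclusive
and include the stop codon, so `end − start + 1 = 3 (n_codons + 1)`.

Circular genomes are scanned across the origin by logically appending the
first `wrap_bp` bases (default `3 (min_extra_codons + 2)` = 96 bp, the
shortest callable gene) and de-duplicating: calls starting past the origin
copy are dropped, and calls sharing one stop codon keep only the longest
(a rotation can expose an origin-truncated segment whose true upstream-most
start lies across the origin). The default window therefore guarantees
rotation invariance only for genes up to 96 bp past the origin; users
expecting long origin-spanning genes should raise `wrap_bp`, and the
rotation-invariance property test does exactly that.

Translation uses the bacterial genetic code (table 11); GTG/CTG/TTG
initiators are rendered as methionine, trailing stops are removed, and an
internal stop is an error naming the codon position. Ambiguity codes other
than `N` are rejected at read time because the scanners assume a four-letter
alphabet; codons containing `N` translate to `X`.

## σ70 promoter scanning

The scan reports every placement, on both strands, of the −35 hexamer
`TTGACA` and the −10 hexamer `TATAAT` separated by a 15–18 nt spacer with
`mm35 + mm10 ≤ promoter_max_mismatches`. The default budget is 0 (exact
consensus): with mismatches allowed the hit count explodes combinatorially
on A+T-rich phage DNA, and any particular nonzero budget is arbitrary, so
fuzziness is exposed as a parameter rather than baked in. Overlapping
placements with different spacers are all reported. For hits on the minus
strand, `pos_minus35` is the leftmost forward-strand coordinate of the −35
element, keeping every reported position in a single coordinate system. The
count of promoters a real genome yields at a given budget is
threshold-sensitive, and the package deliberately treats it as descriptive
rather than as a calibrated quantity.

## Reciprocal-best-hit orthology and the triad partition

Protein pairs are aligned locally (Smith–Waterman) under BLOSUM62 with
affine gap penalties 11/1 — community defaults for protein search. Identity
is identical columns over aligned columns with gap columns in the
denominator; coverage is the aligned span on the shorter protein over the
shorter length. Which sequence anchors the coverage rule is genuinely
ambiguous in standard practice, so it is a parameter
(`coverage_mode = "shorter"` default, with `"query"` and `"both"`
alternatives; the acceptance script records the conserved-gene count under
all three).

Locus *x* of proteome A pairs with *y* of proteome B when each is the
other's best-scoring hit and both directions clear
`min_identity = 40`% and `min_coverage = 80`%. Score ties break by higher
identity and then lexicographic locus id, making the procedure fully
deterministic. Because local alignment scores under a symmetric substitution
matrix are direction-symmetric, one all-against-all pass per genome pair
suffices; the pairing is provably symmetric under genome swap, which the
test suite checks rather than assumes. Strict one-to-one reciprocal best
hits are the default; `pairing = "best_qualifying"` restricts the
best-hit search to threshold-passing candidates first, which is the other
defensible reading of "reciprocal comparison with thresholds" and matters
when a paralog outscores the true ortholog but fails coverage.

The triad partition computes the three pairwise tables and classifies each
locus: **conserved** when it sits in a triple mutually linked by all three
tables, **unique** when it has no threshold-qualifying hit in either other
genome (not merely no reciprocal pair — a locus shadowed by a paralog is
shared, not unique), and **shared-two** otherwise. These three classes
partition each proteome exactly, which is enforced as a class validity
invariant.

Core-genome audits reuse the same machinery with laxer defaults
(`min_identity = 30`, `min_coverage = 50`) because the genes conserved
across the whole T4 superfamily are distant homologs that the 40/80 rule
would miss. Region-level identity (for tail-spike domain comparisons)
offers a gapless mode — strict column-by-column identity over equal-length
ranges, the mode in which printed domain-identity percentages are
reproducible — and a global mode that end-gap-aligns the two excised
regions. Its significance estimate is a Karlin–Altschul-style
approximation (gapped BLOSUM62 parameters λ = 0.267, K = 0.041) and is
labelled approximate: E-values are program- and version-dependent and are
not treated as a reproducible surface.

Synteny blocks chain ortholog anchors sorted by position in the first
genome into maximal runs whose positions in the second advance by exactly
±1 with a consistent sign; the synteny fraction is the share of anchors in
runs of length ≥ 2, and circularly permuted genomes may merge the first and
last run across the origin.

## Poisson distances, neighbor joining, bootstraps

From a protein alignment, each pair's mismatch proportion *p* is computed
over comparable sites — columns where neither row has a gap or unknown
(`-`, `X`, `?`, `.`, `*`) — and corrected for multiple hits as
*d* = −ln(1 − *p*). Pairwise deletion is the default because treating gaps
as unknown states is naturally a per-pair decision; complete deletion
(dropping a column for all pairs) is available as `deletion = "complete"`
since distance programs differ on this point. A pair with *p* = 1 has
infinite corrected distance and raises a saturation error naming the pair;
a pair with no comparable sites is likewise an error, not a silent zero.

The neighbor-joining implementation is the standard Saitou–Nei
agglomeration on the Q-criterion, written in the package rather than
delegated so that its tie-breaking (first minimal Q cell in row-major
order — deterministic under taxon order) and its negative-branch rule are
explicit: a negative branch estimate is clamped to zero with the deficit
transferred to its sibling, so returned trees never carry negative lengths
while total tree length is preserved where possible. On additive matrices
the algorithm recovers the generating tree exactly (topology and branch
lengths), which the tests verify against trees drawn with `ape` and
distances from `cophenetic`; `ape::nj` serves as an independent
cross-check of topology on noisy matrices, never as the implementation.

Bootstraps resample alignment columns with replacement, rebuild the tree
per pseudoreplicate (100 by default), and report for each internal split of
the full-data tree the percentage of replicate trees containing it, as
integer node labels. Replicates in which a pair saturates are skipped with
a warning and the denominator adjusted. All resampling flows through the
user's seed, and identical seeds give identical supports. Maximum-likelihood
and parsimony supports are out of scope: the NJ leg is the fully
self-contained one.

## One-step growth curves, lysis inhibition, label uptake

The one-step estimators operationalize the visual readings of a classic
growth experiment. Titers are treated as log-normally distributed, so
baselines are geometric means. The **eclipse period** is the first sample
at which total phage (chloroform-released, i.e. including intracellular
mature phage) exceeds `rise_factor = 2` times the running geometric-mean
baseline; the **latent period** is the analogous first rise of infective
centers (lysis begins); the **burst size** is the plateau of total phage
divided by the baseline of infective centers. The plateau is found by
smoothing the log-titers with a centered three-point mean, locating the
first post-rise point where the smoothed successive change falls below 10%
(the rise has ended), and taking the geometric mean of all later raw
points — using every plateau sample keeps the burst estimate stable under
multiplicative noise. The 2× threshold and 10% plateau tolerance are
exposed parameters; both are operationalizations of by-eye readings, and
the estimators are scale-invariant in the titers by construction. A series
that never rises reports `rise_detected = FALSE` with an undefined (not
zero) burst.

**Lysis inhibition** — the T4-style high-MOI phenotype in which culture
turbidity keeps climbing long after infection before a late, gradual lysis
— is flagged when the OD600 maximum reaches `od_ratio_threshold = 2` times
the OD at infection *and* lysis onset (first sample below 90% of the
running OD maximum) is later than `onset_threshold_min = 60` minutes. A
monotonically rising OD leaves the onset undefined and the flag falls back
to the ratio criterion with a warning.

**Label uptake** fits least-squares slopes of acid-precipitable counts
versus time for an infected culture and a control; incorporation is flagged
when the infected slope exceeds `min_fraction = 0.1` of the control slope
and is significantly positive (one-sided t-test, α = 0.05; a perfect
noise-free fit with zero residual variance is treated as significance by
sign). A non-positive control slope is an error — it means the label or
the control culture failed, and no classification of the infected series
is meaningful.

## What the synthetic generators emulate — and what they do not

All generators derive their randomness from one user seed through named
substreams, restore the caller's RNG state, and are byte-identical under a
fixed seed.

`simulateGenome()` draws background DNA at a requested GC (default 44.5%,
a typical ViI-like value) and plants non-overlapping gene cassettes and
exact-consensus promoters on random strands. Each cassette carries its SD
hexamer 7 bp upstream of the start, an in-frame stop immediately before the
start codon, and a stop-free body, which makes the planted start the
upstream-most qualifying start of its segment — so exact-coordinate
recovery is a designed property of the truth, not luck. Planted elements
sit in otherwise random sequence, so the caller also reports background
ORFs; the tests require those to equal an independent brute-force scan, not
to be absent. What the generator does **not** emulate: codon usage bias,
operonic gene packing, overlapping genes, mobile elements, or promoters
correlated with gene starts. Perfect recall on this substrate therefore
demonstrates correctness of the scanning logic, not annotation accuracy on
real genomes, where start-codon choice and spurious short ORFs remain
genuinely hard.

`simulateTriad()` builds shared families by mutating a common random
ancestor independently per genome at a per-site substitution probability
(uniform over the 19 alternative residues; no indels by default, a deletion
rate as an option), plus independent random unique genes, with shuffled,
recorded gene orders. Two family members at divergence 0.3 retain ≈ 50%
expected identity at full coverage, comfortably above the 40/80 rule, while
unrelated random proteins essentially never reach 80% coverage at 40%
identity — so planted precision/recall of 1.0 checks the reciprocal logic
and thresholds, not the hard cases (domain shuffling, paralogous families,
length variation) that real proteomes contain. Divergence ≥ 0.5 is
rejected outright as a saturation guard.

`simulateGrowth()` produces a piecewise one-step curve: titers flat at the
baseline until eclipse, a log-linear rise whose first post-eclipse sample
already sits ~4× above baseline (intracellular phage accumulate fast
relative to a 5-minute sampling interval), plateau at `burst ×` baseline by
`latent + 10` minutes, with multiplicative log-normal noise of coefficient
of variation `cv`. The default grid is 25 samples over 120 minutes — the
5-minute interval typical of one-step experiments — and estimator accuracy
for eclipse/latent is inherently limited to one sampling interval, a
resolution caveat the tests encode explicitly. The high-MOI variant adds an
OD trajectory that roughly triples before declining from 90 minutes.
`simulateLabel()` produces linear count trajectories with Gaussian noise.
Neither generator models adsorption kinetics, survivor regrowth, or
saturating scintillation counts.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use: random genomes up to
10 kb for oracle-equality checks and 6 kb across 20 seeds for recall;
the full planted triad at 147 shared families (~160–170 proteins per
genome, mean 300 aa) once, with smaller triads for the property sweeps;
NJ round-trips on trees of up to 8 taxa; 100 bootstrap pseudoreplicates;
and 50 noisy growth-curve draws. These sizes exercise every code path in a
few minutes on one CPU while keeping the planted-truth guarantees exact;
all of them scale up by argument.

## Known limitations

* GenBank parsing is a minimal flat-file reader (LOCUS, DEFINITION,
  ACCESSION/VERSION, CDS/tRNA features with common qualifiers, ORIGIN);
  joined locations are collapsed to their outer span with a message, which
  is adequate for phage records but not for spliced eukaryotic entries.
* The ORF caller requires a terminating stop codon; genes running off the
  end of a contig (or past the circular wrap window) are not called.
* tRNA detection, functional annotation, HMM/domain search and membrane
  topology are out of scope; alignments are consumed, not built.
* The promoter count and the shared-homolog count are threshold-sensitive
  descriptive statistics, not calibrated quantities.
* NJ is the only tree method; for publication-grade phylogenies the
  distance trees here are the reproducible baseline, not a replacement for
  likelihood methods.
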