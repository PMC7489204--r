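---
title: "Benchmarking substitution matrices on simulated divergent evolution"
author: "SubMatBench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking substitution matrices on simulated divergent evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SubMatBench)
```

## The problem

A pairwise protein alignment is only as good as the substitution matrix
and gap penalties behind it, but on real sequences there is no ground
truth to score an alignment against. SubMatBench takes the simulation
route: evolve two descendant sequences from a common ancestor under an
explicit stochastic model, so the *reference alignment* — the set of
residue pairs descending from the same ancestral position — is known by
construction. An algorithmic alignment can then be scored exactly, and
matrices and penalty settings compared on equal footing.

Two quality measures are used throughout. With $I$ the number of residue
pairs shared by the reference and algorithmic alignments, $R$ the
reference pair count and $A$ the algorithmic pair count,

$$\mathrm{Accuracy} = I/R, \qquad \mathrm{Confidence} = I/A .$$

Accuracy asks "how much of the truth did we recover", Confidence "how much
of what we reported is true". Gap columns are never comparisons. When a
local alignment comes back empty ($A = 0$) its Confidence is defined as 0
and the pair stays in the average — on distant test sets a matrix that
finds nothing should pay for it.

## The evolutionary model

The simulator is the Dayhoff PAM point-substitution model plus an
empirical indel process.

**Ancestor.** A Bernoulli-scheme sequence of 200 residues (a typical
polypeptide length), drawn i.i.d. from the Dayhoff background
composition bundled with the package.

**Indels (stage 1).** Each ancestor position is checked once for an indel
event, with probability

$$P(\mathrm{indel}) = 0.0224 - 0.0219\, e^{-0.01168\,\mathrm{PAM}},$$

an empirical saturating law in the branch length. On an event, insertion
before the position or deletion starting at it is chosen equiprobably;
the length is Zipf, $P(L) \propto L^{-1.7}$, truncated at 50 residues.
Deleted stretches are not re-checked, insertions do not create new event
sites, and deletions truncate at the sequence end. The indel literature
constrains the length law's shape but not its exact parameters, so
exponent and truncation are package defaults, fixed once and exposed as
arguments (`zipfExponent`, `zipfMax`); an alternative semantics with
independent insertion and deletion checks per position is kept behind
`indelChecks = 2`.

**Substitutions (stage 2).** Every surviving ancestral position passes
through `pam` cycles of the PAM1 mutation-probability matrix (1 PAM = 1
accepted substitution per 100 residues). Because the cycles form a
homogeneous Markov chain, the package composes them into a single draw
from $\mathrm{PAM1}^{\mathrm{pam}}$ per position — distributionally
identical to the literal loop and far cheaper; `cycles = "explicit"`
keeps the literal path, and the test suite checks the two agree in law.
Inserted residues are drawn from the background composition and never
mutated afterwards: substitutions happen only in material inherited from
the ancestor.

Two descendants are evolved independently, so a pair labelled "PAM 30"
is separated by roughly 60 PAM of total branch length. The reference
alignment matches positions surviving in both descendants:

```{r}
pr <- evolvePair(pam = 30, length = 200, seed = 7)
pr
referenceAlignment(pr)
```

**Calibration.** The identity-versus-distance curve implied by the
bundled PAM1,

```{r}
c(PAM30 = expectedIdentity(30), PAM60 = expectedIdentity(60),
  PAM120 = expectedIdentity(120))
```

decreases from 1 toward the random floor
$\sum_i f_i^2 = `r round(randomIdentity(), 4)`$, passing through the
twilight zone (roughly 10–35 % identity) between about 120 and 330 PAM.
`pamFromIdentity()` inverts this curve: identities down to 15 % use the
directly tabulated range (up to 328 PAM); identities in 10–15 % use a
monotone cubic through six anchors of the extended curve, and anything
below 10 % is reported as a right-censored bound (`"> X"`) because the
curve is numerically flat there.

## The aligners

Global (Needleman–Wunsch) and local (Smith–Waterman) alignment with an
affine gap cost are implemented as a three-state Gotoh dynamic program in
C++. Conventions, fixed package-wide:

* a gap of length $L$ costs $\mathrm{GOP} + (L-1)\,\mathrm{GEP}$;
* terminal gaps are penalized in global mode (the simulated references
  are end-to-end); `freeEndGaps = TRUE` relaxes this;
* scores are real-valued — the classical penalty grids use extensions as
  small as 0.1, so integer arithmetic would be wrong;
* traceback ties prefer residue pair over gap in the second sequence over
  gap in the first, applied from the alignment end, and local alignments
  prefer continuing over restarting on ties — output is bit-reproducible;
* matrices are used as distributed, with no rescaling.

The test suite checks both modes against an oracle that enumerates every
monotone set of residue pairs for sequences up to 7 residues and scores
them in closed form (no dynamic programming), against a linear-gap DP in
the GOP = GEP case, and against independent re-scoring of the returned
alignment at longer lengths.

## The benchmark

`evaluateGrid()` aligns every pair of a test set at every (GOP, GEP) cell
and macro-averages Accuracy and Confidence per cell (unweighted over
pairs, not pooled counts — each simulated pair is one experiment).
`selectOptimum()` picks the cell maximizing the *worse* of the two
metrics, a conservative choice that refuses to trade Confidence for
Accuracy; ties break toward the cheaper penalty. `rankMatrices()` orders
matrices by the mean of the two optimal values, `localGlobalRatio()`
contrasts algorithms, and `correlationReport()` gives all-pairs Pearson
correlations over the 210 unique elements of each symmetric matrix
(upper triangle with diagonal, so off-diagonal entries are not double
counted).

The default grid is GOP $\in \{3, 4, \ldots, 30\}$, GEP
$\in \{0.1, 0.2, 0.5, 1, 2, 3, 4, 8\}$. Cells are independent work
units: results are identical regardless of evaluation order, and a
sub-grid reproduces the corresponding cells of the full grid exactly.

Bundled matrices are the canonical NCBI PAM30/PAM120/PAM250 and
BLOSUM45/50/62 tables; PAM60 is generated from the bundled Dayhoff PAM1
by the log-odds construction in half-bit units (its file marks it as
generated). `pamLogOdds()` generates a log-odds matrix at any distance,
on the half-bit or the original 10·log10 scale; generated and published
tables differ by rounding, so benchmarks default to the bundled files.
Any other matrix loads from NCBI/EMBOSS square text format via
`readScoreMatrix()`. All-positive variants (`positiveShift()`) add
$1 - \lfloor\min\rfloor$, preserving score differences exactly.

## Reproducibility and problem sizes

Everything stochastic is seeded. A test set derives one seed per pair,
`(seed + 1000003 k) mod (2^31 - 1)`, so sets are reproducible and
independent of generation order; `runBenchmark()` writes a JSON manifest
(seed, grid, matrix fingerprints) alongside its TSV outputs and re-runs
byte-identically.

The package's reference study conditions are 1000 pairs of 200-residue
sequences per distance in {30, 60, 120} PAM. At those sizes the
simulator statistics reproduce, at one fixed seed: sequential
(ancestor–descendant) identity 0.752/0.582/0.378 and divergent
(descendant–descendant) identity 0.583/0.379/0.204 — the divergent
identity of a PAM-$p$ set matching the sequential identity at PAM $2p$,
as the Markov model predicts. The test suite runs simulator calibration
at n = 1000 and alignment-quality checks at n = 300 pairs, where a grid
cell (300 alignments of ~200-residue pairs) takes well under a second;
penalty-grid searches in the tests restrict to neighbourhoods of known
optima to keep the cell count small. These sizes are the package's
choices for its own checks; all functions take arbitrary n.

## What the simulation does and does not show

The generator emulates divergence with known ground truth: realistic
composition, distance-dependent substitution, power-law indels. It does
not model site heterogeneity (conserved cores versus loops), structural
constraints, compositional bias across proteomes, or domain
rearrangements. Passing benchmarks here therefore demonstrate that a
matrix recovers alignments *under the PAM model's assumptions* —
consistent with the model family the PAM matrices themselves derive
from, which is also why PAM-series matrices rank near the top on these
test sets. Curated reference alignments from structural benchmarks
(ingested via `readReferenceMsa()`/`msaPairAlignments()`) probe the
complementary, model-free regime; their pair sampling is user-defined,
so numeric results on them are not part of the package's reference
checks.

## Known limitations and numerical notes

* The indel sub-model is the least constrained part: with the default
  Zipf(1.7, ≤ 50) law the sequential indel fraction at PAM 30 comes out
  near 0.027–0.028; reproducing published indel fractions near 0.033
  would need a longer-tailed length law (mean indel length ~4.9 instead
  of ~4.1). Identity statistics are insensitive to this choice.
* `pamFromIdentity()` is only as sharp as the curve is steep: around 20 %
  identity a 0.1 % identity shift moves the inverted distance by ~1.5
  PAM, and different published identity-distance tables disagree by a few
  PAM in that region.
* The matrix reader symmetrizes by averaging only below an asymmetry of
  1e-6; genuinely asymmetric tables are rejected rather than silently
  averaged.
* Grid evaluation is single-threaded; cells are independent, so callers
  can parallelize over cells or matrices externally without changing
  results.
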