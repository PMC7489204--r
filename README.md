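# SubMatBench

Benchmarking amino-acid substitution matrices on simulated divergent
evolution, for people who need to know *which matrix and which gap
penalties* to trust at a given evolutionary distance.

On real sequences there is no ground truth to score an alignment
against. SubMatBench therefore simulates it: an ancestor sequence is
drawn from the Dayhoff background composition and two descendants are
evolved from it independently — Zipf-length insertions/deletions at the
empirical per-position rate `P(indel) = 0.0224 − 0.0219·exp(−0.01168·PAM)`,
then point substitutions through the PAM1 mutation-probability matrix,
one cycle per PAM unit. Positions that survive in both descendants define
the **reference alignment**. Algorithmic alignments (affine-gap
Smith–Waterman and Needleman–Wunsch, compiled Gotoh DP) are scored
against it with

    Accuracy = I/R        Confidence = I/A

where `I` is the number of residue pairs shared by reference and
algorithmic alignment, `R` and `A` their pair counts. A gap-penalty grid
(GOP 3–30, GEP 0.1–8) is scanned per matrix, the optimum maximizes
`min(Accuracy, Confidence)`, and matrices are ranked by the mean of the
two optimal values. Canonical PAM and BLOSUM tables are bundled; any
NCBI/EMBOSS-format matrix file loads with `readScoreMatrix()`.

## Worked example

Distant homologs (a 120-PAM test set — about 20 % residue identity):
which matrix recovers the true alignment, locally?

```r
library(SubMatBench)

ts <- generateTestSet(pam = 120, n = 300, length = 200, seed = 42)
testSetStats(ts)[c("divergentId", "divergentIndel")]
#> $divergentId
#> [1] 0.2028003
#> $divergentIndel
#> [1] 0.1184402

g250 <- evaluateGrid(ts, scoreMatrix("PAM250"), "local",
                     penaltyGrid(gop = c(10, 12, 14), gep = c(0.5, 1)))
g30  <- evaluateGrid(ts, scoreMatrix("PAM30"),  "local",
                     penaltyGrid(gop = c(3, 4, 5),    gep = c(0.5, 1)))
rankMatrices(list(g30, g250))
#>   matrix gop gep  accuracy confidence      mean
#> 2 PAM250  14 0.5 0.7424915  0.8051700 0.7738307
#> 1  PAM30   5 1.0 0.1573253  0.2840034 0.2206643
```

The pairs really are in the twilight zone (20.3 % identity), and the
distance-matched matrix dominates: PAM250 recovers ~74 % of the true
residue pairs where PAM30 recovers ~16 % — even though the two matrices
are highly correlated as score tables
(`matrixCorrelation(scoreMatrix("PAM250"), scoreMatrix("PAM30"))` =
0.928). Correlation between matrices says little about alignment
performance; distance matching is what counts.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/matbench.R simulate --pam 120 --n 1000 --length 200 --seed 1 --out sim/
Rscript inst/cli/matbench.R bench --pam 120 --n 300 --matrices PAM30,PAM250 \
        --modes local,global --out results/
```

See the vignette (`vignettes/benchmarking-substitution-matrices.Rmd`)
for the model, its assumptions, and every numerical convention.

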