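# Shared simulated test sets, generated once per session. Seed 42 is the
# suite-wide convention for simulated data.

.set_cache <- new.env(parent = emptyenv())

cached_set <- function(pam, n) {
  key <- sprintf("p%d_n%d", pam, n)
  if (is.null(.set_cache[[key]]))
    .set_cache[[key]] <- generateTestSet(pam, n = n, length = 200, seed = 42)
  .set_cache[[key]]
}

# mean accuracy/confidence of one penalty cell, via evaluateGrid
cell_quality <- function(ts, matname, mode, gop, gep) {
  gr <- evaluateGrid(ts, scoreMatrix(matname), mode,
                     penaltyGrid(gop = gop, gep = gep))
  gridCells(gr)
}

# per-pair accuracy/confidence vectors at one penalty cell (for bootstrap)
cell_per_pair <- function(ts, matname, mode, gop, gep) {
  m <- scoreMatrix(matname)
  out <- lapply(seq_len(length(ts)), function(k) {
    pr <- ts[[k]]
    ref <- referenceAlignment(pr)
    r <- if (mode == "local") localAlign(pr@s1, pr@s2, m, gop, gep)
         else globalAlign(pr@s1, pr@s2, m, gop, gep)
    scoreAlignment(ref, r@alignment)
  })
  do.call(rbind, out)
}
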