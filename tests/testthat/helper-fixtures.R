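## Shared fixtures, built once per test run.

# full-resolution phantom at the study conditions (1.5 mm grid)
.phantomCache <- new.env()

defaultTestPhantom <- function() {
  if (is.null(.phantomCache$ph))
    .phantomCache$ph <- buildPhantom(phantomSpec())
  .phantomCache$ph
}

# coarse phantom for cheap structural tests
coarseTestPhantom <- function(...) buildPhantom(phantomSpec(spacing = 3, ...))

# memoized full comparisons, keyed by (sigma, seed)
comparisonFor <- function(sigma = 3, seed = 1L) {
  key <- sprintf("cmp_%g_%d", sigma, seed)
  if (is.null(.phantomCache[[key]]))
    .phantomCache[[key]] <- runComparison(
      runConfig(plans = defaultPlans(sigma = sigma), seed = seed))
  .phantomCache[[key]]
}

# small uniform dose grid helper
uniformGrid <- function(dose, dims = c(4, 4, 4), spacing = 1.5,
                        nFractions = 1L) {
  doseGrid(array(dose, dims), spacing, nFractions = nFractions)
}
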