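## Internal helpers.

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
## state afterwards so library code never perturbs the global stream.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.rowVars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

## condition label used throughout: "T0.control", "T24.urea", ...
.conditionOf <- function(sheet) paste(sheet$timepoint, sheet$treatment,
                                      sep = ".")
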