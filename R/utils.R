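# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. A NULL seed leaves the RNG untouched.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Timepoints are numeric hours; compare with a tolerance so 6 and 6.0000001
# (e.g. after CSV round trips) land in the same cell.
tp_match <- function(x, timepoint_h, tol = 1e-8) {
  abs(x - timepoint_h) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
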