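## Shared fixtures: a small, fast synthetic cohort (short recordings,
## "available" segmentation) cached per test run.

smallSynthConfig <- function(seed = 11L, ...) {
  synthConfig(duration = 35, seed = seed, ...)
}

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- force(expr)
  .fixtureCache[[key]]
}

## 6 + 6 recordings of 35 s -> 7 segments each under the available policy
smallCohort <- function() {
  cached("smallCohort", generateCohort(smallSynthConfig(), 6, 6))
}

smallTensors <- function() {
  cached("smallTensors",
         featurizeCohort(smallCohort(), policy = "available"))
}

## a fast classifier spec for protocol tests (not the study conditions)
fastSpec <- function(seed = 1L) modelSpec("gbdt", nTrees = 40L, seed = seed)

## deterministic pseudo-random sequences without touching the global RNG
lcgSequence <- function(n, seed) {
  state <- as.double(seed %% 2147483647)
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    out[i] <- state / 2147483647
  }
  out
}
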