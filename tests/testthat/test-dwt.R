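## Closed-form test signal: mixed sinusoids at 7, 40 and 1.3 Hz sampled at
## 250 Hz.  The frozen coefficients below were computed once with an
## independent reference wavelet implementation (sym6, symmetric
## half-sample extension, 5 levels).
dwtTestSignal <- function() {
  i <- 0:1249
  sin(2 * pi * 7 * i / 250) + 0.5 * sin(2 * pi * 40 * i / 250) +
    0.3 * sin(2 * pi * 1.3 * i / 250 + 0.5)
}

test_that("five-level sym6 decomposition matches the reference toolkit", {
  co <- dwtDecompose(dwtTestSignal(), waveletConfig())
  expect_named(co, c("A5", "D5", "D4", "D3", "D2", "D1"))
  expect_equal(lengths(co),
               c(A5 = 49L, D5 = 49L, D4 = 88L, D3 = 165L, D2 = 320L,
                 D1 = 630L))
  frozen <- list(
    A5 = c(3.97876599824307, 3.31329060513072, 3.37445849532164),
    D5 = c(-2.84798989980227, 0.313977648027839, 0.0779266740207385),
    D4 = c(0.614194531047292, -0.0973480177515656, 0.14068479897387),
    D3 = c(0.544187811913937, -0.55668638168419, 0.0886934929031294)
  )
  for (sb in names(frozen)) {
    expect_equal(co[[sb]][1:3], frozen[[sb]], tolerance = 1e-12)
  }
})

test_that("decomposition is linear and rejects undecomposable inputs", {
  cfgW <- waveletConfig()
  zero <- dwtDecompose(numeric(1250), cfgW)
  expect_true(all(vapply(zero, function(c) all(c == 0), logical(1))))

  x <- dwtTestSignal()
  co1 <- dwtDecompose(x, cfgW)
  co3 <- dwtDecompose(3 * x, cfgW)
  expect_equal(co3$D4, 3 * co1$D4, tolerance = 1e-12)

  expect_error(dwtDecompose(rnorm(8), waveletConfig(levels = 5)),
               class = "decompositionError")
  expect_error(waveletConfig(selectedSubbands = "D9"),
               class = "invalidConfigError")
})

test_that("inverse transform reconstructs the segment", {
  cfgW <- waveletConfig()
  for (n in c(1250L, 777L, 100L)) {
    x <- lcgSequence(n, seed = n) - 0.5
    co <- dwtDecompose(x, cfgW)
    r <- dwtReconstruct(co, cfgW, n)
    expect_lt(max(abs(r - x)) / max(abs(x)), 1e-8)
  }
})

test_that("sub-band frequency ranges follow the dyadic rule and tile", {
  expect_equal(subbandFrequencyRange(5, 250), c(3.90625, 7.8125))
  expect_equal(subbandFrequencyRange(1, 2), c(0.5, 1.0))
  expect_equal(subbandFrequencyRange(5, 250, "approximation"),
               c(0, 3.90625))

  ## {A5, D5..D1} tile (0, 125] without gaps or overlap
  edges <- c(subbandFrequencyRange(5, 250, "approximation"))
  for (lev in 5:1) {
    band <- subbandFrequencyRange(lev, 250)
    expect_equal(band[1], edges[length(edges)])
    edges <- c(edges, band[2])
  }
  expect_equal(edges[length(edges)], 125)
})
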