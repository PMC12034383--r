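test_that("transform reproduces hand-computed phasors", {
  # delta decay: all photons in bin 0 -> unit vector at angle 0, every harmonic
  f <- phasor_transform(decay_stack(c(10, 0, 0, 0, 0, 0, 0, 0), FREQ), 1:3)
  for (j in 1:3) {
    expect_equal(f$G[1, 1, j], 1)
    expect_equal(f$S[1, 1, j], 0)
  }
  # uniform counts: full-period trigonometric sum vanishes
  f <- phasor_transform(decay_stack(rep(7, 16), FREQ), 1)
  expect_equal(f$G[1, 1, 1], 0, tolerance = 1e-14)
  expect_equal(f$S[1, 1, 1], 0, tolerance = 1e-14)
  # B=4, counts [1,1,0,0]: direct 4-term sum gives (0.5, 0.5)
  f <- phasor_transform(decay_stack(c(1, 1, 0, 0), FREQ), 1)
  expect_equal(c(f$G[1, 1, 1], f$S[1, 1, 1]), c(0.5, 0.5))
})

test_that("vectorised transform agrees with the brute-force summation oracle", {
  set.seed(7)
  for (rep in 1:5) {
    counts <- rpois(32, 20)
    if (sum(counts) == 0) counts[1] <- 1
    f <- phasor_transform(decay_stack(counts, FREQ), c(1L, 3L))
    for (j in c(1L, 2L)) {
      n <- c(1L, 3L)[j]
      o <- oracle_phasor(counts, n)
      expect_lt(abs(f$G[1, 1, j] - o[["G"]]), 1e-12)
      expect_lt(abs(f$S[1, 1, j] - o[["S"]]), 1e-12)
    }
  }
})

test_that("transform rejects aliasing harmonics, empty lists, zero pixels", {
  st <- decay_stack(array(1, c(8, 2, 2)), FREQ)
  expect_error(phasor_transform(st, integer(0)), "non-empty")
  expect_error(phasor_transform(st, 8), "alias")
  # zero-intensity pixel flagged invalid, NA coordinates
  cnt <- array(1, c(4, 2, 2)); cnt[, 2, 2] <- 0
  f <- phasor_transform(decay_stack(cnt, FREQ), 1)
  expect_false(f$valid[2, 2])
  expect_true(is.na(f$G[2, 2, 1]))
  expect_equal(f$intensity[1, 1], 4)
})

test_that("phasor linearity: summed stacks give intensity-weighted mean phasors", {
  set.seed(11)
  a <- rpois(64, 30); b <- rpois(64, 5)
  fa <- phasor_transform(decay_stack(a, FREQ), 1:2)
  fb <- phasor_transform(decay_stack(b, FREQ), 1:2)
  fsum <- phasor_transform(decay_stack(a + b, FREQ), 1:2)
  wa <- sum(a) / sum(a + b)
  for (j in 1:2) {
    expect_equal(fsum$G[1, 1, j],
                 wa * fa$G[1, 1, j] + (1 - wa) * fb$G[1, 1, j],
                 tolerance = 1e-12)
    expect_equal(fsum$S[1, 1, j],
                 wa * fa$S[1, 1, j] + (1 - wa) * fb$S[1, 1, j],
                 tolerance = 1e-12)
  }
})

test_that("phasor modulus never exceeds 1 for non-negative counts", {
  set.seed(23)
  for (rep in 1:20) {
    counts <- rpois(16, runif(1, 0.2, 50))
    if (sum(counts) == 0) counts[sample(16, 1)] <- 1
    f <- phasor_transform(decay_stack(counts, FREQ), 1:4)
    expect_true(all(f$G[1, 1, ]^2 + f$S[1, 1, ]^2 <= 1 + 1e-9))
  }
})

test_that("single-exponential closed form hits its limits and the universal circle", {
  expect_equal(unname(single_exp_phasor(0, FREQ, 1)[1, ]), c(1, 0))
  slow <- single_exp_phasor(1e-3, FREQ, 1)   # effectively infinite lifetime
  expect_lt(abs(slow[1, "G"]), 1e-6)
  expect_lt(abs(slow[1, "S"]), 1e-3)
  p <- single_exp_phasor(2e-9, FREQ, 1)
  expect_equal(unname(p[1, "G"]), 0.49737, tolerance = 1e-4)
  expect_equal(unname(p[1, "S"]), 0.49999, tolerance = 1e-4)
  taus <- seq(0.1, 10, by = 0.7) * 1e-9
  gs <- single_exp_phasor(taus, FREQ, 2)
  expect_equal(gs[, "S"]^2, gs[, "G"] - gs[, "G"]^2, tolerance = 1e-14)
})

test_that("binned closed form equals the transform of a noiseless sampled exponential", {
  for (tau in c(0.7e-9, 3e-9)) {
    f <- phasor_transform(exp_stack(tau, bins = 64), 1:2)
    for (j in 1:2) {
      p <- single_exp_phasor_binned(tau, FREQ, j, 64)
      expect_equal(f$G[1, 1, j], unname(p[1, "G"]), tolerance = 1e-12)
      expect_equal(f$S[1, 1, j], unname(p[1, "S"]), tolerance = 1e-12)
    }
  }
})

test_that("box filtering fixes constants, spreads impulses, renormalises at edges", {
  G <- matrix(0.4, 5, 5)
  f <- field_from_coords(G, G * 0 + 0.2)
  ff <- filter_phasor(f, 3, 1)
  expect_equal(ff$G[, , 1], G, tolerance = 1e-14)   # constants unchanged
  # interior impulse: 3x3 box once -> 1/9 at the centre
  G2 <- matrix(0, 5, 5); G2[3, 3] <- 1
  f2 <- filter_phasor(field_from_coords(G2, G2 * 0), 3, 1)
  expect_equal(f2$G[3, 3, 1], 1 / 9, tolerance = 1e-14)
  expect_equal(f2$G[2, 2, 1], 1 / 9, tolerance = 1e-14)
  expect_equal(f2$G[1, 1, 1], 0)
  # corner pixel averages over its 4 in-image neighbours only
  G3 <- matrix(1, 5, 5)
  f3 <- filter_phasor(field_from_coords(G3, G3 * 0), 3, 1)
  expect_equal(f3$G[1, 1, 1], 1, tolerance = 1e-14)
  # repeats compose
  fa <- filter_phasor(field_from_coords(G2, G2 * 0), 3, 2)
  fb <- filter_phasor(filter_phasor(field_from_coords(G2, G2 * 0), 3, 1), 3, 1)
  expect_equal(fa$G, fb$G, tolerance = 1e-14)
  # invalid pixels are excluded and stay invalid
  f4 <- field_from_coords(G2, G2 * 0, intensity = matrix(1, 5, 5))
  f4$valid[3, 4] <- FALSE
  ff4 <- filter_phasor(f4, 3, 1)
  expect_true(is.na(ff4$G[3, 4, 1]))
  expect_equal(ff4$G[3, 2, 1], 1 / 9, tolerance = 1e-14)
  expect_equal(ff4$G[2, 3, 1], 1 / 8, tolerance = 1e-14)  # neighbourhood lost one pixel
  expect_error(filter_phasor(f, 4), "odd")
})

test_that("intensity masking combines thresholds and external masks", {
  f <- field_from_coords(matrix(0.5, 1, 3), matrix(0.2, 1, 3),
                         intensity = matrix(c(0, 10, 100), 1, 3))
  expect_equal(as.vector(intensity_mask(f, 5, 50)$valid), c(FALSE, TRUE, FALSE))
  expect_equal(as.vector(intensity_mask(f, 0, Inf)$valid), c(FALSE, TRUE, TRUE))
  expect_equal(as.vector(intensity_mask(f, external = matrix(FALSE, 1, 3))$valid),
               rep(FALSE, 3))
  expect_error(intensity_mask(f, 10, 5), "tmin")
  expect_error(intensity_mask(f, external = matrix(TRUE, 2, 2)), "shape")
})

test_that("phasor histogram bins, conserves and respects the closed last edge", {
  f <- field_from_coords(matrix(0.5), matrix(0.5))
  h <- phasor_histogram(f, 1, 256)
  # (0.5 - (-1))/2 * 256 = 192 zero-based -> row/col 193 in R indexing
  expect_equal(h$counts[193, 193], 1L)
  expect_equal(sum(h$counts), 1L)
  # last edge closed: a pixel exactly at the max corner still lands in-grid
  f2 <- field_from_coords(matrix(1), matrix(1))
  h2 <- phasor_histogram(f2, 1, 16)
  expect_equal(h2$counts[16, 16], 1L)
  # empty validity mask -> all-zero histogram
  f3 <- field_from_coords(matrix(0.5, 2, 2), matrix(0.5, 2, 2))
  f3$valid[] <- FALSE
  expect_equal(sum(phasor_histogram(f3, 1, 32)$counts), 0L)
  # conservation over a random cloud
  set.seed(3)
  G <- matrix(runif(100, -0.9, 0.9), 10)
  S <- matrix(runif(100, -0.9, 0.9), 10)
  expect_equal(sum(phasor_histogram(field_from_coords(G, S), 1, 64)$counts), 100L)
  expect_error(phasor_histogram(f, 1, 1), "resolution")
  # log scale changes display values only
  hl <- phasor_histogram(f, 1, 32, scale = "log")
  df <- as.data.frame(hl)
  expect_equal(df$display, log1p(df$count))
  expect_equal(sum(hl$counts), 1L)
})
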