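five_taus <- c(0.5, 1, 2, 4, 8) * 1e-9

five_component_set <- function(prediction = "continuous") {
  component_set(
    lapply(seq_along(five_taus), function(i) {
      lifetime_component(paste0("dye", i), five_taus[i])
    }),
    harmonics = 1:2, frequency = FREQ, prediction = prediction
  )
}

test_that("the component matrix stacks closed-form phasors plus the sum row", {
  # single component, one harmonic -> [G1, S1, 1]
  s1 <- component_set(list(lifetime_component("a", 2e-9)),
                      harmonics = 1, frequency = FREQ)
  A1 <- build_component_matrix(s1)
  th <- single_exp_phasor(2e-9, FREQ, 1)
  expect_equal(unname(A1[, 1]), unname(c(th[1, "G"], th[1, "S"], 1)))
  # tau = 0 gives the (1, 0) column at every harmonic
  s0 <- component_set(list(lifetime_component("zero", 0),
                           lifetime_component("b", 3e-9)),
                      harmonics = 1:2, frequency = FREQ)
  expect_equal(unname(build_component_matrix(s0)[, 1]), c(1, 0, 1, 0, 1))
  # 5 x 2 matrix from two lifetimes over two harmonics, against the closed form
  s2 <- component_set(list(lifetime_component("a", 1e-9),
                           lifetime_component("b", 4e-9)),
                      harmonics = 1:2, frequency = FREQ)
  A <- build_component_matrix(s2)
  for (i in 1:2) {
    tau <- c(1e-9, 4e-9)[i]
    for (n in 1:2) {
      w <- 2 * pi * FREQ * n
      expect_equal(unname(A[2 * n - 1, i]), 1 / (1 + (w * tau)^2))
      expect_equal(unname(A[2 * n, i]), w * tau / (1 + (w * tau)^2))
    }
  }
  # capacity bound and duplicate detection
  expect_error(component_set(lapply(1:4, function(i)
    lifetime_component(paste0("c", i), i * 1e-9)), harmonics = 1,
    frequency = FREQ), "2N\\+1")
  sdup <- component_set(list(lifetime_component("a", 2e-9),
                             lifetime_component("b", 2e-9)),
                        harmonics = 1:2, frequency = FREQ)
  expect_error(build_component_matrix(sdup), "identical")
})

test_that("pure and midpoint pixels unmix to the obvious fractions", {
  set <- five_component_set()
  A <- build_component_matrix(set)
  # pixel exactly at component 3's stacked phasor
  f <- field_from_coords(
    array(c(A[1, 3], A[3, 3]), c(1, 1, 2)),
    array(c(A[2, 3], A[4, 3]), c(1, 1, 2)), harmonics = 1:2)
  ff <- unmix_field(f, set)
  expect_equal(as.vector(ff$fractions[1, 1, ]), c(0, 0, 1, 0, 0),
               tolerance = 1e-9)
  # stacked midpoint of components 1 and 5
  mid <- (A[, 1] + A[, 5]) / 2
  f2 <- field_from_coords(array(mid[c(1, 3)], c(1, 1, 2)),
                          array(mid[c(2, 4)], c(1, 1, 2)), harmonics = 1:2)
  ff2 <- unmix_field(f2, set)
  expect_equal(as.vector(ff2$fractions[1, 1, ]), c(0.5, 0, 0, 0, 0.5),
               tolerance = 1e-9)
})

test_that("noiseless convex mixtures at capacity are recovered exactly", {
  set <- five_component_set()
  A <- build_component_matrix(set)
  set.seed(71)
  Wt <- matrix(stats::rexp(5 * 200), 5)
  Wt <- sweep(Wt, 2, colSums(Wt), "/")
  M <- A %*% Wt
  f <- field_from_coords(
    G = array(t(M[c(1, 3), ]), c(20, 10, 2)),
    S = array(t(M[c(2, 4), ]), c(20, 10, 2)), harmonics = 1:2)
  ff <- unmix_field(f, set)
  truth <- array(t(Wt), c(20, 10, 5))
  expect_lt(max(abs(ff$fractions - truth)), 1e-6)
  expect_equal(apply(ff$fractions, c(1, 2), sum),
               matrix(1, 20, 10), tolerance = 1e-9)
  expect_lt(max(ff$residual), 1e-9)
})

test_that("a coarse simplex grid is recovered by the exact-solve branch", {
  # brute-force check on a deterministic grid of convex weights
  set <- five_component_set()
  A <- build_component_matrix(set)
  grid <- as.matrix(expand.grid(w1 = seq(0, 1, 0.5), w2 = seq(0, 1, 0.5),
                                w3 = seq(0, 1, 0.5), w4 = seq(0, 1, 0.5)))
  grid <- grid[rowSums(grid) <= 1, ]
  Wt <- t(cbind(grid, 1 - rowSums(grid)))
  M <- A %*% Wt
  n <- ncol(M)
  f <- field_from_coords(G = array(t(M[c(1, 3), ]), c(n, 1, 2)),
                         S = array(t(M[c(2, 4), ]), c(n, 1, 2)),
                         harmonics = 1:2)
  ff <- unmix_field(f, set)
  expect_lt(max(abs(ff$fractions - array(t(Wt), c(n, 1, 5)))), 1e-9)
})

test_that("least-squares and nonnegative branches behave as documented", {
  # C = 3 < 2N+1 = 5: overdetermined least squares
  taus3 <- c(0.5, 2, 8) * 1e-9
  set3 <- component_set(lapply(1:3, function(i)
    lifetime_component(paste0("c", i), taus3[i])),
    harmonics = 1:2, frequency = FREQ)
  A3 <- build_component_matrix(set3)
  w0 <- c(0.2, 0.5, 0.3)
  m <- A3 %*% w0
  f <- field_from_coords(array(m[c(1, 3)], c(1, 1, 2)),
                         array(m[c(2, 4)], c(1, 1, 2)), harmonics = 1:2)
  ff <- unmix_field(f, set3)
  expect_equal(as.vector(ff$fractions[1, 1, ]), w0, tolerance = 1e-9)
  # off-simplex pixel under nonneg: fractions >= 0 and sum to 1 within 1e-6
  f2 <- field_from_coords(array(c(0.95, 0.9), c(1, 1, 2)),
                          array(c(-0.05, -0.1), c(1, 1, 2)), harmonics = 1:2)
  ff2 <- unmix_field(f2, set3, nonneg = TRUE)
  fr <- as.vector(ff2$fractions[1, 1, ])
  expect_true(all(fr >= 0))
  expect_equal(sum(fr), 1, tolerance = 1e-6)
  # the same pixel unconstrained reports a negative diagnostic fraction
  ff3 <- unmix_field(f2, set3)
  expect_true(any(ff3$fractions[1, 1, ] < 0))
})

test_that("unmixing a summed stack of two pure decays yields their photon shares", {
  # two pure single-exponential stacks, summed bin-wise; binned component
  # prediction removes the finite-binning bias so shares come out exactly
  a <- exp_stack(1e-9, bins = 128, photons = 3e5)
  b <- exp_stack(5e-9, bins = 128, photons = 7e5)
  summed <- decay_stack(a$counts + b$counts, FREQ)
  fld <- phasor_transform(summed, 1:2)
  ref <- phasor_transform(exp_stack(4e-9, bins = 128), 1:2)
  fld <- apply_correction(fld, compute_correction(ref, 4e-9))
  set <- component_set(list(lifetime_component("fast", 1e-9),
                            lifetime_component("slow", 5e-9)),
                       harmonics = 1:2, frequency = FREQ,
                       prediction = "binned")
  ff <- unmix_field(fld, set)
  expect_equal(as.vector(ff$fractions[1, 1, ]), c(0.3, 0.7), tolerance = 1e-9)
})

test_that("ratio-metric images divide fraction pairs with a guarded denominator", {
  fr <- array(0, c(1, 3, 2))
  fr[1, , 1] <- c(0.4, 0.5, 0)
  fr[1, , 2] <- c(0.4, 0, 1e-13)
  ff <- structure(list(fractions = fr, valid = matrix(TRUE, 1, 3),
                       intensity = matrix(1, 1, 3),
                       components = c("a", "b"), colors = c("red", "blue")),
                  class = "fraction_field")
  r <- ratio_image(ff, 1, 2)
  expect_equal(r[1, 1], 0.5)
  expect_equal(r[1, 2], 1)
  expect_true(is.na(r[1, 3]))
  expect_equal(ratio_image(ff, "a", "b"), r)
  rr <- ratio_image(structure(list(
    fractions = array(c(0.2, 0.6), c(1, 1, 2)), valid = matrix(TRUE, 1, 1),
    intensity = matrix(1), components = c("a", "b"),
    colors = c("red", "blue")), class = "fraction_field"), 1, 2)
  expect_equal(rr[1, 1], 0.25)
  expect_error(ratio_image(ff, 1, 1), "distinct")
})

test_that("empirical components are intensity-weighted region means", {
  G <- matrix(c(0.3, 0.5, 0.9), 1, 3)
  S <- matrix(c(0.2, 0.4, 0.1), 1, 3)
  f <- field_from_coords(G, S, intensity = matrix(c(1, 1, 3), 1, 3))
  # single pixel
  reg1 <- matrix(c(TRUE, FALSE, FALSE), 1, 3)
  c1 <- empirical_component(f, reg1, "one")
  expect_equal(unname(c1$phasor[, 1]), c(0.3, 0.2))
  # two equal-intensity pixels: arithmetic mean
  reg2 <- matrix(c(TRUE, TRUE, FALSE), 1, 3)
  c2 <- empirical_component(f, reg2, "two")
  expect_equal(unname(c2$phasor[, 1]), c(0.4, 0.3))
  expect_error(empirical_component(f, matrix(FALSE, 1, 3), "none"), "valid")
  # a homogeneous simulated dye region reproduces the dye's phasor
  st <- exp_stack(2.5e-9, bins = 128, side = 8L, photons = 1e5,
                  noise = TRUE, seed = 5L)
  fld <- phasor_transform(st, 1:2)
  comp <- empirical_component(fld, matrix(TRUE, 8, 8), "dye")
  expected <- single_exp_phasor_binned(2.5e-9, FREQ, 1, 128)
  # tolerance: a few Monte-Carlo standard errors of the pooled estimate
  se <- sqrt(0.5 / (64 * 1e5))
  expect_lt(abs(comp$phasor[1, 1] - expected[1, "G"]), 4 * se)
  expect_lt(abs(comp$phasor[2, 1] - expected[1, "S"]), 4 * se)
})
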