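test_that("C(0) is exactly 1 and bins carry positive pair counts", {
  for (seed in 1:5) {
    p <- random_pattern(30, density = runif(1, 0.3, 1), seed = seed)
    prof <- autocorrelation(p, r_max = 10)
    expect_identical(prof$C[prof$r == 0], 1)
    expect_true(all(prof$n_pairs > 0))
  }
})

test_that("the 2x2 hand-enumerated pattern gives C(1) = -1/3", {
  # 12 ordered pairs in the r=1 bin: 8 axial opposite-colour, 4 diagonal
  # same-colour; covariance -1/12 over a global variance of 1/4
  p <- color_pattern(matrix(c(1L, 2L, 2L, 1L), 2, 2))
  prof <- autocorrelation_reference(p, r_max = 1)
  expect_equal(prof$C, c(1, -1 / 3), tolerance = 1e-12)
  expect_equal(prof$n_pairs, c(4, 12))
})

test_that("checkerboard axial/diagonal cancellation zeroes the r=1 bin", {
  cb <- generate_reference_pattern("checkerboard", L = 60,
                                   boundary = "periodic")
  prof <- autocorrelation(cb, r_max = 2)
  expect_identical(prof$C[prof$r == 1], 0)
  expect_equal(prof$C[prof$r == 2], -1 / 3, tolerance = 1e-12)
  # bounded frames break the cancellation only marginally
  cbb <- generate_reference_pattern("checkerboard", L = 60)
  expect_lt(abs(autocorrelation(cbb, r_max = 1)$C[2]), 0.02)
})

test_that("fast path matches the brute-force oracle bin-for-bin", {
  set.seed(99)
  for (i in 1:10) {
    L <- sample(8:30, 1)
    p <- random_pattern(L, density = runif(1, 0.2, 1),
                        ratio = runif(1, 0.2, 0.8),
                        boundary = sample(c("bounded", "periodic"), 1))
    fast <- autocorrelation(p)
    ref <- autocorrelation_reference(p)
    expect_identical(fast$r, ref$r)
    expect_lt(max(abs(fast$C - ref$C)), 1e-12)
    expect_equal(fast$n_pairs, ref$n_pairs)
  }
})

test_that("C(r) is invariant under colour relabelling and cyclic shifts", {
  p <- random_pattern(24, density = 0.8, seed = 7, boundary = "periodic")
  base <- autocorrelation(p, r_max = 8)
  expect_equal(autocorrelation(swap_colors(p), r_max = 8)$C, base$C,
               tolerance = 1e-12)
  g <- unclass(p)
  shifted <- color_pattern(g[c(6:24, 1:5), c(14:24, 1:13)],
                           boundary = "periodic")
  expect_equal(autocorrelation(shifted, r_max = 8)$C, base$C,
               tolerance = 1e-12)
})

test_that("C(r) stays within [-1, 1] on the reference fixtures", {
  fixtures <- list(
    generate_reference_pattern("stripes", L = 40, w = 4),
    generate_reference_pattern("blocks", L = 40, w = 5),
    generate_reference_pattern("checkerboard", L = 40),
    generate_reference_pattern("voronoi", L = 40, n_seeds = 16, seed = 3),
    random_pattern(40, seed = 4))
  for (p in fixtures) {
    prof <- autocorrelation(p)
    expect_true(all(prof$C <= 1 + 1e-9 & prof$C >= -1 - 1e-9))
  }
})

test_that("single-colour or empty patterns are rejected as zero-variance", {
  expect_error(autocorrelation(color_pattern(matrix(1L, 5, 5))),
               "zero variance")
  expect_error(autocorrelation_reference(color_pattern(matrix(0L, 5, 5))),
               "zero variance")
})

test_that("the first zero is located by linear interpolation and censored at r_max", {
  prof <- structure(data.frame(r = c(0, 1, 2), C = c(1, 0.4, -0.1),
                               n_pairs = c(10, 20, 30)),
                    r_max = 2,
                    class = c("correlation_profile", "data.frame"))
  xi <- correlation_length(prof)
  expect_equal(xi$xi, 1.8)  # 1 + 0.4 / (0.4 + 0.1)
  expect_false(xi$censored)

  pos <- structure(data.frame(r = 0:30, C = seq(1, 0.1, length.out = 31),
                              n_pairs = rep(5, 31)),
                   r_max = 30,
                   class = c("correlation_profile", "data.frame"))
  cens <- correlation_length(pos)
  expect_identical(cens$xi, 30)
  expect_true(cens$censored)
})

test_that("stripe fixtures reproduce their brute-force correlation lengths", {
  # frozen from direct pair enumeration on the 60x60 fixtures; the first
  # zero of a radially averaged square wave sits near (pi/4) w
  anchors <- c(`2` = 1.448304, `4` = 3.228557, `5` = 3.948525,
               `10` = 8.361799)
  xis <- vapply(as.integer(names(anchors)), function(w) {
    p <- generate_reference_pattern("stripes", L = 60, w = w)
    correlation_length(autocorrelation(p))$xi
  }, numeric(1))
  expect_equal(unname(xis), unname(anchors), tolerance = 1e-5)
  expect_true(all(diff(xis) > 0))  # xi scales with the stripe width
  expect_true(all(abs(xis - as.integer(names(anchors)) * pi / 4) < 1))
})
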