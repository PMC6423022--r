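test_that("Gaussian profile ties variance to width at half height", {
  sp <- gaussian_array_spec(H = 500, W = 60, d_p = 200)
  expect_equal(sp$v, (60 / 2)^2 / (2 * log(2)))

  s <- make_gaussian_surface(sp, cells = 1)
  peak <- surface_eval(s, 100, 100)
  expect_equal(peak$z, 500)
  expect_equal(c(peak$fx, peak$fy), c(0, 0))
  expect_equal(c(peak$nx, peak$ny, peak$nz), c(0, 0, 1))

  half <- surface_eval(s, 100 + 30, 100)   # lateral distance W/2 from peak
  expect_equal(half$z, 250, tolerance = 1e-12)

  hole <- make_gaussian_surface(gaussian_array_spec(-550, 60, 200), cells = 1)
  expect_equal(surface_eval(hole, 100, 100)$z, -550)

  pillar <- make_gaussian_surface(gaussian_array_spec(200, 80, 160), cells = 1)
  expect_equal(surface_eval(pillar, 80, 80)$z, 200)

  expect_error(gaussian_array_spec(100, -5, 50), "W")
  expect_error(gaussian_array_spec(100, 50, 0), "d_p")
  expect_error(make_gaussian_surface(sp, cells = 0), "cells")
})

test_that("profile is truncated to zero outside d_p/2 with zero gradient", {
  s <- make_gaussian_surface(gaussian_array_spec(500, 60, 200), cells = 1)
  # cell corners lie beyond the inscribed truncation circle of radius d_p/2
  outside <- surface_eval(s, 2, 3)
  expect_equal(outside$z, 0)
  expect_equal(c(outside$fx, outside$fy), c(0, 0))
  expect_equal(outside$w, 1)
})

test_that("parametric surfaces are periodic to machine precision", {
  s <- make_gaussian_surface(gaussian_array_spec(300, 50, 150), cells = 2)
  x <- c(0, 13.7, 149.99, 287.2)
  a <- surface_eval(s, x, x / 2)
  b <- surface_eval(s, x + s$Lx, x / 2 - s$Ly)
  expect_equal(a$z, b$z, tolerance = 1e-14)
  expect_equal(a$fx, b$fx, tolerance = 1e-14)
  expect_equal(a$fy, b$fy, tolerance = 1e-14)
})

test_that("height-field surfaces interpolate and validate", {
  z <- matrix(5, 16, 16)
  s <- make_heightfield_surface(height_field(z, dx = 2))
  ev <- surface_eval(s, c(1.3, 10.1), c(4.4, 20.2))
  expect_equal(ev$z, c(5, 5))
  expect_equal(ev$w, c(1, 1))
  expect_equal(surface_area(s)$ratio, 1, tolerance = 1e-6)

  # plane z = a*x: interior area element is sqrt(1 + a^2) exactly
  a <- 0.75
  nx <- 32; dx <- 1
  ramp <- height_field(outer((seq_len(nx) - 1) * dx * a, rep(1, nx)), dx = dx)
  sr <- make_heightfield_surface(ramp)
  mid <- surface_eval(sr, seq(8, 24, by = 0.37), seq(2, 30, length.out = 44))
  expect_equal(mid$w, rep(sqrt(1 + a^2), nrow(mid)), tolerance = 1e-12)

  zz <- z; zz[3, 3] <- NA
  expect_error(height_field(zz, 2), "finite")
  expect_error(height_field(matrix(1, 2, 8), 1), "4 x 4")
  expect_error(height_field(z, dx = -1), "dx")

  # a single spike makes the curved area strictly exceed the projected one
  spikez <- matrix(0, 32, 32)
  spikez[14:18, 14:18] <- c(10, 20, 30, 20, 10)
  ss <- make_heightfield_surface(height_field(spikez, dx = 4))
  expect_gt(surface_area(ss)$ratio, 1)
})

test_that("surface area integration converges and matches published ratios", {
  d_p <- calibrate_dp(500, 60, 3.6)
  s <- make_gaussian_surface(gaussian_array_spec(500, 60, d_p), cells = 1)
  ar <- surface_area(s, resolution = 0.7)
  expect_equal(ar$ratio, 3.6, tolerance = 2e-3)
  expect_equal(ar$A_f, d_p^2)
  expect_gte(ar$A_s, ar$A_f)
  # Richardson-style refinement: halving the step moves the ratio < 0.1%
  ar2 <- surface_area(s, resolution = 0.35)
  expect_lt(abs(ar2$ratio - ar$ratio) / ar$ratio, 1e-3)
})

test_that("d_p calibration round-trips, is monotone, and fails for flat", {
  d_p <- calibrate_dp(500, 40, 2.8)
  s <- make_gaussian_surface(gaussian_array_spec(500, 40, d_p), cells = 1)
  expect_equal(surface_area(s)$ratio, 2.8, tolerance = 1.5e-3)

  # a larger target ratio needs the peaks packed closer together
  expect_lt(calibrate_dp(500, 60, 3.6), calibrate_dp(500, 60, 2.8))

  expect_error(calibrate_dp(0, 60, 2), "calibration failure")
  expect_error(calibrate_dp(500, 60, 1.0), "target ratio")
})

test_that("area-weighted sampling reproduces the surface measure", {
  # flat: lateral positions uniform (chi-square on a 10 x 10 binning)
  set.seed(42)
  s <- flat_surface(100, 100)
  p <- sample_surface_point(s, 1e5)
  tab <- table(cut(p$x, seq(0, 100, 10)), cut(p$y, seq(0, 100, 10)))
  expect_gt(chisq.test(as.vector(tab))$p.value, 0.01)

  # spike: lateral-radius law r ~ w(r) * 2 pi r (KS distance < 0.02)
  set.seed(43)
  gs <- make_gaussian_surface(gaussian_array_spec(500, 60, 180), cells = 1)
  q <- sample_surface_point(gs, 1e5)
  r <- sqrt((q$x - 90)^2 + (q$y - 90)^2)
  r <- r[r <= 90]
  rg <- seq(0, 90, length.out = 2001)
  dens <- surface_eval(gs, 90 + rg, rep(90, length(rg)))$w * 2 * pi * rg
  cdf <- cumsum(dens) / sum(dens)
  expect_lt(max(abs(ecdf(r)(rg) - cdf)), 0.02)

  # sampled anchors lie on the surface, normals are unit outward
  ev <- surface_eval(gs, q$x[1:100], q$y[1:100])
  expect_equal(q$z[1:100], ev$z, tolerance = 1e-12)
  expect_equal(q$nx[1:100]^2 + q$ny[1:100]^2 + q$nz[1:100]^2,
               rep(1, 100), tolerance = 1e-12)
  expect_true(all(q$nz > 0))
})

test_that("area element w >= 1 with equality only where the gradient vanishes", {
  gs <- make_gaussian_surface(gaussian_array_spec(-300, 50, 160), cells = 1)
  g <- expand.grid(x = seq(0.5, 159.5, by = 2.5), y = seq(0.5, 159.5, by = 2.5))
  ev <- surface_eval(gs, g$x, g$y)
  expect_true(all(ev$w >= 1 - 1e-12))
  flatish <- abs(ev$fx) < 1e-14 & abs(ev$fy) < 1e-14
  expect_equal(ev$w[flatish], rep(1, sum(flatish)))
  expect_true(all(ev$w[!flatish] > 1))
})
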