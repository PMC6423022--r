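test_that("single-attempt acceptance follows hard-sphere exclusion", {
  surf <- flat_surface(500, 500)
  pm <- protein_model()   # D = 7 nm

  # empty surface: always accepted (B(0) = 1)
  set.seed(1)
  first <- attempt_adsorption(list(centers = NULL), surf, pm)
  expect_true(first$accepted)
  expect_equal(first$deposit$center[3], 3.5)  # tangent sphere on flat

  # existing sphere at (50, 50); centres are coplanar on flat
  st <- list(centers = matrix(c(50, 50, 3.5), 1))
  near <- attempt_adsorption(st, surf, pm, anchor = c(56.9, 50))
  expect_false(near$accepted)
  expect_equal(near$reason, "overlap")
  far <- attempt_adsorption(st, surf, pm, anchor = c(57.1, 50))
  expect_true(far$accepted)

  # deposit geometry: centre sits D/2 along the normal from the anchor
  expect_equal(sqrt(sum((far$deposit$center - far$deposit$anchor)^2)),
               pm$D / 2, tolerance = 1e-9)
})

test_that("substrate penetration is detected in steep concave features", {
  pm <- protein_model()
  hole <- make_gaussian_surface(gaussian_array_spec(-550, 60, 200), cells = 1)
  # the hole floor has curvature radius ~1.2 nm, far below the 3.5 nm
  # sphere radius: a tangent sphere at the bottom digs into the walls
  res <- attempt_adsorption(list(centers = NULL), hole, pm,
                            anchor = c(100, 100), enforce_no_penetration = TRUE)
  expect_false(res$accepted)
  expect_equal(res$reason, "penetration")
  # the pure pair-exclusion variant accepts the same placement
  res2 <- attempt_adsorption(list(centers = NULL), hole, pm,
                             anchor = c(100, 100), enforce_no_penetration = FALSE)
  expect_true(res2$accepted)
})

test_that("runs are deterministic given the seed", {
  surf <- flat_surface(150, 150)
  cfg <- adsorption_config(repeats = 2, seed = 9, stop_after_failures = 1e4,
                           enforce_no_penetration = FALSE)
  a <- run_rsa(surf, protein_model(), cfg)
  b <- run_rsa(surf, protein_model(), cfg)
  expect_identical(a$runs[[1]]$centers, b$runs[[1]]$centers)
  expect_identical(a$runs[[2]]$attempts_used, b$runs[[2]]$attempts_used)
  expect_identical(a$runs[[1]]$n_att, b$runs[[1]]$n_att)
  # repeats use distinct streams
  expect_false(nrow(a$runs[[1]]$centers) == nrow(a$runs[[2]]$centers) &&
               isTRUE(all.equal(a$runs[[1]]$centers, a$runs[[2]]$centers)))
})

test_that("a box that can hold only one sphere jams with exactly one deposit", {
  # in an 8 x 8 nm periodic box no two centres can be >= 7 nm apart
  # (the maximal minimum-image distance is sqrt(32) < 7)
  runs <- run_rsa(flat_surface(8, 8), protein_model(),
                  adsorption_config(repeats = 3, seed = 4,
                                    stop_after_failures = 1e4,
                                    enforce_no_penetration = FALSE))
  for (r in runs$runs) expect_equal(nrow(r$centers), 1L)
})

test_that("hard-core exclusion holds exactly after any run", {
  pm <- protein_model()
  cfg <- adsorption_config(repeats = 1, seed = 17, stop_after_failures = 1e4,
                           enforce_no_penetration = FALSE)
  for (surf in list(flat_surface(100, 100),
                    make_gaussian_surface(gaussian_array_spec(300, 40, 120)),
                    make_gaussian_surface(gaussian_array_spec(-200, 50, 140)))) {
    rs <- run_rsa(surf, pm, cfg)
    expect_gte(min_pair_distance(rs$runs[[1]], surf), pm$D * (1 - 1e-12))
  }
})

test_that("coverage sequence is strictly increasing and below the packing bound", {
  rs <- run_rsa(flat_surface(120, 120), protein_model(),
                adsorption_config(repeats = 2, seed = 5,
                                  stop_after_failures = 1e4,
                                  enforce_no_penetration = FALSE))
  for (r in rs$runs) {
    expect_true(all(diff(r$theta) > 0))
    expect_lt(r$theta_end, pi / (2 * sqrt(3)))  # hexagonal packing bound
    expect_equal(r$theta_end,
                 nrow(r$centers) * protein_model()$sigma / rs$A_s)
  }
})

test_that("exhausting the attempt budget flags the run instead of erroring", {
  rs <- run_rsa(flat_surface(200, 200), protein_model(),
                adsorption_config(repeats = 1, seed = 3, max_attempts = 500,
                                  stop_after_failures = 1e4,
                                  enforce_no_penetration = FALSE))
  expect_true(rs$runs[[1]]$budget_limited)
  expect_lte(rs$runs[[1]]$n_att, 500)
  expect_error(jamming_limit(rs), "budget")
})

test_that("vertical distribution conserves counts and concentrates low", {
  pm <- protein_model()
  flat_rs <- run_rsa(flat_surface(120, 120), pm,
                     adsorption_config(repeats = 1, seed = 2,
                                       stop_after_failures = 1e4,
                                       enforce_no_penetration = FALSE))
  zd <- z_distribution(flat_rs, bin_width = 5)
  expect_equal(nrow(zd), 1L)                       # all anchors at z = 0
  expect_true(zd$z_lo[1] <= 0 && zd$z_hi[1] > 0)
  expect_equal(sum(zd$count), nrow(flat_rs$runs[[1]]$centers))

  pil <- make_gaussian_surface(gaussian_array_spec(200, 80, 170))
  pil_rs <- run_rsa(pil, pm,
                    adsorption_config(repeats = 2, seed = 6,
                                      stop_after_failures = 1e4,
                                      enforce_no_penetration = FALSE))
  zp <- z_distribution(pil_rs, bin_width = 20)
  expect_equal(sum(zp$count),
               sum(vapply(pil_rs$runs, function(r) nrow(r$centers), integer(1))))
  # far more protein at the pillar base than at its top
  expect_gt(zp$count[1], 3 * zp$count[nrow(zp)])
})

test_that("grid and brute-force engines agree on mixed small instances", {
  pm <- protein_model()
  set.seed(99)
  for (k in 1:10) {
    surf <- if (k %% 3 == 0) {
      hf <- height_field(matrix(rnorm(20 * 20, sd = 15), 20, 20), dx = 4)
      make_heightfield_surface(hf)
    } else if (k %% 3 == 1) {
      make_gaussian_surface(gaussian_array_spec(runif(1, -200, 300),
                                                runif(1, 15, 40),
                                                runif(1, 45, 60)), cells = 2)
    } else flat_surface(runif(1, 40, 100), runif(1, 40, 100))
    cfg <- adsorption_config(repeats = 1, seed = 1000 + k,
                             max_attempts = 2e4, stop_after_failures = 1e4,
                             enforce_no_penetration = FALSE)
    g <- run_rsa(surf, pm, cfg, engine = "grid")
    b <- run_rsa(surf, pm, cfg, engine = "brute")
    expect_identical(g$runs[[1]]$centers, b$runs[[1]]$centers)
    expect_identical(g$runs[[1]]$attempts_used, b$runs[[1]]$attempts_used)
    expect_identical(g$runs[[1]]$n_att, b$runs[[1]]$n_att)
  }
})
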