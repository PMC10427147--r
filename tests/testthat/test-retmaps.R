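# Circular arithmetic, group averaging, and the individual-variability metric.

test_that("circ_diff matches wrap-around examples and is a metric on sampled grid points", {
  expect_equal(circ_diff(10, 350), 20)
  expect_equal(circ_diff(90, 270), 180)
  expect_equal(circ_diff(123.4, 123.4), 0)
  expect_equal(circ_diff(0, 360), 0)
  expect_error(circ_diff(NA, 1), "non-finite")
  expect_error(circ_diff(Inf, 1), "non-finite")

  # symmetry and identity, full 1-degree grid
  g <- as.matrix(expand.grid(a = 0:359, b = 0:359))
  d <- circ_diff(g[, "a"], g[, "b"])
  d_rev <- circ_diff(g[, "b"], g[, "a"])
  expect_identical(d, d_rev)
  expect_true(all(d[g[, "a"] == g[, "b"]] == 0))
  expect_true(all(d >= 0 & d <= 180))

  # triangle inequality on seeded triples
  withr::with_seed(42, {
    a <- sample(0:359, 2e4, TRUE)
    b <- sample(0:359, 2e4, TRUE)
    c <- sample(0:359, 2e4, TRUE)
  })
  expect_true(all(circ_diff(a, c) <= circ_diff(a, b) + circ_diff(b, c) + 1e-12))
})

test_that("group_average is the circular mean, with degenerate vertices flagged", {
  patch <- fix_small_patch()
  n <- nrow(patch)
  m1 <- retino_map(patch, rep(10, n), rep(2, n))
  m2 <- retino_map(patch, rep(350, n), rep(4, n))
  avg <- group_average(list(m1, m2))
  expect_equal(circ_diff(avg$polar_angle, rep(0, n)), rep(0, n), tolerance = 1e-9)
  expect_equal(avg$eccentricity, rep(3, n))
  expect_true(all(avg$resultant_length >= 0 & avg$resultant_length <= 1))

  # averaging N copies of one map returns that map
  canon <- fix_small_canon()
  avg_self <- group_average(list(canon, canon, canon))
  expect_equal(circ_diff(avg_self$polar_angle, canon$polar_angle), rep(0, n),
    tolerance = 1e-9)

  # antipodal angles: zero resultant, tie-break to the first map, flagged
  m3 <- retino_map(patch, rep(0, n), rep(1, n))
  m4 <- retino_map(patch, rep(180, n), rep(1, n))
  expect_warning(avg_deg <- group_average(list(m3, m4)), "zero resultant")
  expect_true(all(avg_deg$degenerate))
  expect_equal(avg_deg$polar_angle, rep(0, n))

  # mismatched patches rejected
  other <- make_flat_patch(900, "left", seed = 9)
  m5 <- retino_map(other, rep(0, nrow(other)), rep(1, nrow(other)))
  expect_error(group_average(list(m1, m5)), "same patch")
})

test_that("eccentricity mask keeps 1-8 degrees by default and validates bounds", {
  patch <- fix_small_patch()
  canon <- fix_small_canon()
  avg <- group_average(list(canon))
  mask <- eccentricity_mask(avg)
  expect_identical(mask, avg$eccentricity >= 1 & avg$eccentricity <= 8)
  expect_true(any(mask) && any(!mask))
  expect_true(all(eccentricity_mask(avg, 0, Inf)))
  expect_error(eccentricity_mask(avg, 8, 1), "lo < hi")
})

test_that("individual variability equals a per-vertex loop oracle and known offsets", {
  patch <- fix_small_patch()
  canon <- fix_small_canon()
  avg <- group_average(list(canon))
  mask <- eccentricity_mask(avg)

  expect_equal(
    individual_variability(canon, avg, mask, "V3d", "polar"), 0
  )

  # constant +10 degree polar offset inside the ROI -> exactly 10
  th <- canon$polar_angle
  sel <- patch$roi_label == "V3d"
  th[sel] <- (th[sel] + 10) %% 360
  shifted <- retino_map(patch, th, canon$eccentricity)
  expect_equal(individual_variability(shifted, avg, mask, "V3d", "polar"), 10)
  # the untouched ventral stratum is unaffected
  expect_equal(individual_variability(shifted, avg, mask, "V3v", "polar"), 0)

  # random map equals the straight loop oracle
  withr::with_seed(7, {
    rnd <- retino_map(patch, runif(nrow(patch), 0, 360), runif(nrow(patch), 0, 10))
  })
  for (q in c("polar", "eccentricity")) {
    got <- individual_variability(rnd, avg, mask, c("V2d", "V2v"), q)
    idx <- which(patch$roi_label %in% c("V2d", "V2v") & mask)
    acc <- 0
    for (v in idx) {
      acc <- acc + if (q == "polar") {
        min(
          abs(rnd$polar_angle[v] - avg$polar_angle[v]),
          abs(rnd$polar_angle[v] - avg$polar_angle[v] + 360),
          abs(rnd$polar_angle[v] - avg$polar_angle[v] - 360)
        )
      } else {
        abs(rnd$eccentricity[v] - avg$eccentricity[v])
      }
    }
    expect_equal(got, acc / length(idx), tolerance = 1e-9)
  }

  # invariant to adding full turns to the polar angle
  plus_turn <- retino_map(patch, (rnd$polar_angle + 360) %% 360, rnd$eccentricity)
  expect_equal(
    individual_variability(plus_turn, avg, mask, "V1d", "polar"),
    individual_variability(rnd, avg, mask, "V1d", "polar"),
    tolerance = 1e-9
  )

  expect_error(
    individual_variability(rnd, avg, rep(FALSE, nrow(patch)), "V1d", "polar"),
    "V1d"
  )
})

test_that("covariate and intra-individual variability follow the same aggregation", {
  patch <- fix_small_patch()
  canon <- fix_small_canon()
  avg <- group_average(list(canon))
  mask <- eccentricity_mask(avg)
  n <- nrow(patch)

  f <- rep(0.5, n)
  expect_equal(covariate_variability(f, f, mask, "V1d", patch), 0)
  expect_equal(covariate_variability(f + 0.3, f, mask, "V1d", patch), 0.3)
  withr::with_seed(3, g <- rnorm(n))
  idx <- which(patch$roi_label == "V2v" & mask)
  expect_equal(
    covariate_variability(g, f, mask, "V2v", patch),
    mean(abs(g[idx] - f[idx])),
    tolerance = 1e-12
  )

  expect_equal(intra_individual_variability(canon, canon, mask, "V3d", "polar"), 0)
  th5 <- retino_map(patch, (canon$polar_angle + 5) %% 360, canon$eccentricity)
  expect_equal(intra_individual_variability(canon, th5, mask, "V3d", "polar"), 5)
})

test_that("split-half variability grows with the intra-individual noise scale", {
  patch <- fix_small_patch()
  vals <- sapply(c(2, 6, 12), function(s) {
    spec <- population_spec(4,
      variant_proportions = c(canonical = 1),
      base_polar_sd = 5, intra_polar_sd = s, seed = 11
    )
    pop <- simulate_population(spec, patch)
    mean(sapply(pop$subjects, function(su) {
      intra_individual_variability(su$hemis$left$fit2, su$hemis$left$fit3,
        NULL, "V1d", "polar")
    }))
  })
  expect_true(all(diff(vals) > 0))
})

test_that("normalize_bold scales to (0, 1] and rejects non-positive fields", {
  expect_equal(normalize_bold(c(1, 2, 4)), c(0.25, 0.5, 1))
  expect_equal(normalize_bold(rep(7, 5)), rep(1, 5))
  withr::with_seed(1, b <- runif(100, 0.5, 3))
  expect_equal(normalize_bold(b), normalize_bold(17 * b))
  expect_error(normalize_bold(c(1, 0)), "> 0")
  expect_error(normalize_bold(c(1, -2)), "> 0")
})

test_that("fold_polar_to_meridian maps meridians to the stated anchors", {
  expect_equal(fold_polar_to_meridian(c(90, 270)), c(90, 90))
  expect_equal(fold_polar_to_meridian(c(0, 180)), c(0, 0))
  expect_equal(fold_polar_to_meridian(315), 45)
  th <- seq(0, 359.5, by = 0.5)
  f <- fold_polar_to_meridian(th)
  expect_true(all(f >= 0 & f <= 90))
})

test_that("pairwise correlations recover planted coupling and self-correlation", {
  patch <- fix_small_patch()
  spec <- population_spec(6,
    variant_proportions = c(canonical = 1),
    base_polar_sd = 8, hemisphere_noise_ratio = 1, portion_noise_ratio = 1,
    area_noise_gradient = c(1, 1, 1), seed = 5
  )
  pop <- simulate_population(spec, patch)
  maps <- population_maps(pop, "left", "map")
  pc <- pairwise_correlations(maps, roi_labels = c("V1d", "V1v"))
  expect_setequal(
    unique(c(pc$var1, pc$var2)),
    c("polar_angle", "eccentricity", "curvature", "mean_bold")
  )
  # curvature is constructed anticorrelated with folded polar angle over V1
  r_curv <- pc$r[pc$var1 == "polar_angle" & pc$var2 == "curvature"]
  expect_lt(r_curv, -0.3)
  expect_true(all(pc$p >= 0 & pc$p <= 1))

  # a field correlated with itself -> 1
  m <- maps[[1]]
  same <- list(
    retino_map(m$patch, m$polar_angle, m$eccentricity,
      curvature = fold_polar_to_meridian(m$polar_angle), mean_bold = m$mean_bold),
    retino_map(m$patch, maps[[2]]$polar_angle, maps[[2]]$eccentricity,
      curvature = fold_polar_to_meridian(maps[[2]]$polar_angle),
      mean_bold = maps[[2]]$mean_bold)
  )
  pc2 <- pairwise_correlations(same, roi_labels = "V1d")
  expect_equal(pc2$r[pc2$var1 == "polar_angle" & pc2$var2 == "curvature"], 1)

  # independent random fields stay near zero correlation at large n
  withr::with_seed(21, {
    big <- lapply(1:4, function(i) {
      retino_map(patch, runif(nrow(patch), 0, 360), runif(nrow(patch), 0, 10),
        curvature = rnorm(nrow(patch)), mean_bold = runif(nrow(patch), 0.5, 2))
    })
  })
  pc3 <- pairwise_correlations(big, roi_labels = c("V1d", "V1v", "V2d", "V2v", "V3d", "V3v"))
  expect_true(all(abs(pc3$r) < 0.05))
})
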