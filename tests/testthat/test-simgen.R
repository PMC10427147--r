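# Synthetic patch, canonical fields, motif variants, covariates, populations.

test_that("flat patches are deterministic, banded, and reject tiny inputs", {
  p1 <- make_flat_patch(6000, "left", seed = 1)
  p2 <- make_flat_patch(6000, "left", seed = 1)
  expect_identical(p1, p2)
  p3 <- make_flat_patch(6000, "left", seed = 2)
  expect_false(identical(p1$x, p3$x))

  expect_identical(sort(unique(p1$roi_label)),
    sort(c("V1d", "V1v", "V2d", "V2v", "V3d", "V3v")))
  expect_false(any(duplicated(p1$vertex_id)))
  expect_true(all(is.finite(p1$x)) && all(is.finite(p1$y)))
  # dorsal and ventral labels occupy disjoint half-planes
  dorsal <- p1$roi_label %in% c("V1d", "V2d", "V3d")
  expect_true(all(p1$y[dorsal] > 0))
  expect_true(all(p1$y[!dorsal] < 0))

  expect_error(make_flat_patch(10, "left", 1), ">= 500")
})

test_that("canonical fields carry meridians on area borders and a monotone eccentricity axis", {
  tmpl <- function(y) retinovar:::canonical_polar_template(y, "left")
  expect_equal(tmpl(1), 270) # V1d/V2d border: vertical meridian
  expect_equal(tmpl(2), 0) # V2d/V3d border: horizontal meridian (360 == 0)
  expect_equal(tmpl(-1), 90) # V1v/V2v border
  expect_equal(tmpl(-2), 0) # V2v/V3v border
  expect_equal(tmpl(3), 270) # V3d anterior border
  expect_equal(tmpl(-3), 90) # V3v anterior border

  # right hemisphere: angles mapped through 180
  tmplr <- function(y) retinovar:::canonical_polar_template(y, "right")
  expect_equal(tmplr(1), 270) # vertical meridian is shared
  expect_equal(tmplr(2), 180) # horizontal meridian, right convention
  expect_equal(tmplr(-1), 90)

  canon <- fix_canon()
  patch <- fix_patch()
  expect_true(all(canon$eccentricity >= 0 & canon$eccentricity <= 10))
  ord <- order(patch$x)
  expect_true(all(diff(canon$eccentricity[ord]) >= 0))

  # a patch missing a band is rejected
  broken <- fix_patch()
  broken$roi_label[broken$roi_label == "V2d"] <- "V1d"
  expect_error(canonical_fields(broken), "V2d")
})

test_that("variant constructor validates parameters", {
  expect_error(map_variant("fork", truncation_angle = 200), "270")
  expect_error(map_variant("fork", fork_depth = -1), "fork_depth")
  expect_error(map_variant("fork", noise_kappa = 0), "noise_kappa")
  expect_error(map_variant("spiral"), "arg")
})

test_that("variants preserve labels, eccentricity and the ventral portion", {
  canon <- fix_canon()
  patch <- fix_patch()
  ventral <- patch$roi_label %in% c("V1v", "V2v", "V3v")

  ident <- apply_variant(canon, map_variant("canonical", noise_kappa = Inf))
  expect_equal(ident$polar_angle, canon$polar_angle)
  expect_equal(ident$eccentricity, canon$eccentricity)

  for (kind in c("fork", "truncated")) {
    m <- apply_variant(canon, map_variant(kind, noise_kappa = Inf))
    expect_identical(m$patch$roi_label, patch$roi_label)
    expect_equal(m$eccentricity, canon$eccentricity)
    expect_equal(m$polar_angle[ventral], canon$polar_angle[ventral])
  }

  # fork changes only a pocket inside V3d
  mf <- apply_variant(canon, map_variant("fork", noise_kappa = Inf))
  changed <- which(circ_diff(mf$polar_angle, canon$polar_angle) > 1e-9)
  expect_true(length(changed) > 0)
  expect_true(all(patch$roi_label[changed] == "V3d"))

  # truncated caps the anterior-most polar angle of V3d at the truncation angle
  mt <- apply_variant(canon, map_variant("truncated", truncation_angle = 300,
    noise_kappa = Inf))
  v3d <- patch$roi_label == "V3d"
  sh <- shift_wraparound(mt$polar_angle[v3d], "left")
  expect_true(all(sh >= 300 - 360 - 1e-9))
  expect_true(min(sh) < 300 - 360 + 2) # and it reaches the cap
  # gradient direction is preserved: angle still decreases along +y
  ord <- order(patch$y[v3d])
  fit <- stats::coef(stats::lm(sh[ord] ~ patch$y[v3d][ord]))[2]
  expect_lt(fit, 0)

  # noise is seed-deterministic and vanishes as kappa -> Inf
  n1 <- apply_variant(canon, map_variant("noisy", noise_kappa = 33, seed = 4))
  n2 <- apply_variant(canon, map_variant("noisy", noise_kappa = 33, seed = 4))
  expect_identical(n1$polar_angle, n2$polar_angle)
  n3 <- apply_variant(canon, map_variant("noisy", noise_kappa = 1e12, seed = 4))
  expect_lt(max(circ_diff(n3$polar_angle, canon$polar_angle)), 1e-3)
})

test_that("synthetic covariates are deterministic with planted vein depressions", {
  patch <- fix_patch()
  c1 <- synth_covariates(patch, seed = 5)
  c2 <- synth_covariates(patch, seed = 5)
  expect_identical(c1, c2)

  # bold minimum inside a planted vein region is below the field median
  v <- c1$vein_centers[1, ]
  near <- (patch$x - v["x"])^2 + (patch$y - v["y"])^2 < 0.35^2
  expect_lt(min(c1$bold[near]), stats::median(c1$bold))
  expect_true(all(c1$bold > 0))
})

test_that("population simulation is reproducible and respects the noiseless limit", {
  patch <- fix_small_patch()
  spec <- population_spec(5,
    variant_proportions = c(canonical = 1),
    hemisphere_noise_ratio = 1, portion_noise_ratio = 1,
    area_noise_gradient = c(1, 1, 1),
    base_polar_sd = 0, base_ecc_sd = 0, intra_polar_sd = 0, intra_ecc_sd = 0,
    subject_scale_sd = 0, seed = 3
  )
  pop <- simulate_population(spec, patch)
  canon_l <- canonical_fields(pop$patches$left)
  for (s in pop$subjects) {
    expect_equal(s$hemis$left$map$polar_angle, canon_l$polar_angle)
    expect_equal(s$hemis$left$fit2$polar_angle, canon_l$polar_angle)
  }

  spec2 <- population_spec(4, base_polar_sd = 10, seed = 9)
  p1 <- simulate_population(spec2, patch)
  p2 <- simulate_population(spec2, patch)
  expect_identical(p1$manifest, p2$manifest)
  expect_identical(
    p1$subjects[[3]]$hemis$right$map$polar_angle,
    p2$subjects[[3]]$hemis$right$map$polar_angle
  )

  expect_error(population_spec(1), "n_subjects")
  expect_error(population_spec(10, variant_proportions = c(canonical = 0.7)), "sum to 1")
  expect_error(population_spec(10, hemisphere_noise_ratio = 0), "> 0")
})

test_that("raising a stratum noise ratio raises that stratum's measured variability", {
  # planted-effect monotonicity, checked across seeds
  patch <- fix_small_patch()
  diffs <- sapply(1:20, function(s) {
    spec <- population_spec(8,
      variant_proportions = c(canonical = 1),
      hemisphere_noise_ratio = 1.5, portion_noise_ratio = 1,
      area_noise_gradient = c(1, 1, 1), base_polar_sd = 10,
      subject_scale_sd = 0, seed = 1000 + s
    )
    pop <- simulate_population(spec, patch)
    rec <- variability_records(pop)
    mean(rec$polar_variability[rec$hemisphere == "LH"]) -
      mean(rec$polar_variability[rec$hemisphere == "RH"])
  })
  expect_true(all(diffs > 0))
  expect_gt(mean(diffs), 1)
})
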