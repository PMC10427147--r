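# Synthetic flattened-cortex retinotopy generator: canonical maps, dorsal-V3
# motif variants (fork / truncation), covariate fields, and populations with
# planted variability effects.
#
# Geometry: a rectangular flat patch, x in [0, 10] (eccentricity axis), y in
# [-3, 3] with six parallel ROI bands of unit height ordered
# V3v, V2v, V1v | V1d, V2d, V3d along +y; ventral y < 0, dorsal y > 0. This
# stands in for a flattened cortical surface: the analysis only consumes
# per-vertex values and flat coordinates, which the rectangle preserves.

PATCH_WIDTH <- 10
# Eccentricity deviations are larger-scale than polar-angle ones: real maps
# shift or compress iso-eccentricity bands without reversing the global
# eccentricity gradient, so their noise fields use longer wavelengths.
ECC_WAVELENGTH <- c(6, 12)
BAND_BREAKS <- c(-3, -2, -1, 0, 1, 2, 3)
BAND_ORDER <- c("V3v", "V2v", "V1v", "V1d", "V2d", "V3d")

band_label <- function(y) {
  idx <- findInterval(y, BAND_BREAKS, rightmost.closed = TRUE)
  idx[idx < 1 | idx > 6] <- NA_integer_
  BAND_ORDER[idx]
}

#' Generate a rectangular flat cortical patch with six ROI bands
#'
#' Vertices are laid out as a jittered grid covering x in \[0, 10\] (the
#' eccentricity axis) and y in \[-3, 3\], with unit-height ROI bands ordered
#' V3v, V2v, V1v, V1d, V2d, V3d along +y. Dorsal labels occupy y > 0 and
#' ventral labels y < 0.
#'
#' @param n_vertices number of vertices (>= 500, so each band is well
#'   populated).
#' @param hemisphere `"left"` or `"right"`.
#' @param seed integer seed; the construction is fully deterministic given it.
#' @return a `flat_patch`: a data frame with columns `vertex_id` (0-based),
#'   `x`, `y`, `roi_label`, and a `hemisphere` attribute.
#' @export
make_flat_patch <- function(n_vertices, hemisphere = c("left", "right"), seed = 1L) {
  hemisphere <- match.arg(hemisphere)
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 500L) {
    stop_nf("make_flat_patch: n_vertices must be >= 500 (got ", n_vertices,
      "); fewer vertices cannot populate six ROI bands reliably")
  }
  ny <- max(12L, as.integer(round(sqrt(n_vertices * 6 / PATCH_WIDTH))))
  nx <- as.integer(ceiling(n_vertices / ny))
  dx <- PATCH_WIDTH / nx
  dy <- 6 / ny
  centers <- expand.grid(
    x = (seq_len(nx) - 0.5) * dx,
    y = -3 + (seq_len(ny) - 0.5) * dy
  )
  with_seed(seed, {
    keep <- sort(sample.int(nrow(centers), n_vertices))
    x <- centers$x[keep] + stats::runif(n_vertices, -0.45, 0.45) * dx
    y <- centers$y[keep] + stats::runif(n_vertices, -0.45, 0.45) * dy
  })
  patch <- data.frame(
    vertex_id = seq_len(n_vertices) - 1L,
    x = x,
    y = y,
    roi_label = band_label(y),
    stringsAsFactors = FALSE
  )
  attr(patch, "hemisphere") <- hemisphere
  class(patch) <- c("flat_patch", "data.frame")
  if (length(unique(patch$roi_label)) < 6L) {
    stop_nf("make_flat_patch: patch does not populate all six ROI bands")
  }
  patch
}

#' @export
print.flat_patch <- function(x, ...) {
  cat("<flat_patch> ", nrow(x), " vertices, ", attr(x, "hemisphere"),
    " hemisphere, bands: ", paste(BAND_ORDER, collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

# Canonical polar-angle template (degrees) as a function of the band
# coordinate y, left hemisphere: a piecewise-linear zigzag whose reversals at
# band borders are the vertical (90/270) and horizontal (0/360) meridians.
canonical_polar_template <- function(y, hemisphere) {
  th <- ifelse(y <= -2, -90 * (y + 2), # V3v: 90 -> 0
    ifelse(y <= -1, 90 * (y + 2), # V2v: 0 -> 90
      ifelse(y <= 0, -90 * y, # V1v: 90 -> 0
        ifelse(y <= 1, 360 - 90 * y, # V1d: 360 -> 270
          ifelse(y <= 2, 180 + 90 * y, # V2d: 270 -> 360
            540 - 90 * y # V3d: 360 -> 270
          )
        )
      )
    )
  )
  if (hemisphere == "right") th <- 180 - th
  wrap_angle(th)
}

#' Canonical retinotopic fields on a flat patch
#'
#' Eccentricity increases linearly along +x from 0 to `ecc_max`. Polar angle
#' follows the canonical zigzag in y: area borders carry meridian
#' representations (left hemisphere: 90 deg at the V1v/V2v and V3v anterior
#' borders, 270 deg at V1d/V2d and the V3d anterior border, 0/360 deg at the
#' V2v/V3v and V2d/V3d borders and the dorsoventral midline). Right-hemisphere
#' angles are the left template mapped through 180 deg.
#'
#' @param patch a `flat_patch` containing all six ROI bands.
#' @param ecc_max maximum eccentricity in degrees (>= 8; the default 10
#'   extends a little beyond the 8-degree mask ceiling, as pRF fits do).
#' @return a [retino_map].
#' @export
canonical_fields <- function(patch, ecc_max = 10) {
  stopifnot(inherits(patch, "flat_patch"))
  if (ecc_max < 8) stop_nf("canonical_fields: ecc_max must be >= 8")
  missing <- setdiff(BAND_ORDER, unique(patch$roi_label))
  if (length(missing)) {
    stop_nf("canonical_fields: patch is missing ROI band(s): ",
      paste(missing, collapse = ", "))
  }
  hemi <- attr(patch, "hemisphere")
  retino_map(
    patch,
    polar_angle = canonical_polar_template(patch$y, hemi),
    eccentricity = ecc_max * patch$x / PATCH_WIDTH
  )
}

#' Describe a map variant
#'
#' Variants reproduce the dorsal map motifs seen across individuals:
#' `"canonical"` (the template), `"fork"` (a Y-shaped lower-vertical
#' representation: an extra polar-angle reversal inside anterior V3d that
#' produces an opposite-field-sign pocket), `"truncated"` (dorsal V3 does not
#' reach the lower vertical meridian: polar angle capped at
#' `truncation_angle`), and `"noisy"` (angular noise only).
#'
#' @param kind one of `"canonical"`, `"fork"`, `"truncated"`, `"noisy"`.
#' @param fork_depth degrees of polar-angle incursion of the fork (0--80);
#'   sets the half-height of the reversed pocket (depth/180 band units).
#' @param truncation_angle degrees in \[270, 360): the anterior-most polar
#'   angle reached by dorsal V3 (left-hemisphere convention).
#' @param noise_kappa concentration of the angular noise; the wrapped-normal
#'   noise SD is `(180/pi)/sqrt(noise_kappa)` degrees. `Inf` means no noise.
#' @param ecc_sd eccentricity noise SD in degrees; defaults to the angular
#'   noise SD divided by 23 (the observed polar-to-eccentricity variability
#'   scale ratio).
#' @param seed integer seed for the noise fields.
#' @return an object of class `map_variant`.
#' @export
map_variant <- function(kind = c("canonical", "fork", "truncated", "noisy"),
                        fork_depth = 60, truncation_angle = 300,
                        noise_kappa = Inf, ecc_sd = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (!(truncation_angle >= 270 && truncation_angle < 360)) {
    stop_nf("map_variant: truncation_angle must be in [270, 360)")
  }
  if (fork_depth < 0 || fork_depth > 80) {
    stop_nf("map_variant: fork_depth must be in [0, 80] degrees")
  }
  if (!(noise_kappa > 0)) stop_nf("map_variant: noise_kappa must be > 0")
  sd_deg <- if (is.infinite(noise_kappa)) 0 else (180 / pi) / sqrt(noise_kappa)
  structure(
    list(
      kind = kind, fork_depth = fork_depth,
      truncation_angle = truncation_angle,
      noise_kappa = noise_kappa, polar_sd = sd_deg,
      ecc_sd = ecc_sd %||% (sd_deg / 23),
      seed = as.integer(seed)
    ),
    class = "map_variant"
  )
}

# Fork pocket: ellipse in anterior V3d, centred mid-eccentricity.
fork_pocket <- function(patch, fork_depth) {
  xc <- PATCH_WIDTH / 2
  yc <- 2.55
  a <- 0.18 * PATCH_WIDTH
  b <- fork_depth / 180
  inside <- ((patch$x - xc) / a)^2 + ((patch$y - yc) / b)^2 <= 1
  inside & patch$roi_label == "V3d"
}

#' Apply a map variant to a canonical map
#'
#' `"fork"` mirrors the polar-angle progression about the pocket's centre
#' line inside an elliptical region of anterior V3d, reversing the gradient
#' there so the lower-vertical (270 deg) representation bifurcates;
#' `"truncated"` compresses the V3d polar-angle range so its anterior border
#' reaches only `truncation_angle` instead of the lower vertical meridian (a
#' monotone rescaling: no extra reversal, hence no field-sign discontinuity); `"noisy"` and `"canonical"` add
#' only the angular/eccentricity noise controlled by `noise_kappa`. Motifs
#' never touch the ventral portion, ROI labels, or (noise aside) the
#' eccentricity field.
#'
#' @param map a canonical [retino_map] (see [canonical_fields()]).
#' @param variant a [map_variant].
#' @return a [retino_map] with the motif and noise applied.
#' @export
apply_variant <- function(map, variant) {
  stopifnot(inherits(map, "retino_map"), inherits(variant, "map_variant"))
  patch <- map$patch
  hemi <- map$hemisphere
  theta <- map$polar_angle
  ecc <- map$eccentricity

  if (variant$kind == "fork") {
    pocket <- fork_pocket(patch, variant$fork_depth)
    yc <- 2.55
    theta[pocket] <- canonical_polar_template(2 * yc - patch$y[pocket], hemi)
  } else if (variant$kind == "truncated") {
    v3d <- patch$roi_label == "V3d"
    f <- (360 - variant$truncation_angle) / 90
    if (hemi == "left") {
      # shifted scale: canonical V3d runs 0 -> -90; compress to 0 -> -(360 - cap)
      sh <- shift_wraparound(theta[v3d], "left")
      theta[v3d] <- wrap_angle(pmin(sh, 0) * f)
    } else {
      # canonical V3d runs 180 -> 270; compress towards 180
      theta[v3d] <- 180 + (pmax(theta[v3d], 180) - 180) * f
    }
  } else if (!variant$kind %in% c("canonical", "noisy")) {
    stop_nf("apply_variant: unknown variant kind")
  }

  if (variant$polar_sd > 0 || variant$ecc_sd > 0) {
    with_seed(variant$seed, {
      theta <- wrap_angle(theta + smooth_field(patch$x, patch$y, sd = variant$polar_sd))
      ecc <- pmax(ecc + smooth_field(patch$x, patch$y, sd = variant$ecc_sd,
        wavelength = ECC_WAVELENGTH), 0)
    })
  }
  retino_map(patch, theta, ecc, curvature = map$curvature, mean_bold = map$mean_bold)
}

#' Synthetic covariate fields: curvature and mean BOLD
#'
#' Curvature is a smooth oscillation locked to the polar-angle zigzag phase
#' (`cos(pi * y)`: gyral crowns at area-band midlines, sulcal fundi at the
#' borders) plus a small seeded smooth perturbation, so curvature and folded
#' polar angle are negatively correlated over V1 by construction. The mean
#' BOLD field is a positive baseline with localized "venous" depressions at
#' seeded locations.
#'
#' @param patch a `flat_patch`.
#' @param seed integer seed.
#' @param n_veins number of simulated venous depressions.
#' @return list with components `curvature` and `bold` (per-vertex fields)
#'   and `vein_centers` (matrix of the planted depression centres).
#' @export
synth_covariates <- function(patch, seed = 1L, n_veins = 3L) {
  stopifnot(inherits(patch, "flat_patch"))
  with_seed(seed, {
    curv <- cos(pi * patch$y) +
      0.3 * smooth_field(patch$x, patch$y, sd = 1, wavelength = c(3, 8))
    vx <- stats::runif(n_veins, 1, PATCH_WIDTH - 1)
    vy <- stats::runif(n_veins, -2.5, 2.5)
    bold <- rep(1, nrow(patch))
    for (v in seq_len(n_veins)) {
      d2 <- (patch$x - vx[v])^2 + (patch$y - vy[v])^2
      bold <- bold - 0.6 * exp(-d2 / (2 * 0.35^2))
    }
    bold <- pmax(bold, 0.2) * 1000
  })
  list(curvature = curv, bold = bold, vein_centers = cbind(x = vx, y = vy))
}

#' Specify a synthetic population
#'
#' Defines the study conditions for a simulated cohort: how many subjects,
#' the mixture of dorsal map motifs, and the planted variability structure.
#' Between-subject map deviations are smooth wrapped-Gaussian fields whose
#' vertex-wise SD is `base_polar_sd` scaled multiplicatively by hemisphere
#' (left noisier), portion (dorsal noisier) and visual area (V1 < V2 < V3),
#' mimicking the observed ordering of individual variability. The defaults
#' reproduce the scale of variability reported for the 181-subject reference
#' cohort (metric intercept about 18.6 deg for polar angle).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param variant_proportions named proportions over variant kinds
#'   (must sum to 1).
#' @param hemisphere_noise_ratio multiplier (> 0) applied to left-hemisphere
#'   noise SD.
#' @param portion_noise_ratio multiplier (> 0) applied to dorsal-vertex noise
#'   SD.
#' @param area_noise_gradient length-3 multipliers for V1, V2, V3.
#' @param base_polar_sd baseline between-subject polar-angle SD in degrees.
#' @param base_ecc_sd baseline eccentricity SD in degrees.
#' @param intra_polar_sd,intra_ecc_sd SD of the split-half (intra-individual)
#'   noise in degrees.
#' @param subject_scale_sd SD of the log-normal per-subject noise multiplier
#'   (mean 1); plants subject-level clustering for the mixed model.
#' @param fork_depth,truncation_angle motif parameters passed to
#'   [map_variant()].
#' @param exact_counts if `TRUE`, variant labels are assigned in exact
#'   proportion (rounded) and shuffled, instead of drawn independently.
#' @param ecc_max maximum eccentricity in degrees.
#' @param seed integer population seed; per-subject seeds derive from it.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_subjects,
                            variant_proportions = c(canonical = 1 / 3, fork = 1 / 3, truncated = 1 / 3),
                            hemisphere_noise_ratio = 1.22,
                            portion_noise_ratio = 1.22,
                            area_noise_gradient = c(V1 = 1, V2 = 1.13, V3 = 1.21),
                            base_polar_sd = 23.3,
                            base_ecc_sd = base_polar_sd / 23,
                            intra_polar_sd = 8,
                            intra_ecc_sd = 0.35,
                            subject_scale_sd = 0.10,
                            fork_depth = 60,
                            truncation_angle = 300,
                            ecc_max = 10,
                            exact_counts = FALSE,
                            seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop_nf("population_spec: n_subjects must be >= 2")
  if (is.null(names(variant_proportions)) ||
    !all(names(variant_proportions) %in% c("canonical", "fork", "truncated", "noisy"))) {
    stop_nf("population_spec: variant_proportions must be named with variant kinds")
  }
  if (abs(sum(variant_proportions) - 1) > 1e-8) {
    stop_nf("population_spec: variant_proportions must sum to 1")
  }
  if (hemisphere_noise_ratio <= 0 || portion_noise_ratio <= 0 ||
    any(area_noise_gradient <= 0)) {
    stop_nf("population_spec: noise multipliers must be > 0")
  }
  if (length(area_noise_gradient) != 3L) {
    stop_nf("population_spec: area_noise_gradient must have 3 entries (V1, V2, V3)")
  }
  structure(
    list(
      n_subjects = n_subjects,
      variant_proportions = variant_proportions,
      hemisphere_noise_ratio = hemisphere_noise_ratio,
      portion_noise_ratio = portion_noise_ratio,
      area_noise_gradient = stats::setNames(area_noise_gradient, c("V1", "V2", "V3")),
      base_polar_sd = base_polar_sd,
      base_ecc_sd = base_ecc_sd,
      intra_polar_sd = intra_polar_sd,
      intra_ecc_sd = intra_ecc_sd,
      subject_scale_sd = subject_scale_sd,
      fork_depth = fork_depth,
      truncation_angle = truncation_angle,
      ecc_max = ecc_max,
      exact_counts = isTRUE(exact_counts),
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
}

# Per-vertex noise SD implied by the planted multiplicative structure.
stratum_sd <- function(spec, patch, hemisphere, base) {
  area <- roi_area(patch$roi_label)
  portion <- roi_portion(patch$roi_label)
  s <- rep(base, nrow(patch))
  s <- s * ifelse(is.na(area), 1, spec$area_noise_gradient[area])
  s <- s * ifelse(!is.na(portion) & portion == "dorsal", spec$portion_noise_ratio, 1)
  if (hemisphere == "left") s <- s * spec$hemisphere_noise_ratio
  s
}

#' Simulate a population of subjects with planted structure
#'
#' For each subject, a motif variant is drawn from `variant_proportions` and
#' applied to the canonical template of each hemisphere; a smooth
#' between-subject deviation field (vertex-wise SD set by the planted
#' hemisphere/portion/area multipliers and a per-subject scale factor) is
#' added; two split-half fits add independent intra-individual noise; and
#' per-subject covariate fields (curvature, mean BOLD) are attached. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec a [population_spec].
#' @param patch a left-hemisphere `flat_patch`; the right hemisphere reuses
#'   the same flat geometry with angles mapped through 180 deg.
#' @return an object of class `retino_population`: list with `subjects` (each
#'   holding `map`, `fit2`, `fit3` per hemisphere plus the true variant
#'   label), `patches`, `spec`, and a `manifest` data frame
#'   (subject_id, true_variant, seed).
#' @export
simulate_population <- function(spec, patch) {
  stopifnot(inherits(spec, "population_spec"), inherits(patch, "flat_patch"))
  patches <- list(left = patch, right = patch)
  attr(patches$left, "hemisphere") <- "left"
  attr(patches$right, "hemisphere") <- "right"
  canon <- lapply(patches, canonical_fields, ecc_max = spec$ecc_max)
  base_cov <- synth_covariates(patch, seed = spec$seed)

  kinds <- names(spec$variant_proportions)
  with_seed(spec$seed, {
    variants <- if (spec$exact_counts) {
      counts <- round(spec$variant_proportions * spec$n_subjects)
      while (sum(counts) < spec$n_subjects) counts[1] <- counts[1] + 1
      while (sum(counts) > spec$n_subjects) counts[which.max(counts)] <- max(counts) - 1
      sample(rep(kinds, times = counts))
    } else {
      sample(kinds, spec$n_subjects, replace = TRUE, prob = spec$variant_proportions)
    }
    sub_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_subjects)
  })

  subjects <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    id <- sprintf("sub%03d", i)
    hemis <- list()
    with_seed(sub_seeds[i], {
      u <- exp(stats::rnorm(1, -spec$subject_scale_sd^2 / 2, spec$subject_scale_sd))
      for (h in c("left", "right")) {
        ph <- patches[[h]]
        motif <- apply_variant(
          canon[[h]],
          map_variant(variants[i],
            fork_depth = spec$fork_depth,
            truncation_angle = spec$truncation_angle,
            noise_kappa = Inf
          )
        )
        sd_pol <- stratum_sd(spec, ph, h, spec$base_polar_sd) * u
        sd_ecc <- stratum_sd(spec, ph, h, spec$base_ecc_sd) * u
        z_pol <- smooth_field(ph$x, ph$y, sd = 1)
        z_ecc <- smooth_field(ph$x, ph$y, sd = 1, wavelength = ECC_WAVELENGTH)
        theta <- wrap_angle(motif$polar_angle + sd_pol * z_pol)
        ecc <- pmax(motif$eccentricity + sd_ecc * z_ecc, 0)
        curv <- base_cov$curvature + 0.15 * smooth_field(ph$x, ph$y, sd = 1)
        bold <- pmax(base_cov$bold * (1 + 0.03 * smooth_field(ph$x, ph$y, sd = 1)), 1)
        map <- retino_map(ph, theta, ecc, curvature = curv, mean_bold = bold)
        fits <- lapply(1:2, function(k) {
          retino_map(
            ph,
            wrap_angle(theta + smooth_field(ph$x, ph$y, sd = spec$intra_polar_sd)),
            pmax(ecc + smooth_field(ph$x, ph$y, sd = spec$intra_ecc_sd,
              wavelength = ECC_WAVELENGTH), 0),
            curvature = curv, mean_bold = bold
          )
        })
        hemis[[h]] <- list(map = map, fit2 = fits[[1]], fit3 = fits[[2]])
      }
    })
    subjects[[i]] <- list(
      subject_id = id, variant = variants[i], seed = sub_seeds[i], hemis = hemis
    )
  }
  structure(
    list(
      subjects = subjects,
      patches = patches,
      spec = spec,
      manifest = data.frame(
        subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
        true_variant = variants,
        seed = sub_seeds,
        stringsAsFactors = FALSE
      )
    ),
    class = "retino_population"
  )
}

#' @export
print.retino_population <- function(x, ...) {
  cat("<retino_population> ", length(x$subjects), " subjects; variants: ",
    paste(sprintf("%s=%d", names(table(x$manifest$true_variant)),
      table(x$manifest$true_variant)), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Extract one hemisphere's maps from a population
#'
#' @param pop a `retino_population`.
#' @param hemisphere `"left"` or `"right"`.
#' @param what `"map"`, `"fit2"` or `"fit3"`.
#' @return named list of [retino_map] objects, one per subject.
#' @export
population_maps <- function(pop, hemisphere = c("left", "right"),
                            what = c("map", "fit2", "fit3")) {
  stopifnot(inherits(pop, "retino_population"))
  hemisphere <- match.arg(hemisphere)
  what <- match.arg(what)
  out <- lapply(pop$subjects, function(s) s$hemis[[hemisphere]][[what]])
  names(out) <- pop$manifest$subject_id
  out
}
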