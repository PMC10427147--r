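# Core map containers, circular arithmetic, the individual-variability metric,
# and covariate constructions.

ROI_LABELS <- c("V1d", "V1v", "V2d", "V2v", "V3d", "V3v")
DORSAL_LABELS <- c("V1d", "V2d", "V3d")
VENTRAL_LABELS <- c("V1v", "V2v", "V3v")

roi_area <- function(label) {
  ifelse(label %in% c("V1d", "V1v"), "V1",
    ifelse(label %in% c("V2d", "V2v"), "V2",
      ifelse(label %in% c("V3d", "V3v"), "V3", NA_character_)
    )
  )
}

roi_portion <- function(label) {
  ifelse(label %in% DORSAL_LABELS, "dorsal",
    ifelse(label %in% VENTRAL_LABELS, "ventral", NA_character_)
  )
}

#' Construct a retinotopic map on a flat patch
#'
#' A `retino_map` holds per-vertex polar angle (degrees, wrapped into
#' \[0, 360)) and eccentricity (degrees of visual angle, non-negative) for one
#' subject and hemisphere, with optional curvature and mean-BOLD covariate
#' fields, all aligned with the vertices of a [flat_patch].
#'
#' @param patch a `flat_patch` (see [make_flat_patch()]).
#' @param polar_angle numeric vector of polar angles in degrees; values are
#'   wrapped into \[0, 360).
#' @param eccentricity numeric vector of eccentricities in degrees, `>= 0`.
#' @param curvature optional signed scalar field (sulci negative, gyri
#'   positive by the usual convention).
#' @param mean_bold optional positive scalar field (mean BOLD intensity, a
#'   proxy for the location of large draining veins).
#' @return an object of class `retino_map`.
#' @export
retino_map <- function(patch, polar_angle, eccentricity,
                       curvature = NULL, mean_bold = NULL) {
  stopifnot(inherits(patch, "flat_patch"))
  n <- nrow(patch)
  if (length(polar_angle) != n || length(eccentricity) != n) {
    stop_nf("polar_angle and eccentricity must have one value per patch vertex (", n, ")")
  }
  if (any(!is.finite(polar_angle))) stop_nf("non-finite polar angle")
  if (any(!is.finite(eccentricity)) || any(eccentricity < 0)) {
    stop_nf("eccentricity must be finite and >= 0")
  }
  for (f in list(curvature, mean_bold)) {
    if (!is.null(f) && length(f) != n) stop_nf("covariate field length mismatch")
  }
  structure(
    list(
      patch = patch,
      polar_angle = wrap_angle(polar_angle),
      eccentricity = eccentricity,
      curvature = curvature,
      mean_bold = mean_bold,
      hemisphere = attr(patch, "hemisphere")
    ),
    class = "retino_map"
  )
}

#' @export
print.retino_map <- function(x, ...) {
  cat(
    "<retino_map> ", nrow(x$patch), " vertices, ", x$hemisphere, " hemisphere",
    if (!is.null(x$curvature)) ", +curvature", if (!is.null(x$mean_bold)) ", +BOLD",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Absolute circular difference between angles, in degrees
#'
#' Computes `MIN(|a - b|, |a - b + 360|, |a - b - 360|)`, the shortest angular
#' distance on the circle, returned in degrees in \[0, 180\]. This is the
#' vertex-wise difference score underlying the individual-variability metric.
#'
#' @param a,b angles in degrees (any finite values; vectors recycle).
#' @return numeric vector of circular differences in \[0, 180\].
#' @examples
#' circ_diff(10, 350) # 20
#' circ_diff(90, 270) # 180
#' @export
circ_diff <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop_nf("circ_diff: non-finite input angle")
  }
  d <- a - b
  pmin(abs(d %% 360), abs(d %% 360 - 360))
}

#' Vertex-wise group average of retinotopic maps
#'
#' Polar angle is averaged with the circular (resultant-vector) mean;
#' eccentricity, curvature and normalized mean BOLD with the arithmetic mean.
#' The per-vertex resultant length (in \[0, 1\]) records how concentrated the
#' individual angles are; a vanishing resultant makes the circular mean
#' undefined, in which case the first map's value is kept and the vertex is
#' flagged in `degenerate`.
#'
#' @param maps list of [retino_map] objects on the same patch.
#' @return an object of class `group_avg_map` with fields `polar_angle`,
#'   `eccentricity`, `resultant_length`, `degenerate`, and (when present on
#'   all maps) `curvature` and `mean_bold`.
#' @export
group_average <- function(maps) {
  if (!length(maps)) stop_nf("group_average: need at least one map")
  stopifnot(all(vapply(maps, inherits, logical(1), "retino_map")))
  p0 <- maps[[1]]$patch
  for (m in maps) {
    if (nrow(m$patch) != nrow(p0) ||
      max(abs(m$patch$x - p0$x)) > 1e-9 || max(abs(m$patch$y - p0$y)) > 1e-9) {
      stop_nf("group_average: maps are not on the same patch")
    }
  }
  th <- do.call(cbind, lapply(maps, `[[`, "polar_angle")) * pi / 180
  cs <- rowMeans(cos(th))
  sn <- rowMeans(sin(th))
  rl <- sqrt(cs^2 + sn^2)
  ang <- wrap_angle(atan2(sn, cs) * 180 / pi)
  degen <- rl < 1e-12
  if (any(degen)) {
    ang[degen] <- maps[[1]]$polar_angle[degen]
    warning(sum(degen), " vertex/vertices with zero resultant; first map's angle kept")
  }
  ecc <- rowMeans(do.call(cbind, lapply(maps, `[[`, "eccentricity")))
  avg <- list(
    patch = p0,
    polar_angle = ang,
    eccentricity = ecc,
    resultant_length = rl,
    degenerate = degen,
    hemisphere = attr(p0, "hemisphere")
  )
  if (all(vapply(maps, function(m) !is.null(m$curvature), logical(1)))) {
    avg$curvature <- rowMeans(do.call(cbind, lapply(maps, `[[`, "curvature")))
  }
  if (all(vapply(maps, function(m) !is.null(m$mean_bold), logical(1)))) {
    avg$mean_bold <- rowMeans(do.call(cbind, lapply(
      maps,
      function(m) normalize_bold(m$mean_bold)
    )))
  }
  structure(avg, class = "group_avg_map")
}

#' @export
print.group_avg_map <- function(x, ...) {
  cat(
    "<group_avg_map> ", nrow(x$patch), " vertices, ",
    sum(x$degenerate), " degenerate\n",
    sep = ""
  )
  invisible(x)
}

#' Eccentricity mask from a group-average map
#'
#' Selects vertices whose group-average eccentricity lies in `[lo, hi]`
#' degrees. The default 1--8 degrees excludes the foveal confluence (hard to
#' map) and the periphery beyond the mapping stimulus extent.
#'
#' @param avg a `group_avg_map`.
#' @param lo,hi mask bounds in degrees, `0 <= lo < hi`.
#' @return logical vector, one value per vertex.
#' @export
eccentricity_mask <- function(avg, lo = 1, hi = 8) {
  stopifnot(inherits(avg, "group_avg_map"))
  if (!(lo >= 0 && lo < hi)) stop_nf("eccentricity_mask: need 0 <= lo < hi")
  avg$eccentricity >= lo & avg$eccentricity <= hi
}

select_roi <- function(patch, mask, roi_labels, context) {
  sel <- patch$roi_label %in% roi_labels
  if (!is.null(mask)) sel <- sel & mask
  if (!any(sel)) {
    stop_nf(context, ": no vertices left in ROI {", paste(roi_labels, collapse = ", "),
      "} after masking")
  }
  sel
}

#' Individual-variability metric for one subject and stratum
#'
#' Averages the vertex-wise difference between an individual map and the
#' group-average map over the masked vertices of an ROI: circular difference
#' ([circ_diff]) for polar angle, absolute difference for eccentricity (which
#' is not periodic). The result is one scalar per subject, hemisphere, visual
#' area and portion -- a proxy for large-scale deviations in visual field
#' mapping, in degrees.
#'
#' @param map individual [retino_map].
#' @param avg `group_avg_map` on the same patch.
#' @param mask logical per-vertex mask (e.g. [eccentricity_mask()]), or
#'   `NULL` for no mask.
#' @param roi_labels character vector of ROI band labels, e.g. `"V3d"` or
#'   `c("V1d", "V1v")`.
#' @param quantity `"polar"` or `"eccentricity"`.
#' @return a single non-negative number (degrees).
#' @export
individual_variability <- function(map, avg, mask = NULL, roi_labels,
                                   quantity = c("polar", "eccentricity")) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(map, "retino_map"), inherits(avg, "group_avg_map"))
  sel <- select_roi(map$patch, mask, roi_labels, "individual_variability")
  if (quantity == "polar") {
    mean(circ_diff(map$polar_angle[sel], avg$polar_angle[sel]))
  } else {
    mean(abs(map$eccentricity[sel] - avg$eccentricity[sel]))
  }
}

#' Mean absolute deviation of a covariate field from its group average
#'
#' @param field per-vertex scalar field for one subject.
#' @param avg_field corresponding group-average field.
#' @param mask logical per-vertex mask or `NULL`.
#' @param roi_labels ROI band labels defining the stratum.
#' @param patch the `flat_patch` the fields live on.
#' @return mean absolute difference over the selected vertices.
#' @export
covariate_variability <- function(field, avg_field, mask = NULL, roi_labels, patch) {
  stopifnot(inherits(patch, "flat_patch"),
            length(field) == nrow(patch), length(avg_field) == nrow(patch))
  sel <- select_roi(patch, mask, roi_labels, "covariate_variability")
  mean(abs(field[sel] - avg_field[sel]))
}

#' Normalize a mean-BOLD field to (0, 1]
#'
#' Divides each vertex by the maximum intensity, so the output is scale-free
#' and its maximum is exactly 1. Low values mark candidate venous-eclipse
#' locations.
#'
#' @param bold positive per-vertex field.
#' @return field in (0, 1].
#' @export
normalize_bold <- function(bold) {
  if (any(!is.finite(bold)) || any(bold <= 0)) {
    stop_nf("normalize_bold: all values must be finite and > 0")
  }
  bold / max(bold)
}

#' Intra-individual (split-half) variability
#'
#' Same aggregation as [individual_variability()], applied between two pRF
#' model fits of split halves of one subject's data; a proxy for map
#' reliability, used as a covariate in the mixed model.
#'
#' @param fit2,fit3 the two split-half [retino_map] fits.
#' @inheritParams individual_variability
#' @return a single non-negative number (degrees).
#' @export
intra_individual_variability <- function(fit2, fit3, mask = NULL, roi_labels,
                                         quantity = c("polar", "eccentricity")) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(fit2, "retino_map"), inherits(fit3, "retino_map"))
  if (nrow(fit2$patch) != nrow(fit3$patch)) stop_nf("split-half fits on different patches")
  sel <- select_roi(fit2$patch, mask, roi_labels, "intra_individual_variability")
  if (quantity == "polar") {
    mean(circ_diff(fit2$polar_angle[sel], fit3$polar_angle[sel]))
  } else {
    mean(abs(fit2$eccentricity[sel] - fit3$eccentricity[sel]))
  }
}

#' Fold polar angle onto the meridian scale
#'
#' Maps \[0, 360) onto \[0, 90\] so that 0 corresponds to the horizontal
#' meridian and 90 to the upper and lower vertical meridians:
#' `90 - |90 - (theta mod 180)|`. Used before correlating polar angle with
#' covariate fields, where clock position per se is meaningless.
#'
#' @param theta polar angle in degrees, \[0, 360).
#' @return folded angle in \[0, 90\].
#' @examples
#' fold_polar_to_meridian(c(0, 90, 180, 270, 315)) # 0 90 0 90 45
#' @export
fold_polar_to_meridian <- function(theta) {
  if (any(!is.finite(theta))) stop_nf("fold_polar_to_meridian: non-finite input")
  90 - abs(90 - (theta %% 180))
}

#' Pairwise correlations among retinotopic and covariate maps
#'
#' Vectorizes folded polar angle, eccentricity, curvature and normalized mean
#' BOLD over an ROI for every map, concatenates across subjects, and reports
#' the Pearson correlation with a two-sided p-value for every pair of
#' modalities.
#'
#' @param maps list of [retino_map] objects (curvature and mean BOLD must be
#'   present) -- typically one per subject for a fixed hemisphere.
#' @param roi_labels ROI scope over which maps are vectorized.
#' @param mask optional logical per-vertex mask.
#' @return data frame with columns `var1`, `var2`, `r`, `p`, `n`. Pairs with a
#'   zero-variance member get `NA` correlation.
#' @export
pairwise_correlations <- function(maps, roi_labels, mask = NULL) {
  if (length(maps) < 2) stop_nf("pairwise_correlations: need at least 2 subjects")
  stopifnot(all(vapply(maps, inherits, logical(1), "retino_map")))
  patch <- maps[[1]]$patch
  sel <- select_roi(patch, mask, roi_labels, "pairwise_correlations")
  cols <- list(
    polar_angle = unlist(lapply(maps, function(m) fold_polar_to_meridian(m$polar_angle[sel]))),
    eccentricity = unlist(lapply(maps, function(m) m$eccentricity[sel])),
    curvature = unlist(lapply(maps, function(m) {
      if (is.null(m$curvature)) stop_nf("pairwise_correlations: map lacks curvature")
      m$curvature[sel]
    })),
    mean_bold = unlist(lapply(maps, function(m) {
      if (is.null(m$mean_bold)) stop_nf("pairwise_correlations: map lacks mean_bold")
      normalize_bold(m$mean_bold)[sel]
    }))
  )
  vars <- names(cols)
  out <- NULL
  for (i in seq_along(vars)[-length(vars)]) {
    for (j in seq((i + 1), length(vars))) {
      a <- cols[[i]]
      b <- cols[[j]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        row <- data.frame(
          var1 = vars[i], var2 = vars[j],
          r = NA_real_, p = NA_real_, n = length(a)
        )
      } else {
        ct <- stats::cor.test(a, b, method = "pearson", alternative = "two.sided")
        row <- data.frame(
          var1 = vars[i], var2 = vars[j],
          r = unname(ct$estimate), p = ct$p.value, n = length(a)
        )
      }
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}
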