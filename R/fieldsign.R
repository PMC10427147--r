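# Visual field sign analysis: re-express polar angle continuously, interpolate
# the flattened maps onto a regular grid, take gradients, and classify each
# cell as a mirror (+1) or non-mirror (-1) representation of the retina from
# the signed angle between the two gradient fields.

#' Re-express polar angle without the 360-to-0 wrap inside the mapped hemifield
#'
#' The left hemisphere maps the right visual hemifield (angles near 0/360), so
#' the wrap-around is moved to the ipsilateral horizontal meridian by
#' subtracting 360 from angles >= 180, yielding a continuous range
#' (-180, 180\] centred on the contralateral horizontal meridian. The right
#' hemisphere maps angles around 180 deg, where \[0, 360) is already
#' continuous, so values pass through unchanged.
#'
#' @param theta polar angle in degrees, \[0, 360).
#' @param hemisphere `"left"` or `"right"`.
#' @return continuous polar angle in degrees.
#' @examples
#' shift_wraparound(c(350, 90), "left") # -10 90
#' @export
shift_wraparound <- function(theta, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  if (any(!is.finite(theta))) stop_nf("shift_wraparound: non-finite angle")
  if (hemisphere == "left") {
    ifelse(theta >= 180, theta - 360, theta)
  } else {
    theta
  }
}

#' Interpolate scattered flat-map values onto a regular grid
#'
#' Piecewise-linear interpolation over a Delaunay triangulation of the
#' vertices; grid cells outside the convex hull of the data are masked. Affine
#' fields are reproduced exactly at interior cells.
#'
#' @param x,y flat-map vertex coordinates.
#' @param values per-vertex scalar values.
#' @param nx,ny grid resolution per axis (default 200 x 200 over the
#'   bounding box).
#' @param xlim,ylim grid extent; defaults to the data bounding box.
#' @return an object of class `grid_field`: list with `x`, `y` (cell-centre
#'   coordinates), `values` (nx-by-ny matrix, `NA` outside the hull) and
#'   `valid` (logical matrix).
#' @export
to_grid <- function(x, y, values, nx = 200, ny = 200,
                    xlim = range(x), ylim = range(y)) {
  if (length(x) < 3) stop_nf("to_grid: need at least 3 points")
  ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-14 * max(ev)) {
    stop_nf("to_grid: degenerate (collinear) geometry")
  }
  xo <- seq(xlim[1], xlim[2], length.out = nx)
  yo <- seq(ylim[1], ylim[2], length.out = ny)
  g <- tryCatch(
    interp::interp(x, y, values,
      xo = xo, yo = yo,
      method = "linear", output = "grid", duplicate = "mean"
    ),
    error = function(e) stop_nf("to_grid: interpolation failed: ", conditionMessage(e))
  )
  structure(
    list(x = g$x, y = g$y, values = g$z, valid = !is.na(g$z)),
    class = "grid_field"
  )
}

# One-dimensional finite differences along matrix rows for each column,
# central where both neighbours are valid, one-sided at mask edges, NA where
# no valid neighbour exists.
.diff_along <- function(z, h) {
  n <- nrow(z)
  up <- rbind(z[-1, , drop = FALSE], NA)      # z[i+1, ]
  dn <- rbind(NA, z[-n, , drop = FALSE])      # z[i-1, ]
  central <- (up - dn) / (2 * h)
  fwd <- (up - z) / h
  bwd <- (z - dn) / h
  out <- central
  out[is.na(central)] <- fwd[is.na(central)]
  sel <- is.na(out)
  out[sel] <- bwd[sel]
  out[is.na(z)] <- NA
  out
}

#' Gradient of a gridded field
#'
#' Second-order central differences in the interior of the valid mask,
#' one-sided first-order differences at mask edges, undefined (`NA`) at
#' isolated cells.
#'
#' @param field a `grid_field`.
#' @return an object of class `gradient_field`: list with `x`, `y`, and
#'   matrices `gx`, `gy` holding the two partial derivatives.
#' @export
grid_gradient <- function(field) {
  stopifnot(inherits(field, "grid_field"))
  hx <- field$x[2] - field$x[1]
  hy <- field$y[2] - field$y[1]
  gx <- .diff_along(field$values, hx)
  gy <- t(.diff_along(t(field$values), hy))
  structure(
    list(x = field$x, y = field$y, gx = gx, gy = gy),
    class = "gradient_field"
  )
}

#' Visual field sign from polar-angle and eccentricity gradients
#'
#' Classifies every grid cell by the signed angle from the eccentricity
#' gradient to the polar-angle gradient, computed through the planar cross
#' product: an angle in (0, pi) marks a mirror-image representation (+1, like
#' V1), in (-pi, 0) a non-mirror-image (-1, like V2). Cells where either
#' gradient is (near) zero or the two are parallel carry no sign.
#'
#' Because the sign convention depends on the handedness of the flat-map
#' coordinates, `orientation` (+1 or -1) flips the classification; use
#' [hemisphere_orientation()] for the convention under which the canonical
#' maps generated by this package evaluate V1 as mirror.
#'
#' @param grad_theta gradient of the (wrap-shifted) polar-angle field.
#' @param grad_ecc gradient of the eccentricity field on the same grid.
#' @param orientation +1 or -1 handedness flag.
#' @param tol gradient magnitudes (units per grid step) below this are
#'   treated as zero.
#' @return an object of class `field_sign_map`: list with `x`, `y`, `sign`
#'   (matrix of +1 / -1 / NA) and provenance fields.
#' @export
field_sign <- function(grad_theta, grad_ecc, orientation = 1, tol = 1e-9) {
  stopifnot(inherits(grad_theta, "gradient_field"), inherits(grad_ecc, "gradient_field"))
  if (!identical(dim(grad_theta$gx), dim(grad_ecc$gx)) ||
    max(abs(grad_theta$x - grad_ecc$x)) > 1e-12 ||
    max(abs(grad_theta$y - grad_ecc$y)) > 1e-12) {
    stop_nf("field_sign: gradients are on different grids")
  }
  if (!orientation %in% c(-1, 1)) stop_nf("field_sign: orientation must be +1 or -1")
  cross <- grad_ecc$gx * grad_theta$gy - grad_ecc$gy * grad_theta$gx
  nr <- sqrt(grad_ecc$gx^2 + grad_ecc$gy^2)
  nt <- sqrt(grad_theta$gx^2 + grad_theta$gy^2)
  s <- ifelse(orientation * cross > 0, 1, -1)
  s[!is.finite(cross) | nr < tol | nt < tol | abs(cross) <= tol * nr * nt] <- NA
  structure(
    list(
      x = grad_theta$x, y = grad_theta$y, sign = s,
      orientation = orientation,
      resolution = c(length(grad_theta$x), length(grad_theta$y))
    ),
    class = "field_sign_map"
  )
}

#' Flat-map handedness giving mirror V1 for canonical maps
#'
#' With eccentricity increasing along +x and the canonical polar-angle zigzag
#' along y, the cross-product convention needs a per-hemisphere handedness
#' flip so that canonical V1 evaluates as a mirror-image (+1) representation.
#'
#' @param hemisphere `"left"` or `"right"`.
#' @return -1 for the left hemisphere, +1 for the right.
#' @export
hemisphere_orientation <- function(hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  if (hemisphere == "left") -1 else 1
}

#' Field-sign map of a retinotopic map (end-to-end)
#'
#' Convenience wrapper: shifts the wrap-around, grids both fields, takes
#' gradients, and classifies the field sign with the hemisphere-appropriate
#' orientation.
#'
#' @param map a [retino_map].
#' @param nx,ny grid resolution.
#' @param orientation handedness flag; defaults to
#'   `hemisphere_orientation(map$hemisphere)`.
#' @return a `field_sign_map` (the gridded fields are attached as attributes
#'   `grid_theta` and `grid_ecc`).
#' @export
visual_field_sign <- function(map, nx = 200, ny = 200, orientation = NULL) {
  stopifnot(inherits(map, "retino_map"))
  orientation <- orientation %||% hemisphere_orientation(map$hemisphere)
  th <- shift_wraparound(map$polar_angle, map$hemisphere)
  gt <- to_grid(map$patch$x, map$patch$y, th, nx = nx, ny = ny)
  gr <- to_grid(map$patch$x, map$patch$y, map$eccentricity, nx = nx, ny = ny)
  fs <- field_sign(grid_gradient(gt), grid_gradient(gr), orientation = orientation)
  attr(fs, "grid_theta") <- gt
  attr(fs, "grid_ecc") <- gr
  fs
}

#' @export
print.field_sign_map <- function(x, ...) {
  tab <- table(factor(x$sign, levels = c(-1, 1)))
  cat("<field_sign_map> ", paste(x$resolution, collapse = "x"),
    " grid; mirror(+1): ", tab["1"], ", non-mirror(-1): ", tab["-1"],
    ", undefined: ", sum(is.na(x$sign)), "\n",
    sep = ""
  )
  invisible(x)
}

#' ROI mask on a field-sign grid
#'
#' Transfers vertex ROI labels to grid cells by linearly interpolating the
#' ROI indicator and thresholding at 0.5, then eroding the mask by `erode`
#' cells. Erosion keeps the mask inside the area proper: cells hugging an
#' area border have gradient stencils that straddle the border's polar-angle
#' reversal, where the field sign is not meaningful.
#'
#' @param patch the `flat_patch` the grid was built from.
#' @param roi_labels labels defining the ROI (e.g. `"V3d"`).
#' @param field a `grid_field` or `field_sign_map` defining the grid.
#' @param erode morphological erosion radius in grid cells (Chebyshev).
#' @return logical matrix on the grid.
#' @export
grid_roi_mask <- function(patch, roi_labels, field, erode = 3L) {
  stopifnot(inherits(patch, "flat_patch"))
  ind <- as.numeric(patch$roi_label %in% roi_labels)
  nx <- length(field$x)
  ny <- length(field$y)
  g <- to_grid(patch$x, patch$y, ind,
    nx = nx, ny = ny,
    xlim = range(field$x), ylim = range(field$y)
  )
  mask <- g$valid & !is.na(g$values) & g$values > 0.5
  for (k in seq_len(erode)) {
    up <- rbind(mask[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, mask[-nx, , drop = FALSE])
    le <- cbind(mask[, -1, drop = FALSE], FALSE)
    ri <- cbind(FALSE, mask[, -ny, drop = FALSE])
    mask <- mask & up & dn & le & ri
  }
  mask
}

#' Fraction of dorsal-V3 grid cells with a discordant field sign
#'
#' Scores how much of dorsal V3 carries the opposite field sign to the area's
#' dominant sign. Canonical and truncated maps score near 0; maps with a
#' Y-shaped (forked) lower-vertical representation contain an
#' opposite-sign pocket and score high. A map is flagged discontinuous when
#' the fraction exceeds `threshold`.
#'
#' @param sign_map a `field_sign_map`.
#' @param v3d_mask logical grid matrix marking dorsal V3 (see
#'   [grid_roi_mask()]).
#' @param threshold flag threshold on the discordant fraction.
#' @return list with `score` (fraction in \[0, 1\]), `discontinuous`
#'   (logical), `dominant_sign`, and `n_cells`.
#' @export
v3d_discontinuity_score <- function(sign_map, v3d_mask, threshold = 0.10) {
  stopifnot(inherits(sign_map, "field_sign_map"))
  if (!any(v3d_mask)) stop_nf("v3d_discontinuity_score: empty V3d mask")
  s <- sign_map$sign[v3d_mask]
  s <- s[!is.na(s)]
  if (!length(s)) stop_nf("v3d_discontinuity_score: no defined field-sign cells in mask")
  dominant <- if (sum(s) >= 0) 1 else -1
  score <- mean(s != dominant)
  list(
    score = score,
    discontinuous = score > threshold,
    dominant_sign = dominant,
    n_cells = length(s)
  )
}
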