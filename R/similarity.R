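# Discrete maps, weighted Jaccard similarity, spectral clustering of map
# motifs, and cluster summaries.

POLAR_LEVELS <- c("0", "90", "270", "360")
ECC_LEVELS <- c("0", "2", "4", "6")

new_discrete_map <- function(labels, vertex_id, levels, scope) {
  structure(
    list(labels = labels, vertex_id = vertex_id, levels = levels, scope = scope),
    class = "discrete_map"
  )
}

#' Discretize a polar-angle map into four meridian-anchored labels
#'
#' Each in-scope vertex is assigned one of four labels chosen to highlight
#' visual-area boundaries: `"0"` for angles in \[0, 45\], `"90"` for
#' (45, 180\], `"270"` for \[180, 315) and `"360"` for \[315, 360). The
#' boundary value 180 satisfies two clauses of the published piecewise rule;
#' it resolves to `"90"` (first match), which keeps the mapping deterministic.
#'
#' @param map a [retino_map].
#' @param roi_labels ROI scope (default: the dorsal bands, where the motif
#'   variability lives).
#' @param mask optional logical per-vertex mask.
#' @return an object of class `discrete_map`.
#' @export
discretize_polar <- function(map, roi_labels = DORSAL_LABELS, mask = NULL) {
  stopifnot(inherits(map, "retino_map"))
  sel <- select_roi(map$patch, mask, roi_labels, "discretize_polar")
  th <- map$polar_angle[sel]
  lab <- ifelse(th <= 45, "0",
    ifelse(th <= 180, "90",
      ifelse(th < 315, "270", "360")
    )
  )
  new_discrete_map(lab, map$patch$vertex_id[sel], POLAR_LEVELS, roi_labels)
}

#' Discretize an eccentricity map into four 2-degree bins
#'
#' Bins \[0, 2\], (2, 4\], (4, 6\] and (6, Inf) are labelled `"0"`, `"2"`,
#' `"4"`, `"6"` (closed-above bin edges).
#'
#' @inheritParams discretize_polar
#' @return an object of class `discrete_map`.
#' @export
discretize_eccentricity <- function(map, roi_labels = DORSAL_LABELS, mask = NULL) {
  stopifnot(inherits(map, "retino_map"))
  if (any(map$eccentricity < 0)) stop_nf("discretize_eccentricity: negative eccentricity")
  sel <- select_roi(map$patch, mask, roi_labels, "discretize_eccentricity")
  r <- map$eccentricity[sel]
  lab <- ifelse(r <= 2, "0",
    ifelse(r <= 4, "2",
      ifelse(r <= 6, "4", "6")
    )
  )
  new_discrete_map(lab, map$patch$vertex_id[sel], ECC_LEVELS, roi_labels)
}

#' @export
print.discrete_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$levels))
  cat("<discrete_map> ", length(x$labels), " vertices; ",
    paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Directional weighted Jaccard similarity between two discrete maps
#'
#' For every label L, the Jaccard index J_L is the number of vertices both
#' maps label L divided by the number either labels L; the result is the
#' average of the J_L weighted by the label counts of the *reference* map
#' (which is why the measure is directional). Labels absent from the
#' reference receive weight zero.
#'
#' @param reference,other `discrete_map` objects on the same vertex scope.
#' @return a value in \[0, 1\].
#' @export
directional_jaccard <- function(reference, other) {
  stopifnot(inherits(reference, "discrete_map"), inherits(other, "discrete_map"))
  if (!identical(reference$vertex_id, other$vertex_id)) {
    stop_nf("directional_jaccard: maps cover different vertex scopes")
  }
  if (!length(reference$labels)) stop_nf("directional_jaccard: empty scope")
  levels <- reference$levels
  w <- 0
  acc <- 0
  for (L in levels) {
    in_ref <- reference$labels == L
    in_oth <- other$labels == L
    w_L <- sum(in_ref)
    if (w_L == 0) next
    union <- sum(in_ref | in_oth)
    j_L <- sum(in_ref & in_oth) / union
    acc <- acc + w_L * j_L
    w <- w + w_L
  }
  acc / w
}

#' Symmetrized pairwise Jaccard similarity matrix
#'
#' `S[i, j]` is the mean of the two directional Jaccard scores (i as
#' reference of j, and j as reference of i); the diagonal is exactly 1.
#'
#' @param maps list of >= 2 `discrete_map` objects on a common scope.
#' @return symmetric N-by-N matrix with entries in \[0, 1\] and subject
#'   names as dimnames.
#' @export
pairwise_similarity <- function(maps) {
  n <- length(maps)
  if (n < 2) stop_nf("pairwise_similarity: need at least 2 maps")
  stopifnot(all(vapply(maps, inherits, logical(1), "discrete_map")))
  ids <- names(maps) %||% sprintf("sub%03d", seq_len(n))
  levels <- maps[[1]]$levels
  for (m in maps) {
    if (!identical(m$vertex_id, maps[[1]]$vertex_id)) {
      stop_nf("pairwise_similarity: maps cover different vertex scopes")
    }
  }
  # Per-label vertex-by-subject incidence; intersections via crossprod.
  nv <- length(maps[[1]]$labels)
  counts <- matrix(0, n, length(levels), dimnames = list(ids, levels))
  inter <- vector("list", length(levels))
  names(inter) <- levels
  for (L in levels) {
    A <- vapply(maps, function(m) as.numeric(m$labels == L), numeric(nv))
    counts[, L] <- colSums(A)
    inter[[L]] <- crossprod(A) # n x n intersection counts
  }
  s_dir <- matrix(0, n, n) # s_dir[i, j]: i is the reference
  wsum <- rowSums(counts)
  for (L in levels) {
    un <- outer(counts[, L], counts[, L], `+`) - inter[[L]]
    j_L <- ifelse(un > 0, inter[[L]] / un, 0)
    s_dir <- s_dir + counts[, L] * j_L # recycles counts down columns = by reference i
  }
  s_dir <- s_dir / wsum
  s <- (s_dir + t(s_dir)) / 2
  diag(s) <- 1
  dimnames(s) <- list(ids, ids)
  s
}

validate_similarity <- function(s) {
  if (!is.matrix(s) || nrow(s) != ncol(s)) stop_nf("similarity matrix must be square")
  if (max(abs(s - t(s))) > 1e-8) stop_nf("similarity matrix must be symmetric")
  if (min(s) < -1e-12 || max(s) > 1 + 1e-12) stop_nf("similarity values must lie in [0, 1]")
  invisible(s)
}

#' Spectral clustering of a similarity matrix
#'
#' Normalized spectral clustering: the k leading eigenvectors of
#' `D^(-1/2) S D^(-1/2)` are row-normalized and partitioned with k-means
#' (10 seed-derived restarts). Deterministic given `seed`.
#'
#' @param s symmetric similarity (affinity) matrix with unit diagonal.
#' @param k number of clusters, `2 <= k < N`. The published analysis used
#'   k = 6 on real maps; with planted synthetic variants, k equals the
#'   number of variants.
#' @param seed integer seed for the k-means initializations.
#' @return an object of class `cluster_result`: list with `assignment`
#'   (named integer vector in 1..k), `k`, `seed`, and `eigenvalues`.
#' @export
spectral_cluster <- function(s, k, seed = 1L) {
  validate_similarity(s)
  n <- nrow(s)
  if (!(k >= 2 && k < n)) stop_nf("spectral_cluster: need 2 <= k < N (N = ", n, ")")
  d <- rowSums(s)
  if (any(d <= 0)) stop_nf("spectral_cluster: similarity matrix has an all-zero row")
  dm <- 1 / sqrt(d)
  m <- s * outer(dm, dm)
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  u <- eg$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(u^2))
  rn[rn == 0] <- 1
  u <- u / rn
  km <- with_seed(seed, stats::kmeans(u, centers = k, nstart = 10, iter.max = 100))
  assignment <- stats::setNames(km$cluster, rownames(s))
  structure(
    list(assignment = assignment, k = k, seed = as.integer(seed),
         eigenvalues = eg$values[seq_len(k)]),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> k = ", x$k, "; sizes: ",
    paste(table(x$assignment), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-cluster average continuous maps
#'
#' Averages the continuous retinotopic maps of the individuals assigned to
#' each cluster (circular mean for polar angle, via [group_average()]).
#'
#' @param assignment named cluster assignment (as in a `cluster_result`), or
#'   a `cluster_result`.
#' @param maps named list of [retino_map] objects matching the assignment
#'   names.
#' @return named list of `group_avg_map`, one per non-empty cluster; empty
#'   clusters are reported with a warning and omitted.
#' @export
cluster_average_maps <- function(assignment, maps) {
  if (inherits(assignment, "cluster_result")) assignment <- assignment$assignment
  if (is.null(names(assignment)) || !all(names(assignment) %in% names(maps))) {
    stop_nf("cluster_average_maps: assignment names must match map names")
  }
  ks <- sort(unique(assignment))
  out <- list()
  for (k in ks) {
    members <- names(assignment)[assignment == k]
    if (!length(members)) {
      warning("cluster ", k, " is empty; average omitted")
      next
    }
    out[[as.character(k)]] <- group_average(maps[members])
  }
  out
}

#' Within- and between-cluster similarity summaries
#'
#' Means and SDs of the off-diagonal similarity scores for pairs inside the
#' same cluster and pairs straddling clusters. Size-1 clusters contribute no
#' within pairs.
#'
#' @param s similarity matrix.
#' @param assignment named cluster assignment or `cluster_result`.
#' @return list with `within` and `between`, each holding `mean`, `sd`, `n`.
#' @export
within_between_summary <- function(s, assignment) {
  if (inherits(assignment, "cluster_result")) assignment <- assignment$assignment
  validate_similarity(s)
  if (length(assignment) != nrow(s)) stop_nf("assignment length does not match matrix")
  same <- outer(assignment, assignment, `==`)
  off <- upper.tri(s)
  w <- s[off & same]
  b <- s[off & !same]
  list(
    within = list(mean = mean(w), sd = stats::sd(w), n = length(w)),
    between = list(mean = mean(b), sd = stats::sd(b), n = length(b))
  )
}
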