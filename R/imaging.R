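# Confocal z-stack pipeline for liposome distribution in alginate
# microbeads: per-slice normalization, white-pixel thresholding, connected
# component segmentation, 3D centroid extraction, and a nearest-neighbour
# complete-spatial-randomness (CSR) test.

#' Z-stack container
#'
#' @param voxels 3D intensity array `[x, y, z]` (a matrix is accepted as a
#'   single slice), arbitrary units.
#' @param pixel_size_xy Lateral pixel size, um.
#' @param z_spacing Axial slice spacing, um (default 50, matching
#'   acquisition spaced to avoid double-counting a liposome layer).
#' @param bead_diameter_nominal Nominal bead diameter, um (default 200).
#' @return An object of class `zstack`.
#' @export
zstack <- function(voxels, pixel_size_xy, z_spacing = 50,
                   bead_diameter_nominal = 200) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (length(dim(voxels)) != 3L || dim(voxels)[3] < 1L) {
    stop("`voxels` must be a 3D array with at least one slice", call. = FALSE)
  }
  if (pixel_size_xy <= 0 || z_spacing <= 0) {
    stop("`pixel_size_xy` and `z_spacing` must be positive", call. = FALSE)
  }
  structure(
    list(voxels = voxels, pixel_size_xy = pixel_size_xy,
         z_spacing = z_spacing,
         bead_diameter_nominal = bead_diameter_nominal),
    class = "zstack"
  )
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("zstack: %d x %d px x %d slices (%.3g um/px, %g um z-spacing)\n",
              d[1], d[2], d[3], x$pixel_size_xy, x$z_spacing))
  invisible(x)
}

#' Segmentation parameters
#'
#' @param normalization `"minmax"` (rescaled to the min/max range) or
#'   `"percentile"` (rescaled to a percentile window, saturating hot
#'   pixels).
#' @param scope `"stack"` (default) computes the normalization range over
#'   the whole z-stack; `"slice"` normalizes each slice to its own range. A
#'   shared range keeps spot-free slices dark instead of stretching their
#'   noise across `[0, 1]`.
#' @param threshold Foreground threshold as a fraction of the normalized
#'   range, strictly in (0, 1); default 0.5.
#' @param min_region_px Smallest region kept, in pixels (default 3).
#' @param percentiles Lower/upper percentile window for
#'   `normalization = "percentile"`.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(normalization = c("minmax", "percentile"),
                                scope = c("stack", "slice"),
                                threshold = 0.5, min_region_px = 3,
                                percentiles = c(0.01, 0.99)) {
  normalization <- match.arg(normalization)
  scope <- match.arg(scope)
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be strictly inside (0, 1)", call. = FALSE)
  }
  if (min_region_px < 1) stop("`min_region_px` must be >= 1", call. = FALSE)
  structure(
    list(normalization = normalization, scope = scope, threshold = threshold,
         min_region_px = as.integer(min_region_px),
         percentiles = percentiles),
    class = "segmentation_params"
  )
}

#' Normalize one image slice to [0, 1]
#'
#' Min-max mode maps the slice range linearly onto `[0, 1]`; a constant
#' slice maps to all zeros. Percentile mode clips to the configured
#' percentile window before rescaling, so isolated hot pixels saturate at 1
#' without compressing the rest of the dynamic range.
#'
#' @param slice 2D numeric matrix.
#' @param params A [segmentation_params()].
#' @param range Optional externally supplied `(lo, hi)` normalization range
#'   (used by [binarize_and_segment()] to share a stack-wide range across
#'   slices); computed from the slice itself when `NULL`.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
normalize_slice <- function(slice, params = segmentation_params(),
                            range = NULL) {
  if (!is.matrix(slice) || length(slice) == 0) {
    stop("`slice` must be a nonempty matrix", call. = FALSE)
  }
  if (is.null(range)) range <- normalization_range(slice, params)
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) return(matrix(0, nrow(slice), ncol(slice)))
  pmin(pmax((slice - lo) / (hi - lo), 0), 1)
}

normalization_range <- function(values, params) {
  if (params$normalization == "minmax") {
    c(min(values), max(values))
  } else {
    stats::quantile(values, params$percentiles, names = FALSE)
  }
}

# merge 4-connected labels that touch diagonally, giving 8-connectivity
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  if (max(lab) == 0) return(lab)
  pairs <- NULL
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1L), if (off[2] > 0) seq_len(nc - 1L) else 2:nc]
    b <- lab[2:nr, if (off[2] > 0) 2:nc else seq_len(nc - 1L)]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) return(lab)
  parent <- seq_len(max(lab)) # union-find over label ids
  for (r in seq_len(nrow(pairs))) {
    ra <- pairs[r, 1]; rb <- pairs[r, 2]
    while (parent[ra] != ra) ra <- parent[ra]
    while (parent[rb] != rb) rb <- parent[rb]
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(parent), function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }, integer(1))
  remap <- c(0L, root)
  matrix(remap[lab + 1L], nr, nc)
}

#' Threshold and segment a z-stack
#'
#' Each slice is normalized (against the stack-wide intensity range by
#' default, see [segmentation_params()]), thresholded at the configured
#' fraction of the normalized range ("white pixels"), and labeled into
#' 8-connected 2D components. Slices are segmented independently — the 50 um acquisition
#' spacing was chosen so that one liposome appears in one slice only — and
#' the per-slice labels are stacked with globally unique region ids. Regions
#' smaller than `min_region_px` are discarded. An empty foreground yields an
#' empty label set, not an error.
#'
#' @param stack A [zstack()].
#' @param params A [segmentation_params()].
#' @return List of class `segmentation`: `labels` (3D integer array, 0 =
#'   background), `n_regions`, `region_sizes` (named by region id), and the
#'   input metadata.
#' @export
binarize_and_segment <- function(stack, params = segmentation_params()) {
  stopifnot(inherits(stack, "zstack"), inherits(params, "segmentation_params"))
  d <- dim(stack$voxels)
  labels <- array(0L, d)
  next_id <- 0L
  shared_range <- if (params$scope == "stack") {
    normalization_range(stack$voxels, params)
  }
  for (z in seq_len(d[3])) {
    norm <- normalize_slice(stack$voxels[, , z], params, range = shared_range)
    mask <- norm >= params$threshold
    if (!any(mask)) next
    lab <- EBImage::bwlabel(mask)
    lab <- merge_diagonal_labels(matrix(as.integer(lab), d[1], d[2]))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= params$min_region_px)
    if (length(keep) == 0) next
    remap <- integer(max(lab))
    remap[keep] <- next_id + seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
    labels[, , z] <- lab
    next_id <- next_id + length(keep)
  }
  sizes <- if (next_id > 0) tabulate(labels[labels > 0], next_id) else integer(0)
  structure(
    list(labels = labels, n_regions = next_id,
         region_sizes = stats::setNames(sizes, seq_len(next_id)),
         pixel_size_xy = stack$pixel_size_xy, z_spacing = stack$z_spacing,
         bead_diameter_nominal = stack$bead_diameter_nominal),
    class = "segmentation"
  )
}

# bead center (um, image coordinates): xy from the centroid of the convex
# hull of all foreground pixels, z from the foreground z midrange; falls
# back to the image center for an empty foreground
estimate_bead_center <- function(seg) {
  d <- dim(seg$labels)
  fg <- which(seg$labels > 0, arr.ind = TRUE)
  ctr_img <- c((d[1] + 1) / 2 * seg$pixel_size_xy,
               (d[2] + 1) / 2 * seg$pixel_size_xy,
               (d[3] + 1) / 2 * seg$z_spacing)
  if (nrow(fg) < 3) return(ctr_img)
  xy <- unique(fg[, 1:2, drop = FALSE])
  hull <- xy[grDevices::chull(xy[, 1], xy[, 2]), , drop = FALSE]
  if (nrow(hull) < 3) {
    cxy <- colMeans(xy)
  } else {
    # polygon area centroid (shoelace)
    x <- hull[, 1]; y <- hull[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cross <- x * yn - xn * y
    a <- sum(cross) / 2
    cxy <- if (abs(a) < 1e-9) colMeans(hull) else
      c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a)
  }
  c(cxy * seg$pixel_size_xy,
    (min(fg[, 3]) + max(fg[, 3])) / 2 * seg$z_spacing)
}

#' 3D centroid set container
#'
#' @param points Matrix with columns `x_um`, `y_um`, `z_um` of bead-centered
#'   coordinates.
#' @param bead_radius Bead radius, um.
#' @param region_sizes Optional region sizes in pixels.
#' @param tol_um Tolerance (um) allowed beyond `bead_radius` for the
#'   inside-bead invariant; defaults to one 50 um voxel.
#' @return An object of class `centroid_set`.
#' @export
centroid_set <- function(points, bead_radius, region_sizes = NULL,
                         tol_um = 50) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("`points` must have 3 columns", call. = FALSE)
  colnames(points) <- c("x_um", "y_um", "z_um")
  if (nrow(points) > 0) {
    r <- sqrt(rowSums(points^2))
    if (any(r > bead_radius + tol_um)) {
      stop(sprintf(
        "centroid %.1f um from the bead center lies outside the bead radius %.1f um (tolerance %g um)",
        max(r), bead_radius, tol_um), call. = FALSE)
    }
  }
  structure(
    list(points = points, bead_radius = bead_radius,
         region_sizes = region_sizes),
    class = "centroid_set"
  )
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("centroid_set: %d points in a bead of radius %g um\n",
              nrow(x$points), x$bead_radius))
  invisible(x)
}

#' Extract 3D region centroids from a segmentation
#'
#' Unweighted (binary-mask) centroid of each labeled region, converted to um
#' with the pixel size in x/y and the slice spacing in z, then re-expressed
#' in bead-centered coordinates.
#'
#' @param seg A `segmentation` from [binarize_and_segment()].
#' @param bead_center Optional bead center in image um coordinates
#'   `(x, y, z)`; estimated from the foreground convex hull when `NULL`.
#' @param bead_radius Bead radius, um; defaults to half the nominal diameter.
#' @return A [centroid_set()].
#' @export
extract_centroids <- function(seg, bead_center = NULL, bead_radius = NULL) {
  stopifnot(inherits(seg, "segmentation"))
  if (is.null(bead_radius)) bead_radius <- seg$bead_diameter_nominal / 2
  if (is.null(bead_center)) bead_center <- estimate_bead_center(seg)
  if (seg$n_regions == 0) {
    return(centroid_set(matrix(numeric(0), 0, 3), bead_radius))
  }
  idx <- which(seg$labels > 0, arr.ind = TRUE)
  lab <- seg$labels[seg$labels > 0]
  if (any(tabulate(lab, seg$n_regions) == 0)) {
    stop("internal error: labeled region with zero voxels", call. = FALSE)
  }
  cx <- tapply(idx[, 1], lab, mean) * seg$pixel_size_xy
  cy <- tapply(idx[, 2], lab, mean) * seg$pixel_size_xy
  cz <- tapply(idx[, 3], lab, mean) * seg$z_spacing
  pts <- cbind(cx - bead_center[1], cy - bead_center[2], cz - bead_center[3])
  centroid_set(pts, bead_radius,
               region_sizes = seg$region_sizes,
               tol_um = max(seg$z_spacing, seg$pixel_size_xy))
}

# mean nearest-neighbour distance of a point matrix
mean_nn_distance <- function(pts) {
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  mean(apply(dm, 1, min))
}

# n points uniform in a sphere of given radius
runif_sphere <- function(n, radius) {
  dir <- matrix(stats::rnorm(3 * n), n, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  dir * radius * stats::runif(n)^(1 / 3)
}

#' Monte-Carlo CSR test of spatial uniformity
#'
#' Tests whether liposome centroids are distributed uniformly within the
#' bead: the observed mean nearest-neighbour distance is ranked against a
#' Monte-Carlo null of the same number of points placed uniformly at random
#' in a sphere of the bead radius (complete spatial randomness). The
#' two-sided p-value is rank-based, so clustering (small mean NN distance)
#' and over-regularity (large) both reject.
#'
#' @param centroids A [centroid_set()] with at least 2 points.
#' @param n_monte_carlo Number of null draws (default 999).
#' @param seed RNG seed; the test is a pure function of its inputs.
#' @return An object of class `spatial_stats`: `n_points`,
#'   `mean_nn_distance` (um), `null_mean_nn` (Monte-Carlo mean),
#'   `csr_p_value`, `n_monte_carlo`, `seed`.
#' @export
csr_uniformity_test <- function(centroids, n_monte_carlo = 999, seed = 1) {
  stopifnot(inherits(centroids, "centroid_set"))
  n <- nrow(centroids$points)
  if (n < 2) {
    stop("need at least 2 centroids for nearest-neighbour statistics",
         call. = FALSE)
  }
  obs <- mean_nn_distance(centroids$points)
  null_stats <- withr_seed(seed, {
    vapply(seq_len(n_monte_carlo), function(i) {
      mean_nn_distance(runif_sphere(n, centroids$bead_radius))
    }, numeric(1))
  })
  n_le <- sum(null_stats <= obs)
  n_ge <- sum(null_stats >= obs)
  p <- min(1, 2 * (min(n_le, n_ge) + 1) / (n_monte_carlo + 1))
  structure(
    list(n_points = n, mean_nn_distance = obs,
         null_mean_nn = mean(null_stats), csr_p_value = p,
         n_monte_carlo = n_monte_carlo, seed = seed),
    class = "spatial_stats"
  )
}

#' @export
print.spatial_stats <- function(x, ...) {
  cat(sprintf(
    "spatial_stats: %d points, mean NN %.2f um (CSR null %.2f um), p = %.3f [%d draws, seed %d]\n",
    x$n_points, x$mean_nn_distance, x$null_mean_nn, x$csr_p_value,
    x$n_monte_carlo, x$seed))
  invisible(x)
}

# run code under a local RNG seed without disturbing the caller's RNG state
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Match extracted centroids to ground-truth positions
#'
#' Greedy nearest matching of truth points to extracted centroids within a
#' distance cutoff; used to score segmentation round trips against the
#' synthetic generator's ground truth.
#'
#' @param truth,found Matrices (or `centroid_set`s) of 3D coordinates, um.
#' @param max_dist Match cutoff, um.
#' @return List with `n_matched`, `recall`, `mean_error` (um over matches),
#'   and the index pairs.
#' @export
match_centroids <- function(truth, found, max_dist) {
  tp <- if (inherits(truth, "centroid_set")) truth$points else as.matrix(truth)
  fp <- if (inherits(found, "centroid_set")) found$points else as.matrix(found)
  if (nrow(tp) == 0) {
    return(list(n_matched = 0L, recall = NA_real_, mean_error = NA_real_,
                pairs = cbind(truth = integer(0), found = integer(0))))
  }
  if (nrow(fp) == 0) {
    return(list(n_matched = 0L, recall = 0, mean_error = NA_real_,
                pairs = cbind(truth = integer(0), found = integer(0))))
  }
  dm <- outer(seq_len(nrow(tp)), seq_len(nrow(fp)), Vectorize(function(i, j) {
    sqrt(sum((tp[i, ] - fp[j, ])^2))
  }))
  pairs <- NULL
  errs <- numeric(0)
  repeat {
    m <- which.min(dm)
    if (!length(m) || min(dm) > max_dist) break
    i <- (m - 1) %% nrow(dm) + 1
    j <- (m - 1) %/% nrow(dm) + 1
    pairs <- rbind(pairs, c(truth = i, found = j))
    errs <- c(errs, dm[i, j])
    dm[i, ] <- Inf
    dm[, j] <- Inf
  }
  n_matched <- if (is.null(pairs)) 0L else nrow(pairs)
  list(n_matched = n_matched, recall = n_matched / nrow(tp),
       mean_error = if (n_matched) mean(errs) else NA_real_,
       pairs = pairs)
}
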