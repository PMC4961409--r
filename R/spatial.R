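#' A spatial frame: bacterial positions plus an intestinal region mask
#'
#' One imaging time point: continuous bacterial coordinates (micrometers), a
#' binary voxel mask marking the intestinal interior (2-D matrix or 3-D
#' array; anything outside the grid counts as exterior), the voxel edge
#' length, and optionally each position's scalar coordinate along the
#' anterior-posterior gut axis. Voxel \code{(i, j[, k])} spans
#' \code{[(i-1)*voxel_size, i*voxel_size)} along each dimension, so its
#' center sits at \code{(i - 0.5) * voxel_size}.
#'
#' @param positions numeric matrix, one row per bacterium, 2 or 3 columns of
#'   coordinates in micrometers.
#' @param mask logical matrix (2-D) or array (3-D); TRUE marks interior.
#' @param voxel_size voxel edge length, micrometers.
#' @param axis_coord optional numeric vector, per-position coordinate along
#'   the gut axis, micrometers.
#' @param frame_time time stamp (hours) or frame index.
#' @return object of class \code{spatial_frame}.
#' @export
spatial_frame <- function(positions, mask, voxel_size = 1,
                          axis_coord = NULL, frame_time = NA_real_) {
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || !ncol(positions) %in% c(2L, 3L)) {
    stop("'positions' must be a numeric matrix with 2 or 3 columns")
  }
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  nd <- length(dim(mask))
  if (!nd %in% c(2L, 3L)) stop("'mask' must be a 2-D matrix or a 3-D array")
  if (nd != ncol(positions)) {
    stop("mask dimensionality (", nd, ") and position columns (",
         ncol(positions), ") disagree")
  }
  if (!is.finite(voxel_size) || voxel_size <= 0) {
    stop("'voxel_size' must be positive")
  }
  if (!is.null(axis_coord) && length(axis_coord) != nrow(positions)) {
    stop("'axis_coord' length must match the number of positions")
  }
  structure(list(positions = positions, mask = mask,
                 voxel_size = voxel_size, axis_coord = axis_coord,
                 frame_time = frame_time),
            class = "spatial_frame")
}

#' @export
print.spatial_frame <- function(x, ...) {
  cat(sprintf("spatial_frame: %d position(s), %s mask %s, voxel %g um\n",
              nrow(x$positions), paste0(length(dim(x$mask)), "-D"),
              paste(dim(x$mask), collapse = "x"), x$voxel_size))
  invisible(x)
}

#' Probability density of bacteria along the gut axis
#'
#' Histogram of axis coordinates pooled over frames, normalized so the
#' density integrates to one (sum of density times bin width = 1). Frames
#' lacking an explicit \code{axis_coord} contribute their first position
#' coordinate.
#'
#' @param frames a list of [spatial_frame()] objects (a single frame is
#'   accepted).
#' @param bin_width histogram bin width, micrometers (default 10 um against
#'   an imaged intestine of roughly 1200 um).
#' @return data frame with columns \code{bin_lo}, \code{bin_hi}, \code{mid},
#'   \code{count}, \code{density} (1/um).
#' @export
axis_density <- function(frames, bin_width = 10) {
  if (inherits(frames, "spatial_frame")) frames <- list(frames)
  if (bin_width <= 0) stop("'bin_width' must be positive")
  coords <- unlist(lapply(frames, function(f) {
    if (!is.null(f$axis_coord)) f$axis_coord else f$positions[, 1]
  }))
  if (length(coords) < 1) stop("no positions in input frames")
  lo <- floor(min(coords) / bin_width) * bin_width
  breaks <- seq(lo, max(coords) + bin_width, by = bin_width)
  h <- graphics::hist(coords, breaks = breaks, plot = FALSE)
  data.frame(bin_lo = utils::head(h$breaks, -1),
             bin_hi = utils::tail(h$breaks, -1),
             mid = h$mids, count = h$counts,
             density = h$counts / (length(coords) * bin_width))
}

# centers (in um) of boundary voxels: interior voxels with at least one
# face-adjacent exterior neighbour; outside the grid counts as exterior
.boundary_voxel_centers <- function(mask, voxel_size) {
  nd <- length(dim(mask))
  # face-neighbour interior test via direct slicing (2-D and 3-D cases)
  interior_all_nb <- mask
  d <- dim(mask)
  shift_ok <- function(offset) {
    # TRUE where the neighbour at 'offset' exists and is interior
    out <- array(FALSE, d)
    if (nd == 2) {
      i <- seq_len(d[1]); j <- seq_len(d[2])
      si <- i + offset[1]; sj <- j + offset[2]
      vi <- si >= 1 & si <= d[1]; vj <- sj >= 1 & sj <= d[2]
      out[vi, vj] <- mask[si[vi], sj[vj]]
    } else {
      i <- seq_len(d[1]); j <- seq_len(d[2]); k <- seq_len(d[3])
      si <- i + offset[1]; sj <- j + offset[2]; sk <- k + offset[3]
      vi <- si >= 1 & si <= d[1]; vj <- sj >= 1 & sj <= d[2]
      vk <- sk >= 1 & sk <= d[3]
      out[vi, vj, vk] <- mask[si[vi], sj[vj], sk[vk]]
    }
    out
  }
  offsets <- if (nd == 2) {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  } else {
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
         c(0, 0, 1), c(0, 0, -1))
  }
  for (off in offsets) interior_all_nb <- interior_all_nb & shift_ok(off)
  boundary <- mask & !interior_all_nb
  idx <- which(boundary, arr.ind = TRUE)
  (idx - 0.5) * voxel_size
}

#' Distance of each bacterium to the epithelial wall
#'
#' Minimum Euclidean distance from each position to the mask boundary, where
#' the boundary is the set of interior voxels face-adjacent to the exterior
#' (grid edges count as exterior) and distances are measured to their voxel
#' centers. Positions falling outside the interior get a negative distance
#' (their distance to the boundary, negated) and raise a warning.
#'
#' @param frame a [spatial_frame()]; the mask must contain both interior and
#'   exterior voxels.
#' @return numeric vector of distances, micrometers (one per position).
#' @export
wall_distances <- function(frame) {
  stopifnot(inherits(frame, "spatial_frame"))
  mask <- frame$mask
  if (!any(mask)) stop("mask has no interior voxels")
  if (all(mask)) {
    # an all-interior grid still has a boundary at the grid edge, but a mask
    # that never distinguishes interior from exterior is suspect
    warning("mask is all-interior; the grid edge is taken as the wall")
  }
  bc <- .boundary_voxel_centers(mask, frame$voxel_size)
  if (nrow(bc) == 0) stop("mask has no boundary voxels")
  pos <- frame$positions
  n <- nrow(pos)
  if (n == 0) return(numeric(0))
  d <- numeric(n)
  chunk <- 512L
  for (a in seq(1, n, by = chunk)) {
    b <- min(a + chunk - 1L, n)
    block <- pos[a:b, , drop = FALSE]
    # squared distances block (rows) x boundary voxels (cols)
    d2 <- outer(rowSums(block^2), rowSums(bc^2), "+") -
      2 * tcrossprod(block, bc)
    amin <- max.col(-d2, ties.method = "first")
    d[a:b] <- sqrt(pmax(d2[cbind(seq_len(nrow(d2)), amin)], 0))
  }
  inside <- .positions_inside(pos, mask, frame$voxel_size)
  if (any(!inside)) {
    warning(sum(!inside), " position(s) outside the mask interior; ",
            "their distances are reported as negative")
    d[!inside] <- -d[!inside]
  }
  d
}

# TRUE for positions whose containing voxel is interior
.positions_inside <- function(pos, mask, voxel_size) {
  d <- dim(mask)
  idx <- floor(pos / voxel_size) + 1
  ok <- rep(TRUE, nrow(pos))
  for (j in seq_along(d)) ok <- ok & idx[, j] >= 1 & idx[, j] <= d[j]
  inside <- rep(FALSE, nrow(pos))
  if (any(ok)) {
    lin <- idx[ok, 1]
    mult <- 1
    for (j in seq_along(d)[-1]) {
      mult <- mult * d[j - 1]
      lin <- lin + (idx[ok, j] - 1) * mult
    }
    inside[ok] <- mask[lin]
  }
  inside
}

#' Uniform space-filling null model for wall distances
#'
#' Distributes \code{n_points_per_frame} points (default 1000) uniformly at
#' random inside each frame's intestinal mask by rejection sampling from the
#' mask's bounding box, then returns their wall distances pooled over frames.
#' This is the null distribution against which observed bacterial
#' distance-to-wall distributions are compared.
#'
#' @param frames list of [spatial_frame()] objects (positions are ignored;
#'   only masks are used).
#' @param n_points_per_frame points sampled per frame.
#' @param seed integer seed.
#' @return numeric vector of \code{n_frames * n_points_per_frame} distances,
#'   micrometers.
#' @export
uniform_null <- function(frames, n_points_per_frame = 1000, seed = 1L) {
  if (inherits(frames, "spatial_frame")) frames <- list(frames)
  if (n_points_per_frame < 1) stop("'n_points_per_frame' must be >= 1")
  set.seed(seed)
  out <- lapply(frames, function(f) {
    pts <- .sample_uniform_in_mask(f$mask, f$voxel_size, n_points_per_frame)
    wall_distances(spatial_frame(pts, f$mask, f$voxel_size))
  })
  unlist(out)
}

.sample_uniform_in_mask <- function(mask, voxel_size, n) {
  d <- dim(mask)
  hi <- d * voxel_size
  frac_interior <- mean(mask)
  if (frac_interior < 1e-4) {
    stop("rejection sampling efficiency below 1e-4; tighten the mask's bounding box")
  }
  got <- matrix(numeric(0), ncol = length(d))
  while (nrow(got) < n) {
    m <- ceiling((n - nrow(got)) / frac_interior * 1.1) + 16
    cand <- sapply(hi, function(h) stats::runif(m, 0, h))
    keep <- .positions_inside(cand, mask, voxel_size)
    got <- rbind(got, cand[keep, , drop = FALSE])
  }
  got[seq_len(n), , drop = FALSE]
}

#' Percentile bootstrap confidence interval
#'
#' Nonparametric bootstrap of an arbitrary statistic with percentile
#' endpoints (order statistics of the bootstrap distribution at the
#' \code{(1 - level)/2} and \code{(1 + level)/2} quantiles).
#'
#' @param samples numeric vector, at least 2 values.
#' @param statistic function of a numeric vector returning one number
#'   (default [mean()]).
#' @param n_boot bootstrap replicates (a warning is raised below 100).
#' @param level confidence level.
#' @param seed integer seed.
#' @return named numeric vector \code{c(low, high)}.
#' @examples
#' bootstrap_ci(rnorm(100), mean, n_boot = 500, seed = 2)
#' @export
bootstrap_ci <- function(samples, statistic = mean, n_boot = 1000,
                         level = 0.95, seed = 1L) {
  if (length(samples) < 2) stop("at least 2 samples are required")
  if (n_boot < 100) warning("'n_boot' < 100 gives unstable percentile endpoints")
  set.seed(seed)
  stat <- vapply(seq_len(n_boot), function(b) {
    statistic(samples[sample.int(length(samples), replace = TRUE)])
  }, numeric(1))
  q <- stats::quantile(stat, c((1 - level) / 2, (1 + level) / 2),
                       names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}
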