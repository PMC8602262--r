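#' Correlation map of a volumetric movie
#'
#' For every voxel, the Pearson correlation between its fluorescence time
#' course and the average time course of its eight in-plane neighbours
#' (border voxels use the neighbours that exist). Active structures with
#' coherent dynamics light up; independent noise stays near zero.
#'
#' @param movie numeric array `[x, y, z, t]` (a 3-D `[x, y, t]` array is
#'   treated as a single plane).
#' @return array `[x, y, z]` of correlations (`NA` for constant voxels).
#' @export
correlation_map <- function(movie) {
  movie <- as_movie(movie)
  d <- dim(movie)
  out <- array(NA_real_, d[1:3])
  for (z in seq_len(d[3])) {
    P <- movie[, , z, , drop = TRUE]
    dim(P) <- c(d[1], d[2], d[4])
    nb_sum <- array(0, dim(P))
    nb_cnt <- array(0L, c(d[1], d[2]))
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      xs <- seq_len(d[1]) + dx
      ys <- seq_len(d[2]) + dy
      okx <- xs >= 1 & xs <= d[1]
      oky <- ys >= 1 & ys <= d[2]
      nb_sum[okx, oky, ] <- nb_sum[okx, oky, ] + P[xs[okx], ys[oky], ]
      nb_cnt[okx, oky] <- nb_cnt[okx, oky] + 1L
    }
    nb_mean <- nb_sum / as.vector(nb_cnt)
    V <- matrix(P, d[1] * d[2], d[4])
    Nb <- matrix(nb_mean, d[1] * d[2], d[4])
    out[, , z] <- matrix(row_cor(V, Nb), d[1], d[2])
  }
  out
}

# Row-wise Pearson correlation between two matrices.
row_cor <- function(A, B) {
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  den <- sqrt(rowSums(A^2) * rowSums(B^2))
  r <- rowSums(A * B) / den
  r[den == 0] <- NA_real_
  r
}

as_movie <- function(movie) {
  if (length(dim(movie)) == 3L)
    dim(movie) <- c(dim(movie)[1], dim(movie)[2], 1L, dim(movie)[3])
  if (length(dim(movie)) != 4L) stop("movie must be an [x, y, z, t] array")
  if (dim(movie)[4] < 2L) stop("movie needs at least 2 time points")
  movie
}

#' Segment somata-sized ROIs by correlation-map region growing
#'
#' Plane-wise iterative segmentation: each ROI is seeded at the unassigned
#' voxel with the highest correlation-map value (at least `seed_thr`), then
#' grown by adding 8-adjacent unassigned voxels whose correlation with the
#' average fluorescence time course of the voxels already in the ROI
#' exceeds a threshold that ramps linearly from `grow_thr[1]` at the seed
#' to `grow_thr[2]` at `ramp_dist` micrometres (in-plane Euclidean distance
#' from the seed). ROIs outside the somata-scale area bounds are discarded
#' (their voxels stay assigned so segmentation terminates). The trace of a
#' kept ROI is the sum of its voxels' fluorescence.
#'
#' @param movie numeric array `[x, y, z, t]` (or `[x, y, t]`).
#' @param voxel_size voxel dimensions in micrometres `c(dx, dy, dz)`.
#' @param seed_thr minimal correlation-map value of a seed.
#' @param grow_thr inclusion-threshold ramp endpoints.
#' @param ramp_dist distance (um) at which the ramp saturates.
#' @param area_bounds admissible ROI area (um^2).
#' @return list with `rois` (data frame: `id`, `plane`, `n_vox`,
#'   `area_um2`, seed coordinates), `masks` (list of `[x, y]` index
#'   matrices), `traces` (ROIs x time matrix) and the `correlation_map`.
#' @export
segment_rois <- function(movie, voxel_size = c(0.6, 0.6, 7),
                         seed_thr = 0.3, grow_thr = c(0.3, 0.35),
                         ramp_dist = 3, area_bounds = c(9, 28)) {
  movie <- as_movie(movie)
  d <- dim(movie)
  cmap <- correlation_map(movie)
  vox_area <- voxel_size[1] * voxel_size[2]
  max_vox <- floor(area_bounds[2] / vox_area)
  rois <- list(); masks <- list(); traces <- list()
  id <- 0L
  for (z in seq_len(d[3])) {
    P <- matrix(movie[, , z, ], d[1] * d[2], d[4])
    cm <- cmap[, , z]
    assigned <- matrix(FALSE, d[1], d[2])
    vox_i <- function(x, y) (y - 1L) * d[1] + x
    repeat {
      cand <- cm
      cand[assigned | is.na(cand) | cand < seed_thr] <- -Inf
      if (!any(is.finite(cand))) break
      seed <- arrayInd(which.max(cand), dim(cand))
      members <- matrix(seed, 1)
      assigned[seed] <- TRUE
      repeat {
        if (nrow(members) > max_vox) break
        roi_mean <- colMeans(P[vox_i(members[, 1], members[, 2]), ,
                               drop = FALSE])
        # unassigned 8-neighbours of current members
        nb <- unique(do.call(rbind, lapply(seq_len(nrow(members)), function(i)
          cbind(members[i, 1] + rep(-1:1, 3), members[i, 2] + rep(-1:1, each = 3)))))
        nb <- nb[nb[, 1] >= 1 & nb[, 1] <= d[1] &
                 nb[, 2] >= 1 & nb[, 2] <= d[2], , drop = FALSE]
        nb <- nb[!assigned[nb], , drop = FALSE]
        if (!nrow(nb)) break
        dist <- sqrt(((nb[, 1] - seed[1]) * voxel_size[1])^2 +
                     ((nb[, 2] - seed[2]) * voxel_size[2])^2)
        thr <- grow_thr[1] + (grow_thr[2] - grow_thr[1]) *
          pmin(dist, ramp_dist) / ramp_dist
        cc <- row_cor(P[vox_i(nb[, 1], nb[, 2]), , drop = FALSE],
                      matrix(roi_mean, nrow(nb), d[4], byrow = TRUE))
        add <- which(!is.na(cc) & cc > thr)
        if (!length(add)) break
        members <- rbind(members, nb[add, , drop = FALSE])
        assigned[nb[add, , drop = FALSE]] <- TRUE
      }
      area <- nrow(members) * vox_area
      if (area >= area_bounds[1] && area <= area_bounds[2]) {
        id <- id + 1L
        rois[[id]] <- data.frame(id = id, plane = z, n_vox = nrow(members),
                                 area_um2 = area, seed_x = seed[1],
                                 seed_y = seed[2])
        colnames(members) <- c("x", "y")
        masks[[id]] <- members
        traces[[id]] <- colSums(P[vox_i(members[, 1], members[, 2]), ,
                                  drop = FALSE])
      }
    }
  }
  list(rois = if (id) do.call(rbind, rois) else
         data.frame(id = integer(), plane = integer(), n_vox = integer(),
                    area_um2 = numeric(), seed_x = integer(),
                    seed_y = integer()),
       masks = masks,
       traces = if (id) do.call(rbind, traces) else
         matrix(numeric(), 0, d[4]),
       correlation_map = cmap)
}
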