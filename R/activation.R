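#' Activation mapping and ROI selection from a calibration series
#'
#' Fits the GLM (intercept + linear drift + convolved task regressor)
#' voxel-wise over the whole calibration series, converts the task-beta
#' t map to z through the normal quantile of the t CDF, thresholds,
#' clusters with 6-connectivity, and returns the cluster with the
#' highest peak statistic -- the region with the strongest
#' protocol-related activity.
#'
#' @param series a [volume_series()] (smoothed beforehand if desired).
#' @param design per-volume boxcar, or an already convolved regressor
#'   when `convolved = TRUE`.
#' @param z_threshold one-sided z threshold for voxel inclusion.
#' @param min_cluster minimum surviving-cluster size in voxels.
#' @param convolved is `design` already convolved with the HRF?
#' @return list with `map` (z array + `df`) and `mask` (a
#'   [roi_mask()]). No surviving cluster is an error instructing a
#'   threshold reduction.
#' @export
activation_roi <- function(series, design, z_threshold = 3,
                           min_cluster = 4L, convolved = FALSE) {
  gs <- dim(series$data)[1:3]
  nvol <- n_volumes(series)
  if (length(design) != nvol)
    stop("design length must match the number of volumes", call. = FALSE)
  reg <- if (convolved) design
         else convolve_design(design, hrf_double_gamma(series$tr))
  Y <- matrix(series$data, nrow = prod(gs), ncol = nvol)
  state <- iglm(c("intercept", "drift", "task"), n_targets = nrow(Y))
  for (k in seq_len(nvol))
    state <- iglm_update(state, design_row(k, reg), Y[, k])
  est <- iglm_estimates(state, contrasts = c(0, 0, 1))
  tmap <- est$t[1, ]
  z <- t_to_z(tmap, est$df)
  zarr <- array(z, gs)

  above <- which(!is.na(z) & z >= z_threshold)
  clusters <- label_clusters(above, gs)
  sizes <- vapply(clusters, length, integer(1))
  clusters <- clusters[sizes >= min_cluster]
  if (!length(clusters))
    stop(sprintf(
      "no activation cluster of >= %d voxels survives z >= %g; lower the threshold",
      min_cluster, z_threshold), call. = FALSE)
  peak <- vapply(clusters, function(ix) max(z[ix]), numeric(1))
  size <- vapply(clusters, length, integer(1))
  first_ix <- vapply(clusters, min, integer(1))
  # highest peak; ties by larger size, then lowest linear index
  ord <- order(-peak, -size, first_ix)
  best <- clusters[[ord[1]]]
  list(map = list(z = zarr, df = est$df),
       mask = roi_mask(best, gs, label = "activation"))
}

# t -> z via log CDF for numerical stability at large |t|
t_to_z <- function(t, df) {
  z <- numeric(length(t))
  pos <- !is.na(t) & t >= 0
  z[pos] <- -qnorm(pt(t[pos], df, lower.tail = FALSE, log.p = TRUE),
                   log.p = TRUE)
  neg <- !is.na(t) & t < 0
  z[neg] <- qnorm(pt(t[neg], df, log.p = TRUE), log.p = TRUE)
  z[is.na(t)] <- NA_real_
  z
}

# connected components (6-neighborhood) among the given linear voxel
# indices; returns a list of integer index vectors
label_clusters <- function(indices, grid_shape) {
  if (!length(indices)) return(list())
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  inset <- logical(nx * ny * nz)
  inset[indices] <- TRUE
  visited <- logical(length(inset))
  coords <- arrayInd(indices, grid_shape)
  rownames(coords) <- as.character(indices)
  out <- list()
  for (start in indices) {
    if (visited[start]) next
    comp <- integer()
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      ci <- arrayInd(v, grid_shape)
      for (d in 1:3) for (s in c(-1L, 1L)) {
        cj <- ci
        cj[d] <- cj[d] + s
        if (cj[d] < 1L || cj[d] > grid_shape[d]) next
        w <- cj[1] + (cj[2] - 1L) * nx + (cj[3] - 1L) * nx * ny
        if (inset[w] && !visited[w]) {
          visited[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    out <- c(out, list(sort(comp)))
  }
  out
}
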