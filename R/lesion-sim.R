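# voxel grid helpers shared by the lesion simulator and the mapping module

lin2xyz <- function(idx, dims) {
  idx0 <- idx - 1L
  x <- idx0 %% dims[1]
  y <- (idx0 %/% dims[1]) %% dims[2]
  z <- idx0 %/% (dims[1] * dims[2])
  cbind(x + 1L, y + 1L, z + 1L)
}

xyz2lin <- function(xyz, dims) {
  (xyz[, 3] - 1L) * dims[1] * dims[2] + (xyz[, 2] - 1L) * dims[1] + xyz[, 1]
}

# linear indices of the voxels in the Euclidean ball of given radius (voxels)
roi_ball <- function(dims, center, radius) {
  r <- ceiling(radius)
  xs <- max(1, center[1] - r):min(dims[1], center[1] + r)
  ys <- max(1, center[2] - r):min(dims[2], center[2] + r)
  zs <- max(1, center[3] - r):min(dims[3], center[3] + r)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  d2 <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 + (g[, 3] - center[3])^2
  xyz2lin(g[d2 <= radius^2, , drop = FALSE], dims)
}

face_neighbours <- function(idx, dims) {
  xyz <- lin2xyz(idx, dims)
  out <- integer(0)
  for (d in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- xyz
      nb[d] <- nb[d] + s
      if (nb[d] >= 1L && nb[d] <= dims[d]) out <- c(out, xyz2lin(nb, dims))
    }
  }
  out
}

# grow a contiguous blob of `size` voxels from a seed by random frontier growth
grow_lesion <- function(dims, seed_idx, size) {
  inside <- logical(prod(dims))
  frontier <- seed_idx
  members <- integer(0)
  while (length(members) < size && length(frontier) > 0) {
    k <- if (length(frontier) > 1) sample.int(length(frontier), 1) else 1L
    v <- frontier[k]
    frontier <- frontier[-k]
    if (inside[v]) next
    inside[v] <- TRUE
    members <- c(members, v)
    frontier <- c(frontier, face_neighbours(v, dims))
  }
  members
}

#' Generate a synthetic lesion cohort
#'
#' Each patient receives one contiguous binary lesion, grown by random
#' frontier expansion from a seed voxel to a size drawn uniformly from
#' `lesion_size_range`. When `effect_delta > 0`, `n_roi` of the seeds are
#' planted inside the region of interest so the cohort actually contains
#' ROI-damaged patients; the remaining seeds are uniform over the grid.
#' Behavioural persistence biases are
#' `ip_mean - effect_delta * [lesion overlaps ROI] + N(0, noise_sd)`.
#'
#' @param n_patients Number of patients.
#' @param grid_dims Integer length-3 grid dimensions (default 20 x 24 x 20
#'   voxels at a nominal 2.4 mm pitch).
#' @param roi_center Voxel coordinate of the ROI centre.
#' @param roi_radius_vox ROI ball radius in voxels.
#' @param effect_delta Reduction in persistence bias caused by ROI damage.
#' @param noise_sd Behavioural noise s.d.
#' @param lesion_size_range Min/max lesion size (voxels).
#' @param ip_mean Baseline persistence bias.
#' @param n_roi Number of lesions seeded inside the ROI (default 5 when
#'   `effect_delta > 0`, else 0).
#' @return An object of class `gp_lesion_cohort`: binary 3-D `maps` (one per
#'   patient), `biases`, `roi_damaged` labels, and grid/ROI geometry.
#' @export
gen_lesion_cohort <- function(n_patients = 23, grid_dims = c(20L, 24L, 20L),
                              roi_center = c(10L, 18L, 7L),
                              roi_radius_vox = 3, effect_delta = 3,
                              noise_sd = 1, lesion_size_range = c(50, 400),
                              ip_mean = 3,
                              n_roi = if (effect_delta > 0) 5L else 0L) {
  grid_dims <- as.integer(grid_dims)
  if (any(roi_center < 1) || any(roi_center > grid_dims)) {
    stop("ROI centre outside grid")
  }
  ball <- roi_ball(grid_dims, roi_center, roi_radius_vox)
  if (length(ball) == 0) stop("empty ROI: impossible geometry")
  n_roi <- min(n_roi, n_patients)
  sizes <- round(stats::runif(n_patients, lesion_size_range[1],
                              lesion_size_range[2]))
  maps <- vector("list", n_patients)
  overlap <- logical(n_patients)
  for (i in seq_len(n_patients)) {
    seed_idx <- if (i <= n_roi) {
      if (length(ball) > 1) sample(ball, 1) else ball
    } else {
      sample.int(prod(grid_dims), 1)
    }
    vox <- grow_lesion(grid_dims, seed_idx, sizes[i])
    m <- array(0L, dim = grid_dims)
    m[vox] <- 1L
    maps[[i]] <- m
    overlap[i] <- any(vox %in% ball)
  }
  biases <- ip_mean - effect_delta * overlap + stats::rnorm(n_patients, 0,
                                                            noise_sd)
  structure(list(maps = maps, biases = biases, roi_damaged = overlap,
                 grid_dims = grid_dims, roi_center = as.integer(roi_center),
                 roi_radius_vox = roi_radius_vox, voxel_size_mm = 2.4),
            class = "gp_lesion_cohort")
}

#' @export
print.gp_lesion_cohort <- function(x, ...) {
  cat(sprintf("Synthetic lesion cohort: %d patients, %dx%dx%d grid\n",
              length(x$maps), x$grid_dims[1], x$grid_dims[2], x$grid_dims[3]))
  cat(sprintf("  ROI-damaged: %d; mean bias %0.2f\n", sum(x$roi_damaged),
              mean(x$biases)))
  invisible(x)
}

#' Write / read lesion maps as NIfTI volumes
#'
#' One binary volume per patient (`patient_<i>.nii.gz`) plus a `cohort.csv`
#' of biases and ROI-damage labels. Requires the `RNifti` package.
#'
#' @param cohort A `gp_lesion_cohort`.
#' @param dir Output directory (created if missing).
#' @return `write_lesion_maps()` the directory, invisibly;
#'   `read_lesion_maps()` a `gp_lesion_cohort` (geometry metadata restored
#'   from `cohort.csv`).
#' @export
write_lesion_maps <- function(cohort, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required to write NIfTI volumes")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$maps)) {
    RNifti::writeNifti(cohort$maps[[i]],
                       file.path(dir, sprintf("patient_%02d.nii.gz", i)),
                       datatype = "uint8")
  }
  meta <- data.frame(patient = seq_along(cohort$maps), bias = cohort$biases,
                     roi_damaged = cohort$roi_damaged)
  utils::write.csv(meta, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_lesion_maps
#' @export
read_lesion_maps <- function(dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required to read NIfTI volumes")
  }
  meta <- utils::read.csv(file.path(dir, "cohort.csv"))
  files <- file.path(dir, sprintf("patient_%02d.nii.gz", meta$patient))
  maps <- lapply(files, function(f) {
    m <- RNifti::readNifti(f)
    array(as.integer(m > 0), dim = dim(m))
  })
  structure(list(maps = maps, biases = meta$bias,
                 roi_damaged = as.logical(meta$roi_damaged),
                 grid_dims = dim(maps[[1]]), roi_center = NULL,
                 roi_radius_vox = NULL, voxel_size_mm = 2.4),
            class = "gp_lesion_cohort")
}
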