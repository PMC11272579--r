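# Precompute the damage design for fast repeated t-map evaluation:
# D is the n_patients x n_voxels binary matrix, mask the tested voxels.
lesion_design <- function(cohort, min_overlap = 2) {
  D <- vapply(cohort$maps, as.vector, numeric(prod(cohort$grid_dims)))
  D <- t(D)  # patients x voxels
  n <- nrow(D)
  n1 <- colSums(D)
  mask <- n1 >= min_overlap & (n - n1) >= min_overlap
  list(D = D[, mask, drop = FALSE], mask = mask, n = n,
       n1 = n1[mask], dims = cohort$grid_dims)
}

# Voxelwise two-group t statistics on the masked design, signed so that
# positive t = damage predicts LOWER scores. Identical to the simple
# regression t on a binary damage regressor.
lesion_tvals <- function(design, y) {
  n <- design$n
  n1 <- design$n1
  n0 <- n - n1
  s1 <- drop(crossprod(design$D, y))
  q1 <- drop(crossprod(design$D, y^2))
  s <- sum(y)
  q <- sum(y^2)
  m1 <- s1 / n1
  m0 <- (s - s1) / n0
  ss1 <- q1 - s1^2 / n1
  ss0 <- (q - q1) - (s - s1)^2 / n0
  sp2 <- (ss1 + ss0) / (n - 2)
  (m0 - m1) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

#' Voxelwise lesion-behaviour t-map
#'
#' For every voxel damaged in at least `min_overlap` patients and intact in
#' at least `min_overlap` patients, computes the two-group pooled-variance t
#' statistic for persistence bias by damage status (algebraically identical
#' to the regression t on a binary damage regressor), signed so that positive
#' t means damage predicts *lower* persistence bias. Untested voxels carry
#' `NA`.
#'
#' @param cohort A `gp_lesion_cohort` (binary maps on a common grid).
#' @param min_overlap Minimum damaged and intact patient counts per voxel.
#' @return An object of class `gp_tmap`: the 3-D `t` array, logical `mask`
#'   array of tested voxels, and `n_patients`.
#' @export
voxelwise_t <- function(cohort, min_overlap = 2) {
  if (length(cohort$maps) < 2) stop("need >= 2 patients")
  if (!all(vapply(cohort$maps, function(m) all(m %in% c(0L, 1L)), TRUE))) {
    stop("lesion maps must be binary")
  }
  design <- lesion_design(cohort, min_overlap)
  if (!any(design$mask)) warning("empty mask: no voxel meets min_overlap")
  tarr <- array(NA_real_, dim = cohort$grid_dims)
  tarr[design$mask] <- lesion_tvals(design, cohort$biases)
  structure(list(t = tarr, mask = array(design$mask, cohort$grid_dims),
                 n_patients = length(cohort$maps),
                 min_overlap = min_overlap),
            class = "gp_tmap")
}

# connectivity offsets for 6 (faces), 18 (faces+edges), 26 (full cube)
conn_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

# connected components of a set of linear voxel indices; returns a list of
# integer vectors of linear indices
label_components <- function(idx, dims, connectivity = 6) {
  if (length(idx) == 0) return(list())
  offs <- conn_offsets(connectivity)
  in_set <- logical(prod(dims))
  in_set[idx] <- TRUE
  seen <- logical(prod(dims))
  comps <- list()
  for (start in idx) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, v)
      xyz <- lin2xyz(v, dims)
      nb <- cbind(xyz[1] + offs[, 1], xyz[2] + offs[, 2], xyz[3] + offs[, 3])
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nbl <- xyz2lin(nb[ok, , drop = FALSE], dims)
      nbl <- nbl[in_set[nbl] & !seen[nbl]]
      seen[nbl] <- TRUE
      queue <- c(queue, nbl)
    }
    comps[[length(comps) + 1]] <- members
  }
  comps
}

#' Extract supra-threshold clusters from a t-map
#'
#' Connected components of `{t > threshold}` under the configured voxel
#' connectivity (default 6-neighbour face adjacency), sorted by size
#' descending.
#'
#' @param tmap A [voxelwise_t()] object.
#' @param threshold Cluster-forming threshold (default 2.3, one-sided
#'   p < 0.01 for the cohort sizes in view).
#' @param connectivity 6, 18 or 26.
#' @return List of clusters, each a list with `voxels` (linear indices),
#'   `size`, `peak` (voxel coordinate), `peak_t`.
#' @export
extract_clusters <- function(tmap, threshold = 2.3, connectivity = 6) {
  dims <- dim(tmap$t)
  supra <- which(!is.na(tmap$t) & tmap$t > threshold)
  comps <- label_components(supra, dims, connectivity)
  out <- lapply(comps, function(v) {
    pk <- v[which.max(tmap$t[v])]
    list(voxels = v, size = length(v), peak = drop(lin2xyz(pk, dims)),
         peak_t = tmap$t[pk])
  })
  out[order(-vapply(out, `[[`, 0, "size"))]
}

# cluster sizes above threshold for a given bias vector (permutation core)
cluster_sizes_for <- function(design, y, threshold, connectivity) {
  tv <- lesion_tvals(design, y)
  supra_masked <- which(tv > threshold)
  if (length(supra_masked) == 0) return(integer(0))
  supra <- which(design$mask)[supra_masked]
  vapply(label_components(supra, design$dims, connectivity), length, 0L)
}

#' Permutation-based minimum significant cluster size
#'
#' Shuffles persistence biases across patients `n_perm` times, recomputes the
#' voxelwise t-map and its supra-threshold cluster sizes each time, and
#' returns the minimum cluster size for significance: the smallest integer
#' `m` such that the chance of a null cluster of size >= `m` is at most
#' `alpha`. With `null = "pooled"` the chance distribution pools every
#' cluster found across permutations (the 95% cut-off of all clusters found
#' by chance); with `null = "max"` it is the per-permutation maximum cluster
#' size (standard family-wise error control; permutations with no cluster
#' contribute 0).
#'
#' @param cohort A `gp_lesion_cohort`.
#' @param n_perm Number of permutations (default 1000).
#' @param threshold Cluster-forming t threshold.
#' @param alpha Significance level for the cut-off.
#' @param null `"pooled"` or `"max"`.
#' @param connectivity,min_overlap Passed through to the t-map/clustering.
#' @return Integer minimum significant cluster size (0 iff no chance cluster
#'   was ever found, in which case any observed cluster is significant).
#' @export
permutation_cluster_threshold <- function(cohort, n_perm = 1000,
                                          threshold = 2.3, alpha = 0.05,
                                          null = c("pooled", "max"),
                                          connectivity = 6, min_overlap = 2) {
  null <- match.arg(null)
  if (n_perm < 100) warning("n_perm < 100: chance distribution will be coarse")
  design <- lesion_design(cohort, min_overlap)
  sizes <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    y <- sample(cohort$biases)
    cs <- cluster_sizes_for(design, y, threshold, connectivity)
    sizes[[i]] <- if (null == "max") {
      if (length(cs) == 0) 0L else max(cs)
    } else cs
  }
  chance <- unlist(sizes)
  if (length(chance) == 0 || max(chance) == 0) return(0L)
  # smallest m with P(chance size >= m) <= alpha
  for (m in seq_len(max(chance) + 1L)) {
    if (mean(chance >= m) <= alpha) return(as.integer(m))
  }
  as.integer(max(chance) + 1L)
}

#' Full voxelwise lesion-mapping pipeline
#'
#' Computes the t-map, extracts supra-threshold clusters, calibrates the
#' minimum significant cluster size by permutation, and returns the
#' significant clusters.
#'
#' @inheritParams permutation_cluster_threshold
#' @return List with `tmap`, `clusters` (all supra-threshold),
#'   `min_cluster_size`, and `significant` (clusters at or above it).
#' @export
lesion_pipeline <- function(cohort, n_perm = 1000, threshold = 2.3,
                            alpha = 0.05, null = c("pooled", "max"),
                            connectivity = 6, min_overlap = 2) {
  null <- match.arg(null)
  tmap <- voxelwise_t(cohort, min_overlap)
  clusters <- extract_clusters(tmap, threshold, connectivity)
  mcs <- permutation_cluster_threshold(cohort, n_perm, threshold, alpha,
                                       null, connectivity, min_overlap)
  sig <- Filter(function(cl) cl$size >= mcs && mcs > 0, clusters)
  list(tmap = tmap, clusters = clusters, min_cluster_size = mcs,
       significant = sig)
}

#' Split patients by damage within a spherical ROI
#'
#' A patient is labelled ROI-damaged iff any lesioned voxel lies within the
#' Euclidean ball of `roi_radius_vox` voxels around `roi_center` (radius 0
#' degenerates to the centre voxel itself).
#'
#' @param cohort A `gp_lesion_cohort`.
#' @param roi_center Voxel coordinate of the ROI centre (defaults to the
#'   cohort's stored centre).
#' @param roi_radius_vox Ball radius in voxels (default 3).
#' @return Logical vector, `TRUE` for ROI-damaged patients.
#' @export
roi_split <- function(cohort, roi_center = cohort$roi_center,
                      roi_radius_vox = 3) {
  dims <- cohort$grid_dims
  if (is.null(roi_center) || any(roi_center < 1) || any(roi_center > dims)) {
    stop("ROI outside grid")
  }
  ball <- roi_ball(dims, roi_center, roi_radius_vox)
  vapply(cohort$maps, function(m) any(m[ball] == 1L), TRUE)
}

#' Cluster report as a data frame
#'
#' @param clusters Output of [extract_clusters()].
#' @return Data frame `cluster_id,size,peak_x,peak_y,peak_z,peak_t`.
#' @export
cluster_report <- function(clusters) {
  if (length(clusters) == 0) {
    return(data.frame(cluster_id = integer(0), size = integer(0),
                      peak_x = integer(0), peak_y = integer(0),
                      peak_z = integer(0), peak_t = numeric(0)))
  }
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster_id = i, size = cl$size, peak_x = cl$peak[1],
               peak_y = cl$peak[2], peak_z = cl$peak[3], peak_t = cl$peak_t)
  }))
}
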