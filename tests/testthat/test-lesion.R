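# build a tiny cohort by hand: maps as arrays, biases chosen directly
hand_cohort <- function(maps, biases, dims) {
  structure(list(maps = maps, biases = biases,
                 roi_damaged = rep(FALSE, length(maps)),
                 grid_dims = dims, roi_center = NULL, roi_radius_vox = NULL,
                 voxel_size_mm = 2.4),
            class = "gp_lesion_cohort")
}

test_that("voxelwise t is signed so damage-lowers-bias gives positive t", {
  dims <- c(4L, 4L, 4L)
  n <- 10
  maps <- lapply(1:n, function(i) array(0L, dims))
  # voxel 1 damaged in patients 1:4 who have clearly lower biases
  for (i in 1:4) maps[[i]][1, 1, 1] <- 1L
  # a second voxel damaged in a mixed set
  for (i in c(1, 5, 6)) maps[[i]][2, 2, 2] <- 1L
  biases <- c(0, 0.2, 0.1, 0.05, 3, 3.1, 2.9, 3.2, 3.05, 2.95)
  coh <- hand_cohort(maps, biases, dims)
  tm <- voxelwise_t(coh, min_overlap = 2)
  expect_gt(tm$t[1, 1, 1], 5)
  expect_true(is.na(tm$t[4, 4, 4]))  # untested voxel is sentinel NA
  expect_equal(sum(!is.na(tm$t)), 2)
})

test_that("binary-regressor t equals the two-sample pooled t (lm oracle)", {
  set.seed(61)
  coh <- gen_lesion_cohort(n_patients = 14, grid_dims = c(8L, 8L, 8L),
                           roi_center = c(4L, 4L, 4L), effect_delta = 2,
                           lesion_size_range = c(20, 80))
  tm <- voxelwise_t(coh, min_overlap = 2)
  tested <- which(!is.na(tm$t))
  pick <- sample(tested, min(20, length(tested)))
  D <- t(vapply(coh$maps, as.vector, numeric(prod(coh$grid_dims))))
  for (v in pick) {
    fit <- lm(coh$biases ~ D[, v])
    t_lm <- -summary(fit)$coefficients[2, 3]  # damage lowers bias: sign flip
    expect_equal(tm$t[v], t_lm, tolerance = 1e-10)
  }
})

test_that("permuted biases give Student-t distributed voxel statistics", {
  set.seed(62)
  coh <- gen_lesion_cohort(n_patients = 16, effect_delta = 0)
  design <- goalpursuit:::lesion_design(coh, 2)
  tnull <- c(replicate(60, {
    tv <- goalpursuit:::lesion_tvals(design, sample(coh$biases))
    tv[sample(length(tv), 5)]
  }))
  # compare against the t(n-2) reference
  ks <- suppressWarnings(ks.test(tnull, pt, df = 14))
  expect_gt(ks$p.value, 0.01)
})

test_that("cluster extraction respects connectivity semantics", {
  dims <- c(3L, 3L, 3L)
  tarr <- array(NA_real_, dims)
  tarr[,,] <- 0
  tarr[1, 1, 1] <- 3
  tarr[2, 2, 2] <- 3.5  # touches (1,1,1) only at a corner
  tm <- structure(list(t = tarr, mask = array(TRUE, dims), n_patients = 10),
                  class = "gp_tmap")
  c6 <- extract_clusters(tm, threshold = 2.3, connectivity = 6)
  c18 <- extract_clusters(tm, threshold = 2.3, connectivity = 18)
  c26 <- extract_clusters(tm, threshold = 2.3, connectivity = 26)
  expect_length(c6, 2)
  expect_length(c18, 2)
  expect_length(c26, 1)
  expect_equal(c26[[1]]$peak_t, 3.5)
  expect_equal(sum(vapply(c6, `[[`, 0, "size")), 2)
  # no supra-threshold voxels: empty list
  expect_length(extract_clusters(tm, threshold = 10), 0)
  # sizes partition the supra-threshold set on a random map
  set.seed(63)
  tarr2 <- array(rnorm(27 * 8), c(6L, 6L, 6L))
  tm2 <- structure(list(t = tarr2, mask = array(TRUE, c(6L, 6L, 6L))),
                   class = "gp_tmap")
  cl <- extract_clusters(tm2, threshold = 1)
  expect_equal(sum(vapply(cl, `[[`, 0, "size")), sum(tarr2 > 1))
})

test_that("ROI splitting uses the Euclidean ball", {
  dims <- c(9L, 9L, 9L)
  ctr <- c(5L, 5L, 5L)
  m_center <- array(0L, dims)
  m_center[5, 5, 5] <- 1L
  m_outside <- array(1L, dims)
  ball <- goalpursuit:::roi_ball(dims, ctr, 3)
  m_outside[ball] <- 0L
  coh <- hand_cohort(list(m_center, m_outside), c(1, 2), dims)
  expect_equal(roi_split(coh, ctr, 3), c(TRUE, FALSE))
  # radius 0 degenerates to the centre voxel
  expect_equal(roi_split(coh, ctr, 0), c(TRUE, FALSE))
  expect_equal(roi_split(coh, c(1L, 1L, 1L), 0), c(FALSE, TRUE))
  expect_error(roi_split(coh, c(50, 1, 1), 3), "outside")
})

test_that("permutation threshold is integer-valued and detects implanted effects", {
  set.seed(64)
  coh <- gen_lesion_cohort(effect_delta = 3, noise_sd = 1)
  thr <- permutation_cluster_threshold(coh, n_perm = 150)
  expect_true(thr == as.integer(thr) && thr >= 0)
  res <- lesion_pipeline(coh, n_perm = 150)
  expect_gt(length(res$significant), 0)
  ball <- goalpursuit:::roi_ball(coh$grid_dims, coh$roi_center,
                                 coh$roi_radius_vox)
  expect_true(any(res$significant[[1]]$voxels %in% ball))
  expect_warning(permutation_cluster_threshold(coh, n_perm = 50), "coarse")
  # cluster report data frame
  rep <- cluster_report(res$clusters)
  expect_true(all(c("cluster_id", "size", "peak_t") %in% names(rep)))
  expect_equal(nrow(cluster_report(list())), 0)
})

test_that("voxelwise and ROI-split pipelines converge on the same patients", {
  set.seed(65)
  hits <- 0
  for (i in 1:5) {
    coh <- gen_lesion_cohort(effect_delta = 3, noise_sd = 1)
    res <- lesion_pipeline(coh, n_perm = 120)
    roi_lab <- roi_split(coh, coh$roi_center, coh$roi_radius_vox)
    if (length(res$significant) > 0) {
      clvox <- res$significant[[1]]$voxels
      in_cluster <- vapply(coh$maps, function(m) any(m[clvox] == 1L), TRUE)
      agree <- mean(in_cluster == roi_lab)
      if (agree >= 0.8) hits <- hits + 1
    }
  }
  expect_gte(hits, 4)
})
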