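test_that("the ventral-striatum box has its catalogued volume", {
  ph <- build_phantom()
  roi <- builtin_roi("ventral_striatum", ph)
  expect_identical(roi$volume_mm3, 24 * 12 * 18)
  # rasterization error bounded by one voxel layer around the box surface
  expect_lt(abs(roi$raster_volume_mm3 - roi$volume_mm3),
            2 * (24 * 12 + 24 * 18 + 12 * 18) * 3)
  mb <- builtin_roi("midbrain", ph)
  expect_gt(sum(mb$mask), 0)
  expect_error(roi_from_box(rbind(x = c(0, 0), y = c(0, 1), z = c(0, 1)), ph),
               "degenerate")
})

test_that("cluster connectivity rules distinguish face, edge and corner contact", {
  corner <- array(0, dim = c(4, 4, 4))
  corner[1, 1, 1] <- 5; corner[2, 2, 2] <- 5
  expect_length(define_clusters(corner, 1, connectivity = 6)$sizes, 2)
  expect_length(define_clusters(corner, 1, connectivity = 18)$sizes, 2)
  expect_length(define_clusters(corner, 1, connectivity = 26)$sizes, 1)
  edge <- array(0, dim = c(4, 4, 4))
  edge[1, 1, 1] <- 5; edge[2, 2, 1] <- 5
  expect_length(define_clusters(edge, 1, connectivity = 6)$sizes, 2)
  expect_length(define_clusters(edge, 1, connectivity = 18)$sizes, 1)
  face <- array(0, dim = c(4, 4, 4))
  face[1, 1, 1] <- 5; face[2, 1, 1] <- 5
  expect_length(define_clusters(face, 1, connectivity = 6)$sizes, 1)
})

test_that("cluster extraction finds planted blocks and respects masks", {
  m <- array(0, dim = c(10, 10, 10))
  m[3:6, 3:6, 3:6] <- 9
  cl <- define_clusters(m, 5)
  expect_equal(cl$sizes, 64L)
  expect_equal(cl$peaks$peak, 9)
  expect_length(define_clusters(array(0, dim = c(5, 5, 5)), 2)$sizes, 0)
  expect_error(define_clusters(m, 5, mask = array(FALSE, dim = dim(m))),
               "empty mask")
  # monotonicity: a lower threshold never shrinks the largest cluster
  noisy <- m + withr::with_seed(1, array(rnorm(1000), dim = dim(m)))
  k_hi <- max(define_clusters(noisy, 5)$sizes)
  k_lo <- max(define_clusters(noisy, 3)$sizes)
  expect_gte(k_lo, k_hi)
})

test_that("sign-flip correction is deterministic with a bounded minimal p", {
  set.seed(20)
  shape <- c(8L, 8L, 6L)
  maps <- lapply(1:16, function(i) {
    a <- array(rnorm(prod(shape)), dim = shape)
    a[3:5, 3:5, 3:4] <- a[3:5, 3:5, 3:4] + 3  # saturating effect
    a
  })
  pn1 <- permutation_correct(maps, n_perm = 200, cdt_p = 0.001, seed = 5)
  pn2 <- permutation_correct(maps, n_perm = 200, cdt_p = 0.001, seed = 5)
  expect_identical(pn1$null_max_t, pn2$null_max_t)
  expect_identical(pn1$p_cluster, pn2$p_cluster)
  tb <- cluster_report(pn1)
  expect_equal(min(tb$p_peak), 1 / 201)   # saturated extreme rank
  expect_true(all(tb$p_cluster > 0 & tb$p_cluster <= 1))
  expect_true(all(diff(tb$t) <= 0))       # sorted by peak statistic
})

test_that("small cohorts trigger exhaustive sign enumeration", {
  shape <- c(4L, 4L, 4L)
  maps <- lapply(1:3, function(i)
    array(rnorm(prod(shape), mean = 1), dim = shape))
  expect_message(pn <- permutation_correct(maps, n_perm = 100, seed = 1),
                 "enumerating")
  expect_equal(pn$n_perm, 8L)  # 2^3 assignments
  expect_gte(min(pn$p_peak, na.rm = TRUE), 1 / 9)
})

test_that("ROI correction is at least as powerful as whole-volume correction", {
  set.seed(21)
  ph <- build_phantom()
  roi <- builtin_roi("ventral_striatum", ph)
  maps <- lapply(1:12, function(i) {
    a <- array(rnorm(prod(ph$shape)), dim = ph$shape)
    a[roi$mask] <- a[roi$mask] + 0.8
    a
  })
  pn_roi <- permutation_correct(maps, mask = roi, n_perm = 300, seed = 2,
                                cdt_p = 0.01, cluster = FALSE)
  pn_all <- permutation_correct(maps, n_perm = 300, seed = 2,
                                cdt_p = 0.001, cluster = FALSE)
  # null maxima over a subset cannot exceed maxima over the whole volume
  expect_true(all(pn_roi$null_max_t <= pn_all$null_max_t + 1e-12))
  inroi <- which(roi$mask)
  expect_true(all(pn_roi$p_peak[inroi] <= pn_all$p_peak[inroi] + 1e-12))
})

test_that("group-label permutation flags a planted two-group difference", {
  set.seed(22)
  shape <- c(8L, 8L, 6L)
  maps_a <- lapply(1:8, function(i) {
    a <- array(rnorm(prod(shape)), dim = shape)
    a[3:5, 3:5, 3:4] <- a[3:5, 3:5, 3:4] + 2.5
    a
  })
  maps_b <- lapply(1:8, function(i) array(rnorm(prod(shape)), dim = shape))
  pn <- permutation_correct(c(maps_a, maps_b), n_perm = 300,
                            analysis_type = "two_sample",
                            group_labels = rep(c("a", "b"), each = 8),
                            cdt_p = 0.001, seed = 3)
  tb <- cluster_report(pn)
  expect_gte(nrow(tb), 1)
  expect_lte(tb$p_cluster[1], 0.05)
  expect_error(permutation_correct(c(maps_a, maps_b), n_perm = 50,
                                   analysis_type = "two_sample", seed = 1),
               "group_labels")
})

test_that("cluster tables report world coordinates from the grid affine", {
  ph <- build_phantom()
  m <- array(0, dim = ph$shape)
  m[10, 12, 9] <- 8  # near the grid centre
  maps <- lapply(1:6, function(i)
    m + withr::with_seed(30 + i, array(rnorm(prod(ph$shape), sd = 0.5),
                                       dim = ph$shape)))
  pn <- permutation_correct(maps, n_perm = 100, cdt_p = 0.001, seed = 4)
  tb <- cluster_report(pn, ph)
  expect_gte(nrow(tb), 1)
  # peak voxel (10, 12, 9) maps to world (x, y, z) via the RAS affine
  expect_lt(max(abs(c(tb$x[1], tb$y[1], tb$z[1]) -
                      (ph$affine[1:3, 1:3] %*% c(9, 11, 8) +
                         ph$affine[1:3, 4]))), 1e-9)
  # sub-threshold maps give an empty table
  flat <- lapply(1:6, function(i)
    withr::with_seed(40 + i, array(rnorm(prod(ph$shape), sd = 0.1),
                                   dim = ph$shape)))
  pn0 <- permutation_correct(flat, n_perm = 100, cdt_p = 1e-6, seed = 5)
  expect_equal(nrow(cluster_report(pn0, ph)), 0)
})
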