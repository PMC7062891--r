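#' Built-in region-of-interest masks
#'
#' `"ventral_striatum"` is the a-priori box at MNI coordinates
#' x -12..+12, y 0..+12, z -12..+6 (analytic volume 5184 mm^3).
#' `"midbrain"` is a synthetic surrogate box around the midbrain
#' (x -15..+15, y -28..-8, z -20..0); the study's hand-drawn midbrain mask
#' cannot be reconstructed, so no equivalence is claimed.
#'
#' @param name ROI name.
#' @param phantom a [build_phantom()] supplying grid shape and affine.
#' @return An `roi_mask`: logical `mask` aligned to the grid, `name`,
#'   `volume_mm3` (analytic, from the bounds), `raster_volume_mm3`
#'   (in-mask voxel count times voxel volume), and the `bounds` (mm).
#' @export
builtin_roi <- function(name = c("ventral_striatum", "midbrain"), phantom) {
  name <- match.arg(name)
  bounds <- switch(name,
    ventral_striatum = rbind(x = c(-12, 12), y = c(0, 12), z = c(-12, 6)),
    midbrain = rbind(x = c(-15, 15), y = c(-28, -8), z = c(-20, 0)))
  roi_from_box(bounds, phantom, name)
}

#' Rasterize an axis-aligned world-space box into a grid mask
#' @param bounds 3 x 2 matrix of lower/upper bounds in mm (rows x, y, z).
#' @param phantom a [build_phantom()].
#' @param name label for the mask.
#' @return An `roi_mask` (see [builtin_roi()]).
#' @export
roi_from_box <- function(bounds, phantom, name = "box") {
  if (any(bounds[, 2] <= bounds[, 1]))
    stop_tdbold("degenerate ROI box: zero or negative extent on an axis")
  aff <- phantom$affine
  shape <- phantom$shape
  centers <- lapply(1:3, function(ax)
    aff[ax, ax] * (seq_len(shape[ax]) - 1L) + aff[ax, 4])
  inb <- lapply(1:3, function(ax)
    centers[[ax]] >= bounds[ax, 1] & centers[[ax]] <= bounds[ax, 2])
  mask <- array(outer(outer(inb[[1]], inb[[2]], "&"), inb[[3]], "&"),
                dim = shape)
  if (!any(mask)) stop_tdbold("ROI box does not intersect the grid")
  structure(list(mask = mask, name = name,
                 volume_mm3 = prod(bounds[, 2] - bounds[, 1]),
                 raster_volume_mm3 = sum(mask) * prod(phantom$voxel_size),
                 bounds = bounds),
            class = "roi_mask")
}

connectivity_offsets <- function(connectivity = 18L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop_tdbold("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(off != 0)
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

# Connected components over a set of supra-threshold voxels given by linear
# indices; returns component id per index. Union-find with path halving.
label_components <- function(idx, dim3, connectivity = 18L) {
  k <- length(idx)
  if (k == 0L) return(integer(0))
  ord <- order(idx)
  idx_s <- idx[ord]
  coords <- arrayInd(idx_s, dim3)
  off <- connectivity_offsets(connectivity)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  strides <- c(1L, dim3[1], dim3[1] * dim3[2])
  for (o in seq_len(nrow(off))) {
    nb <- coords + matrix(off[o, ], k, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dim3[1] &
      nb[, 2] >= 1 & nb[, 2] <= dim3[2] &
      nb[, 3] >= 1 & nb[, 3] <= dim3[3]
    if (!any(ok)) next
    lin <- (nb[ok, 1] - 1L) * strides[1] + (nb[ok, 2] - 1L) * strides[2] +
      (nb[ok, 3] - 1L) * strides[3] + 1L
    hit <- match(lin, idx_s)
    src <- which(ok)[!is.na(hit)]
    dst <- hit[!is.na(hit)]
    for (j in seq_along(src)) {
      a <- find(src[j]); b <- find(dst[j])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  lab_s <- match(roots, unique(roots))
  lab <- integer(k)
  lab[ord] <- lab_s
  lab
}

#' Define supra-threshold clusters in a statistic map
#'
#' Thresholds the map (within an optional mask) and labels the connected
#' components of the surviving voxels under the given connectivity rule
#' (18-connectivity by default: voxels sharing a face or an edge merge;
#' corner-only contact does not).
#'
#' @param stat_map 3-D statistic array (`NA` treated as sub-threshold).
#' @param threshold cluster-defining statistic value (e.g. from
#'   [t_cluster_threshold()]).
#' @param mask optional logical array or `roi_mask` restricting the search.
#' @param connectivity 6, 18 or 26.
#' @return A list with `labels` (integer array, 0 = sub-threshold), `sizes`
#'   (voxels per cluster), `peaks` (data frame: cluster, peak statistic,
#'   peak voxel indices).
#' @export
define_clusters <- function(stat_map, threshold, mask = NULL,
                            connectivity = 18L) {
  dim3 <- dim(stat_map)
  m <- if (is.null(mask)) TRUE else {
    mk <- if (inherits(mask, "roi_mask")) mask$mask else mask
    if (!any(mk)) stop_tdbold("empty mask")
    mk
  }
  supra <- which(!is.na(stat_map) & stat_map >= threshold & m)
  labels <- array(0L, dim = dim3)
  if (!length(supra)) {
    return(list(labels = labels, sizes = integer(0),
                peaks = data.frame(cluster = integer(0), peak = numeric(0),
                                   i = integer(0), j = integer(0),
                                   k = integer(0))))
  }
  lab <- label_components(supra, dim3, connectivity)
  labels[supra] <- lab
  n_cl <- max(lab)
  sizes <- tabulate(lab, n_cl)
  peaks <- do.call(rbind, lapply(seq_len(n_cl), function(cl) {
    ii <- supra[lab == cl]
    best <- ii[which.max(stat_map[ii])]
    co <- arrayInd(best, dim3)
    data.frame(cluster = cl, peak = stat_map[best],
               i = co[1], j = co[2], k = co[3])
  }))
  list(labels = labels, sizes = sizes, peaks = peaks)
}

#' Cluster-defining t threshold from an uncorrected p
#' @param p one-sided uncorrected p-value.
#' @param dof t degrees of freedom.
#' @return The t value whose upper tail probability is `p`.
#' @export
t_cluster_threshold <- function(p, dof) stats::qt(1 - p, df = dof)

#' Permutation-based family-wise-error correction
#'
#' Builds null distributions of the maximal peak t and (optionally) the
#' maximal supra-threshold cluster size over permutations of the group-level
#' model: random sign flips of the subject maps for the one-sample design
#' (exchangeable under symmetric errors), random relabelling of group
#' membership for the two-sample design.  Corrected p-values use the +1
#' smoothing \eqn{p = (1 + \#\{null \ge obs\}) / (1 + n_{perm})}, so they
#' are bounded below by \eqn{1/(n_{perm}+1)}.  Tests are one-sided.
#'
#' @param subject_maps list of per-subject 3-D contrast maps (or a voxels x
#'   subjects matrix plus `shape`).
#' @param mask optional logical array or `roi_mask`; maxima are taken within
#'   the mask ("the confines of a region") or the whole volume.
#' @param n_perm number of permutation samples.
#' @param cdt_p cluster-defining uncorrected one-sided p.
#' @param analysis_type `"one_sample"` or `"two_sample"`.
#' @param group_labels labels for the two-sample design.
#' @param connectivity cluster connectivity rule.
#' @param cluster logical; also build the max-cluster-size null.
#' @param seed integer seed.
#' @param shape grid dimensions when `subject_maps` is a matrix.
#' @return A `permutation_null`: observed `t_map`, `dof`, `clusters`,
#'   per-voxel corrected peak p map `p_peak`, per-cluster corrected p
#'   `p_cluster`, null vectors `null_max_t` / `null_max_cluster`, the
#'   threshold used, and bookkeeping fields.
#' @export
permutation_correct <- function(subject_maps, mask = NULL, n_perm = 6000L,
                                cdt_p = 0.001,
                                analysis_type = c("one_sample", "two_sample"),
                                group_labels = NULL, connectivity = 18L,
                                cluster = TRUE, seed = 1L, shape = NULL) {
  analysis_type <- match.arg(analysis_type)
  if (is.matrix(subject_maps)) {
    M <- subject_maps
    if (is.null(shape)) stop_tdbold("shape required with a matrix input")
  } else {
    shape <- dim(subject_maps[[1]])
    M <- sapply(subject_maps, as.vector)
  }
  n <- ncol(M)
  if (n < 2L) stop_tdbold("need at least 2 subject maps")
  mk <- if (is.null(mask)) rep(TRUE, nrow(M)) else
    as.vector(if (inherits(mask, "roi_mask")) mask$mask else mask)
  vox <- which(mk)
  V <- M[vox, , drop = FALSE]

  if (analysis_type == "one_sample") {
    dof <- n - 1L
    sumsq <- rowSums(V^2)
    t_from_mean <- function(m) {
      s2 <- (sumsq - n * m^2) / dof  # recycles over permutation columns
      s2[s2 < 0] <- 0
      tt <- m / sqrt(s2 / n)
      tt[!is.finite(tt)] <- NA_real_
      tt
    }
    t_obs <- t_from_mean(rowMeans(V))
    exhaustive <- 2^n < n_perm
    if (exhaustive) {
      message("2^n < n_perm; enumerating all ", 2^n, " sign assignments")
      S <- t(as.matrix(expand.grid(rep(list(c(-1, 1)), n))))
      n_perm <- ncol(S)
    } else {
      S <- with_seed(seed, matrix(sample(c(-1, 1), n * n_perm, replace = TRUE),
                                  n, n_perm))
    }
    Mean <- (V %*% S) / n
    Tnull <- t_from_mean(Mean)  # vectorizes column-wise
  } else {
    if (is.null(group_labels)) stop_tdbold("two_sample needs group_labels")
    g <- as.integer(factor(group_labels))
    n1 <- sum(g == 1L); n2 <- sum(g == 2L)
    dof <- n1 + n2 - 2L
    V2 <- V^2
    t_two <- function(ind1) {  # ind1: logical/0-1 vector marking group 1
      P <- matrix(as.numeric(ind1), n, 1)
      m1 <- drop(V %*% P) / n1; m2 <- drop(V %*% (1 - P)) / n2
      s1 <- drop(V2 %*% P); s2 <- drop(V2 %*% (1 - P))
      sp2 <- pmax(0, (s1 - n1 * m1^2 + s2 - n2 * m2^2) / dof)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      ifelse(se > 0, (m1 - m2) / se, NA_real_)
    }
    t_obs <- t_two(g == 1L)
    Tnull <- with_seed(seed, {
      sapply(seq_len(n_perm), function(p) t_two(sample(g) == 1L))
    })
  }

  t_cdt <- t_cluster_threshold(cdt_p, dof)
  full_t <- rep(NA_real_, nrow(M)); full_t[vox] <- t_obs
  t_map <- array(full_t, dim = shape)
  obs_cl <- define_clusters(t_map, t_cdt, mask = array(mk, dim = shape),
                            connectivity = connectivity)

  Tnull <- matrix(Tnull, nrow = nrow(V))
  Tnull[is.na(Tnull)] <- -Inf
  null_max_t <- Tnull[cbind(max.col(t(Tnull), "first"), seq_len(n_perm))]
  # corrected peak p via the empirical upper tail of the null maxima:
  # #{null >= t0} = n_perm - #{null < t0}
  srt <- sort(null_max_t)
  n_ge <- n_perm - findInterval(t_obs, srt, left.open = TRUE)
  p_peak_vec <- (1 + n_ge) / (1 + n_perm)
  p_peak_vec[is.na(t_obs)] <- NA_real_
  full_p <- rep(NA_real_, nrow(M)); full_p[vox] <- p_peak_vec
  p_peak <- array(full_p, dim = shape)

  null_max_cluster <- NULL
  p_cluster <- NULL
  if (cluster) {
    dim3 <- shape
    null_max_cluster <- integer(n_perm)
    for (p in seq_len(n_perm)) {
      supra_local <- which(Tnull[, p] >= t_cdt)
      if (!length(supra_local)) next
      lab <- label_components(vox[supra_local], dim3, connectivity)
      null_max_cluster[p] <- max(tabulate(lab))
    }
    p_cluster <- vapply(obs_cl$sizes, function(k)
      (1 + sum(null_max_cluster >= k)) / (1 + n_perm), numeric(1))
  }

  structure(list(t_map = t_map, dof = dof, cdt_p = cdt_p, t_cdt = t_cdt,
                 clusters = obs_cl, p_peak = p_peak, p_cluster = p_cluster,
                 null_max_t = null_max_t, null_max_cluster = null_max_cluster,
                 n_perm = n_perm, connectivity = connectivity,
                 analysis_type = analysis_type, seed = seed, shape = shape,
                 mask = array(mk, dim = shape)),
            class = "permutation_null")
}

#' Cluster table of a corrected analysis
#'
#' One row per observed supra-threshold cluster, sorted by peak statistic:
#' peak world coordinates, peak t, extent in voxels, cluster-level and
#' peak-level corrected p-values from the permutation null distributions.
#'
#' @param null a [permutation_correct()] result.
#' @param phantom the [build_phantom()] supplying the affine (optional; grid
#'   indices are reported when absent).
#' @return A data frame with columns `cluster`, `x`, `y`, `z`, `k`,
#'   `p_cluster`, `t`, `p_peak`.
#' @export
cluster_report <- function(null, phantom = NULL) {
  pk <- null$clusters$peaks
  if (!nrow(pk)) {
    return(data.frame(cluster = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), k = integer(0), p_cluster = numeric(0),
                      t = numeric(0), p_peak = numeric(0)))
  }
  co <- as.matrix(pk[, c("i", "j", "k")])
  if (!is.null(phantom)) {
    aff <- phantom$affine
    world <- t(aff %*% rbind(t(co) - 1, 1))[, 1:3, drop = FALSE]
  } else world <- co
  lin <- (co[, 1] - 1L) + (co[, 2] - 1L) * null$shape[1] +
    (co[, 3] - 1L) * null$shape[1] * null$shape[2] + 1L
  out <- data.frame(cluster = pk$cluster,
                    x = world[, 1], y = world[, 2], z = world[, 3],
                    k = null$clusters$sizes[pk$cluster],
                    p_cluster = if (is.null(null$p_cluster)) NA_real_
                                else null$p_cluster[pk$cluster],
                    t = pk$peak,
                    p_peak = null$p_peak[lin])
  out[order(-out$t), , drop = FALSE]
}

#' Write a cluster table as tab-separated text
#' @param table a [cluster_report()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
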