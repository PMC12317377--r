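#' Integer voxel offsets of a sphere
#'
#' All integer offsets whose Euclidean norm is at most `radius_vox`,
#' including the center. A radius of 3 yields 123 offsets.
#'
#' @param radius_vox Sphere radius in voxels (>= 0).
#' @return Integer matrix with columns `dx`, `dy`, `dz`.
#' @export
sphere_offsets <- function(radius_vox) {
  if (radius_vox < 0) stop("radius must be >= 0")
  r <- floor(radius_vox)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= radius_vox^2
  m <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

#' Searchlight decoding over a masked volume
#'
#' Slides a sphere of `radius_vox` voxels over every in-mask voxel and runs
#' the identical leave-one-run-out pipeline (voxel-wise z-scoring of event
#' betas, condition averaging per run, per-fold min-max scaling, linear
#' C-SVC) on the sphere's in-mask voxels. Spheres are clipped at the mask
#' border; centers whose clipped sphere holds fewer than 2 voxels get `NA`.
#'
#' Because z-scoring and condition averaging are voxel-wise they commute
#' with voxel subsetting, so a sphere covering exactly an ROI's voxel set
#' reproduces the ROI pipeline's accuracy bit for bit.
#'
#' @param betas Event x voxel beta matrix for one participant, columns in
#'   the order of `which(mask)`.
#' @param events Tibble with one row per event: columns `run` and the label
#'   column named by the task's level.
#' @param mask 3-dimensional logical array.
#' @param task A [classification_task()].
#' @param radius_vox Sphere radius in voxels (default 3).
#' @param cost Soft-margin cost C.
#' @param zscore Standardize betas first (default TRUE).
#' @return Numeric vector of accuracies, one per in-mask voxel (aligned
#'   with `which(mask)`).
#' @export
searchlight_decode <- function(betas, events, mask, task, radius_vox = 3,
                               cost = 1, zscore = TRUE) {
  stopifnot(length(dim(mask)) == 3)
  vox <- which(mask)
  if (length(vox) == 0) stop("empty mask")
  if (ncol(betas) != length(vox))
    stop("betas has ", ncol(betas), " columns but the mask has ",
         length(vox), " voxels")
  dims <- dim(mask)
  coords <- arrayInd(vox, dims)
  # linear index -> column position in `betas`
  col_of <- integer(prod(dims)); col_of[vox] <- seq_along(vox)

  df <- events
  df$beta <- betas
  if (zscore) df <- zscore_events(df)
  patt <- average_conditions(df, task)
  folds <- lapply(build_folds_unscaled(patt), identity)

  offs <- sphere_offsets(radius_vox)
  acc <- rep(NA_real_, length(vox))
  for (ci in seq_along(vox)) {
    pts <- sweep(offs, 2, coords[ci, ], "+")
    ok <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
      pts[, 2] >= 1 & pts[, 2] <= dims[2] &
      pts[, 3] >= 1 & pts[, 3] <= dims[3]
    lin <- pts[ok, 1] + (pts[ok, 2] - 1) * dims[1] +
      (pts[ok, 3] - 1) * dims[1] * dims[2]
    cols <- col_of[lin]
    cols <- cols[cols > 0]
    if (length(cols) < 2) next
    acc[ci] <- decode_fold_subset(folds, patt$condition, cols, cost)
  }
  acc
}

# Unscaled folds: scaling must happen after voxel subsetting (min-max is
# per voxel, so it commutes, but computing it lazily per sphere keeps the
# ROI-equivalence exact).
build_folds_unscaled <- function(patterns) {
  runs <- sort(unique(patterns$run))
  if (length(runs) < 2) stop("leave-one-run-out needs >= 2 runs")
  purrr::map(runs, function(r) {
    list(train = patterns$pattern[patterns$run != r, , drop = FALSE],
         test = patterns$pattern[patterns$run == r, , drop = FALSE],
         train_cond = patterns$condition[patterns$run != r],
         test_cond = patterns$condition[patterns$run == r])
  })
}

decode_fold_subset <- function(folds, all_cond, cols, cost) {
  conds <- sort(unique(all_cond))
  n_correct <- 0L; n_total <- 0L
  for (f in folds) {
    sc <- scale_train_apply_test(f$train[, cols, drop = FALSE],
                                 f$test[, cols, drop = FALSE])
    pred <- svc_train_predict(sc$train,
                              as.integer(match(f$train_cond, conds)),
                              sc$test, cost)
    n_correct <- n_correct + sum(conds[pred] == f$test_cond)
    n_total <- n_total + length(pred)
  }
  n_correct / n_total
}

#' Group t-map over participant searchlight maps
#'
#' One-sample, one-sided t-test against chance at every in-mask voxel.
#'
#' @param maps Participant x voxel matrix of accuracies (columns aligned
#'   with `which(mask)`).
#' @param chance Chance accuracy level.
#' @return Tibble with columns `voxel` (index into `which(mask)`), `mean`,
#'   `t`, `p`; voxels with zero variance or missing data get `NA`.
#' @export
group_map_test <- function(maps, chance) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 2) stop("need >= 2 participants")
  mu <- colMeans(maps)
  s <- apply(maps, 2, stats::sd)
  t_stat <- (mu - chance) / (s / sqrt(n))
  t_stat[!is.finite(t_stat)] <- NA_real_
  p <- pt(t_stat, df = n - 1, lower.tail = FALSE)
  tibble::tibble(voxel = seq_len(ncol(maps)), mean = mu, t = t_stat, p = p)
}

# 26-connectivity connected components of a logical 3D array.
# Returns an integer array of component labels (0 = background).
label_components <- function(x) {
  dims <- dim(x)
  lab <- array(0L, dims)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- as.matrix(offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ])
  idx <- which(x)
  nxt <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      co <- arrayInd(cur, dims)
      nb <- sweep(offs, 2, as.integer(co), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      lin <- nb[ok, 1] + (nb[ok, 2] - 1) * dims[1] +
        (nb[ok, 3] - 1) * dims[1] * dims[2]
      new <- lin[x[lin] & lab[lin] == 0L]
      lab[new] <- nxt
      stack <- c(stack, new)
    }
  }
  lab
}

# Separable Gaussian smoothing of a 3D array (sigma in voxels).
gaussian_smooth3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    n <- dp[1]
    # banded smoothing matrix with edge renormalization
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      w <- k[j - i + r + 1]
      S[i, j] <- w / sum(w)
    }
    sm <- S %*% m
    ap2 <- array(sm, dp)
    aperm(ap2, order(perm))
  }
  for (ax in 1:3) x <- smooth_axis(x, ax)
  x
}

#' Monte-Carlo cluster-size threshold correction
#'
#' Estimates the minimum cluster size controlling the family-wise error of
#' a voxelwise-thresholded map: `n_mc` smoothness-matched Gaussian noise
#' volumes are generated, standardized within the mask, thresholded at the
#' voxelwise level `voxel_p`, and the maximum 26-connected cluster size is
#' recorded per volume; the minimum size is the `1 - cluster_alpha`
#' quantile of those maxima. Observed supra-threshold clusters at least
#' that large survive.
#'
#' @param p_map Numeric vector of voxelwise p-values over `which(mask)`.
#' @param mask 3-dimensional logical array.
#' @param voxel_p Voxelwise threshold (default 0.01).
#' @param n_mc Number of Monte-Carlo volumes (default 1000).
#' @param smoothness_fwhm_mm Spatial smoothness (FWHM, mm) of the matched
#'   noise (0 = independent voxels).
#' @param voxel_size_mm Isotropic voxel size, mm (default 2).
#' @param cluster_alpha Cluster-level significance (default 0.05).
#' @param seed Integer seed.
#' @return A list with `min_cluster_size`, `clusters` (tibble: `id`,
#'   `size`, `peak` 0-based voxel coordinates, `survives`), `surviving_mask`
#'   (logical array), and `max_null_sizes`.
#' @export
cluster_threshold <- function(p_map, mask, voxel_p = 0.01, n_mc = 1000,
                              smoothness_fwhm_mm = 0, voxel_size_mm = 2,
                              cluster_alpha = 0.05, seed = 1L) {
  stopifnot(length(dim(mask)) == 3)
  if (n_mc * cluster_alpha < 1)
    stop("n_mc too small to estimate the ", 1 - cluster_alpha, " quantile")
  vox <- which(mask)
  if (length(p_map) != length(vox))
    stop("p_map must have one value per in-mask voxel")
  dims <- dim(mask)
  sigma <- smoothness_fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  z_thr <- qnorm(1 - voxel_p)

  max_sizes <- with_seed(seed, {
    vapply(seq_len(n_mc), function(i) {
      noise <- array(rnorm(prod(dims)), dims)
      if (sigma > 0) noise <- gaussian_smooth3d(noise, sigma)
      v <- noise[vox]
      v <- (v - mean(v)) / stats::sd(v)
      supra <- array(FALSE, dims)
      supra[vox[v > z_thr]] <- TRUE
      lab <- label_components(supra)
      if (max(lab) == 0L) 0L else max(tabulate(lab[lab > 0L]))
    }, integer(1))
  })
  min_size <- ceiling(quantile(max_sizes, 1 - cluster_alpha, type = 1,
                               names = FALSE))
  min_size <- max(1L, as.integer(min_size))

  supra <- array(FALSE, dims)
  supra[vox[p_map < voxel_p & !is.na(p_map)]] <- TRUE
  lab <- label_components(supra)
  surviving <- array(FALSE, dims)
  clusters <- tibble::tibble(id = integer(), size = integer(),
                             peak_x = integer(), peak_y = integer(),
                             peak_z = integer(), survives = logical())
  if (max(lab) > 0L) {
    p_arr <- array(NA_real_, dims); p_arr[vox] <- p_map
    clusters <- purrr::map(seq_len(max(lab)), function(id) {
      members <- which(lab == id)
      pk <- members[which.min(p_arr[members])]
      co <- arrayInd(pk, dims) - 1L  # 0-based
      tibble::tibble(id = id, size = length(members),
                     peak_x = co[1], peak_y = co[2], peak_z = co[3],
                     survives = length(members) >= min_size)
    }) |> dplyr::bind_rows()
    for (id in clusters$id[clusters$survives])
      surviving[lab == id] <- TRUE
  }
  list(min_cluster_size = min_size, clusters = clusters,
       surviving_mask = surviving, max_null_sizes = max_sizes)
}
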