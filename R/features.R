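# Per-voxel quantities consumed by the energy: multi-channel features,
# Gaussian region models, LBP-TOP cumulative histograms with the L1
# Wasserstein distance, spin-image-like descriptors and the EMD edge weight.

# separable Gaussian blur with edge replication; sigma in voxel units
gaussian_blur3 <- function(arr, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  dm <- dim(arr)
  for (ax in 1:3) {
    out <- array(0, dm)
    n <- dm[ax]
    for (t in -r:r) {
      idx <- pmin(pmax(seq_len(n) + t, 1L), n)
      sl <- switch(ax,
                   arr[idx, , , drop = FALSE],
                   arr[, idx, , drop = FALSE],
                   arr[, , idx, drop = FALSE])
      out <- out + w[t + r + 1L] * sl
    }
    arr <- out
  }
  arr
}

#' Build the per-voxel feature stack
#'
#' Channel 1 is the raw intensity; channel 2 is a Gaussian blur at scale
#' `sigma_blur` (voxel units, edge replication). These two channels are the
#' feature vectors x_p used by both the Gaussian data term and the boundary
#' term.
#'
#' @param v a [volume()].
#' @param sigma_blur blur scale in voxel units (default 1).
#' @return A `feature_stack`: list with `x` (nvox x 2 matrix, x-fastest
#'   voxel order), `dims`, `spacing`.
#' @export
feature_stack <- function(v, sigma_blur = 1) {
  stopifnot(inherits(v, "volume"))
  if (sigma_blur <= 0) stop("sigma_blur must be positive")
  raw <- as.vector(v$data)
  blur <- as.vector(gaussian_blur3(v$data, sigma_blur))
  structure(list(x = cbind(raw, blur, deparse.level = 0),
                 dims = dim(v$data), spacing = v$spacing),
            class = "feature_stack")
}

#' Fit a d-dimensional Gaussian model over a voxel region
#'
#' Mean vector and covariance matrix of the feature vectors in `region`,
#' using the 1/n (maximum-likelihood) covariance convention. The covariance
#' is regularized by `max(1e-6 * tr(xi)/d, 1e-8) * I` so constant regions
#' (common in phantoms) stay invertible.
#'
#' @param fs a [feature_stack()].
#' @param region voxel set: linear indices or a logical array.
#' @return A `gaussian_model`: list with `mu`, `sigma`, `sigma_inv`,
#'   `log_det`, `d`.
#' @export
fit_gaussian <- function(fs, region) {
  stopifnot(inherits(fs, "feature_stack"))
  idx <- if (is.logical(region) || is.array(region)) which(region != 0)
         else as.integer(region)
  d <- ncol(fs$x)
  if (length(idx) < d + 1L)
    stop("region too small to fit a ", d, "-dimensional Gaussian")
  xs <- fs$x[idx, , drop = FALSE]
  mu <- colMeans(xs)
  ctr <- sweep(xs, 2, mu)
  sig <- crossprod(ctr) / nrow(ctr)
  reg <- max(1e-6 * sum(diag(sig)) / d, 1e-8)
  sig <- sig + diag(reg, d)
  structure(list(mu = mu, sigma = sig, sigma_inv = solve(sig),
                 log_det = determinant(sig, logarithm = TRUE)$modulus[1],
                 d = d),
            class = "gaussian_model")
}

gaussian_nll <- function(model, x) {
  diff <- x - model$mu
  0.5 * (model$d * log(2 * pi) + model$log_det) +
    0.5 * sum(diff * (model$sigma_inv %*% diff))
}

# vectorized negative log-likelihood over rows of a feature matrix
gaussian_nll_rows <- function(model, xmat) {
  ctr <- sweep(xmat, 2, model$mu)
  maha <- rowSums((ctr %*% model$sigma_inv) * ctr)
  0.5 * (model$d * log(2 * pi) + model$log_det) + 0.5 * maha
}

#' Gaussian data term at a voxel
#'
#' The negative log-likelihood
#' \deqn{D_p = \tfrac12 \ln((2\pi)^d |\xi|) +
#'   \tfrac12 (x_p-\mu)^T \xi^{-1} (x_p-\mu),}
#' minimized at \eqn{x_p = \mu}.
#'
#' @param fs a [feature_stack()].
#' @param model a `gaussian_model` from [fit_gaussian()].
#' @param p voxel: linear index, `c(x, y, z)` 1-based coordinates, or (for
#'   closed-form checks) a raw feature vector of length `model$d` passed with
#'   `fs = NULL`.
#' @return The data term value (a real; negative values are possible for
#'   very concentrated models, as for any continuous log-density).
#' @export
data_term <- function(fs, model, p) {
  stopifnot(inherits(model, "gaussian_model"))
  if (is.null(fs)) return(gaussian_nll(model, as.numeric(p)))
  stopifnot(inherits(fs, "feature_stack"))
  if (length(p) == 3L)
    p <- p[1] + fs$dims[1] * ((p[2] - 1L) + fs$dims[2] * (p[3] - 1L))
  gaussian_nll(model, fs$x[p, ])
}

# ---------------------------------------------------------------------------
# Local binary patterns

#' Volume local binary pattern code at a voxel
#'
#' Thresholds P sampling points on the circle of radius R (angles 2*pi*k/P,
#' bilinear interpolation, edge replication) in the XY plane through the
#' center against the center gray value:
#' \deqn{VLBP = \sum_{k=0}^{P-1} s(g_k - g_c) 2^k,\quad s(x) = 1[x \ge 0].}
#' `L` (the z sampling interval) is part of the parameterization for the
#' three-orthogonal-plane simplification used by [lbp_top_histograms()],
#' where it sets the z radius of the XZ/YZ plane ellipses; the single-plane
#' code here does not use it.
#'
#' @param v a [volume()].
#' @param c voxel center, 1-based `c(x, y, z)`.
#' @param L z interval (kept for interface symmetry).
#' @param P number of sampling points (default 8).
#' @param R sampling radius in voxels (default 1).
#' @return Integer code in `[0, 2^P)`; constant volumes give `2^P - 1`
#'   because `s(0) = 1`.
#' @export
vlbp_code <- function(v, c, L = 2L, P = 8L, R = 1) {
  stopifnot(inherits(v, "volume"), length(c) == 3L)
  codes <- cpp_lbp_codes(as.vector(v$data), as.integer(dim(v$data)),
                         as.integer(P), R, R, 0L)
  dm <- dim(v$data)
  codes[c[1] + dm[1] * ((c[2] - 1L) + dm[2] * (c[3] - 1L))]
}

lbp_plane_codes <- function(vdata, P, R, L) {
  dm <- as.integer(dim(vdata))
  vv <- as.vector(vdata)
  list(xy = cpp_lbp_codes(vv, dm, as.integer(P), R, R, 0L),
       xz = cpp_lbp_codes(vv, dm, as.integer(P), R, L, 1L),
       yz = cpp_lbp_codes(vv, dm, as.integer(P), R, L, 2L))
}

#' LBP-TOP cumulative-histogram model
#'
#' Computes per-plane (XY, XZ, YZ) 2D LBP codes for the whole volume, then
#' the seed-region reference: the mean cumulative histogram H0 of the codes
#' pooled over the local window around each seed voxel, and the scale
#' \eqn{(\sigma_0^i)^2 =} mean squared Wasserstein distance of seed-voxel
#' histograms to H0 (floored at 1e-6). Per-voxel histograms are materialized
#' on demand ([lbp_cumhist()]) rather than stored, since a full 3 x 2^P field
#' per voxel would dwarf the volume itself.
#'
#' The full 2^P code set is used (no uniform-pattern collapsing), ordered by
#' numeric code value. For seed sets above `max_seed_sample` voxels, H0 and
#' sigma0 are estimated on a deterministic stride subsample.
#'
#' @param v a [volume()].
#' @param window odd `c(wx, wy, wz)` pooling window (default 15, 15, 7).
#' @param P,R LBP points and in-plane radius (defaults 8 and 1).
#' @param L z radius for the XZ/YZ planes (default 2).
#' @param seed_region voxel set (linear indices or logical array) supplying
#'   the reference texture.
#' @param codes optional precomputed plane codes (internal reuse).
#' @param max_seed_sample subsample cap for the reference estimate.
#' @return An `lbp_histograms` object: plane codes, `H0` (list of 3
#'   cumulative histograms), `sigma0_sq` (length 3), window, dims.
#' @export
lbp_top_histograms <- function(v, window = c(15L, 15L, 7L), P = 8L, R = 1,
                               L = 2, seed_region, codes = NULL,
                               max_seed_sample = 4000L) {
  stopifnot(inherits(v, "volume"))
  window <- as.integer(window)
  if (any(window %% 2L == 0L)) stop("window dimensions must be odd")
  dm <- dim(v$data)
  if (any(window > dm)) stop("window larger than the volume")
  seed_idx <- if (is.logical(seed_region) || is.array(seed_region))
    which(seed_region != 0) else as.integer(seed_region)
  if (length(seed_idx) < 1L) stop("seed region is empty")
  if (length(seed_idx) > max_seed_sample)
    seed_idx <- seed_idx[seq(1L, length(seed_idx),
                             length.out = max_seed_sample)]
  if (is.null(codes)) codes <- lbp_plane_codes(v$data, P, R, L)
  ncodes <- 2L^as.integer(P)
  dmi <- as.integer(dm)
  H0 <- lapply(codes, function(cd)
    cpp_mean_cumhist(cd, dmi, window[1], window[2], window[3],
                     seed_idx, ncodes))
  sigma0_sq <- mapply(function(cd, h0) {
    wd <- cpp_window_wd(cd, dmi, window[1], window[2], window[3],
                        matrix(h0, ncol = 1), seed_idx)[, 1]
    max(mean(wd^2), 1e-6)
  }, codes, H0)
  structure(list(codes = codes, H0 = H0, sigma0_sq = sigma0_sq,
                 window = window, dims = dm, P = as.integer(P)),
            class = "lbp_histograms")
}

#' Per-voxel cumulative LBP histograms
#'
#' The three per-plane cumulative histograms of codes pooled over the window
#' around voxel `p` (computed on demand).
#'
#' @param hists an `lbp_histograms` object.
#' @param p voxel: linear index or `c(x, y, z)`.
#' @return List of 3 cumulative histograms (XY, XZ, YZ).
#' @export
lbp_cumhist <- function(hists, p) {
  dm <- hists$dims
  if (length(p) == 3L)
    p <- p[1] + dm[1] * ((p[2] - 1L) + dm[2] * (p[3] - 1L))
  w <- hists$window
  lapply(hists$codes, function(cd)
    cpp_mean_cumhist(cd, as.integer(dm), w[1], w[2], w[3],
                     as.integer(p), 2L^hists$P))
}

#' L1 Wasserstein distance between cumulative histograms
#'
#' For 1D distributions the Wasserstein-1 distance equals the L1 distance
#' between CDFs: \eqn{\sum_k |H_a[k] - H_b[k]|}, in bin units.
#'
#' @param ha,hb cumulative histograms of equal length.
#' @return Non-negative scalar.
#' @export
wasserstein_l1 <- function(ha, hb) {
  if (length(ha) != length(hb))
    stop("cumulative histograms have different lengths")
  if (any(diff(ha) < -1e-9) || any(diff(hb) < -1e-9))
    stop("inputs are not non-decreasing cumulative histograms")
  sum(abs(ha - hb))
}

#' Local appearance term at a voxel
#'
#' \deqn{J_p = \sum_{i=1}^{3} WD(H_p^i, H_0^i) / (\sigma_0^i)^2,} the
#' Wasserstein distance of the voxel's windowed LBP histogram to the seed
#' reference on each orthogonal plane, scaled by the seed-region variance.
#' Zero on voxels whose windows are texturally identical to the seeds.
#'
#' @inheritParams lbp_cumhist
#' @return Non-negative scalar.
#' @export
appearance_term <- function(hists, p) {
  hp <- lbp_cumhist(hists, p)
  sum(mapply(function(h, h0) wasserstein_l1(h, h0), hp, hists$H0) /
        hists$sigma0_sq)
}

# vectorized appearance term over linear voxel indices
appearance_field <- function(hists, idx) {
  dmi <- as.integer(hists$dims)
  w <- hists$window
  out <- numeric(length(idx))
  for (i in 1:3)
    out <- out + cpp_window_wd(hists$codes[[i]], dmi, w[1], w[2], w[3],
                               matrix(hists$H0[[i]], ncol = 1),
                               as.integer(idx))[, 1] /
      hists$sigma0_sq[i]
  out
}

# both label references in one histogram pass: returns cbind(J_fg, J_bg)
appearance_field2 <- function(hfg, hbg, idx) {
  dmi <- as.integer(hfg$dims)
  w <- hfg$window
  out <- matrix(0, length(idx), 2)
  for (i in 1:3) {
    wd <- cpp_window_wd(hfg$codes[[i]], dmi, w[1], w[2], w[3],
                        cbind(hfg$H0[[i]], hbg$H0[[i]]), as.integer(idx))
    out[, 1] <- out[, 1] + wd[, 1] / hfg$sigma0_sq[i]
    out[, 2] <- out[, 2] + wd[, 2] / hbg$sigma0_sq[i]
  }
  out
}

# ---------------------------------------------------------------------------
# Spin descriptors and EMD weights

#' Spin-image-like descriptor at a voxel
#'
#' Every voxel q in the discrete ball of radius `r` around `p` contributes
#' the soft-binning kernel
#' \deqn{\exp(-(d-d_b)^2/2\sigma_d^2 - (i-i_b)^2/2\sigma_i^2)}
#' to each (distance, intensity) bin, where d = ||q - p|| in voxel units
#' mapped to [0, bins[1]) and the intensity is min-max normalized inside the
#' patch to [0, bins[2]) (a constant patch puts the intensity coordinate at
#' the center of bin 0). The descriptor is normalized to unit mass and is
#' rotation invariant because d depends only on the radius.
#'
#' @param v a [volume()].
#' @param p voxel, linear index or `c(x, y, z)`.
#' @param r patch radius in voxels (default 4).
#' @param bins `c(distance_bins, intensity_bins)`, default `c(4, 4)`.
#' @param sigma_d,sigma_i kernel scales in bin units (defaults 0.5).
#' @return `bins[1] x bins[2]` matrix (rows = distance bins), entries >= 0
#'   summing to 1.
#' @export
spin_descriptor <- function(v, p, r = 4L, bins = c(4L, 4L), sigma_d = 0.5,
                            sigma_i = 0.5) {
  stopifnot(inherits(v, "volume"))
  dm <- dim(v$data)
  if (length(p) == 3L)
    p <- p[1] + dm[1] * ((p[2] - 1L) + dm[2] * (p[3] - 1L))
  m <- cpp_spin(as.vector(v$data), as.integer(dm), as.integer(p),
                as.integer(r), as.integer(bins[1]), as.integer(bins[2]),
                sigma_d, sigma_i)
  matrix(m[1, ], nrow = bins[1])
}

# descriptors for many voxels at once: n x (bins[1]*bins[2]) matrix
spin_descriptors <- function(v, idx, r = 4L, bins = c(4L, 4L),
                             sigma_d = 0.5, sigma_i = 0.5) {
  cpp_spin(as.vector(v$data), as.integer(dim(v$data)), as.integer(idx),
           as.integer(r), as.integer(bins[1]), as.integer(bins[2]),
           sigma_d, sigma_i)
}

#' EMD boundary weight between two spin descriptors
#'
#' Earth Mover's Distance between two unit-mass descriptors under the L1
#' ground distance on the bin grid, divided by the grid diameter
#' (`(nrow-1) + (ncol-1)`, i.e. 6 for 4 x 4 descriptors) so the weight lies
#' in [0, 1]. Symmetric; 0 iff the descriptors are identical.
#'
#' @param ha,hb descriptors from [spin_descriptor()] (matrices of equal
#'   shape, entries >= 0 summing to 1).
#' @return Weight in `[0, 1]`.
#' @export
emd_weight <- function(ha, hb) {
  ha <- as.matrix(ha); hb <- as.matrix(hb)
  if (!identical(dim(ha), dim(hb)))
    stop("descriptors have different shapes")
  if (abs(sum(ha) - 1) > 1e-6 || abs(sum(hb) - 1) > 1e-6 ||
      any(ha < -1e-12) || any(hb < -1e-12))
    stop("descriptors must be non-negative with unit mass")
  dmax <- (nrow(ha) - 1) + (ncol(ha) - 1)
  cpp_emd_l1_grid(as.vector(ha), as.vector(hb), nrow(ha), ncol(ha)) / dmax
}
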