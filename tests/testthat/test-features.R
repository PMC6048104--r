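test_that("feature stack blur behaves like a normalized Gaussian kernel", {
  # constant volume: both channels constant
  fs <- feature_stack(volume(array(7, c(6, 6, 6))))
  expect_lt(max(abs(fs$x - 7)), 1e-12)   # blur of a constant is constant

  # impulse response equals a dense-convolution oracle
  v <- volume(array(0, c(9, 9, 9)))
  v$data[5, 5, 5] <- 1
  fs2 <- feature_stack(v, sigma_blur = 1)
  r <- 4L
  off <- -r:r
  k3 <- exp(-outer(outer(off^2, off^2, `+`), off^2, `+`) / 2)
  k3 <- k3 / sum(k3)
  oracle <- array(0, c(9, 9, 9))
  for (i in seq_along(off)) for (j in seq_along(off))
    for (k in seq_along(off))
      oracle[5 + off[i], 5 + off[j], 5 + off[k]] <- k3[i, j, k]
  expect_equal(array(fs2$x[, 2], c(9, 9, 9)), oracle, tolerance = 1e-12)
  expect_equal(sum(fs2$x[, 2]), 1, tolerance = 1e-6)
  expect_error(feature_stack(v, sigma_blur = 0), "positive")
})

test_that("fit_gaussian follows the 1/n convention with regularization", {
  dm <- c(4, 1, 1)
  fs <- structure(list(x = cbind(c(0, 0, 2, 2), c(0, 0, 0, 0)),
                       dims = dm, spacing = c(1, 1, 1)),
                  class = "feature_stack")
  m <- fit_gaussian(fs, 1:4)
  expect_equal(m$mu, c(1, 0))
  expect_equal(m$sigma[1, 1], 1, tolerance = 1e-5)   # MLE variance of 0,0,2,2

  # permutation invariance
  m2 <- fit_gaussian(fs, c(3, 1, 4, 2))
  expect_equal(m2$mu, m$mu)
  expect_equal(m2$sigma, m$sigma)

  # constant region: covariance is the absolute floor times identity
  fsc <- structure(list(x = cbind(rep(5, 6), rep(5, 6)),
                        dims = c(6, 1, 1), spacing = c(1, 1, 1)),
                   class = "feature_stack")
  mc <- fit_gaussian(fsc, 1:6)
  expect_equal(mc$mu, c(5, 5))
  expect_equal(mc$sigma, diag(1e-8, 2))
  expect_error(fit_gaussian(fs, 1:2), "too small")
})

test_that("data term evaluates the Gaussian NLL closed forms", {
  mdl1 <- structure(list(mu = 0, sigma = matrix(1), sigma_inv = matrix(1),
                         log_det = 0, d = 1), class = "gaussian_model")
  expect_equal(data_term(NULL, mdl1, 0), 0.5 * log(2 * pi))
  expect_equal(data_term(NULL, mdl1, 2), 0.5 * log(2 * pi) + 2)

  mdl2 <- structure(list(mu = c(1, -1), sigma = diag(2),
                         sigma_inv = diag(2), log_det = 0, d = 2),
                    class = "gaussian_model")
  for (x in list(c(0, 0), c(3, 2), c(-1, 5)))
    expect_equal(data_term(NULL, mdl2, x),
                 log(2 * pi) + 0.5 * sum((x - c(1, -1))^2))

  # D(x) - D(mu) is half the squared Mahalanobis distance
  set.seed(41)
  fs <- feature_stack(rand_volume(c(6, 6, 6)))
  m <- fit_gaussian(fs, 1:216)
  for (p in sample(216, 5)) {
    diffv <- fs$x[p, ] - m$mu
    expect_equal(data_term(fs, m, p) - data_term(NULL, m, m$mu),
                 0.5 * drop(diffv %*% m$sigma_inv %*% diffv))
  }
})

test_that("vlbp codes match Eq.-level brute force and its invariances", {
  # constant volume: s(0) = 1 on every bit
  expect_equal(vlbp_code(volume(array(3, c(7, 7, 7))), c(4, 4, 4)), 255L)

  # strictly dominant center: all bits clear
  v <- volume(array(0, c(7, 7, 7)))
  v$data[4, 4, 4] <- 10
  expect_equal(vlbp_code(v, c(4, 4, 4)), 0L)

  # independent bit-by-bit oracle with its own bilinear interpolation
  oracle_code <- function(vol, c, P = 8L, R = 1) {
    gc <- vol[c[1], c[2], c[3]]
    dm <- dim(vol)
    bil <- function(x, y, z) {
      x0 <- floor(x); y0 <- floor(y)
      fx <- x - x0; fy <- y - y0
      if (fx < 1e-9) fx <- 0
      if (fy < 1e-9) fy <- 0
      if (fx > 1 - 1e-9) { fx <- 0; x0 <- x0 + 1 }
      if (fy > 1 - 1e-9) { fy <- 0; y0 <- y0 + 1 }
      cl <- function(i, n) min(max(i, 1), n)
      acc <- 0
      for (bx in 0:1) for (by in 0:1) {
        w <- (if (bx) fx else 1 - fx) * (if (by) fy else 1 - fy)
        if (w > 0)
          acc <- acc + w * vol[cl(x0 + bx, dm[1]), cl(y0 + by, dm[2]), z]
      }
      acc
    }
    code <- 0L
    for (k in 0:(P - 1)) {
      th <- 2 * pi * k / P
      dx <- R * cos(th); dy <- R * sin(th)
      if (abs(dx) < 1e-12) dx <- 0
      if (abs(dy) < 1e-12) dy <- 0
      gp <- bil(c[1] + dx, c[2] + dy, c[3])
      if (gp - gc >= 0) code <- code + bitwShiftL(1L, k)
    }
    code
  }
  set.seed(42)
  vr <- rand_volume(c(5, 5, 5))
  for (t in 1:20) {
    c0 <- sample(2:4, 3, replace = TRUE)
    expect_identical(vlbp_code(vr, c0), oracle_code(vr$data, c0))
  }

  # gray-scale invariance: affine positive rescaling preserves codes
  v2 <- volume(3 * vr$data + 11, vr$spacing)
  for (t in 1:5) {
    c0 <- sample(2:4, 3, replace = TRUE)
    expect_identical(vlbp_code(v2, c0), vlbp_code(vr, c0))
  }
})

test_that("LBP-TOP histograms and the appearance term behave as specified", {
  # constant volume: every histogram is a point mass at code 2^P - 1
  vc <- volume(array(4, c(9, 9, 9)))
  hc <- lbp_top_histograms(vc, window = c(3, 3, 3),
                           seed_region = array(TRUE, c(9, 9, 9)))
  for (h in lbp_cumhist(hc, c(5, 5, 5))) {
    expect_equal(h[256], 1)
    expect_equal(h[255], 0)       # nothing below the all-ones code
  }
  expect_equal(appearance_term(hc, c(5, 5, 5)), 0)

  # two-texture volume: seeds on the textured left half
  set.seed(43)
  dm <- c(20, 12, 12)
  arr <- array(10, dm)
  arr[11:20, , ] <- 10 + matrix(rnorm(10 * 144), 10)  # noisy right half
  vt <- volume(arr)
  seeds <- array(FALSE, dm); seeds[2:5, 3:10, 3:10] <- TRUE
  ht <- lbp_top_histograms(vt, window = c(5, 5, 5), seed_region = seeds)
  j_left <- appearance_term(ht, c(4, 6, 6))
  j_right <- appearance_term(ht, c(17, 6, 6))
  expect_lt(j_left, j_right)
  expect_gt(j_right, 0)

  # 1x1x1 window: the per-voxel histogram is a point mass at the own code
  h1 <- lbp_top_histograms(vt, window = c(1, 1, 1), seed_region = seeds)
  p <- c(9, 6, 6)
  own <- lbp_cumhist(h1, p)
  code_xy <- h1$codes$xy[p[1] + dm[1] * ((p[2] - 1) + dm[2] * (p[3] - 1))]
  expect_equal(own[[1]], cumsum(replace(rep(0, 256), code_xy + 1, 1)))

  expect_error(lbp_top_histograms(vt, window = c(4, 5, 5),
                                  seed_region = seeds), "odd")
  expect_error(lbp_top_histograms(vt, window = c(31, 31, 31),
                                  seed_region = seeds), "larger")
})

test_that("appearance term is the per-plane Wasserstein sum over sigma0^2", {
  # two public paths must agree: appearance_term vs manual
  # wasserstein_l1(lbp_cumhist)/sigma0^2 summation
  set.seed(44)
  v <- rand_volume(c(10, 10, 10))
  seeds <- array(FALSE, c(10, 10, 10)); seeds[3:8, 3:8, 3:8] <- TRUE
  h <- lbp_top_histograms(v, window = c(3, 3, 3), seed_region = seeds)
  for (p in list(c(2, 2, 2), c(5, 5, 5), c(9, 4, 7))) {
    hp <- lbp_cumhist(h, p)
    manual <- sum(mapply(wasserstein_l1, hp, h$H0) / h$sigma0_sq)
    expect_equal(appearance_term(h, p), manual, tolerance = 1e-12)
  }

  # halving 1/sigma0^2 halves J
  h2 <- h
  h2$sigma0_sq <- 2 * h$sigma0_sq
  expect_equal(appearance_term(h2, c(5, 5, 5)),
               appearance_term(h, c(5, 5, 5)) / 2)
})

test_that("wasserstein_l1 equals analytic and LP-oracle transport", {
  expect_equal(wasserstein_l1(rep(1, 8), rep(1, 8)), 0)
  # point mass at bin 0 vs bin 3 on 8 bins: 3 bins of transport
  expect_equal(wasserstein_l1(cumsum(c(1, 0, 0, 0, 0, 0, 0, 0)),
                              cumsum(c(0, 0, 0, 1, 0, 0, 0, 0))), 3)
  expect_error(wasserstein_l1(rep(1, 4), rep(1, 5)), "length")
  expect_error(wasserstein_l1(c(1, 0.5, 1, 1), rep(1, 4)),
               "non-decreasing")

  set.seed(45)
  k <- 12
  cost <- abs(outer(0:(k - 1), 0:(k - 1), `-`))
  pairs <- lapply(1:10, function(i) list(a = rand_hist(k),
                                         b = rand_hist(k)))
  lp <- lp_transport(cost, pairs)
  for (i in seq_along(pairs))
    expect_equal(wasserstein_l1(cumsum(pairs[[i]]$a),
                                cumsum(pairs[[i]]$b)),
                 lp[i], tolerance = 1e-9)
})

test_that("spin descriptors are normalized, rotation invariant and match
           brute force", {
  # constant patch: intensity coordinate pinned to bin 0's center
  vc <- volume(array(2, c(11, 11, 11)))
  s0 <- spin_descriptor(vc, c(6, 6, 6))
  expect_equal(sum(s0), 1)
  expect_true(all(s0 >= 0))
  csum <- colSums(s0)
  expect_equal(which.max(csum), 1L)
  # the intensity marginal follows the fixed kernel at coordinate 0.5
  kern <- exp(-((0.5 - (0:3 + 0.5))^2) / (2 * 0.25))
  expect_equal(csum / sum(csum), kern / sum(kern), tolerance = 1e-12)

  # exact invariance under a 90-degree rotation about z
  set.seed(46)
  v <- rand_volume(c(13, 13, 13))
  rot <- volume(aperm(v$data[, 13:1, ], c(2, 1, 3)), v$spacing)
  s1 <- spin_descriptor(v, c(7, 7, 7))
  s2 <- spin_descriptor(rot, c(7, 7, 7))
  expect_equal(s1, s2, tolerance = 1e-12)

  # voxel-by-voxel brute-force accumulation of the soft-binning kernel
  r <- 4L
  p <- c(5, 5, 5)
  patch_idx <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  d <- sqrt(rowSums(patch_idx^2))
  keep <- d <= r
  patch_idx <- patch_idx[keep, ]; d <- d[keep]
  cl <- function(i) pmin(pmax(i, 1), 9)
  v9 <- rand_volume(c(9, 9, 9))
  vals <- v9$data[cbind(cl(p[1] + patch_idx$dx), cl(p[2] + patch_idx$dy),
                        cl(p[3] + patch_idx$dz))]
  dco <- d / r * 4
  ico <- (vals - min(vals)) / (max(vals) - min(vals)) * 4
  h <- matrix(0, 4, 4)
  for (bd in 1:4) for (bi in 1:4)
    h[bd, bi] <- sum(exp(-(dco - (bd - 0.5))^2 / (2 * 0.25) -
                           (ico - (bi - 0.5))^2 / (2 * 0.25)))
  h <- h / sum(h)
  expect_equal(spin_descriptor(v9, p), h, tolerance = 1e-12)
})

test_that("emd_weight matches the LP oracle and metric axioms", {
  ha <- matrix(0, 4, 4); ha[1, 1] <- 1
  hb <- matrix(0, 4, 4); hb[4, 4] <- 1
  expect_equal(emd_weight(ha, ha), 0)
  expect_equal(emd_weight(ha, hb), 1)   # L1 corner distance 6 / dmax 6
  expect_error(emd_weight(2 * ha, hb), "unit mass")

  set.seed(47)
  # L1 ground cost on the 4x4 grid, row index fastest
  idx <- expand.grid(r = 0:3, c = 0:3)
  cost <- abs(outer(idx$r, idx$r, `-`)) + abs(outer(idx$c, idx$c, `-`))
  pairs <- lapply(1:10, function(i)
    list(a = rand_hist(16), b = rand_hist(16)))
  lp <- lp_transport(cost, pairs)
  for (i in seq_along(pairs)) {
    A <- matrix(pairs[[i]]$a, 4); B <- matrix(pairs[[i]]$b, 4)
    expect_equal(emd_weight(A, B), lp[i] / 6, tolerance = 1e-9)
    expect_equal(emd_weight(A, B), emd_weight(B, A), tolerance = 1e-12)
  }

  # triangle inequality on sampled triples (both transport distances)
  for (t in 1:10) {
    A <- matrix(rand_hist(16), 4); B <- matrix(rand_hist(16), 4)
    C <- matrix(rand_hist(16), 4)
    expect_lte(emd_weight(A, C),
               emd_weight(A, B) + emd_weight(B, C) + 1e-12)
    ca <- cumsum(rand_hist(8)); cb <- cumsum(rand_hist(8))
    cc <- cumsum(rand_hist(8))
    expect_lte(wasserstein_l1(ca, cc),
               wasserstein_l1(ca, cb) + wasserstein_l1(cb, cc) + 1e-12)
  }
})
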