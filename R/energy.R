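# Shape-constrained multi-dimensional energy assembly, s-t min-cut and the
# iterated refinement loop.
#
# Label-cost routing (the one genuinely interpretive step of the energy):
# the per-voxel terms all "push" a label, so each is charged to the t-link
# whose cut would assign the label it argues against. The organ-label cost
# at p is alpha*D_p(fg) + beta*J_p + gamma*S_p -- a voxel texturally unlike
# the organ seeds (large J) or far outside the current shape (large S) is
# expensive to call organ. The background-label cost is alpha*D_p(bg). In
# the s-t graph the edge (s, p) is cut when p lands on the sink side, so it
# carries the background-label cost, and (p, t) carries the organ-label
# cost. Negative Gaussian log-likelihoods can make a cost negative; both
# t-links of a voxel are then shifted up together, which changes no labeling
# comparison and keeps all capacities non-negative.

#' Energy weights
#'
#' Defaults follow the reference parameterization: alpha = beta = 10,
#' gamma = 80, 5 refinement iterations; sigma1 = 0.1 scales the boundary
#' term (on min-max-normalized intensities); lambda = 10 is the regional
#' weight of the intensity-only baseline.
#'
#' @param alpha data-term weight.
#' @param beta appearance-term weight.
#' @param gamma shape-term weight.
#' @param lam balance coefficient of the intensity-only baseline.
#' @param sigma1 boundary-term scale.
#' @param iterations refinement iterations (>= 1).
#' @return An `energy_weights` list.
#' @export
energy_weights <- function(alpha = 10, beta = 10, gamma = 80, lam = 10,
                           sigma1 = 0.1, iterations = 5L) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, lam >= 0, sigma1 > 0,
            iterations >= 1)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lam = lam,
                 sigma1 = sigma1, iterations = as.integer(iterations)),
            class = "energy_weights")
}

#' Pipeline configuration
#'
#' All tunable parameters of the coarse-to-fine pipeline with their
#' reference defaults: seed thresholds phi_s = 25, phi_t = 35 (mm), LBP
#' P = 8, R = 1, L = 2 with a 15 x 15 x 7 pooling window, 4 x 4 spin
#' descriptors with sigma_d = sigma_i = 0.5, atlas-selection threshold
#' phi = 0.8.
#'
#' @param phi_s,phi_t seed thresholds (mm unless `threshold_units` says
#'   otherwise).
#' @param threshold_units `"mm"` or `"voxels"`.
#' @param sigma_blur feature-stack blur scale (voxel units).
#' @param lbp_P,lbp_R,lbp_L LBP sampling parameters.
#' @param window LBP pooling window (odd voxel dims). The reference value
#'   15 x 15 x 7 is voxel-denominated on ~0.7 x 0.7 x 2 mm clinical CT.
#' @param window_mm optional physical window size in mm; when set it
#'   overrides `window`, converted per volume to odd voxel counts. Use this
#'   on grids much coarser than clinical CT so the pooling region keeps the
#'   reference physical extent (~10.5 x 10.5 x 14 mm) instead of tripling
#'   with the voxel size.
#' @param spin_r spin patch radius (voxels).
#' @param spin_bins spin descriptor bins `c(distance, intensity)`.
#' @param sigma_d,sigma_i spin soft-binning scales.
#' @param phi atlas-selection threshold.
#' @param bg_shell_mm thickness of the exterior shell (beyond phi_t) used to
#'   fit the background model.
#' @param refit_each_iteration re-estimate the Gaussian models and the LBP
#'   references every iteration (default TRUE). With a realistically poor
#'   initialization the first models are contaminated and must adapt as
#'   the shape improves; `FALSE` freezes the first estimates, which only
#'   helps when the initialization is already near-perfect.
#' @return A `shapecut_config` list.
#' @export
shapecut_config <- function(phi_s = 25, phi_t = 35,
                            threshold_units = c("mm", "voxels"),
                            sigma_blur = 1, lbp_P = 8L, lbp_R = 1,
                            lbp_L = 2, window = c(15L, 15L, 7L),
                            window_mm = NULL,
                            spin_r = 4L, spin_bins = c(4L, 4L),
                            sigma_d = 0.5, sigma_i = 0.5, phi = 0.8,
                            bg_shell_mm = 10,
                            refit_each_iteration = TRUE) {
  structure(list(phi_s = phi_s, phi_t = phi_t,
                 threshold_units = match.arg(threshold_units),
                 sigma_blur = sigma_blur, lbp_P = as.integer(lbp_P),
                 lbp_R = lbp_R, lbp_L = lbp_L, window = as.integer(window),
                 window_mm = window_mm,
                 spin_r = as.integer(spin_r),
                 spin_bins = as.integer(spin_bins), sigma_d = sigma_d,
                 sigma_i = sigma_i, phi = phi, bg_shell_mm = bg_shell_mm,
                 refit_each_iteration = refit_each_iteration),
            class = "shapecut_config")
}

#' Exponential shape penalty at a voxel
#'
#' \deqn{S_p = 1 - \exp(-d(p, \Phi_0)/r_0)} with d forced to 0 on interior
#' voxels, so the penalty is 0 on and inside the current shape and grows
#' toward 1 with exterior distance on the scale of the enclosing radius.
#'
#' @param df a `distance_field`.
#' @param r0 enclosing-sphere radius of the current shape (mm), > 0.
#' @param p voxel, linear index or `c(x, y, z)`.
#' @return Value in `[0, 1)`.
#' @export
shape_term <- function(df, r0, p) {
  stopifnot(inherits(df, "distance_field"), r0 > 0)
  if (length(p) == 3L) {
    dm <- dim(df$dist)
    p <- p[1] + dm[1] * ((p[2] - 1L) + dm[2] * (p[3] - 1L))
  }
  d <- if (df$inside[p]) 0 else df$dist[p]
  1 - exp(-d / r0)
}

shape_term_field <- function(df, r0) {
  d <- df$dist
  d[df$inside] <- 0
  1 - exp(-d / r0)
}

#' Radius of the sphere enclosing a shape
#'
#' Maximum physical distance from a foreground voxel center to the
#' foreground centroid, floored at one voxel diagonal so degenerate
#' single-voxel shapes stay usable.
#'
#' @param shape_mask nonempty binary [label_volume()].
#' @return Radius in mm.
#' @export
enclosing_radius <- function(shape_mask) {
  stopifnot(inherits(shape_mask, "volume"))
  fg <- which(shape_mask$data > 0)
  if (length(fg) == 0L) stop("shape mask is empty")
  dm <- dim(shape_mask$data)
  co <- arrayInd(fg, dm)
  phys <- sweep(co - 1, 2, shape_mask$spacing, `*`)
  ctr <- colMeans(phys)
  r0 <- sqrt(max(rowSums(sweep(phys, 2, ctr)^2)))
  max(r0, sqrt(sum(shape_mask$spacing^2)))
}

#' Boundary capacity between two neighboring voxels
#'
#' \deqn{B_{p,q} = \exp(-\omega_{pq} ||x_p - x_q||^2 / 2\sigma_1^2) \cdot
#'   1/dist(p,q)} with \eqn{\omega_{pq}} the [emd_weight()] of the two spin
#' descriptors, the feature distance Euclidean over the 2-channel stack and
#' dist(p,q) the physical neighbor distance in mm. Identical spin
#' descriptors (omega = 0) give `1/dist(p,q)` regardless of the feature
#' difference.
#'
#' @param fs a [feature_stack()].
#' @param spins per-voxel descriptor matrix from `spin_descriptors()` (rows
#'   in x-fastest voxel order) or a list of two descriptors for p, q.
#' @param p,q linear voxel indices of a 6-neighbor pair.
#' @param sigma1 boundary scale.
#' @param spacing mm spacing triple.
#' @return Positive capacity; symmetric in (p, q).
#' @export
boundary_capacity <- function(fs, spins, p, q, sigma1, spacing) {
  stopifnot(inherits(fs, "feature_stack"))
  nb <- if (is.list(spins)) spins else
    list(matrix(spins[p, ], nrow = round(sqrt(ncol(spins)))),
         matrix(spins[q, ], nrow = round(sqrt(ncol(spins)))))
  w <- emd_weight(nb[[1]], nb[[2]])
  dm <- fs$dims
  cp <- arrayInd(p, dm)[1, ]
  cq <- arrayInd(q, dm)[1, ]
  dist_pq <- sqrt(sum(((cp - cq) * spacing)^2))
  dx2 <- sum((fs$x[p, ] - fs$x[q, ])^2)
  exp(-w * dx2 / (2 * sigma1^2)) / dist_pq
}

# 6-neighbor pairs inside the band: returns linear-index pairs and the axis
band_neighbor_pairs <- function(band, dims) {
  strides <- c(1L, dims[1], dims[1] * dims[2])
  plist <- list(); qlist <- list(); axlist <- list()
  lin <- array(seq_len(prod(dims)), dims)
  for (ax in 1:3) {
    n <- dims[ax]
    if (n < 2L) next
    idx_lo <- lapply(dims, seq_len)
    idx_lo[[ax]] <- 1:(n - 1)
    a <- lin[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]]]
    keep <- band[a] & band[a + strides[ax]]
    plist[[ax]] <- a[keep]
    qlist[[ax]] <- a[keep] + strides[ax]
    axlist[[ax]] <- rep(ax, sum(keep))
  }
  list(p = unlist(plist), q = unlist(qlist), axis = unlist(axlist))
}

#' Assemble the shape-constrained energy graph
#'
#' Builds per-node terminal capacities and 6-neighbor n-link capacities on
#' the band (see the routing note at the top of this file). Source seeds get
#' an effectively infinite source t-link (`1e6` times the largest finite
#' capacity); sink seeds lie outside the band and are represented by the
#' sink terminal itself.
#'
#' @param domain a `graph_domain`.
#' @param fs a [feature_stack()].
#' @param hists an `lbp_histograms` reference (or NULL to drop the
#'   appearance term).
#' @param spins full-volume descriptor matrix (or NULL together with
#'   `omega` to supply precomputed edge weights).
#' @param stf shape-term array from `shape_term_field()` (or NULL to drop
#'   the shape term).
#' @param fg_model,bg_model `gaussian_model`s for the organ and background.
#' @param w an [energy_weights()].
#' @param omega optional precomputed per-edge EMD weights (internal reuse).
#' @return An `energy_graph`: `tlinks` (n x 2: to-source, to-sink), `edges`
#'   (m x 2 node ids), `ncap`, `inf_cap`, `domain`, `dims`.
#' @export
assemble_energy <- function(domain, fs, hists, spins, stf, fg_model,
                            bg_model, w, omega = NULL) {
  stopifnot(inherits(domain, "graph_domain"), inherits(w, "energy_weights"))
  dims <- dim(domain$band)
  band_idx <- domain$band_idx
  n <- length(band_idx)
  node_of <- domain$node_id

  is_seed <- domain$source_seeds[band_idx]
  d_fg <- gaussian_nll_rows(fg_model, fs$x[band_idx, , drop = FALSE])
  d_bg <- gaussian_nll_rows(bg_model, fs$x[band_idx, , drop = FALSE])
  jp_fg <- jp_bg <- numeric(n)
  if (!is.null(hists) && w$beta > 0) {
    nz <- which(!is_seed)
    if (inherits(hists, "lbp_histograms")) {
      # single reference: appearance charged to the organ label only
      jp_fg[nz] <- appearance_field(hists, band_idx[nz])
    } else {
      # per-label references (the J_p(L) reading): each label pays the
      # dissimilarity to its own seed-region texture
      j2 <- appearance_field2(hists$fg, hists$bg, band_idx[nz])
      jp_fg[nz] <- j2[, 1]
      jp_bg[nz] <- j2[, 2]
    }
  }
  sp <- if (is.null(stf)) numeric(n) else stf[band_idx]

  cost_fg <- w$alpha * d_fg + w$beta * jp_fg + w$gamma * sp  # organ label
  cost_bg <- w$alpha * d_bg + w$beta * jp_bg            # background label
  shift <- pmax(0, -pmin(cost_fg, cost_bg))
  cost_fg <- cost_fg + shift
  cost_bg <- cost_bg + shift
  if (any(!is.finite(cost_fg)) || any(!is.finite(cost_bg))) {
    bad <- which(!is.finite(cost_fg) | !is.finite(cost_bg))[1]
    stop("non-finite terminal capacity at voxel ", band_idx[bad])
  }

  pr <- band_neighbor_pairs(domain$band, dims)
  m <- length(pr$p)
  if (m > 0L) {
    if (is.list(omega)) {  # per-axis full-grid weight arrays
      ov <- numeric(m)
      for (ax in 1:3) {
        sel <- pr$axis == ax
        ov[sel] <- omega[[ax]][pr$p[sel]]
      }
      omega <- ov
    }
    if (is.null(omega)) {
      edge_rows <- cbind(pr$p, pr$q)
      omega <- cpp_emd_weights(spins, edge_rows,
                               as.integer(round(sqrt(ncol(spins)))),
                               as.integer(round(sqrt(ncol(spins)))),
                               (round(sqrt(ncol(spins))) - 1) * 2)
    }
    dx2 <- rowSums((fs$x[pr$p, , drop = FALSE] -
                      fs$x[pr$q, , drop = FALSE])^2)
    ncap <- exp(-omega * dx2 / (2 * w$sigma1^2)) /
      domain$spacing[pr$axis]
    if (any(!is.finite(ncap)))
      stop("non-finite n-link capacity at voxel ",
           pr$p[which(!is.finite(ncap))[1]])
  } else {
    ncap <- numeric(0)
  }

  inf_cap <- 1e6 * max(c(cost_fg, cost_bg, ncap, 1))
  tlinks <- cbind(to_source = cost_bg, to_sink = cost_fg)
  tlinks[is_seed, 1] <- inf_cap
  tlinks[is_seed, 2] <- 0

  structure(list(n_nodes = n,
                 tlinks = tlinks,
                 edges = cbind(node_of[pr$p], node_of[pr$q]),
                 ncap = ncap, inf_cap = inf_cap,
                 domain = domain, dims = dims),
            class = "energy_graph")
}

#' Solve the energy graph by s-t min-cut
#'
#' Exact max-flow/min-cut (igraph's implementation). The returned
#' `cut_value` equals the energy of the returned labeling, i.e. the sum of
#' the t-link costs of the assigned labels plus the n-link capacities of cut
#' neighbor pairs (see [energy_of_labeling()]).
#'
#' @param g an `energy_graph` (from [assemble_energy()] or built directly
#'   for small instances).
#' @param solver `"bk"` (Boykov-Kolmogorov, the default; the usual choice
#'   for vision grid graphs) or `"igraph"` (igraph's max-flow), two fully
#'   independent exact routes that the test suite cross-checks.
#' @return List with `labels` (0/1 per node, 1 = source/organ side),
#'   `cut_value`, and -- when the graph carries a `graph_domain` --
#'   `labeling`, a [label_volume()] over the full grid (background outside
#'   the band).
#' @export
min_cut <- function(g, solver = c("bk", "igraph")) {
  stopifnot(inherits(g, "energy_graph"))
  solver <- match.arg(solver)
  n <- g$n_nodes
  if (solver == "bk") {
    edges <- g$edges
    if (is.null(edges) || nrow(edges) == 0L)
      edges <- matrix(integer(0), ncol = 2)
    bk <- cpp_bk_mincut(g$tlinks, edges, as.numeric(g$ncap))
    labels <- bk$labels
    value <- bk$value
  } else {
    s <- n + 1L
    t <- n + 2L
    src_e <- which(g$tlinks[, 1] > 0)
    snk_e <- which(g$tlinks[, 2] > 0)
    el <- rbind(cbind(rep(s, length(src_e)), src_e),
                cbind(snk_e, rep(t, length(snk_e))),
                g$edges)
    caps <- c(g$tlinks[src_e, 1], g$tlinks[snk_e, 2], g$ncap)
    keep <- caps > 0
    gr <- igraph::graph_from_edgelist(el[keep, , drop = FALSE],
                                      directed = FALSE)
    if (igraph::vcount(gr) < t)
      gr <- igraph::add_vertices(gr, t - igraph::vcount(gr))
    mf <- igraph::max_flow(gr, source = s, target = t,
                           capacity = caps[keep])
    labels <- integer(n)
    p1 <- as.integer(mf$partition1)
    if (s %in% p1) labels[p1[p1 <= n]] <- 1L
    else {
      p2 <- as.integer(mf$partition2)
      labels[p2[p2 <= n]] <- 1L
    }
    value <- mf$value
  }
  out <- list(labels = labels, cut_value = value)
  if (!is.null(g$domain)) {
    arr <- array(0L, g$dims)
    arr[g$domain$band_idx[labels == 1L]] <- 1L
    out$labeling <- label_volume(arr, g$domain$spacing)
  }
  out
}

#' Energy of an explicit labeling on an energy graph
#'
#' Independent re-summation used to audit [min_cut()]: labeled-1 nodes pay
#' their to-sink cost, labeled-0 nodes their to-source cost, and every
#' n-link with differing endpoint labels pays its capacity.
#'
#' @param g an `energy_graph`.
#' @param labels 0/1 vector over nodes.
#' @return Total energy.
#' @export
energy_of_labeling <- function(g, labels) {
  stopifnot(length(labels) == g$n_nodes)
  tsum <- sum(ifelse(labels == 1L, g$tlinks[, 2], g$tlinks[, 1]))
  if (length(g$ncap))
    tsum <- tsum + sum(g$ncap[labels[g$edges[, 1]] != labels[g$edges[, 2]]])
  tsum
}

# 6-connected morphological closing (radius 1 voxel): seals voxel-wide
# tunnels so the subsequent cavity fill can do its job; run after
# largest-component selection so discarded structures cannot re-attach
close6 <- function(mask) {
  dm <- dim(mask)
  shift_or <- function(m, combine) {
    out <- m
    for (ax in 1:3)
      for (by in c(1L, -1L)) {
        n <- dm[ax]
        idx <- pmin(pmax(seq_len(n) + by, 1L), n)
        sl <- switch(ax, m[idx, , , drop = FALSE],
                     m[, idx, , drop = FALSE], m[, , idx, drop = FALSE])
        out <- combine(out, sl)
      }
    out
  }
  ero_dil <- shift_or(mask, `|`)       # dilate
  shift_or(ero_dil, `&`)               # erode
}

# shape update between iterations: largest 6-connected component,
# radius-1 closing, enclosed-cavity fill
shape_update <- function(mask, dm) {
  lc <- array(cpp_largest_component_fill(as.vector(mask), as.integer(dm)),
              dm)
  cl <- close6(lc)
  array(cpp_largest_component_fill(as.vector(cl), as.integer(dm)), dm)
}

# effective pooling window in voxels for a given spacing
effective_window <- function(cfg, spacing) {
  if (is.null(cfg$window_mm)) return(cfg$window)
  pmax(2L * as.integer(floor(cfg$window_mm / spacing / 2)) + 1L, 3L)
}

# model-fitting regions for one iteration; degenerate shapes (hard seeds
# scarcer than a stable covariance needs) fall back to the deepest
# interior voxels
fit_regions <- function(df, domain, cfg) {
  fg <- which(domain$source_seeds)
  if (length(fg) < 50L) {
    interior <- which(df$inside)
    fg <- interior[order(df$dist[interior], decreasing = TRUE)]
    fg <- fg[seq_len(min(50L, length(fg)))]
  }
  shell <- !df$inside & df$dist > domain$phi_t &
    df$dist <= domain$phi_t + cfg$bg_shell_mm
  if (sum(shell) < 8L) shell <- !df$inside & df$dist > domain$phi_t
  if (sum(shell) < 8L) shell <- !df$inside & !domain$band
  list(fg = fg, bg = which(shell))
}

#' Iterated shape-constrained segmentation
#'
#' Runs the refinement loop: per iteration (1) distance field and graph
#' domain from the current shape, (2) Gaussian models and LBP reference
#' from the current seed regions, (3) energy assembly, (4) min-cut, (5)
#' shape update to the largest 6-connected component of the organ side with
#' enclosed cavities filled. An empty cut reverts to the previous shape and
#' stops early (flagged in the diagnostics).
#'
#' @param target the intensity [volume()] (internally min-max normalized to
#'   `[0, 1]`, on which the reference sigma1 = 0.1 is calibrated).
#' @param init_mask nonempty binary [label_volume()] (e.g. from
#'   [fuse_atlases()]).
#' @param w an [energy_weights()].
#' @param cfg a [shapecut_config()].
#' @param verbose print per-iteration progress.
#' @return List with `mask` (final [label_volume()]) and `diagnostics`
#'   (data.frame: iteration, energy, dice vs previous shape, seed/band
#'   counts, reverted flag).
#' @export
segment_volume <- function(target, init_mask, w = energy_weights(),
                           cfg = shapecut_config(), verbose = FALSE) {
  stopifnot(inherits(target, "volume"), inherits(init_mask, "volume"))
  assert_same_grid(target, init_mask, "init mask")
  if (!any(init_mask$data > 0)) stop("initial mask is empty")
  dm <- dim(target$data)

  rng <- range(target$data)
  if (diff(rng) == 0) stop("constant target volume cannot be segmented")
  vn <- volume((target$data - rng[1]) / diff(rng), target$spacing,
               target$origin)
  fs <- feature_stack(vn, cfg$sigma_blur)
  codes <- lbp_plane_codes(vn$data, cfg$lbp_P, cfg$lbp_R, cfg$lbp_L)
  spins <- spin_descriptors(vn, seq_len(prod(dm)), cfg$spin_r,
                            cfg$spin_bins, cfg$sigma_d, cfg$sigma_i)
  # EMD weights depend only on the (fixed) volume: compute once per
  # neighbor axis over the whole grid and reuse across iterations
  all_pairs <- band_neighbor_pairs(array(TRUE, dm), dm)
  omega_all <- cpp_emd_weights(spins, cbind(all_pairs$p, all_pairs$q),
                               cfg$spin_bins[1], cfg$spin_bins[2],
                               sum(cfg$spin_bins) - 2)
  omega_arrays <- lapply(1:3, function(ax) {
    v <- numeric(prod(dm))
    sel <- all_pairs$axis == ax
    v[all_pairs$p[sel]] <- omega_all[sel]
    v
  })

  cur <- init_mask$data > 0
  diag_rows <- list()
  hists <- NULL
  fg_model <- bg_model <- NULL
  for (it in seq_len(w$iterations)) {
    mask_lv <- label_volume(cur * 1L, target$spacing, target$origin)
    df <- unsigned_distance_field(mask_lv)
    domain <- build_graph_domain(df, cfg$phi_s, cfg$phi_t,
                                 cfg$threshold_units)
    if (cfg$refit_each_iteration || is.null(fg_model)) {
      reg <- fit_regions(df, domain, cfg)
      fg_model <- fit_gaussian(fs, reg$fg)
      bg_model <- fit_gaussian(fs, reg$bg)
      win <- effective_window(cfg, target$spacing)
      hists <- list(
        fg = lbp_top_histograms(vn, win, cfg$lbp_P, cfg$lbp_R,
                                cfg$lbp_L, seed_region = reg$fg,
                                codes = codes),
        bg = lbp_top_histograms(vn, win, cfg$lbp_P, cfg$lbp_R,
                                cfg$lbp_L, seed_region = reg$bg,
                                codes = codes))
    }
    stf <- shape_term_field(df, enclosing_radius(mask_lv))
    g <- assemble_energy(domain, fs, hists, NULL, stf, fg_model, bg_model,
                         w, omega = omega_arrays)
    mc <- min_cut(g)
    new_mask <- mc$labeling$data > 0
    reverted <- FALSE
    if (!any(new_mask)) {
      reverted <- TRUE
      new_mask <- cur
    } else {
      new_mask <- shape_update(new_mask, dm)
    }
    d_prev <- 2 * sum(new_mask & cur) / (sum(new_mask) + sum(cur))
    diag_rows[[it]] <- data.frame(iteration = it, energy = mc$cut_value,
                                  dice_prev = d_prev,
                                  n_source = sum(domain$source_seeds),
                                  n_band = length(domain$band_idx),
                                  reverted = reverted)
    if (verbose)
      message(sprintf("iter %d: energy %.4g, dice-prev %.4f, seeds %d, band %d",
                      it, mc$cut_value, d_prev,
                      sum(domain$source_seeds), length(domain$band_idx)))
    converged <- identical(new_mask, cur)
    cur <- new_mask
    if (reverted) break
    if (converged) break  # fixed point: further iterations are no-ops
  }
  list(mask = label_volume(cur * 1L, target$spacing, target$origin),
       diagnostics = do.call(rbind, diag_rows))
}

#' Intensity-only graph-cut baseline
#'
#' The classical formulation: regional term from 1D intensity Gaussian
#' negative log-likelihoods weighted by `lam`, boundary term with
#' omega = 1 on 1D intensity features, seeds and band from the same
#' automatic construction, a single cut and no shape or appearance terms.
#'
#' @inheritParams segment_volume
#' @param lam regional balance coefficient (default 10).
#' @return The segmented [label_volume()].
#' @export
segment_intensity_only <- function(target, init_mask, lam = 10,
                                   cfg = shapecut_config()) {
  stopifnot(inherits(target, "volume"), inherits(init_mask, "volume"))
  assert_same_grid(target, init_mask, "init mask")
  dm <- dim(target$data)
  rng <- range(target$data)
  if (diff(rng) == 0) stop("constant target volume cannot be segmented")
  vn <- (target$data - rng[1]) / diff(rng)
  fs1 <- structure(list(x = matrix(as.vector(vn), ncol = 1),
                        dims = dm, spacing = target$spacing),
                   class = "feature_stack")
  mask_lv <- label_volume((init_mask$data > 0) * 1L, target$spacing,
                          target$origin)
  df <- unsigned_distance_field(mask_lv)
  domain <- build_graph_domain(df, cfg$phi_s, cfg$phi_t,
                               cfg$threshold_units)
  reg <- fit_regions(df, domain, cfg)
  fg_model <- fit_gaussian(fs1, reg$fg)
  bg_model <- fit_gaussian(fs1, reg$bg)
  w <- energy_weights(alpha = lam, beta = 0, gamma = 0, lam = lam,
                      sigma1 = 0.1, iterations = 1L)
  pr <- band_neighbor_pairs(domain$band, dm)
  g <- assemble_energy(domain, fs1, NULL, NULL, NULL, fg_model, bg_model,
                       w, omega = rep(1, length(pr$p)))
  mc <- min_cut(g)
  mc$labeling
}
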