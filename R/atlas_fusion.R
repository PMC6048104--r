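# Multi-atlas initialization: NMI-based atlas selection and weighted
# majority voting over pre-warped atlas label maps.
#
# Registration is deliberately external. The expected preprocessing for real
# data is an affine stage followed by a B-spline free-form deformation (for
# example with elastix: `elastix -f target.nii.gz -m atlasK.nii.gz -p
# affine.txt -p bspline.txt`, then `transformix` applied to the atlas label
# with nearest-neighbour interpolation). This module's contract starts at
# atlas intensity/label pairs already resampled onto the target grid.

#' Normalized mutual information between two volumes over a region
#'
#' NMI is fixed to the registration-literature form
#' \deqn{NMI(a, b) = (H(a) + H(b)) / H(a, b)} computed from a joint histogram
#' of the two intensity samples restricted to `region > 0`. Each marginal is
#' binned linearly over its own range inside the region. The value is >= 1,
#' and equals 2 when `a == b` (non-constant) over the region.
#'
#' @param a,b [volume()] objects on the same grid.
#' @param region a [label_volume()] (or logical/numeric array) marking the
#'   voxels to compare; must contain at least two voxels.
#' @param bins number of histogram bins per marginal (default 32).
#' @return NMI as a scalar.
#' @export
nmi <- function(a, b, region, bins = 32L) {
  stopifnot(inherits(a, "volume"), inherits(b, "volume"))
  assert_same_grid(a, b, "second image")
  rdat <- if (inherits(region, "volume")) region$data else region
  sel <- which(rdat > 0)
  if (length(sel) < 2L)
    stop("region must contain at least two voxels")
  av <- a$data[sel]
  bv <- b$data[sel]
  if (max(av) == min(av) || max(bv) == min(bv))
    stop("constant image inside region: entropies are zero, NMI undefined")
  cut_idx <- function(x) {
    i <- floor((x - min(x)) / (max(x) - min(x)) * bins) + 1L
    pmin(i, bins)
  }
  joint <- table(factor(cut_idx(av), levels = seq_len(bins)),
                 factor(cut_idx(bv), levels = seq_len(bins)))
  p <- joint / sum(joint)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  (ent(rowSums(p)) + ent(colSums(p))) / ent(as.vector(p))
}

#' Score pre-warped atlases against a target and select a subset
#'
#' Each atlas intensity image is compared to the target by [nmi()] over a
#' region Omega, and ratios \eqn{r_i = NMI_i / max_j NMI_j} are formed. An
#' atlas is selected when \eqn{r_i \ge \varphi}; the selection weight is
#' \eqn{\omega_i = r_i}. The argmax atlas always has \eqn{r = 1} and is
#' always selected.
#'
#' Omega cannot be the (unknown) target organ, so by default it is the union
#' of all warped atlas labels dilated by `dilate_mm` (policy
#' `"atlas_union_dilated"`); `"whole_image"` uses every voxel.
#'
#' @param target the target [volume()].
#' @param atlases list of `list(intensity = volume, label = label_volume)`
#'   pairs, all on the target grid.
#' @param phi selection threshold in (0, 1], default 0.8.
#' @param region_policy `"atlas_union_dilated"` or `"whole_image"`.
#' @param dilate_mm dilation radius for the atlas-union region, in mm.
#' @param bins histogram bins passed to [nmi()].
#' @return A data.frame with one row per atlas: `nmi`, `r`, `selected`,
#'   `weight` (`r` for selected atlases, `NA` otherwise).
#' @export
score_and_select <- function(target, atlases, phi = 0.8,
                             region_policy = c("atlas_union_dilated",
                                               "whole_image"),
                             dilate_mm = 5, bins = 32L) {
  region_policy <- match.arg(region_policy)
  stopifnot(length(atlases) >= 1L, phi > 0, phi <= 1)
  for (i in seq_along(atlases)) {
    assert_same_grid(target, atlases[[i]]$intensity,
                     sprintf("atlas %d intensity", i))
    assert_same_grid(target, atlases[[i]]$label, sprintf("atlas %d label", i))
  }
  dm <- dim(target$data)
  if (region_policy == "whole_image") {
    region <- array(TRUE, dm)
  } else {
    uni <- Reduce(`|`, lapply(atlases, function(a) a$label$data > 0))
    if (!any(uni)) stop("all warped atlas labels are empty")
    d2 <- cpp_edt_sq(as.vector(uni), as.integer(dm), target$spacing)
    region <- array(d2 <= dilate_mm^2, dm)
  }
  nmis <- vapply(seq_along(atlases), function(i) {
    tryCatch(nmi(target, atlases[[i]]$intensity, region, bins),
             error = function(e)
               stop(sprintf("atlas %d: %s", i, conditionMessage(e)),
                    call. = FALSE))
  }, 0)
  r <- nmis / max(nmis)
  selected <- r >= phi
  selected[which.max(r)] <- TRUE  # the argmax is always selected
  data.frame(nmi = nmis, r = r, selected = selected,
             weight = ifelse(selected, r, NA_real_))
}

#' Weighted majority voting over label volumes
#'
#' Per voxel p the fused label is
#' \deqn{L(p) = \arg\max_c \sum_i \omega_i \, \delta[c, L_i(p)] /
#'   \sum_i \omega_i,} the weighted vote over the candidate labels. Ties are
#' broken toward the smaller class index, so background wins an exact tie.
#'
#' @param labels list of [label_volume()] on one grid.
#' @param weights positive per-atlas weights, same length as `labels`.
#' @return The fused [label_volume()].
#' @export
weighted_majority_vote <- function(labels, weights) {
  stopifnot(length(labels) >= 1L, length(weights) == length(labels))
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("all weights must be positive")
  ref <- labels[[1]]
  for (i in seq_along(labels))
    assert_same_grid(ref, labels[[i]], sprintf("label volume %d", i))
  classes <- sort(unique(unlist(lapply(labels,
                                       function(l) l$label_set %||%
                                         unique(as.vector(l$data))))))
  dm <- dim(ref$data)
  best_score <- array(-Inf, dm)
  best_class <- array(classes[1], dm)
  for (cl in classes) {  # ascending: strict > keeps the smaller class on ties
    sc <- array(0, dm)
    for (i in seq_along(labels))
      sc <- sc + weights[i] * (labels[[i]]$data == cl)
    upd <- sc > best_score
    best_score[upd] <- sc[upd]
    best_class[upd] <- cl
  }
  label_volume(best_class, ref$spacing, ref$origin)
}

#' Fuse a set of pre-warped atlases into an initial segmentation
#'
#' Convenience wrapper: [score_and_select()] then [weighted_majority_vote()]
#' restricted to the selected atlases.
#'
#' @inheritParams score_and_select
#' @return `list(mask = label_volume, scores = data.frame)`.
#' @export
fuse_atlases <- function(target, atlases, phi = 0.8,
                         region_policy = "atlas_union_dilated",
                         dilate_mm = 5, bins = 32L) {
  scores <- score_and_select(target, atlases, phi, region_policy,
                             dilate_mm, bins)
  keep <- which(scores$selected)
  mask <- weighted_majority_vote(lapply(atlases[keep],
                                        function(a) a$label),
                                 scores$weight[keep])
  # initialization cleanup: a single closed shape (largest component,
  # sealed and cavity-filled), as the downstream distance field expects
  if (any(mask$data > 0)) {
    dm <- dim(mask$data)
    mask <- label_volume(shape_update(mask$data > 0, dm) * 1L,
                         mask$spacing, mask$origin)
  }
  list(mask = mask, scores = scores)
}
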