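# Evaluation measures: Dice and the MICCAI'07 volume/surface measures
# (VOE, SRVD, ASD, RMSD, MSD), plus a per-voxel surface distance map.

#' Dice coefficient
#'
#' \deqn{Dice = 2|V_{seg} \cap V_{ref}| / (|V_{seg}| + |V_{ref}|)} on voxel
#' counts. Two empty masks are defined to agree perfectly (Dice 1); empty
#' vs nonempty gives 0.
#'
#' @param seg,ref binary [label_volume()]s on the same grid.
#' @return Value in `[0, 1]`.
#' @export
dice <- function(seg, ref) {
  stopifnot(inherits(seg, "volume"), inherits(ref, "volume"))
  assert_same_grid(seg, ref, "reference")
  a <- seg$data > 0
  b <- ref$data > 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Volumetric overlap error and signed relative volume difference
#'
#' \deqn{VOE = 100 (1 - |A \cap B| / |A \cup B|)\%,\qquad
#'   SRVD = 100 (|A| - |B|) / |B|\%} with A the segmentation and B the
#' reference; over-segmentation gives positive SRVD.
#'
#' @inheritParams dice
#' @return `c(voe_pct, srvd_pct)`.
#' @export
volume_measures <- function(seg, ref) {
  stopifnot(inherits(seg, "volume"), inherits(ref, "volume"))
  assert_same_grid(seg, ref, "reference")
  a <- seg$data > 0
  b <- ref$data > 0
  if (!any(b)) stop("reference mask is empty")
  c(voe_pct = 100 * (1 - sum(a & b) / sum(a | b)),
    srvd_pct = 100 * (sum(a) - sum(b)) / sum(b))
}

#' Symmetric surface distances
#'
#' Border voxels (foreground voxels with a background 6-neighbor) of both
#' masks are collected; every border voxel of one mask contributes its
#' physical distance (mm, voxel-center to voxel-center) to the nearest
#' border voxel of the other mask, in both directions. ASD is the mean,
#' RMSD the root mean square and MSD the maximum of the pooled distances.
#' `distance_map` assigns each seg-border voxel its distance to the
#' reference border (NA elsewhere) for distance renderings.
#'
#' @inheritParams dice
#' @return List with `asd_mm`, `rmsd_mm`, `msd_mm`, `distance_map` (3D
#'   array).
#' @export
surface_measures <- function(seg, ref) {
  stopifnot(inherits(seg, "volume"), inherits(ref, "volume"))
  assert_same_grid(seg, ref, "reference")
  a <- seg$data > 0
  b <- ref$data > 0
  if (!any(a) || !any(b)) stop("surface distances need two nonempty masks")
  dm <- dim(a)
  sa <- surface_voxels(a)
  sb <- surface_voxels(b)
  spacing <- seg$spacing
  d_to_b <- sqrt(cpp_edt_sq(as.vector(sb), as.integer(dm), spacing))
  d_to_a <- sqrt(cpp_edt_sq(as.vector(sa), as.integer(dm), spacing))
  da <- d_to_b[which(sa)]   # seg border -> ref border
  db <- d_to_a[which(sb)]   # ref border -> seg border
  pooled <- c(da, db)
  dmap <- array(NA_real_, dm)
  dmap[which(sa)] <- da
  list(asd_mm = mean(pooled), rmsd_mm = sqrt(mean(pooled^2)),
       msd_mm = max(pooled), distance_map = dmap)
}

#' Full evaluation report
#'
#' Dice, VOE, SRVD, ASD, RMSD and MSD in one list, keys matching the
#' JSON report of the command-line `evaluate` subcommand.
#'
#' @inheritParams dice
#' @return List with `dice`, `voe_pct`, `srvd_pct`, `asd_mm`, `rmsd_mm`,
#'   `msd_mm`.
#' @export
evaluate_segmentation <- function(seg, ref) {
  vm <- volume_measures(seg, ref)
  sm <- surface_measures(seg, ref)
  list(dice = dice(seg, ref), voe_pct = unname(vm["voe_pct"]),
       srvd_pct = unname(vm["srvd_pct"]), asd_mm = sm$asd_mm,
       rmsd_mm = sm$rmsd_mm, msd_mm = sm$msd_mm)
}
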