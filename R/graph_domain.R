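# Automatic graph construction: unsigned distance field around the current
# shape, hard source/sink seed selection and the banded graph domain.

#' Unsigned Euclidean distance field of a binary shape
#'
#' The shape surface is the set of foreground voxels having at least one
#' background 6-neighbor. Every voxel's distance is the minimum physical
#' (anisotropic, mm) Euclidean distance to a surface voxel; it is 0 exactly
#' on the surface and carries no sign -- the interior flag is kept as a
#' separate channel.
#'
#' @param shape_mask binary [label_volume()] with nonempty foreground and
#'   background.
#' @return A `distance_field`: list with `dist` (3D array, mm), `inside`
#'   (logical 3D array), `surface` (logical 3D array), `spacing`.
#' @export
unsigned_distance_field <- function(shape_mask) {
  stopifnot(inherits(shape_mask, "volume"))
  fg <- shape_mask$data > 0
  if (!any(fg)) stop("shape mask is empty: no surface exists")
  if (all(fg)) stop("shape mask fills the volume: no surface exists")
  dm <- dim(fg)
  surf <- surface_voxels(fg)
  d2 <- cpp_edt_sq(as.vector(surf), as.integer(dm), shape_mask$spacing)
  structure(list(dist = array(sqrt(d2), dm), inside = fg,
                 surface = surf, spacing = shape_mask$spacing),
            class = "distance_field")
}

# foreground voxels with >= 1 background 6-neighbor (volume border counts as
# foreground continuation, i.e. a face on the border is not a surface unless
# a background neighbor exists inside the volume)
surface_voxels <- function(fg) {
  dm <- dim(fg)
  shift_bg <- function(ax, by) {
    out <- array(FALSE, dm)
    idx_src <- lapply(dm, seq_len)
    idx_dst <- idx_src
    n <- dm[ax]
    if (by == 1L) { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    else          { idx_dst[[ax]] <- 2:n;       idx_src[[ax]] <- 1:(n - 1) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      !fg[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  has_bg <- array(FALSE, dm)
  for (ax in 1:3)
    for (by in c(1L, -1L))
      has_bg <- has_bg | shift_bg(ax, by)
  fg & has_bg
}

#' Derive source/sink seeds and the banded graph domain
#'
#' Source seeds are interior voxels deeper than `phi_s`; sink seeds are
#' exterior voxels farther than `phi_t` (they are represented only by the
#' sink terminal and are not graph nodes). The graph band covers the whole
#' interior plus the exterior shell with distance `< phi_t`. Node ids
#' enumerate band voxels in x-fastest lexicographic order.
#'
#' Thresholds are interpreted in mm by default; `units = "voxels"` rescales
#' them by the geometric-mean voxel size for spacing-free experiments.
#'
#' @param df a `distance_field` from [unsigned_distance_field()].
#' @param phi_s,phi_t positive seed thresholds (defaults 25 and 35).
#' @param units `"mm"` (default) or `"voxels"`.
#' @return A `graph_domain`: list with logical arrays `band`,
#'   `source_seeds`, `sink_seeds`, integer array `node_id` (NA outside the
#'   band), `band_idx` (linear voxel indices of nodes in order), and the
#'   thresholds used.
#' @export
build_graph_domain <- function(df, phi_s = 25, phi_t = 35,
                               units = c("mm", "voxels")) {
  stopifnot(inherits(df, "distance_field"), phi_s > 0, phi_t > 0)
  units <- match.arg(units)
  if (units == "voxels") {
    vox <- prod(df$spacing)^(1 / 3)
    phi_s <- phi_s * vox
    phi_t <- phi_t * vox
  }
  src <- df$inside & df$dist > phi_s
  snk <- !df$inside & df$dist > phi_t
  band <- df$inside | (!df$inside & df$dist < phi_t)
  if (!any(band)) stop("graph band is empty")
  if (!any(src)) {
    # shape thinner than phi_s everywhere: fall back to the deepest core
    # (argmax set widened by one voxel diagonal so the anchor is not a
    # single voxel)
    warning("no interior voxel deeper than phi_s; ",
            "using the distance-field argmax core as source seeds")
    mx <- max(df$dist[df$inside])
    src <- df$inside & df$dist >= mx - sqrt(sum(df$spacing^2))
  }
  dm <- dim(df$dist)
  band_idx <- which(band)
  node_id <- array(NA_integer_, dm)
  node_id[band_idx] <- seq_along(band_idx)
  structure(list(band = band, source_seeds = src, sink_seeds = snk,
                 node_id = node_id, band_idx = band_idx,
                 phi_s = phi_s, phi_t = phi_t, spacing = df$spacing),
            class = "graph_domain")
}
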