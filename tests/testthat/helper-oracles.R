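# Shared fixtures and independent oracles (built in code, no stored data).

# ---- random fixtures -------------------------------------------------------

rand_mask <- function(dims, p = 0.25) {
  m <- array(stats::runif(prod(dims)) < p, dims)
  m[ceiling(dims[1] / 2), ceiling(dims[2] / 2), ceiling(dims[3] / 2)] <- TRUE
  m
}

rand_volume <- function(dims, spacing = c(1, 1, 1)) {
  volume(array(stats::rnorm(prod(dims)), dims), spacing)
}

# random energy graph over n nodes; optionally with hard seeds
rand_energy_graph <- function(n, m, seeds = TRUE) {
  tl <- cbind(stats::runif(n, 0, 3), stats::runif(n, 0, 3))
  if (seeds && n >= 2) {
    tl[1, ] <- c(1e7, 0)
    tl[2, ] <- c(0, 1e7)
  }
  ed <- if (m > 0) t(replicate(m, sample(n, 2))) else
    matrix(integer(0), ncol = 2)
  structure(list(n_nodes = n, tlinks = tl, edges = ed,
                 ncap = stats::runif(m, 0, 2), inf_cap = 1e7,
                 domain = NULL, dims = NULL),
            class = "energy_graph")
}

# ---- independent oracles ---------------------------------------------------

# exhaustive minimum over all 2^n labelings
enum_min_energy <- function(g) {
  n <- g$n_nodes
  best <- Inf
  for (b in 0:(2^n - 1)) {
    lab <- as.integer(intToBits(b))[1:n]
    best <- min(best, energy_of_labeling(g, lab))
  }
  best
}

# all-pairs physical distance from every voxel to the nearest surface voxel
brute_surface_distance <- function(surface, dims, spacing) {
  co <- arrayInd(which(surface), dims)
  cop <- sweep(co - 1, 2, spacing, `*`)
  all_idx <- arrayInd(seq_len(prod(dims)), dims)
  allp <- sweep(all_idx - 1, 2, spacing, `*`)
  apply(allp, 1, function(p) sqrt(min(colSums((t(cop) - p)^2))))
}

# linear-program transport oracle via scipy (pre-installed python)
lp_transport <- function(cost, pairs) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(list(cost = cost, pairs = pairs), fin,
                       digits = NA, auto_unbox = FALSE)
  status <- system2("python", c(test_path("lp_oracle.py"), fin, fout),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout))
    stop("LP oracle failed: ", paste(status, collapse = "\n"))
  unlist(jsonlite::read_json(fout))
}

# normalized random histogram
rand_hist <- function(k) {
  h <- stats::rgamma(k, 1)
  h / sum(h)
}

# ---- cached heavy pipeline results for the acceptance criteria -------------

.acceptance_cache <- new.env(parent = emptyenv())

# the phantom-scale experiment: fuse + refine every standard-suite case and
# the case-1 intensity-only baseline (one computation, reused by several
# acceptance tests). Master seed 17 fixed ahead of evaluation.
acceptance_results <- function() {
  if (!is.null(.acceptance_cache$res)) return(.acceptance_cache$res)
  cfg <- shapecut_config(window_mm = c(10.5, 10.5, 14))
  suite <- standard_suite(17L)
  cases <- lapply(seq_along(suite), function(i) {
    ca <- suite[[i]]
    fu <- fuse_atlases(ca$image, ca$atlases)
    # the deep-seed fallback warning is expected mid-refinement on thin
    # intermediate shapes; it has its own dedicated test
    seg <- suppressWarnings(segment_volume(ca$image, fu$mask, cfg = cfg))
    out <- list(case = ca, fused = fu,
                init_eval = evaluate_segmentation(fu$mask, ca$truth),
                final = seg,
                final_eval = evaluate_segmentation(seg$mask, ca$truth))
    if (i == 1) {
      base <- segment_intensity_only(ca$image, fu$mask)
      out$baseline_dice <- dice(base, ca$truth)
    }
    out
  })
  .acceptance_cache$res <- cases
  cases
}
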