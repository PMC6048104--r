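# small spec for fast unit checks (full-size cases live in the acceptance
# suite)
small_spec <- function(seed = 5L, ...) {
  phantom_spec(shape = rep(32L, 3), spacing = c(3, 3, 3),
               organ = list(center = c(16, 15, 16), radii = c(11, 9, 8),
                            lobe_center = NULL, lobe_radii = NULL),
               neighbor = list(shape = "ellipsoid", center = c(16, 28, 16),
                               radii = c(6, 3, 5), delta = 0),
               n_clutter = 2L, seed = seed, ...)
}

test_that("generation is deterministic given the spec", {
  a <- generate_phantom(small_spec())
  b <- generate_phantom(small_spec())
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$data, b$truth$data)
  for (k in seq_along(a$atlases)) {
    expect_identical(a$atlases[[k]]$intensity$data,
                     b$atlases[[k]]$intensity$data)
    expect_identical(a$atlases[[k]]$label$data, b$atlases[[k]]$label$data)
  }
  # and a different seed changes the noise realization, not the geometry
  c2 <- generate_phantom(small_spec(seed = 6L))
  expect_identical(c2$truth$data, a$truth$data)
  expect_false(identical(c2$image$data, a$image$data))
})

test_that("the equal-intensity regime is exact when noise is disabled", {
  sp <- small_spec(noise_sd = 0, texture = 0, bias_sd = 0)
  sp$n_clutter <- 0L
  ca <- generate_phantom(sp)
  nb <- shapecut:::neighbor_mask(sp)
  expect_gt(sum(nb), 0)
  organ_vals <- unique(ca$image$data[ca$truth$data > 0])
  nb_vals <- unique(ca$image$data[nb])
  expect_identical(organ_vals, nb_vals)
})

test_that("overlapping structures are rejected at generation", {
  sp <- small_spec()
  sp$neighbor$center <- sp$organ$center
  expect_error(generate_phantom(sp), "overlap")
})

test_that("atlas agreement with the truth decays with jitter amplitude", {
  mean_dice <- sapply(c(4, 12, 24), function(amp) {
    ca <- generate_phantom(small_spec(seed = 7L, jitter_amp = amp,
                                      jitter_shared_frac = 0,
                                      jitter_shared_max_mm = amp))
    mean(sapply(ca$atlases, function(a) dice(a$label, ca$truth)))
  })
  expect_true(all(diff(mean_dice) < 0))
})

test_that("standard suite covers the four difficulty modes", {
  specs <- standard_specs(17L)
  expect_length(specs, 4)
  expect_true(all(sapply(specs, function(s) prod(s$shape) <= 64^3)))

  t0 <- proc.time()
  suite <- standard_suite(17L)
  gen_time <- (proc.time() - t0)[3]
  expect_length(suite, 4)
  expect_lt(gen_time, 60)   # generous single-CPU bound

  for (ca in suite) {
    tr <- ca$truth$data > 0
    expect_gt(sum(tr), 0)
    # single 6-connected component without cavities
    cleaned <- array(shapecut:::cpp_largest_component_fill(
      as.vector(tr), as.integer(dim(tr))), dim(tr))
    expect_identical(cleaned, tr)
    for (a in ca$atlases)
      expect_true(check_same_grid(ca$image, a$label))
  }

  # case 1: organ and neighbor match in mean but differ in texture
  ca1 <- suite[[1]]
  nb <- shapecut:::neighbor_mask(ca1$spec)
  organ_core <- ca1$truth$data > 0
  # means match up to the bias-field scale (the exact equal-intensity
  # construction is asserted separately with noise disabled)
  expect_lt(abs(mean(ca1$image$data[organ_core]) -
                  mean(ca1$image$data[nb])), 2 * ca1$spec$bias_sd)
  expect_gt(stats::sd(ca1$image$data[organ_core]),
            1.2 * stats::sd(ca1$image$data[nb]))

  # case 2 carries internal lesions darker than the parenchyma
  ca2 <- suite[[2]]
  les <- shapecut:::ellipsoid_mask(dim(ca2$truth$data),
                                   ca2$spec$lesions[[1]]$center,
                                   rep(ca2$spec$lesions[[1]]$radius, 3))
  core2 <- ca2$truth$data > 0
  expect_true(all(ca2$truth$data[les] == 1))   # lesions belong to the organ
  expect_lt(mean(ca2$image$data[les]),
            mean(ca2$image$data[core2 & !les]) - 20)
})
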