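test_that("nmi matches its closed forms and limits", {
  set.seed(21)
  a <- rand_volume(c(12, 12, 12))
  region <- array(TRUE, c(12, 12, 12))

  # identical non-constant images: H(a,b) = H(a), NMI = 2 exactly
  expect_equal(nmi(a, a, region), 2, tolerance = 1e-12)

  # an independent permutation of the same values: joint histogram is
  # product-like, NMI -> 1. Oracle: direct entropy computation from the
  # 2x2 joint table, independent of the implementation's binning path.
  b <- volume(array(sample(a$data), dim(a$data)), a$spacing)
  got <- nmi(a, b, region, bins = 2L)
  med_a <- stats::median(a$data)
  ja <- a$data > med_a
  jb <- b$data > med_a
  tab <- table(ja, jb) / length(ja)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  # not numerically identical to the implementation (bin edges differ at
  # the median tie) but both must approach 1
  oracle <- (ent(rowSums(tab)) + ent(colSums(tab))) / ent(as.vector(tab))
  expect_lt(abs(got - 1), 0.05)
  expect_lt(abs(oracle - 1), 0.05)
  expect_lt(abs(got - oracle), 0.05)
})

test_that("nmi rejects degenerate regions", {
  a <- rand_volume(c(6, 6, 6))
  one <- array(FALSE, c(6, 6, 6))
  one[3, 3, 3] <- TRUE
  expect_error(nmi(a, a, one), "two voxels")
  const <- volume(array(5, c(6, 6, 6)))
  expect_error(nmi(const, a, array(TRUE, c(6, 6, 6))), "constant")
})

make_atlas_set <- function(target, n, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(k) {
    noisy <- volume(target$data + rnorm(length(target$data), 0, k / 2),
                    target$spacing)
    lab <- array(0L, dim(target$data))
    lab[3:8, 3:8, 3:8] <- 1L
    list(intensity = noisy, label = label_volume(lab, target$spacing))
  }))
}

test_that("score_and_select normalizes ratios and applies the phi rule", {
  set.seed(22)
  target <- rand_volume(c(10, 10, 10))
  atlases <- make_atlas_set(target, 4)

  sc <- score_and_select(target, atlases, phi = 0.8)
  expect_equal(max(sc$r), 1, tolerance = 1e-12)
  expect_equal(sc$r, sc$nmi / max(sc$nmi))
  expect_identical(sc$selected, sc$r >= 0.8 | sc$r == max(sc$r))
  expect_true(any(sc$selected))

  # phi ~ 0 selects everything; phi = 1 selects exactly the argmax set
  expect_true(all(score_and_select(target, atlases, phi = 1e-9)$selected))
  sc1 <- score_and_select(target, atlases, phi = 1)
  expect_identical(which(sc1$selected), which(sc1$r == max(sc1$r)))

  # single atlas: r = 1, selected, weight 1
  sc_one <- score_and_select(target, atlases[1], phi = 0.8)
  expect_equal(sc_one$r, 1)
  expect_true(sc_one$selected)
  expect_equal(sc_one$weight, 1)
})

test_that("weighted majority voting follows the weighted-delta rule", {
  mk <- function(val) label_volume(array(val, c(2, 2, 2)))

  # unanimity
  expect_equal(weighted_majority_vote(list(mk(1), mk(1), mk(1)),
                                      c(1, 1, 1))$data[1], 1)
  # labels (1, 0, 0) with weights (.9, .5, .5): background wins 1.0 vs 0.9
  expect_equal(weighted_majority_vote(list(mk(1), mk(0), mk(0)),
                                      c(0.9, 0.5, 0.5))$data[1], 0)
  # exact tie breaks toward the smaller class index (background)
  expect_equal(weighted_majority_vote(list(mk(1), mk(0)),
                                      c(0.7, 0.7))$data[1], 0)
  expect_error(weighted_majority_vote(list(mk(1)), 0), "positive")
})

test_that("voting is permutation- and weight-scale-invariant and matches
           unweighted majority at equal weights", {
  set.seed(23)
  for (trial in 1:25) {
    labs <- lapply(1:5, function(k)
      label_volume(array(sample(0:2, 8^3, TRUE), c(8, 8, 8))))
    w <- runif(5, 0.2, 2)
    v1 <- weighted_majority_vote(labs, w)

    per <- sample(5)
    expect_identical(weighted_majority_vote(labs[per], w[per])$data, v1$data)
    expect_identical(weighted_majority_vote(labs, 7.3 * w)$data, v1$data)

    # equal weights == plain majority, brute-forced per voxel
    ve <- weighted_majority_vote(labs, rep(1, 5))
    stack <- sapply(labs, function(l) as.vector(l$data))
    plain <- apply(stack, 1, function(r) {
      tb <- table(r)
      cls <- as.integer(names(tb))
      cls[tb == max(tb)][1]          # ties -> smallest class
    })
    expect_identical(as.vector(ve$data), as.numeric(plain))
  }
})
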