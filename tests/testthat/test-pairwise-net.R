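test_that("pair enumeration is canonical and counts choose(n, 2)", {
  expect_equal(nrow(enumerate_pairs(100)), 4950)
  expect_equal(nrow(enumerate_pairs(10)), 45)
  expect_identical(enumerate_pairs(2), cbind(i = 1L, j = 2L))
  p4 <- enumerate_pairs(4)
  expect_identical(p4[, "i"], c(1L, 1L, 1L, 2L, 2L, 3L))
  expect_identical(p4[, "j"], c(2L, 3L, 4L, 3L, 4L, 4L))
  expect_true(all(p4[, 1] < p4[, 2]))
  expect_error(enumerate_pairs(1),
               class = "dispersr_error_insufficient_samples")
})

test_that("the block layout follows the kernel-2 / pool-10 recipe", {
  s5000 <- network_spec(n = 10, m = 5000)
  expect_equal(s5000$n_blocks, 3)
  expect_equal(unname(s5000$layout[, "L_out"]), c(499, 49, 4))
  expect_equal(s5000$filters, c(32L, 64L, 128L))
  s500 <- network_spec(n = 10, m = 500)
  expect_equal(s500$n_blocks, 2)
  # tiny inputs shrink the final pool instead of vanishing
  s8 <- network_spec(n = 4, m = 8)
  expect_true(all(s8$layout[, "L_out"] >= 1))
  expect_error(network_spec(n = 10, m = 500, k_extract = 46),
               class = "dispersr_error_config")
  expect_error(network_spec(n = 10, m = 1), class = "dispersr_error_config")
})

test_that("forward pass equals an independent loop-based evaluation", {
  cases <- list(
    list(n = 4, m = 30, pool = 10, filters = c(3L), dense = 5L, phased = FALSE),
    list(n = 6, m = 50, pool = 4, filters = c(4L, 2L), dense = 7L, phased = FALSE),
    list(n = 5, m = 24, pool = 3, filters = c(2L, 3L), dense = 4L, phased = FALSE),
    list(n = 4, m = 40, pool = 5, filters = c(3L, 4L), dense = 6L, phased = TRUE)
  )
  for (cs in cases) {
    spec <- network_spec(n = cs$n, m = cs$m, phased = cs$phased,
                         pool_width = cs$pool, filters = cs$filters,
                         pair_dense = cs$dense)
    w <- rough_weights(spec, seed = 100 + cs$n)
    withr::with_seed(cs$n * 7, {
      rows <- if (cs$phased) 2 * cs$n else cs$n
      vals <- if (cs$phased) 0:1 else 0:2
      counts <- matrix(sample(vals, rows * cs$m, replace = TRUE), rows, cs$m)
      loc <- tibble::tibble(sample_id = as.character(seq_len(cs$n)),
                            x = runif(cs$n, 0, 10), y = runif(cs$n, 0, 10))
    })
    g <- genotype_matrix(counts, seq_len(cs$m), as.character(seq_len(cs$n)),
                         phased = cs$phased)
    expect_equal(net_forward(g, loc, w), oracle_forward(counts, loc, w),
                 tolerance = 1e-5)
  }
})

test_that("sigma estimates ignore k_extract entirely", {
  ds <- make_toy_dataset(6, 40, seed = 4)
  for (k in c(1L, 10L, 15L)) {
    spec <- network_spec(n = 6, m = 40, pool_width = 5, filters = c(3L, 2L),
                         pair_dense = 5, k_extract = k)
    w <- rough_weights(spec, seed = 9)
    est <- suppressWarnings(net_forward(ds$genotypes, ds$locations, w))
    if (k == 1L) base <- est
    expect_identical(est, base)
  }
})

test_that("zeroed weights reduce the network to its head bias", {
  spec <- network_spec(n = 5, m = 30, filters = c(3L), pair_dense = 4)
  w <- init_weights(spec, seed = 1, norm = c(0, 1), dist_scale = 1)
  for (nm in names(w$params)) w$params[[nm]] <- w$params[[nm]] * 0
  w$params$head_b <- 2.75
  ds <- make_toy_dataset(5, 30, seed = 6)
  expect_equal(net_forward(ds$genotypes, ds$locations, w), 2.75)
  # and the pair feature vector is all zeros
  slab <- ds$genotypes$counts[1:2, ]
  expect_equal(extract_pair_features(slab, 1.2, w), rep(0, 4))
})

test_that("the distance input feeds the network only through its pathway", {
  spec <- network_spec(n = 4, m = 20, filters = c(2L), pair_dense = 3)
  w <- rough_weights(spec, seed = 3)
  # zero all convolution weights: features can differ only via distance
  w$params$conv_W1 <- w$params$conv_W1 * 0
  w$params$conv_b1 <- w$params$conv_b1 * 0
  ds <- make_toy_dataset(4, 20, seed = 8)
  f1 <- suppressWarnings(net_forward(ds$genotypes, ds$locations, w))
  ds2 <- ds
  ds2$locations$x <- ds2$locations$x * 2
  ds2$locations$y <- ds2$locations$y * 2
  f2 <- suppressWarnings(net_forward(ds$genotypes, ds2$locations, w))
  expect_false(isTRUE(all.equal(f1, f2)))
  # cutting the dense column for distance makes the output distance-blind
  w$params$dense_W[, ncol(w$params$dense_W)] <- 0
  expect_equal(suppressWarnings(net_forward(ds$genotypes, ds$locations, w)),
               suppressWarnings(net_forward(ds$genotypes, ds2$locations, w)))
})

test_that("estimates are invariant to rigid motions of the coordinates", {
  spec <- network_spec(n = 6, m = 40, pool_width = 5, filters = c(3L, 2L),
                       pair_dense = 5)
  w <- rough_weights(spec, seed = 21)
  ds <- make_toy_dataset(6, 40, seed = 22)
  base <- suppressWarnings(net_forward(ds$genotypes, ds$locations, w))
  # translation
  tr <- ds$locations
  tr$x <- tr$x + 103.2
  tr$y <- tr$y - 55.5
  expect_equal(suppressWarnings(net_forward(ds$genotypes, tr, w)), base,
               tolerance = 1e-12)
  # rotation about an arbitrary point
  th <- 0.77
  rot <- ds$locations
  rot$x <- cos(th) * ds$locations$x - sin(th) * ds$locations$y + 5
  rot$y <- sin(th) * ds$locations$x + cos(th) * ds$locations$y - 2
  expect_equal(suppressWarnings(net_forward(ds$genotypes, rot, w)), base,
               tolerance = 1e-9)
})

test_that("extractor size is independent of the number of samples", {
  w10 <- init_weights(network_spec(n = 10, m = 100), seed = 1)
  w50 <- init_weights(network_spec(n = 50, m = 100), seed = 1)
  expect_equal(dispersr:::extractor_param_count(w10),
               dispersr:::extractor_param_count(w50))
  # while the head grows with the number of pairs
  expect_equal(length(w50$params$head_w) / length(w10$params$head_w),
               nrow(enumerate_pairs(50)) / nrow(enumerate_pairs(10)))
})

test_that("pair selection for the extractor is uniform and reproducible", {
  pairs <- enumerate_pairs(10)
  all_sel <- select_extract_pairs(pairs, 45, rng_seed = 1)
  expect_equal(nrow(all_sel), 45)
  one <- select_extract_pairs(pairs, 1, rng_seed = 2)
  expect_equal(nrow(one), 1)
  expect_true(attr(one, "rows") %in% 1:45)
  expect_identical(select_extract_pairs(pairs, 7, rng_seed = 5),
                   select_extract_pairs(pairs, 7, rng_seed = 5))
  expect_error(select_extract_pairs(pairs, 0), class = "dispersr_error_config")
  expect_error(select_extract_pairs(pairs, 46), class = "dispersr_error_config")
})

test_that("mismatched shapes are configuration errors", {
  spec <- network_spec(n = 5, m = 30, filters = c(3L), pair_dense = 4)
  w <- init_weights(spec, seed = 1)
  ds <- make_toy_dataset(6, 30, seed = 1)
  expect_error(net_forward(ds$genotypes, ds$locations, w),
               class = "dispersr_error_config")
  expect_error(extract_pair_features(matrix(0L, 3, 30), 1, w),
               class = "dispersr_error_config")
})
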