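test_that("sigma_f prior draws are uniform, reproducible, and validated", {
  x <- vapply(1:50, function(i) draw_sigma_f(0.2, 3, rng_seed = i), numeric(1))
  expect_true(all(x >= 0.2 & x <= 3))
  expect_identical(draw_sigma_f(0.2, 3, rng_seed = 7),
                   draw_sigma_f(0.2, 3, rng_seed = 7))
  expect_equal(draw_sigma_f(1, 1 + 1e-9, rng_seed = 1), 1, tolerance = 1e-6)
  expect_error(draw_sigma_f(3, 0.2), class = "dispersr_error_config")
  expect_error(draw_sigma_f(1, 1), class = "dispersr_error_config")

  # Monte-Carlo mean of U(0.2, 3): analytic oracle (0.2 + 3) / 2 = 1.6
  mc <- mean(vapply(1:10000, function(i)
    draw_sigma_f(0.2, 3, rng_seed = i), numeric(1)))
  expect_lt(abs(mc - 1.6), 0.03)
})

test_that("effective sigma applies the sqrt(3/2) parent-displacement factor", {
  expect_identical(effective_sigma(0), 0)
  expect_equal(effective_sigma(2), 2.449489742783178, tolerance = 1e-12)
  expect_equal(effective_sigma(0.2), 0.2449489742783178, tolerance = 1e-12)
  expect_error(effective_sigma(-1), class = "dispersr_error_config")
})

test_that("sim_params validates inputs and derives the burn-in default", {
  p <- sim_params(sigma_f = 2, habitat_width = 10, seed = 1)
  expect_equal(p$n_generations, 50) # ceiling(10 * 10 / 2)
  p2 <- sim_params(sigma_f = 0.1, habitat_width = 50, generation_cap = 120)
  expect_equal(p2$n_generations, 120) # capped
  expect_error(sim_params(sigma_f = -1), class = "dispersr_error_config")
  expect_error(sim_params(sigma_f = 1, habitat_width = 0),
               class = "dispersr_error_config")
  expect_error(sim_params(sigma_f = 1, carrying_capacity = -2),
               class = "dispersr_error_config")
})

test_that("a zero dispersal scale places every offspring on its mother", {
  p <- sim_params(sigma_f = 0, habitat_width = 5, carrying_capacity = 2,
                  n_generations = 3, seed = 21)
  sim <- run_simulation(p, n_loci = 0)
  expect_true(all(sim$displacements$dx == 0))
  expect_true(all(sim$displacements$dy == 0))
})

test_that("offspring displacements follow the Gaussian kernel away from edges", {
  sim <- desk_sim(sigma_f = 1, seed = 31, n_loci = 0)
  d <- sim$displacements
  interior <- d[d$edge_dist > 3, ]
  expect_gt(nrow(interior), 5000)
  expect_lt(abs(sqrt(mean(interior$dx^2)) - 1), 0.05)
  expect_lt(abs(sqrt(mean(interior$dy^2)) - 1), 0.05)
  # displacements near the boundary stay inside the habitat
  expect_true(all(sim$locations$x >= 0 & sim$locations$x <= 10))
  expect_true(all(sim$locations$y >= 0 & sim$locations$y <= 10))
})

test_that("census settles near carrying capacity times habitat area", {
  sims <- lapply(41:43, function(s) desk_sim(sigma_f = 1.5, seed = s, n_loci = 0))
  census <- vapply(sims, function(s) s$census, numeric(1))
  expect_true(all(abs(census - 500) / 500 < 0.25))
})

test_that("population extinction raises an explicit error", {
  p <- sim_params(sigma_f = 1, habitat_width = 1, carrying_capacity = 1,
                  n_generations = 500, generation_cap = 500, seed = 3)
  expect_error(run_simulation(p, n_loci = 0),
               class = "dispersr_error_extinct")
})

test_that("labels and stored metadata are internally consistent", {
  sim <- desk_sim(sigma_f = 0.8, seed = 51, n_loci = 200)
  expect_equal(sim$sigma_true / sim$sigma_f, sqrt(1.5), tolerance = 1e-12)
  expect_equal(nrow(sim$genotypes$counts), nrow(sim$locations))
  expect_true(all(diff(sim$genotypes$positions) > 0))
  expect_true(all(sim$genotypes$counts %in% 0:2))
  # minor-allele polarization
  expect_true(all(colMeans(sim$genotypes$counts) / 2 <= 0.5 + 1e-12))
})

test_that("identical parameters and seed reproduce the simulation exactly", {
  p <- desk_params(1.2, seed = 61, n_generations = 20)
  a <- run_simulation(p, n_loci = 50)
  b <- run_simulation(p, n_loci = 50)
  expect_identical(a$locations, b$locations)
  expect_identical(a$genotypes$counts, b$genotypes$counts)
  expect_identical(a$displacements, b$displacements)
})

test_that("uniform sampling without replacement returns aligned subsets", {
  sim <- desk_sim(sigma_f = 0.8, seed = 51, n_loci = 200)
  sub <- sample_individuals(sim, 12, rng_seed = 5)
  expect_equal(nrow(sub$locations), 12)
  expect_equal(nrow(sub$genotypes$counts), 12)
  expect_equal(sub$locations$sample_id, sub$genotypes$sample_ids)
  expect_equal(length(unique(sub$sampled_idx)), 12)
  # full-census draw is the identity subset
  all_sub <- sample_individuals(sim, sim$census, rng_seed = 1)
  expect_identical(all_sub$sampled_idx, seq_len(sim$census))
  expect_error(sample_individuals(sim, sim$census + 1),
               class = "dispersr_error_insufficient_individuals")
})

test_that("nearest-to-localities sampling matches brute-force claiming", {
  sim <- desk_sim(sigma_f = 0.8, seed = 51, n_loci = 200)
  # a locality exactly on an individual claims that individual
  loc1 <- sim$locations[7, ]
  hit <- sample_individuals(sim, 1, scheme = "nearest",
                            localities = loc1)
  expect_equal(hit$sampled_idx, 7L)
  # random localities: greedy claiming oracle in the same order
  localities <- withr::with_seed(9, tibble::tibble(x = runif(8, 0, 10),
                                                   y = runif(8, 0, 10)))
  got <- sample_individuals(sim, 8, scheme = "nearest", localities = localities)
  claimed <- logical(sim$census)
  expected <- integer(8)
  for (i in 1:8) {
    d2 <- (sim$locations$x - localities$x[i])^2 +
      (sim$locations$y - localities$y[i])^2
    d2[claimed] <- Inf
    expected[i] <- which.min(d2)
    claimed[expected[i]] <- TRUE
  }
  expect_identical(got$sampled_idx, expected)
})

test_that("per-draw datasets have sample-ascertained, polarized SNPs", {
  sim <- desk_sim(sigma_f = 0.8, seed = 51, n_loci = 200)
  ds <- sample_dataset(sim, 10, 300, rng_seed = 71)
  expect_s3_class(ds, "dispersal_dataset")
  expect_equal(dim(ds$genotypes$counts), c(10L, 300L))
  freq <- colMeans(ds$genotypes$counts) / 2
  expect_true(all(freq > 0))          # segregating within the sample
  expect_true(all(freq <= 0.5 + 1e-12))
  expect_equal(ds$sigma_true, sim$sigma_true)
  # same seed, same draw
  ds2 <- sample_dataset(sim, 10, 300, rng_seed = 71)
  expect_identical(ds$genotypes$counts, ds2$genotypes$counts)
  # phased draws expose two 0/1 rows per individual
  dp <- sample_dataset(sim, 6, 100, rng_seed = 72, phased = TRUE)
  expect_equal(dim(dp$genotypes$counts), c(12L, 100L))
  expect_true(all(dp$genotypes$counts %in% 0:1))
})

test_that("training-set generation is deterministic and correctly labelled", {
  tmpl <- desk_params(1, seed = 1, n_generations = 25)
  p1 <- withr::local_tempfile(fileext = ".bin")
  p2 <- withr::local_tempfile(fileext = ".bin")
  s1 <- generate_training_set(2, 3, 8, 60, tmpl, rng_seed = 11, path = p1)
  s2 <- generate_training_set(2, 3, 8, 60, tmpl, rng_seed = 11, path = p2)
  expect_equal(s1$count, 6)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  labs <- store_labels(s1)
  expect_equal(length(unique(labs)), 2) # one sigma per simulation
  expect_true(all(labs >= 0.2 * sqrt(1.5) & labs <= 3 * sqrt(1.5)))
  # draws from one simulation differ in sampled individuals
  expect_false(identical(s1$records[[1]]$genotypes$counts,
                         s1$records[[2]]$genotypes$counts))
})

test_that("isolation by distance strengthens as dispersal shrinks", {
  slope_of <- function(sigma_f, seed) {
    sim <- cached(sprintf("ibd_sim_%g_%d", sigma_f, seed), run_simulation(
      desk_params(sigma_f, seed, n_generations = 100), n_loci = 0,
      record_displacements = FALSE
    ))
    ds <- sample_dataset(sim, 30, 300, rng_seed = seed + 1)
    pairs <- enumerate_pairs(30)
    d <- sqrt((ds$locations$x[pairs[, 1]] - ds$locations$x[pairs[, 2]])^2 +
                (ds$locations$y[pairs[, 1]] - ds$locations$y[pairs[, 2]])^2)
    a <- vapply(seq_len(nrow(pairs)), function(k)
      pairwise_stat(ds$genotypes, pairs[k, 1], pairs[k, 2]), numeric(1))
    fit_ibd(a, d)$slope
  }
  seeds <- 81:90
  s_small <- vapply(seeds, function(s) slope_of(0.4, s), numeric(1))
  s_large <- vapply(seeds, function(s) slope_of(3, s), numeric(1))
  expect_gt(mean(s_small), 0)            # positive Mantel-type signal
  expect_gt(mean(s_small), mean(s_large)) # steeper IBD at small sigma
})
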