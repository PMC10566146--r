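#' Sample individuals from a simulation
#'
#' Subsets a [run_simulation()] result to `n` individuals, either uniformly
#' at random or by matching a table of empirical sampling localities: each
#' locality, in row order, claims the closest not-yet-claimed simulated
#' individual by Euclidean distance. Genotype columns are re-polarized so
#' minor-allele counts refer to the sampled individuals.
#'
#' @param sim A `sim_output` object.
#' @param n Number of individuals to keep (`<=` the final census). For the
#'   nearest-to-localities scheme it must equal `nrow(localities)`.
#' @param scheme `"uniform"` or `"nearest"` (nearest-to-localities).
#' @param localities Data frame with numeric `x`, `y` columns (one row per
#'   empirical locality); required iff `scheme = "nearest"`.
#' @param rng_seed Integer seed for the uniform draw.
#' @return A `sim_output` subset (indices of the chosen individuals are kept
#'   in `$sampled_idx`).
#' @export
sample_individuals <- function(sim, n, scheme = c("uniform", "nearest"),
                               localities = NULL, rng_seed = 1L) {
  stopifnot(inherits(sim, "sim_output"))
  scheme <- match.arg(scheme)
  check_number(n, "n", min = 1, integer = TRUE)
  if (n > sim$census) {
    abort_runtime(
      sprintf("Requested %d individuals but the final census is %d.",
              n, sim$census),
      class = "dispersr_error_insufficient_individuals"
    )
  }
  if (scheme == "nearest") {
    if (is.null(localities)) {
      abort_config("`localities` is required for scheme = \"nearest\".")
    }
    if (nrow(localities) != n) {
      abort_config(sprintf(
        "`n` (%d) must equal the number of localities (%d) for the nearest scheme.",
        n, nrow(localities)
      ))
    }
    idx <- claim_nearest(localities$x, localities$y,
                         sim$locations$x, sim$locations$y)
  } else {
    idx <- sort(with_seed_(rng_seed, sample.int(sim$census, n)))
  }
  subset_sim(sim, idx)
}

# Greedy nearest-neighbour claiming in locality order; ties break to the
# lowest individual index.
claim_nearest <- function(lx, ly, px, py) {
  claimed <- logical(length(px))
  idx <- integer(length(lx))
  for (i in seq_along(lx)) {
    d2 <- (px - lx[i])^2 + (py - ly[i])^2
    d2[claimed] <- Inf
    j <- which.min(d2)
    claimed[j] <- TRUE
    idx[i] <- j
  }
  idx
}

subset_sim <- function(sim, idx) {
  out <- sim
  out$locations <- sim$locations[idx, , drop = FALSE]
  out$sampled_idx <- idx
  out$census <- length(idx)
  if (!is.null(sim$haplotypes)) {
    hap_rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    out$haplotypes <- sim$haplotypes[hap_rows, , drop = FALSE]
  }
  if (!is.null(sim$genotypes)) {
    counts <- polarize_minor(sim$genotypes$counts[idx, , drop = FALSE])
    out$genotypes <- genotype_matrix(
      counts = counts,
      positions = sim$genotypes$positions,
      sample_ids = sim$locations$sample_id[idx],
      phased = FALSE
    )
  }
  out
}

#' Draw one training dataset from a simulation
#'
#' Samples `n` individuals from the final generation and overlays fresh
#' neutral mutations on the realized genealogy of exactly those individuals
#' (the same ascertainment as overlaying mutations on a sampled tree
#' sequence), so every SNP is segregating within the sample. The site set is
#' then uniformly subsampled down to `m` SNPs.
#'
#' @inheritParams sample_individuals
#' @param m Number of SNPs per dataset.
#' @param phased Return two 0/1 haplotype rows per individual instead of
#'   0/1/2 minor-allele counts.
#' @param linkage_blocks Number of linkage blocks for the mutation overlay
#'   (sites within a block share one realized genealogy, blocks recombine
#'   freely). `NULL` derives the expected breakpoint count over the
#'   pedigree depth, `ceiling(n_generations * recomb_rate * genome_length)`.
#' @return A `dispersal_dataset`: list with `genotypes`
#'   ([genotype_matrix()]), `locations` (tibble), `sigma_true`, `sigma_f`,
#'   and `habitat_width`.
#' @export
sample_dataset <- function(sim, n, m, scheme = c("uniform", "nearest"),
                           localities = NULL, rng_seed = 1L, phased = FALSE,
                           linkage_blocks = NULL) {
  stopifnot(inherits(sim, "sim_output"))
  check_number(m, "m", min = 1, integer = TRUE)
  sub <- sample_individuals(sim, n, scheme, localities,
                            rng_seed = derive_seed(rng_seed, 1L))
  idx <- sub$sampled_idx
  hap_ids <- as.vector(rbind(2L * idx - 1L, 2L * idx))

  ask <- as.integer(ceiling(1.15 * m) + 8L)
  ov <- with_seed_(
    derive_seed(rng_seed, 2L),
    overlay_mutations(sim$pedigree, hap_ids, ask, sim$params$genome_length,
                      n_blocks = linkage_blocks,
                      recomb_rate = sim$params$recomb_rate)
  )
  if (ncol(ov$haplotypes) < m) {
    ov <- with_seed_(
      derive_seed(rng_seed, 3L),
      overlay_mutations(sim$pedigree, hap_ids, 2L * ask,
                        sim$params$genome_length,
                        n_blocks = linkage_blocks,
                        recomb_rate = sim$params$recomb_rate)
    )
  }
  if (ncol(ov$haplotypes) < m) {
    abort_runtime(
      sprintf("Only %d segregating SNPs could be placed (requested %d).",
              ncol(ov$haplotypes), m),
      class = "dispersr_error_too_few_snps"
    )
  }

  hap <- polarize_minor_hap(ov$haplotypes)
  if (phased) {
    g <- genotype_matrix(hap, ov$positions,
                         sample_ids = sub$locations$sample_id, phased = TRUE)
  } else {
    counts <- hap[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
      hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    g <- genotype_matrix(polarize_minor(counts), ov$positions,
                         sample_ids = sub$locations$sample_id, phased = FALSE)
  }
  g <- subsample_snps(g, m, rng_seed = derive_seed(rng_seed, 4L))

  structure(
    list(
      genotypes = g,
      locations = sub$locations,
      sigma_true = sim$sigma_true,
      sigma_f = sim$sigma_f,
      habitat_width = sim$params$habitat_width
    ),
    class = "dispersal_dataset"
  )
}

# Flip haplotype columns so 1 encodes the minor allele (ties keep derived).
polarize_minor_hap <- function(hap) {
  freq <- colMeans(hap)
  flip <- freq > 0.5
  hap[, flip] <- 1L - hap[, flip, drop = FALSE]
  storage.mode(hap) <- "integer"
  hap
}

#' Generate a training set of simulated datasets
#'
#' Runs `n_sims` forward simulations whose interaction scale is drawn from
#' `U(sigma_range[1], sigma_range[2])`, draws `draws_per_sim` datasets from
#' each (different sampled individuals and an independent mutation overlay
#' per draw), and writes all `n_sims * draws_per_sim` records to a binary
#' [write_store()] file together with their true effective sigma labels.
#'
#' @param n_sims Number of independent simulations.
#' @param draws_per_sim Datasets drawn per simulation.
#' @param n Individuals per dataset.
#' @param m SNPs per dataset.
#' @param params_template A [sim_params()] object supplying habitat,
#'   demography and run length; its `sigma_f` and `seed` are replaced per
#'   simulation.
#' @param rng_seed Master seed; every simulation and draw derives its own
#'   stream from it.
#' @param path File path for the dataset store.
#' @param sigma_range Bounds of the uniform prior on `sigma_f`.
#' @param phased Store phased haplotypes instead of unphased counts.
#' @param progress Print one line per completed simulation.
#' @return A `dataset_store` (see [read_store()]), invisibly reloadable from
#'   `path`.
#' @export
generate_training_set <- function(n_sims, draws_per_sim, n, m,
                                  params_template, rng_seed = 1L,
                                  path = tempfile(fileext = ".bin"),
                                  sigma_range = c(0.2, 3),
                                  phased = FALSE, progress = FALSE) {
  stopifnot(inherits(params_template, "sim_params"))
  check_number(n_sims, "n_sims", min = 1, integer = TRUE)
  check_number(draws_per_sim, "draws_per_sim", min = 1, integer = TRUE)

  records <- vector("list", n_sims * draws_per_sim)
  k <- 0L
  for (i in seq_len(n_sims)) {
    seed_i <- derive_seed(rng_seed, i)
    sf <- draw_sigma_f(sigma_range[1], sigma_range[2], rng_seed = seed_i)
    params_i <- sim_params(
      sigma_f = sf,
      habitat_width = params_template$habitat_width,
      carrying_capacity = params_template$carrying_capacity,
      genome_length = params_template$genome_length,
      recomb_rate = params_template$recomb_rate,
      n_generations = params_template$n_generations,
      boundary = params_template$boundary,
      seed = derive_seed(seed_i, 7L)
    )
    sim <- run_simulation(params_i, n_loci = 0, record_displacements = FALSE)
    for (d in seq_len(draws_per_sim)) {
      ds <- tryCatch(
        sample_dataset(sim, n, m, rng_seed = derive_seed(seed_i, 100L + d),
                       phased = phased),
        dispersr_error_too_few_snps = function(e) {
          abort_runtime(
            sprintf("Simulation %d (sigma_f = %.3f): %s", i, sf, conditionMessage(e)),
            class = "dispersr_error_too_few_snps"
          )
        }
      )
      k <- k + 1L
      records[[k]] <- ds
    }
    if (progress) {
      message(sprintf("sim %d/%d: sigma_f = %.3f, census = %d",
                      i, n_sims, sf, sim$census))
    }
  }
  write_store(records, path, habitat_width = params_template$habitat_width)
}
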