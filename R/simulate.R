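#' Run the continuous-space forward simulation
#'
#' Simulates `params$n_generations` non-overlapping generations of a
#' population on a square habitat. Each individual attempts reproduction
#' with a Poisson number of offspring whose mean is regulated by local
#' density (Gaussian competition kernel of scale `sigma_f`, relative to the
#' carrying capacity); for every offspring the mother chooses a father with
#' probability proportional to a Gaussian kernel of scale `sigma_f`
#' truncated at `3 * sigma_f` (a mother with no candidate in range skips
#' that attempt); the offspring is displaced from its mother by independent
#' per-axis Gaussian draws of scale `sigma_f`, with out-of-bounds
#' displacements redrawn (or reflected, per `params$boundary`).
#'
#' After the forward pass, neutral biallelic SNPs are overlaid on the
#' realized genealogy of the final generation: the lineage of every final
#' haplotype is traced back through the recorded pedigree (Mendelian coin
#' per meiosis) and a single mutation is placed on a uniformly chosen
#' surviving pedigree branch, so each locus is segregating in the final
#' generation. Linkage is approximated piecewise: genomically adjacent
#' sites are grouped into `linkage_blocks` blocks that each share one
#' realized genealogy, while blocks recombine freely. SNP positions are
#' drawn uniformly along the genome and sorted.
#'
#' When `sigma_f == 0` the model degenerates: offspring sit exactly on their
#' mother, mate choice is uniform over the population, and density
#' regulation is global.
#'
#' @param params A [sim_params()] object.
#' @param n_loci Target number of segregating SNPs to overlay (0 skips the
#'   genetic overlay entirely, e.g. for demographic checks).
#' @param record_displacements Keep a log of every birth's per-axis
#'   displacement (used to verify the dispersal kernel).
#' @param linkage_blocks Number of linkage blocks in the mutation overlay;
#'   `NULL` derives `ceiling(n_generations * recomb_rate * genome_length)`
#'   (the expected breakpoint count over the pedigree depth).
#' @return A `sim_output` object with elements
#'   \describe{
#'     \item{genotypes}{[genotype_matrix()] of minor-allele counts for all
#'       final-generation individuals (`NULL` when `n_loci = 0`).}
#'     \item{haplotypes}{0/1 matrix of the underlying `2N x m` haplotypes.}
#'     \item{locations}{tibble of final-generation coordinates.}
#'     \item{sigma_true}{`effective_sigma(sigma_f)`, the regression target.}
#'     \item{sigma_f, params, census}{generating parameters and final size.}
#'     \item{displacements}{tibble with one row per recorded birth: `gen`,
#'       `dx`, `dy`, and the mother's distance to the nearest edge.}
#'     \item{implied_mutation_rate}{realized mutations per genome per
#'       generation of pedigree branch length.}
#'   }
#' @examples
#' sim <- run_simulation(
#'   sim_params(sigma_f = 1, habitat_width = 6, n_generations = 10, seed = 2),
#'   n_loci = 50
#' )
#' sim$census
#' @export
run_simulation <- function(params, n_loci = 1000, record_displacements = TRUE,
                           linkage_blocks = NULL) {
  stopifnot(inherits(params, "sim_params"))
  check_number(n_loci, "n_loci", min = 0, integer = TRUE)
  with_seed_(params$seed,
             run_simulation_impl(params, n_loci, record_displacements,
                                 linkage_blocks))
}

run_simulation_impl <- function(params, n_loci, record_displacements,
                                linkage_blocks = NULL) {
  W <- params$habitat_width
  K <- params$carrying_capacity
  sf <- params$sigma_f
  G <- params$n_generations

  n0 <- max(2L, round(K * W^2))
  x <- runif(n0, 0, W)
  y <- runif(n0, 0, W)

  pedigree <- vector("list", G)
  disp_log <- if (record_displacements) vector("list", G) else NULL

  for (gen in seq_len(G)) {
    n <- length(x)
    if (n < 2L) {
      abort_runtime(
        sprintf("Population extinct at generation %d (census %d).", gen, n),
        class = "dispersr_error_extinct"
      )
    }
    if (sf > 0) {
      step <- .spatial_generation(x, y, sf, K, W,
                                  params$boundary == "redraw")
      if (is.null(step)) {
        abort_runtime(
          sprintf("Population extinct at generation %d (no offspring produced).",
                  gen),
          class = "dispersr_error_extinct"
        )
      }
    } else {
      # degenerate kernel: offspring sit on their mother, mating is uniform,
      # regulation is global
      dens <- (n - 1) / W^2
      n_off <- rpois(n, 2 / (1 + dens / K))
      mothers <- rep.int(seq_len(n), n_off)
      m_total <- length(mothers)
      if (m_total == 0L) {
        abort_runtime(
          sprintf("Population extinct at generation %d (no offspring produced).",
                  gen),
          class = "dispersr_error_extinct"
        )
      }
      fathers <- vapply(mothers, function(i) {
        f <- sample.int(n - 1L, 1L)
        if (f >= i) f + 1L else f
      }, integer(1))
      step <- list(x = x[mothers], y = y[mothers], mothers = mothers,
                   fathers = fathers,
                   dx = numeric(m_total), dy = numeric(m_total),
                   edge_dist = pmin(x[mothers], W - x[mothers],
                                    y[mothers], W - y[mothers]))
    }
    pedigree[[gen]] <- cbind(mother = step$mothers, father = step$fathers)
    if (record_displacements) {
      disp_log[[gen]] <- cbind(gen = gen, dx = step$dx, dy = step$dy,
                               edge_dist = step$edge_dist)
    }
    x <- step$x
    y <- step$y
  }

  n_final <- length(x)
  locations <- tibble::tibble(
    sample_id = as.character(seq_len(n_final)),
    x = x, y = y
  )
  displacements <- if (record_displacements) {
    tibble::as_tibble(do.call(rbind, disp_log))
  } else {
    NULL
  }

  genotypes <- NULL
  haplotypes <- NULL
  implied_rate <- NA_real_
  if (n_loci > 0) {
    ov <- overlay_mutations(pedigree, seq_len(2L * n_final), n_loci,
                            params$genome_length,
                            n_blocks = linkage_blocks,
                            recomb_rate = params$recomb_rate)
    haplotypes <- ov$haplotypes
    implied_rate <- ov$implied_rate
    counts <- haplotypes[seq(1L, 2L * n_final, by = 2L), , drop = FALSE] +
      haplotypes[seq(2L, 2L * n_final, by = 2L), , drop = FALSE]
    genotypes <- genotype_matrix(
      counts = polarize_minor(counts),
      positions = ov$positions,
      sample_ids = locations$sample_id,
      phased = FALSE
    )
  }

  structure(
    list(
      genotypes = genotypes,
      haplotypes = haplotypes,
      locations = locations,
      sigma_true = effective_sigma(params$sigma_f),
      sigma_f = params$sigma_f,
      params = params,
      census = n_final,
      displacements = displacements,
      implied_mutation_rate = implied_rate,
      pedigree = pedigree
    ),
    class = "sim_output"
  )
}

# Mirror coordinates into [0, W] (used for boundary = "reflect" and as the
# fallback after exhausting redraws).
reflect_into <- function(v, W) {
  v <- abs(v) %% (2 * W)
  ifelse(v > W, 2 * W - v, v)
}

#' @export
print.sim_output <- function(x, ...) {
  cat("<sim_output>\n")
  cat(sprintf("  census: %d individuals, sigma_f = %g, sigma_true = %.4f\n",
              x$census, x$sigma_f, x$sigma_true))
  if (!is.null(x$genotypes)) {
    cat(sprintf("  genotypes: %d x %d minor-allele counts\n",
                nrow(x$genotypes$counts), ncol(x$genotypes$counts)))
  }
  invisible(x)
}

# --- mutation overlay ------------------------------------------------------

# Trace the given final-generation haplotypes back through the pedigree and
# place one mutation per locus on a uniformly chosen surviving branch, so
# every kept locus is segregating among exactly those haplotypes (the same
# ascertainment as overlaying mutations on a sampled tree sequence).
# Linkage is approximated piecewise: sites are assigned contiguously (in
# genomic order) to `n_blocks` linkage blocks; all sites of a block share
# one realized genealogy (perfect within-block linkage) while blocks
# recombine freely. The default block count comes from how fast marginal
# genealogies decorrelate along a genome: about `r * L` crossovers per
# meiosis accumulate to `r * L * t` by pedigree depth `t`, and t = 50
# (half the benchmark pedigree depth) gives ceiling(50 * r * L).
overlay_mutations <- function(pedigree, hap_ids, n_loci, genome_length,
                              n_blocks = NULL, recomb_rate = 1e-8) {
  G <- length(pedigree)
  H <- length(hap_ids)
  if (is.null(n_blocks)) {
    n_blocks <- ceiling(G * recomb_rate * genome_length)
  }
  n_blocks <- max(1L, min(as.integer(n_blocks), as.integer(n_loci)))

  # Auxiliary traces estimate, per generation, how many pedigree branches
  # still carry ancestry of the final sample; these weight the mutation
  # generations (approximate branch-length weighting).
  n_aux <- 4L
  A <- matrix(hap_ids, H, n_aux)
  surv <- matrix(0L, G, n_aux)
  for (g in rev(seq_len(G))) {
    for (l in seq_len(n_aux)) surv[g, l] <- length(unique(A[, l]))
    if (g > 1L) A <- step_back(A, pedigree[[g]])
  }
  w <- pmax(rowMeans(surv) - 1, 0) # branches that can host a segregating site
  if (sum(w) <= 0) {
    abort_runtime("Pedigree too shallow to place segregating mutations.",
                  class = "dispersr_error_too_few_snps")
  }
  gstar <- sample(seq_len(G), n_loci, replace = TRUE, prob = w)

  # Main pass: A's columns track the linkage blocks still being traced;
  # each site freezes at its mutation generation, where a branch of its
  # block's genealogy is chosen. Sites are laid out contiguously across
  # blocks so that linked sites are also adjacent in genomic position.
  site_block <- rep(seq_len(n_blocks), each = ceiling(n_loci / n_blocks),
                    length.out = n_loci)
  A <- matrix(hap_ids, H, n_blocks)
  derived <- matrix(FALSE, H, n_loci)
  keep <- logical(n_loci)
  block_last <- vapply(seq_len(n_blocks), function(b) {
    gs <- gstar[site_block == b]
    if (length(gs) == 0L) Inf else min(gs) # deepest generation needed
  }, numeric(1))
  active <- seq_len(n_blocks)
  for (g in rev(seq_len(G))) {
    for (s in which(gstar == g)) {
      k <- match(site_block[s], active)
      col <- A[, k]
      counts <- tabulate(col, nbins = max(col))
      cand <- which(counts > 0L & counts < H)
      if (length(cand) > 0L) {
        h_star <- cand[sample.int(length(cand), 1L)]
        derived[, s] <- col == h_star
        keep[s] <- TRUE
      }
    }
    done <- block_last[active] >= g
    A <- A[, !done, drop = FALSE]
    active <- active[!done]
    if (length(active) == 0L) break
    if (g > 1L) A <- step_back(A, pedigree[[g]])
  }

  haplotypes <- derived[, keep, drop = FALSE]
  m <- ncol(haplotypes)
  if (m == 0L) {
    abort_runtime("No segregating sites could be placed on the genealogy.",
                  class = "dispersr_error_too_few_snps")
  }
  positions <- sort(sample.int(genome_length, m))
  branch_total <- sum(rowMeans(surv))
  list(
    haplotypes = haplotypes * 1L,
    positions = positions,
    implied_rate = m / branch_total
  )
}

# One backward step through generation g's pedigree: each haplotype copy of
# generation g picks one of its parent's two haplotypes, independently per
# locus (unlinked sites). Lineages that have coalesced onto the same
# haplotype must make the same choice, so coins are drawn per distinct
# ancestor within each locus column. For few lineages that is done
# column-by-column; for many, via one dense coin matrix over all
# generation-g haplotypes.
step_back <- function(A, ped) {
  n_g <- nrow(ped)
  h_g <- 2L * n_g
  n_active <- ncol(A)
  # parent individual for maternal (odd) and paternal (even) haplotype rows
  p_ind <- integer(h_g)
  p_ind[seq(1L, h_g, by = 2L)] <- ped[, 1L]
  p_ind[seq(2L, h_g, by = 2L)] <- ped[, 2L]
  if (nrow(A) <= 256L) {
    return(.step_back_sparse(A, p_ind))
  }
  coins <- matrix(
    sample.int(2L, h_g * n_active, replace = TRUE) - 1L,
    h_g, n_active
  )
  Tm <- 2L * p_ind - coins # maps gen-g haplotype -> gen-(g-1) haplotype, per locus
  lin <- as.vector(A) +
    rep.int((seq_len(n_active) - 1L) * h_g, rep.int(nrow(A), n_active))
  matrix(Tm[lin], nrow(A), n_active)
}

# Flip columns so each encodes counts of its minor allele; exact 0.5 ties
# keep the original (derived) allele.
polarize_minor <- function(counts) {
  n <- nrow(counts)
  freq <- colSums(counts) / (2 * n)
  flip <- freq > 0.5
  counts[, flip] <- 2L - counts[, flip, drop = FALSE]
  storage.mode(counts) <- "integer"
  counts
}
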