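# Shared fixtures. Expensive simulations are built lazily and cached for
# the whole test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The reduced-scale study conditions used throughout the suite: 10 x 10
# habitat, carrying capacity 5, 100 non-overlapping generations.
desk_params <- function(sigma_f, seed, n_generations = 100) {
  sim_params(
    sigma_f = sigma_f, habitat_width = 10, carrying_capacity = 5,
    n_generations = n_generations, seed = seed
  )
}

desk_sim <- function(sigma_f = 1, seed = 1, ...) {
  key <- sprintf("desk_sim_%g_%d", sigma_f, seed)
  cached(key, run_simulation(desk_params(sigma_f, seed), ...))
}

# A small random dataset (not from the simulator) for network unit tests.
make_toy_dataset <- function(n, m, seed, sigma_true = 1.7) {
  withr::with_seed(seed, {
    counts <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    structure(
      list(
        genotypes = genotype_matrix(counts, sort(sample.int(1e6, m)),
                                    as.character(seq_len(n))),
        locations = tibble::tibble(sample_id = as.character(seq_len(n)),
                                   x = runif(n, 0, 10), y = runif(n, 0, 10)),
        sigma_true = sigma_true,
        sigma_f = sigma_true / sqrt(1.5)
      ),
      class = "dispersal_dataset"
    )
  })
}

# Weights with every parameter perturbed away from zero, so no rectified
# unit sits exactly at its kink (two-sided finite differences are valid),
# and with mildly positive biases so the rectified pathways stay active.
rough_weights <- function(spec, seed = 12, norm = c(1.5, 0.8),
                          dist_scale = 10) {
  w <- init_weights(spec, seed = seed, norm = norm, dist_scale = dist_scale)
  withr::with_seed(seed + 1000, {
    for (nm in names(w$params)) {
      w$params[[nm]] <- w$params[[nm]] +
        stats::rnorm(length(w$params[[nm]]), 0, 0.3)
      if (grepl("_b", nm, fixed = TRUE)) {
        w$params[[nm]] <- abs(w$params[[nm]]) + 0.8
      }
    }
  })
  w
}

# Independent loop-based evaluation of the full network: plain R loops over
# filters, positions and pairs, written without reference to the engine.
oracle_forward <- function(counts, loc, w) {
  spec <- w$spec
  p <- w$params
  pairs <- enumerate_pairs(spec$n)
  feats <- c()
  for (pi in seq_len(nrow(pairs))) {
    if (spec$phased) {
      r <- c(2 * pairs[pi, 1] - 1, 2 * pairs[pi, 1],
             2 * pairs[pi, 2] - 1, 2 * pairs[pi, 2])
    } else {
      r <- c(pairs[pi, 1], pairs[pi, 2])
    }
    A <- counts[r, , drop = FALSE]
    for (b in seq_len(spec$n_blocks)) {
      lay <- spec$layout[b, ]
      K <- spec$conv_kernel
      W <- p[[paste0("conv_W", b)]]
      bb <- p[[paste0("conv_b", b)]]
      Fb <- spec$filters[b]
      Z <- matrix(0, Fb, lay[["L_conv"]])
      for (f in seq_len(Fb)) {
        for (t in seq_len(lay[["L_conv"]])) {
          acc <- bb[f]
          for (o in 0:(K - 1)) {
            for (cc in seq_len(nrow(A))) {
              acc <- acc + W[f, o * nrow(A) + cc] * A[cc, t + o]
            }
          }
          Z[f, t] <- max(acc, 0)
        }
      }
      pw <- lay[["pool"]]
      Lo <- lay[["L_out"]]
      A2 <- matrix(0, Fb, Lo)
      for (f in seq_len(Fb)) {
        for (t in seq_len(Lo)) {
          A2[f, t] <- mean(Z[f, ((t - 1) * pw + 1):(t * pw)])
        }
      }
      A <- A2
    }
    d <- sqrt((loc$x[pairs[pi, 1]] - loc$x[pairs[pi, 2]])^2 +
                (loc$y[pairs[pi, 1]] - loc$y[pairs[pi, 2]])^2)
    din <- c(as.vector(A), d / w$dist_scale)
    h <- pmax(as.vector(p$dense_W %*% din) + p$dense_b, 0)
    feats <- c(feats, h)
  }
  (sum(p$head_w * feats) + p$head_b) * w$norm[2] + w$norm[1]
}

# Loss in which only the selected pairs' features respond to extractor
# parameters (the unselected features are frozen at the base weights);
# finite differences of this surrogate equal the gated gradient.
gated_surrogate_loss <- function(w_mod, w_base, ds, sel) {
  spec <- w_base$spec
  pairs <- enumerate_pairs(spec$n)
  sel_mask <- seq_len(nrow(pairs)) %in% sel
  d <- sqrt((ds$locations$x[pairs[, 1]] - ds$locations$x[pairs[, 2]])^2 +
              (ds$locations$y[pairs[, 1]] - ds$locations$y[pairs[, 2]])^2)
  H_of <- function(w) {
    vapply(seq_len(nrow(pairs)), function(pi) {
      slab <- ds$genotypes$counts[c(pairs[pi, 1], pairs[pi, 2]), , drop = FALSE]
      extract_pair_features(slab, d[pi], w)
    }, numeric(spec$pair_dense))
  }
  H <- H_of(w_base)
  H[, sel_mask] <- H_of(w_mod)[, sel_mask]
  yhat <- sum(w_base$params$head_w * as.vector(H)) + w_base$params$head_b
  (yhat - (ds$sigma_true - w_base$norm[1]) / w_base$norm[2])^2
}
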