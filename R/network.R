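#' Enumerate all unordered sample pairs
#'
#' Pairs are generated in canonical lexicographic order (`i < j`, `i`
#' ascending, then `j`); the same order is frozen into trained weights so
#' the position-specific head layer sees pairs consistently between
#' training and prediction.
#'
#' @param n Number of samples, `>= 2`.
#' @return Integer matrix with columns `i`, `j` and `choose(n, 2)` rows.
#' @examples
#' nrow(enumerate_pairs(100)) # 4950
#' @export
enumerate_pairs <- function(n) {
  check_number(n, "n", integer = TRUE)
  if (n < 2) {
    abort_config("At least two samples are needed to form pairs.",
                 class = "dispersr_error_insufficient_samples")
  }
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Architecture of the pairwise feature extractor
#'
#' Describes the shared per-pair subnetwork ("extractor") and the final
#' head. Each block applies a 1-D convolution whose kernel spans
#' `conv_kernel` SNPs across both individuals' genotype channels, a
#' rectified-linear activation, and average pooling over `pool_width`
#' SNPs. Blocks are stacked until the SNP axis drops below `pool_width`
#' (the final block's pool shrinks if needed so the axis never vanishes).
#' The flattened convolution output is concatenated with the pair's scaled
#' Euclidean distance and passed through one fully connected layer of width
#' `pair_dense` (rectified linear), giving the pair's feature vector. The
#' features of all `choose(n, 2)` pairs are stacked and a single linear
#' unit maps them to the sigma estimate.
#'
#' @param n Samples per dataset.
#' @param m SNPs per dataset.
#' @param phased Whether inputs are phased (4 genotype channels per pair
#'   instead of 2).
#' @param conv_kernel SNPs spanned by each convolution kernel.
#' @param pool_width SNPs averaged by each pooling step.
#' @param filters Filter counts per block; recycled (last value repeated)
#'   if fewer than the number of blocks.
#' @param pair_dense Width of the per-pair fully connected layer.
#' @param k_extract Number of randomly chosen pairs whose computations
#'   contribute gradients to the extractor weights (`NULL` = all pairs).
#'   Forward passes always use every pair.
#' @return A `network_spec` object.
#' @export
network_spec <- function(n, m, phased = FALSE, conv_kernel = 2L,
                         pool_width = 10L, filters = c(32L, 64L, 128L),
                         pair_dense = 128L, k_extract = NULL) {
  check_number(n, "n", min = 2, integer = TRUE)
  check_number(m, "m", min = 1, integer = TRUE)
  check_number(conv_kernel, "conv_kernel", min = 1, integer = TRUE)
  check_number(pool_width, "pool_width", min = 1, integer = TRUE)
  check_number(pair_dense, "pair_dense", min = 1, integer = TRUE)
  if (m < conv_kernel) {
    abort_config("`m` must be at least `conv_kernel`.")
  }
  n_pairs <- n * (n - 1) / 2
  if (!is.null(k_extract)) {
    check_number(k_extract, "k_extract", min = 1, max = n_pairs, integer = TRUE)
  }
  layout <- conv_layout(m, conv_kernel, pool_width)
  n_blocks <- nrow(layout)
  filters <- as.integer(filters)
  if (length(filters) < n_blocks) {
    filters <- c(filters, rep(filters[length(filters)],
                              n_blocks - length(filters)))
  }
  filters <- filters[seq_len(n_blocks)]
  structure(
    list(
      n = as.integer(n), m = as.integer(m), phased = isTRUE(phased),
      conv_kernel = as.integer(conv_kernel),
      pool_width = as.integer(pool_width),
      n_blocks = n_blocks, filters = filters,
      pair_dense = as.integer(pair_dense),
      k_extract = if (is.null(k_extract)) as.integer(n_pairs) else as.integer(k_extract),
      layout = layout,
      n_pairs = as.integer(n_pairs)
    ),
    class = "network_spec"
  )
}

# Per-block SNP-axis lengths: columns L_in, L_conv, pool, L_out.
conv_layout <- function(m, kernel, pool) {
  rows <- list()
  L <- m
  repeat {
    Lc <- L - (kernel - 1L)
    pw <- min(pool, Lc)
    Lo <- Lc %/% pw
    rows[[length(rows) + 1L]] <- c(L_in = L, L_conv = Lc, pool = pw, L_out = Lo)
    L <- Lo
    if (L < pool || L < kernel) break
  }
  do.call(rbind, rows)
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> n = %d (%d pairs), m = %d SNPs, %s\n",
              x$n, x$n_pairs, x$m, if (x$phased) "phased" else "unphased"))
  for (b in seq_len(x$n_blocks)) {
    cat(sprintf("  block %d: conv(k=%d, %d filters) + avgpool(%d): %d -> %d\n",
                b, x$conv_kernel, x$filters[b], x$layout[b, "pool"],
                x$layout[b, "L_in"], x$layout[b, "L_out"]))
  }
  cat(sprintf("  pair dense: %d units; head: %d x %d -> 1; k_extract = %d\n",
              x$pair_dense, x$n_pairs, x$pair_dense, x$k_extract))
  invisible(x)
}

#' Initialise network weights
#'
#' He-normal initialisation for convolution and dense weights, zero biases,
#' and a small-variance head.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @param norm Target normalisation constants `c(mean, sd)` stored in the
#'   weights (identity `c(0, 1)` until training sets them).
#' @param dist_scale Divisor applied to pair distances before they enter
#'   the network (typically the habitat width).
#' @return A `model_weights` object.
#' @export
init_weights <- function(spec, seed = 1L, norm = c(0, 1), dist_scale = 1) {
  stopifnot(inherits(spec, "network_spec"))
  with_seed_(seed, {
    params <- list()
    C <- if (spec$phased) 4L else 2L
    for (b in seq_len(spec$n_blocks)) {
      fan_in <- C * spec$conv_kernel
      Fb <- spec$filters[b]
      params[[paste0("conv_W", b)]] <-
        matrix(rnorm(Fb * fan_in, 0, sqrt(2 / fan_in)), Fb, fan_in)
      params[[paste0("conv_b", b)]] <- numeric(Fb)
      C <- Fb
    }
    d_in <- spec$filters[spec$n_blocks] *
      spec$layout[spec$n_blocks, "L_out"] + 1L
    params$dense_W <- matrix(rnorm(spec$pair_dense * d_in, 0, sqrt(2 / d_in)),
                             spec$pair_dense, d_in)
    params$dense_b <- numeric(spec$pair_dense)
    h_in <- spec$n_pairs * spec$pair_dense
    params$head_w <- rnorm(h_in, 0, sqrt(1 / h_in))
    params$head_b <- 0
    structure(
      list(params = params, spec = spec,
           norm = as.numeric(norm), dist_scale = as.numeric(dist_scale)),
      class = "model_weights"
    )
  })
}

#' @export
print.model_weights <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<model_weights> %d parameters (extractor %d, head %d)\n",
              n_par, n_par - length(x$params$head_w) - 1L,
              length(x$params$head_w) + 1L))
  cat(sprintf("  target norm: mean %.4g, sd %.4g; distance scale %.4g\n",
              x$norm[1], x$norm[2], x$dist_scale))
  invisible(x)
}

# Number of parameters in the shared extractor (independent of n).
extractor_param_count <- function(weights) {
  p <- weights$params
  sum(vapply(p[setdiff(names(p), c("head_w", "head_b"))], length, numeric(1)))
}

# --- forward / backward engine --------------------------------------------
# The numerical core lives in src/network.cpp; these wrappers marshal the
# weight container into the fixed argument layout the C++ pass expects.

marshal_params <- function(weights) {
  spec <- weights$spec
  p <- weights$params
  list(
    conv_W = lapply(seq_len(spec$n_blocks), function(b) p[[paste0("conv_W", b)]]),
    conv_b = lapply(seq_len(spec$n_blocks), function(b) p[[paste0("conv_b", b)]]),
    dense_W = p$dense_W, dense_b = p$dense_b,
    head_w = p$head_w, head_b = p$head_b
  )
}

net_pass <- function(counts, dists, weights, pairs, want_grad = FALSE,
                     y_norm = 0, loss_scale = 1, selected = NULL) {
  spec <- weights$spec
  mp <- marshal_params(weights)
  if (is.null(selected)) selected <- rep(TRUE, nrow(pairs))
  storage.mode(counts) <- "double"
  .net_pass_cpp(counts, pairs, as.numeric(dists), mp$conv_W, mp$conv_b,
                mp$dense_W, as.numeric(mp$dense_b), as.numeric(mp$head_w),
                as.numeric(mp$head_b), spec$layout, spec$conv_kernel,
                spec$phased, weights$dist_scale, want_grad, y_norm,
                loss_scale, selected)
}

net_forward_cache <- function(counts, dists, weights, pairs) {
  net_pass(counts, dists, weights, pairs, want_grad = FALSE)
}

#' Extract the feature vector for one pair of individuals
#'
#' Runs the shared extractor on a single pair slab: convolution/pooling
#' blocks, flattening, concatenation of the scaled Euclidean distance, and
#' the rectified-linear pair dense layer.
#'
#' @param g_pair A 2-row (unphased) or 4-row (phased) genotype slab.
#' @param d_ij Euclidean distance between the two individuals (map units).
#' @param weights A `model_weights` object.
#' @return Numeric feature vector of length `pair_dense`.
#' @export
extract_pair_features <- function(g_pair, d_ij, weights) {
  stopifnot(inherits(weights, "model_weights"))
  spec <- weights$spec
  g_pair <- as.matrix(g_pair)
  expected_rows <- if (spec$phased) 4L else 2L
  if (nrow(g_pair) != expected_rows || ncol(g_pair) != spec$m) {
    abort_config(sprintf(
      "Pair slab must be %d x %d for this network; got %d x %d.",
      expected_rows, spec$m, nrow(g_pair), ncol(g_pair)
    ))
  }
  pairs <- matrix(c(1L, 2L), 1L)
  ex <- net_pass(g_pair, d_ij, weights, pairs)
  pmax(as.vector(ex$H), 0)
}

#' Predict sigma for one dataset with fixed weights
#'
#' The forward pass: features are extracted from all `choose(n, 2)` pairs
#' (regardless of `k_extract`, which only gates gradients during training),
#' stacked in canonical order, passed through the single-unit linear head,
#' and the target normalisation is inverted. Negative estimates are
#' reported as-is with a warning (they indicate an under-trained model).
#'
#' @param g A [genotype_matrix()].
#' @param loc Locations tibble aligned to `g` (columns `x`, `y`).
#' @param weights A `model_weights` object.
#' @return The dispersal estimate `sigma_hat` in map units.
#' @export
net_forward <- function(g, loc, weights) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(weights, "model_weights"))
  spec <- weights$spec
  if (length(g$sample_ids) != spec$n || n_snps(g) != spec$m ||
      g$phased != spec$phased) {
    abort_config(sprintf(
      "Dataset (n = %d, m = %d, %s) does not match the network (n = %d, m = %d, %s).",
      length(g$sample_ids), n_snps(g), if (g$phased) "phased" else "unphased",
      spec$n, spec$m, if (spec$phased) "phased" else "unphased"
    ))
  }
  if (nrow(loc) != spec$n) {
    abort_config("Locations and genotypes disagree on the number of samples.",
                 class = "dispersr_error_alignment")
  }
  pairs <- enumerate_pairs(spec$n)
  dists <- all_pair_distances(loc, pairs)
  cache <- net_forward_cache(g$counts, dists, weights, pairs)
  sigma_hat <- from_norm_scale(cache$yhat_norm, weights)
  if (sigma_hat < 0) {
    warn(sprintf("Negative sigma estimate (%.4g); the model looks under-trained.",
                 sigma_hat))
  }
  sigma_hat
}

#' Randomly choose the pairs that train the extractor
#'
#' Uniform subset of `k_extract` pairs without replacement; redrawn every
#' training batch by [train_network()].
#'
#' @param pairs Pair matrix from [enumerate_pairs()].
#' @param k_extract Subset size, `1 <= k_extract <= nrow(pairs)`.
#' @param rng_seed Integer seed.
#' @return The selected rows of `pairs` (attribute `"rows"` holds their
#'   indices).
#' @export
select_extract_pairs <- function(pairs, k_extract, rng_seed = 1L) {
  check_number(k_extract, "k_extract", min = 1, max = nrow(pairs),
               integer = TRUE)
  rows <- sort(with_seed_(rng_seed, sample.int(nrow(pairs), k_extract)))
  out <- pairs[rows, , drop = FALSE]
  attr(out, "rows") <- rows
  out
}
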