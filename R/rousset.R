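#' Rousset's genetic differentiation statistic for a pair of individuals
#'
#' Computes an individual-pair analogue of `F/(1 - F)` from minor-allele
#' counts, following Rousset's approach of contrasting probabilities of
#' allelic identity within and between individuals. Per locus with counts
#' `g_i, g_j` (copies of the minor allele):
#' identity between the pair `Q_b = (g_i g_j + (2 - g_i)(2 - g_j)) / 4`,
#' and identity within an individual `Q_w = 1` if homozygous, `0` if
#' heterozygous. With bars denoting averages over loci (and, for `Q_w`,
#' over all individuals in the dataset), the statistic is
#' `a_hat = (Qw_bar - Qb_bar(i,j)) / (1 - Qw_bar)`.
#' Under isolation by distance its regression on log geographic distance
#' has slope `1 / (4 pi D sigma^2)`.
#'
#' @param g A [genotype_matrix()] (unphased).
#' @param i,j Sample indices.
#' @return The pairwise statistic (unitless, symmetric in `i`, `j`).
#' @export
pairwise_stat <- function(g, i, j) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$phased) {
    abort_config("The pairwise statistic is computed from unphased counts.")
  }
  qw <- rousset_qw(g$counts)
  if (qw >= 1) {
    abort_runtime("All sites are monomorphic (or fully homozygous); the statistic is undefined.",
                  class = "dispersr_error_monomorphic")
  }
  gi <- g$counts[i, ]
  gj <- g$counts[j, ]
  qb <- mean((gi * gj + (2 - gi) * (2 - gj)) / 4)
  (qw - qb) / (1 - qw)
}

rousset_qw <- function(counts) {
  mean(counts != 1L)
}

# All pairwise statistics at once: Qb = (G G' + (2-G)(2-G)') / (4 m).
rousset_pair_stats <- function(counts, pairs) {
  m <- ncol(counts)
  G <- counts
  Qb <- (tcrossprod(G) + tcrossprod(2 - G)) / (4 * m)
  qw <- rousset_qw(counts)
  if (qw >= 1) {
    abort_runtime("All sites are monomorphic (or fully homozygous); the statistic is undefined.",
                  class = "dispersr_error_monomorphic")
  }
  a <- (qw - Qb) / (1 - qw)
  a[cbind(pairs[, 1], pairs[, 2])]
}

#' Fit the isolation-by-distance regression
#'
#' Ordinary least squares of the pairwise genetic statistic on geographic
#' distance: on `log(distance)` for two-dimensional habitats (Rousset's
#' theory for 2-D isolation by distance) or raw distance for linear
#' habitats. Pairs at exactly zero distance are excluded (with a message)
#' because their log-distance is undefined.
#'
#' @param pair_stats Per-pair genetic statistic.
#' @param distances Per-pair geographic distance, map units.
#' @param dimension `"2D"` (default) or `"1D"`.
#' @return List with `slope`, `intercept`, `n_used`, `n_zero_excluded`.
#' @export
fit_ibd <- function(pair_stats, distances, dimension = c("2D", "1D")) {
  dimension <- match.arg(dimension)
  if (length(pair_stats) != length(distances)) {
    abort_config("`pair_stats` and `distances` must have equal length.")
  }
  keep <- distances > 0
  n_zero <- sum(!keep)
  if (n_zero > 0) {
    inform(sprintf("Excluded %d pair(s) at zero geographic distance.", n_zero))
  }
  x <- if (dimension == "2D") log(distances[keep]) else distances[keep]
  ys <- pair_stats[keep]
  if (length(unique(x)) < 2) {
    abort_runtime("All pair distances are equal; the regression is singular.",
                  class = "dispersr_error_singular_fit")
  }
  fit <- stats::lm(ys ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_used = sum(keep), n_zero_excluded = n_zero)
}

#' Invert the isolation-by-distance slope to a dispersal estimate
#'
#' In two dimensions the regression slope estimates
#' `1 / (4 pi D sigma^2)` (the reciprocal of Wright's neighbourhood size),
#' so `sigma_hat = sqrt(1 / (4 pi D slope))` given the population density
#' `D`. A non-positive slope makes the inversion impossible and yields
#' `NA` (the "undefined output" case counted separately during batch
#' evaluation).
#'
#' @param slope IBD regression slope.
#' @param density Individuals per square map unit, `> 0`.
#' @return `sigma_hat` in map units, or `NA_real_` if `slope <= 0`.
#' @examples
#' sigma_from_slope(1 / (4 * pi), density = 1) # 1
#' @export
sigma_from_slope <- function(slope, density) {
  check_number(density, "density", min = 0, allow_min = FALSE)
  if (!is.finite(slope) || slope <= 0) {
    return(NA_real_)
  }
  sqrt(1 / (4 * pi * density * slope))
}

#' Rousset's dispersal estimate for one dataset
#'
#' Composes [pairwise_stat()] over all pairs, [fit_ibd()], and
#' [sigma_from_slope()].
#'
#' @param g A [genotype_matrix()].
#' @param loc Locations tibble aligned to `g`.
#' @param density Population density, individuals per square map unit
#'   (the true simulation density in benchmarks; user-supplied for
#'   empirical data).
#' @param dimension Habitat dimensionality for the regression.
#' @return An `ibd_regression` object: per-pair points, fitted `slope` and
#'   `intercept`, `density`, and `sigma_hat` (`NA` when the slope is
#'   non-positive).
#' @export
rousset_estimate <- function(g, loc, density, dimension = c("2D", "1D")) {
  stopifnot(inherits(g, "genotype_matrix"))
  dimension <- match.arg(dimension)
  n <- length(g$sample_ids)
  if (nrow(loc) != n) {
    abort_config("Locations and genotypes disagree on the number of samples.",
                 class = "dispersr_error_alignment")
  }
  if (n < 3) {
    abort_config("At least 3 individuals are needed for the IBD regression.",
                 class = "dispersr_error_insufficient_samples")
  }
  if (n_snps(g) < 2) {
    abort_config("At least 2 polymorphic sites are required.")
  }
  pairs <- enumerate_pairs(n)
  stats_ <- rousset_pair_stats(g$counts, pairs)
  dists <- all_pair_distances(loc, pairs)
  fit <- fit_ibd(stats_, dists, dimension)
  structure(
    list(
      points = tibble::tibble(i = pairs[, 1], j = pairs[, 2],
                              distance = dists, a_hat = stats_),
      slope = fit$slope,
      intercept = fit$intercept,
      density = density,
      dimension = dimension,
      sigma_hat = sigma_from_slope(fit$slope, density),
      n_used = fit$n_used,
      n_zero_excluded = fit$n_zero_excluded
    ),
    class = "ibd_regression"
  )
}

#' @export
print.ibd_regression <- function(x, ...) {
  cat("<ibd_regression>\n")
  cat(sprintf("  slope: %.6g, intercept: %.6g (%d pairs, %d zero-distance excluded)\n",
              x$slope, x$intercept, x$n_used, x$n_zero_excluded))
  if (is.na(x$sigma_hat)) {
    cat("  sigma_hat: UNDEFINED (non-positive slope)\n")
  } else {
    cat(sprintf("  sigma_hat: %.4g (density %.4g)\n", x$sigma_hat, x$density))
  }
  invisible(x)
}

#' Run the Rousset baseline over a store of datasets
#'
#' @param store A `dataset_store` (or list of datasets) with known labels.
#' @param density Population density used for every inversion.
#' @return List with `estimates` (tibble: `dataset`, `sigma_true`,
#'   `slope`, `sigma_hat`) and `metrics` (a [metrics_report()] row whose
#'   `undefined_fraction` counts non-positive slopes).
#' @export
evaluate_rousset <- function(store, density) {
  recs <- as_record_list(store)
  est <- purrr::map_dfr(seq_along(recs), function(k) {
    r <- recs[[k]]
    ibd <- rousset_estimate(r$genotypes, r$locations, density)
    tibble::tibble(dataset = k, sigma_true = r$sigma_true %||% NA_real_,
                   slope = ibd$slope, sigma_hat = ibd$sigma_hat)
  })
  list(
    estimates = est,
    metrics = metrics_report(est$sigma_true, est$sigma_hat)
  )
}
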