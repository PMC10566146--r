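#' Simulation parameters for the continuous-space model
#'
#' Bundles the parameters of the individual-based, continuous-space forward
#' simulation used to generate training data with a known dispersal rate.
#' The population lives on a `habitat_width` x `habitat_width` square with
#' local carrying capacity `carrying_capacity` individuals per square map
#' unit. A single interaction scale, `sigma_f`, is shared by the
#' mother-offspring dispersal kernel, the mate-choice kernel, and the
#' local-competition kernel. The effective dispersal rate of the model --
#' the root-mean-square single-axis displacement between a child and a
#' randomly chosen parent -- is `sigma_f * sqrt(3/2)` (see
#' [effective_sigma()]).
#'
#' @param sigma_f Interaction scale in map units (dispersal, mating and
#'   competition share this value). Must be `>= 0`.
#' @param habitat_width Side of the square habitat, map units.
#' @param carrying_capacity Local carrying capacity, individuals per square
#'   map unit.
#' @param genome_length Genome size in base pairs (SNP positions are drawn
#'   uniformly along it).
#' @param recomb_rate Crossovers per base pair per generation. At the default
#'   scale (`1e8` bp at `1e-8`) SNPs drawn along the genome are effectively
#'   unlinked, which is the approximation the mutation overlay uses.
#' @param n_generations Number of non-overlapping generations to simulate.
#'   `NULL` uses `ceiling(10 * habitat_width / sigma_f)` capped at
#'   `generation_cap`.
#' @param generation_cap Upper bound applied to the default `n_generations`.
#' @param boundary How offspring displacements that leave the habitat are
#'   handled: `"redraw"` (draw a fresh displacement, the default) or
#'   `"reflect"` (mirror across the boundary).
#' @param seed Integer seed; every stochastic step of the simulation is
#'   reproducible from it.
#'
#' @return An object of class `sim_params`.
#' @examples
#' p <- sim_params(sigma_f = 1, habitat_width = 10, seed = 1)
#' p$n_generations
#' @export
sim_params <- function(sigma_f,
                       habitat_width = 50,
                       carrying_capacity = 5,
                       genome_length = 1e8,
                       recomb_rate = 1e-8,
                       n_generations = NULL,
                       generation_cap = 200,
                       boundary = c("redraw", "reflect"),
                       seed = 1L) {
  check_number(sigma_f, "sigma_f", min = 0)
  check_number(habitat_width, "habitat_width", min = 0, allow_min = FALSE)
  check_number(carrying_capacity, "carrying_capacity", min = 0, allow_min = FALSE)
  check_number(genome_length, "genome_length", min = 1)
  check_number(recomb_rate, "recomb_rate", min = 0)
  check_number(generation_cap, "generation_cap", min = 1, integer = TRUE)
  boundary <- match.arg(boundary)
  if (is.null(n_generations)) {
    n_generations <- if (sigma_f > 0) {
      min(ceiling(10 * habitat_width / sigma_f), generation_cap)
    } else {
      generation_cap
    }
  }
  check_number(n_generations, "n_generations", min = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(
    list(
      habitat_width = habitat_width,
      carrying_capacity = carrying_capacity,
      sigma_f = sigma_f,
      genome_length = genome_length,
      recomb_rate = recomb_rate,
      n_generations = as.integer(n_generations),
      boundary = boundary,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  habitat: %g x %g, carrying capacity %g / unit^2\n",
              x$habitat_width, x$habitat_width, x$carrying_capacity))
  cat(sprintf("  sigma_f: %g (effective sigma %.4f)\n",
              x$sigma_f, effective_sigma(x$sigma_f)))
  cat(sprintf("  genome: %g bp, recombination %g /bp/gen\n",
              x$genome_length, x$recomb_rate))
  cat(sprintf("  generations: %d, boundary: %s, seed: %d\n",
              x$n_generations, x$boundary, x$seed))
  invisible(x)
}

#' Draw an interaction scale from its training prior
#'
#' The training prior over the simulation interaction scale is uniform; the
#' benchmark range is 0.2 to 3 map units.
#'
#' @param low,high Bounds of the uniform prior, `0 <= low < high`.
#' @param rng_seed Integer seed making the draw reproducible.
#' @return A single draw from `U(low, high)`.
#' @examples
#' draw_sigma_f(0.2, 3, rng_seed = 42)
#' @export
draw_sigma_f <- function(low = 0.2, high = 3, rng_seed = 1L) {
  check_number(low, "low", min = 0)
  check_number(high, "high")
  if (low >= high) {
    abort_config(sprintf("`low` (%g) must be strictly less than `high` (%g).",
                         low, high))
  }
  with_seed_(rng_seed, runif(1L, low, high))
}

#' Effective dispersal rate implied by the interaction scale
#'
#' In the simulation model the mother-offspring displacement has scale
#' `sigma_f` per axis and the mate (father) is displaced by a Gaussian of the
#' same scale, so the displacement from a child to a randomly chosen parent
#' has root-mean-square per-axis scale `sigma_f * sqrt(3/2)`. This is the
#' quantity the estimators target.
#'
#' @param sigma_f Interaction scale, map units, `>= 0`.
#' @return `sigma_f * sqrt(3/2)`.
#' @examples
#' effective_sigma(2) # 2.449...
#' @export
effective_sigma <- function(sigma_f) {
  if (!is.numeric(sigma_f) || any(!is.finite(sigma_f)) || any(sigma_f < 0)) {
    abort_config("`sigma_f` must be finite and non-negative.")
  }
  sigma_f * sqrt(3 / 2)
}
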