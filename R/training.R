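#' Training configuration
#'
#' Defaults follow the reference training recipe: mean squared error loss
#' on normalised targets, Adam optimiser, learning rate `1e-4`. Early
#' stopping monitors validation loss with the given `patience` and the best
#' checkpoint is restored.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Datasets per optimisation step.
#' @param max_epochs Maximum passes over the training set.
#' @param patience Epochs without validation improvement before stopping.
#' @param k_extract Pairs used to optimise the extractor each batch
#'   (`NULL` = all pairs).
#' @param seed Seed controlling shuffling, pair selection and weight
#'   initialisation.
#' @param validation_fraction Fraction of simulations held out for
#'   validation (datasets drawn from one simulation never straddle the
#'   split).
#' @param weight_decay Decoupled (AdamW-style) weight decay applied at
#'   every step; 0 disables it.
#' @param target_transform Scale on which targets are z-scored:
#'   `"identity"` or `"log"` (see [normalize_targets()]).
#' @param augment_permute Randomly permute the sample order of each
#'   training presentation. The estimand is invariant under sample
#'   reordering, so this is label-preserving augmentation; it pushes the
#'   position-specific head towards symmetric aggregation over pairs,
#'   which regularises strongly when training sets are small.
#' @return A `training_config` object.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 16L,
                            max_epochs = 100L, patience = 10L,
                            k_extract = NULL, seed = 1L,
                            validation_fraction = 0.15,
                            weight_decay = 0, augment_permute = TRUE,
                            target_transform = c("identity", "log")) {
  check_number(learning_rate, "learning_rate", min = 0, allow_min = FALSE)
  check_number(batch_size, "batch_size", min = 1, integer = TRUE)
  check_number(max_epochs, "max_epochs", min = 1, integer = TRUE)
  check_number(patience, "patience", min = 1, integer = TRUE)
  check_number(validation_fraction, "validation_fraction", min = 0, max = 0.9)
  check_number(weight_decay, "weight_decay", min = 0)
  target_transform <- match.arg(target_transform)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         k_extract = k_extract, seed = as.integer(seed),
         validation_fraction = validation_fraction,
         weight_decay = weight_decay,
         augment_permute = isTRUE(augment_permute),
         target_transform = target_transform),
    class = "training_config"
  )
}

# Label-preserving augmentation: relabel the samples of one record in a
# random order (genotype rows and coordinates move together).
permute_record <- function(r, perm) {
  g <- r$genotypes
  counts <- if (g$phased) {
    rows <- as.vector(rbind(2L * perm - 1L, 2L * perm))
    g$counts[rows, , drop = FALSE]
  } else {
    g$counts[perm, , drop = FALSE]
  }
  r$genotypes <- genotype_matrix(counts, g$positions, g$sample_ids[perm],
                                 g$phased)
  r$locations <- r$locations[perm, , drop = FALSE]
  r
}

#' Normalise regression targets
#'
#' Maps the training sigmas to zero mean and unit variance, optionally on
#' the log scale (useful when relative rather than absolute error is the
#' quantity of interest, as in the MRAE metric). The constants and the
#' transform are stored in the trained weights and inverted at prediction.
#'
#' @param sigmas Positive numeric vector of true sigma values.
#' @param transform `"identity"` (z-score of sigma) or `"log"` (z-score of
#'   `log(sigma)`).
#' @return List with `normalized` values and `constants = c(mean, sd)`
#'   (carrying the transform as an attribute).
#' @export
normalize_targets <- function(sigmas, transform = c("identity", "log")) {
  transform <- match.arg(transform)
  if (any(!is.finite(sigmas)) || any(sigmas <= 0)) {
    abort_config("All target sigmas must be finite and positive.")
  }
  y <- if (transform == "log") log(sigmas) else sigmas
  s <- stats::sd(y)
  if (length(sigmas) < 2 || s == 0) {
    abort_config("Targets have zero variance; cannot normalise a degenerate training set.",
                 class = "dispersr_error_degenerate")
  }
  m <- mean(y)
  constants <- c(mean = m, sd = s)
  attr(constants, "transform") <- transform
  list(normalized = (y - m) / s, constants = constants)
}

# Forward / inverse target maps used by training and prediction.
to_norm_scale <- function(sigma, weights) {
  y <- if (identical(attr(weights$norm, "transform"), "log")) log(sigma) else sigma
  (y - weights$norm[1]) / weights$norm[2]
}

from_norm_scale <- function(yhat, weights) {
  y <- yhat * weights$norm[2] + weights$norm[1]
  if (identical(attr(weights$norm, "transform"), "log")) exp(y) else y
}

# Mean squared error loss and parameter gradients over a batch of records,
# with extractor gradients gated to the selected pairs.
batch_gradients <- function(weights, batch, selected) {
  spec <- weights$spec
  pairs <- enumerate_pairs(spec$n)
  sel <- logical(spec$n_pairs)
  sel[selected] <- TRUE
  B <- length(batch)
  total <- NULL
  loss <- 0
  for (r in batch) {
    dists <- all_pair_distances(r$locations, pairs)
    y_norm <- to_norm_scale(r$sigma_true, weights)
    out <- net_pass(r$genotypes$counts, dists, weights, pairs,
                    want_grad = TRUE, y_norm = y_norm, loss_scale = 1 / B,
                    selected = sel)
    loss <- loss + out$loss
    g <- c(
      setNames(out$g_conv_W, paste0("conv_W", seq_len(spec$n_blocks))),
      setNames(out$g_conv_b, paste0("conv_b", seq_len(spec$n_blocks))),
      list(dense_W = out$g_dense_W, dense_b = out$g_dense_b,
           head_w = out$g_head_w, head_b = out$g_head_b)
    )
    total <- if (is.null(total)) g else Map(`+`, total, g)
  }
  list(loss = loss, grads = total[names(weights$params)])
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps) -
      lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

#' One gated optimisation step
#'
#' Computes the mean squared error over `batch` using forward passes
#' through all pairs, but lets gradients reach the extractor weights only
#' through the computations of `selected_pairs`; the head layer receives
#' gradients from every pair. With all pairs selected the step is identical
#' to ungated training.
#'
#' @param batch List of `dispersal_dataset` records.
#' @param weights A `model_weights` object.
#' @param selected_pairs Integer indices into the canonical pair order (or
#'   the matrix returned by [select_extract_pairs()]).
#' @param state Adam optimiser state (`NULL` starts a fresh one).
#' @param learning_rate Adam step size.
#' @param weight_decay Decoupled weight decay (see [training_config()]).
#' @return List with updated `weights`, optimiser `state` and the batch
#'   `loss` (on the normalised scale).
#' @export
gated_training_step <- function(batch, weights, selected_pairs,
                                state = NULL, learning_rate = 1e-4,
                                weight_decay = 0) {
  if (is.matrix(selected_pairs)) {
    selected_pairs <- attr(selected_pairs, "rows") %||%
      abort_config("Pass pair indices or the result of select_extract_pairs().")
  }
  if (length(selected_pairs) == 0) {
    abort_config("At least one pair must be selected for the extractor step.")
  }
  if (any(selected_pairs < 1 | selected_pairs > weights$spec$n_pairs)) {
    abort_config("Selected pair indices are out of range.")
  }
  bg <- batch_gradients(weights, batch, selected_pairs)
  if (!is.finite(bg$loss)) {
    abort_runtime("Non-finite training loss.", class = "dispersr_error_divergence")
  }
  if (is.null(state)) state <- adam_init(weights$params)
  up <- adam_update(weights$params, bg$grads, state, learning_rate,
                    weight_decay = weight_decay)
  weights$params <- up$params
  list(weights = weights, state = up$state, loss = bg$loss)
}

#' Train the pairwise network on a dataset store
#'
#' Minimises mean squared error on z-scored sigma targets with Adam and the
#' gated training step: every batch re-draws `k_extract` pairs that are
#' allowed to back-propagate into the shared extractor. Validation datasets
#' are split off by simulation (datasets sharing a generating simulation
#' stay on one side of the split), the best-validation checkpoint is kept,
#' and training stops early after `patience` epochs without improvement.
#'
#' @param store A `dataset_store` from [generate_training_set()] or
#'   [read_store()].
#' @param spec A [network_spec()] matching the store's `n` and `m`.
#' @param cfg A [training_config()].
#' @param verbose Print one line per epoch.
#' @return A `dispersal_model`: list with the best `weights`, a `history`
#'   tibble (`epoch`, `train_loss`, `val_loss`), and the configuration.
#' @export
train_network <- function(store, spec, cfg = training_config(),
                          verbose = FALSE) {
  stopifnot(inherits(store, "dataset_store"), inherits(spec, "network_spec"))
  if (store$count == 0) {
    abort_config("Cannot train on an empty store.")
  }
  if (store$n != spec$n || store$m != spec$m || store$phased != spec$phased) {
    abort_config(sprintf(
      "Store (n = %d, m = %d) does not match the network spec (n = %d, m = %d).",
      store$n, store$m, spec$n, spec$m
    ))
  }
  records <- store$records
  k_extract <- cfg$k_extract %||% spec$n_pairs
  check_number(k_extract, "k_extract", min = 1, max = spec$n_pairs,
               integer = TRUE)

  # Split by simulation: records from one simulation share sigma_f exactly.
  sim_key <- vapply(records, function(r) sprintf("%.12g", r$sigma_f), "")
  sims <- unique(sim_key)
  n_val_sims <- floor(length(sims) * cfg$validation_fraction)
  val_sims <- if (n_val_sims > 0) {
    with_seed_(derive_seed(cfg$seed, 1L), sample(sims, n_val_sims))
  } else {
    character()
  }
  is_val <- sim_key %in% val_sims
  train_idx <- which(!is_val)
  val_idx <- which(is_val)

  targets <- vapply(records[train_idx], function(r) r$sigma_true, numeric(1))
  nt <- normalize_targets(targets, transform = cfg$target_transform)
  dist_scale <- if (is.finite(store$habitat_width)) store$habitat_width else {
    pairs <- enumerate_pairs(spec$n)
    max(vapply(records, function(r) max(all_pair_distances(r$locations, pairs)),
               numeric(1)))
  }
  weights <- init_weights(spec, seed = derive_seed(cfg$seed, 2L),
                          norm = nt$constants, dist_scale = dist_scale)

  val_loss_fun <- function(w, idx) {
    if (length(idx) == 0) return(NA_real_)
    pairs <- enumerate_pairs(spec$n)
    mean(vapply(records[idx], function(r) {
      dists <- all_pair_distances(r$locations, pairs)
      yhat <- net_forward_cache(r$genotypes$counts, dists, w, pairs)$yhat_norm
      (yhat - to_norm_scale(r$sigma_true, w))^2
    }, numeric(1)))
  }

  state <- NULL
  best <- list(weights = weights, val = Inf, epoch = 0L)
  history <- vector("list", cfg$max_epochs)
  stale <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed_(derive_seed(cfg$seed, 100L + epoch),
                      sample(train_idx))
    batch_starts <- seq(1L, length(ord), by = cfg$batch_size)
    epoch_loss <- 0
    for (bi in seq_along(batch_starts)) {
      ids <- ord[batch_starts[bi]:min(batch_starts[bi] + cfg$batch_size - 1L,
                                      length(ord))]
      batch <- records[ids]
      if (cfg$augment_permute) {
        batch <- with_seed_(
          derive_seed(cfg$seed, 20000L + 1000L * epoch + bi),
          lapply(batch, function(r) permute_record(r, sample.int(spec$n)))
        )
      }
      sel <- select_extract_pairs(
        enumerate_pairs(spec$n), k_extract,
        rng_seed = derive_seed(cfg$seed, 10000L + 1000L * epoch + bi)
      )
      step <- gated_training_step(batch, weights, sel,
                                  state = state,
                                  learning_rate = cfg$learning_rate,
                                  weight_decay = cfg$weight_decay)
      weights <- step$weights
      state <- step$state
      epoch_loss <- epoch_loss + step$loss * length(ids)
    }
    epoch_loss <- epoch_loss / length(ord)
    vl <- val_loss_fun(weights, val_idx)
    monitor <- if (is.na(vl)) epoch_loss else vl
    if (monitor < best$val) {
      best <- list(weights = weights, val = monitor, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = epoch_loss,
                                       val_loss = vl)
    if (verbose) {
      message(sprintf("epoch %3d: train %.5f val %s%s", epoch, epoch_loss,
                      ifelse(is.na(vl), "-", sprintf("%.5f", vl)),
                      if (stale == 0L) " *" else ""))
    }
    if (stale >= cfg$patience) break
  }
  structure(
    list(
      weights = best$weights,
      history = dplyr::bind_rows(history),
      best_epoch = best$epoch,
      cfg = cfg,
      spec = spec,
      n_train = length(train_idx),
      n_val = length(val_idx)
    ),
    class = "dispersal_model"
  )
}

#' @export
print.dispersal_model <- function(x, ...) {
  cat(sprintf("<dispersal_model> trained %d epoch(s), best at epoch %d\n",
              nrow(x$history), x$best_epoch))
  cat(sprintf("  train/validation datasets: %d/%d\n", x$n_train, x$n_val))
  invisible(x)
}

#' Predict sigma for new datasets
#'
#' @param object A `dispersal_model` (or pass `model_weights` to
#'   [net_forward()] directly for a single dataset).
#' @param newdata A `dispersal_dataset`, a list of them, or a
#'   `dataset_store`.
#' @param ... Unused.
#' @return A tibble with one row per dataset: `dataset`, `sigma_hat`, and
#'   `sigma_true` where known.
#' @export
predict.dispersal_model <- function(object, newdata, ...) {
  recs <- as_record_list(newdata)
  tibble::tibble(
    dataset = seq_along(recs),
    sigma_true = vapply(recs, function(r) r$sigma_true %||% NA_real_,
                        numeric(1)),
    sigma_hat = vapply(recs, function(r)
      net_forward(r$genotypes, r$locations, object$weights), numeric(1))
  )
}

as_record_list <- function(newdata) {
  if (inherits(newdata, "dataset_store")) {
    if (newdata$count == 0) {
      abort_config("Cannot evaluate on an empty store.",
                   class = "dispersr_error_empty_input")
    }
    newdata$records
  } else if (inherits(newdata, "dispersal_dataset")) {
    list(newdata)
  } else if (is.list(newdata)) {
    newdata
  } else {
    abort_config("`newdata` must be a dataset, list of datasets, or store.")
  }
}

#' Error metrics for dispersal estimates
#'
#' Computes the benchmarking metrics: mean relative absolute error
#' `MRAE = mean(|estimate - truth| / truth)`, root mean squared error, and
#' `r^2`, the squared Pearson correlation of truth and estimate. Undefined
#' estimates (`NA`, e.g. from the isolation-by-distance baseline when its
#' slope is non-positive) are excluded from the error metrics and counted
#' in `undefined_fraction`.
#'
#' @param truth,estimate Numeric vectors of true and estimated sigma.
#' @return A one-row tibble: `mrae`, `rmse`, `r2`, `n_eval`,
#'   `undefined_fraction`.
#' @export
metrics_report <- function(truth, estimate) {
  if (length(truth) != length(estimate) || length(truth) == 0) {
    abort_config("`truth` and `estimate` must be equal-length, non-empty vectors.",
                 class = "dispersr_error_empty_input")
  }
  ok <- is.finite(estimate)
  undefined_fraction <- mean(!ok)
  t_ok <- truth[ok]
  e_ok <- estimate[ok]
  r2 <- if (length(t_ok) >= 3 && stats::sd(e_ok) > 0 && stats::sd(t_ok) > 0) {
    stats::cor(t_ok, e_ok)^2
  } else {
    NA_real_
  }
  tibble::tibble(
    mrae = mean(abs(e_ok - t_ok) / t_ok),
    rmse = sqrt(mean((e_ok - t_ok)^2)),
    r2 = r2,
    n_eval = length(t_ok),
    undefined_fraction = undefined_fraction
  )
}

#' Evaluate a trained model on a held-out store
#'
#' @param model A `dispersal_model` or `model_weights`.
#' @param store A `dataset_store` (or list of datasets) with known labels.
#' @return A one-row [metrics_report()] tibble.
#' @export
evaluate_model <- function(model, store) {
  weights <- if (inherits(model, "dispersal_model")) model$weights else model
  stopifnot(inherits(weights, "model_weights"))
  recs <- as_record_list(store)
  truth <- vapply(recs, function(r) r$sigma_true, numeric(1))
  est <- vapply(recs, function(r)
    net_forward(r$genotypes, r$locations, weights), numeric(1))
  metrics_report(truth, est)
}
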