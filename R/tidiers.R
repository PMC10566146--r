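#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an isolation-by-distance regression
#'
#' @param x An `ibd_regression`.
#' @param ... Unused.
#' @return One row per regression term (`intercept`, `log_distance` or
#'   `distance`) with its `estimate`.
#' @method tidy ibd_regression
#' @export
tidy.ibd_regression <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", if (x$dimension == "2D") "log_distance" else "distance"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname tidy.ibd_regression
#' @method glance ibd_regression
#' @export
glance.ibd_regression <- function(x, ...) {
  tibble::tibble(
    sigma_hat = x$sigma_hat,
    slope = x$slope,
    intercept = x$intercept,
    density = x$density,
    n_pairs = x$n_used,
    n_zero_excluded = x$n_zero_excluded,
    undefined = is.na(x$sigma_hat)
  )
}

#' Tidy a trained dispersal model
#'
#' @param x A `dispersal_model`.
#' @param ... Unused.
#' @return The per-epoch training history as a tibble.
#' @method tidy dispersal_model
#' @export
tidy.dispersal_model <- function(x, ...) {
  x$history
}

#' @rdname tidy.dispersal_model
#' @method glance dispersal_model
#' @export
glance.dispersal_model <- function(x, ...) {
  best <- x$history[x$best_epoch, ]
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    train_loss = best$train_loss,
    val_loss = best$val_loss,
    n_train = x$n_train,
    n_val = x$n_val,
    learning_rate = x$cfg$learning_rate,
    k_extract = x$cfg$k_extract %||% x$spec$n_pairs
  )
}

#' Plot the training history of a dispersal model
#'
#' @param object A `dispersal_model`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch.
#' @method autoplot dispersal_model
#' @export
autoplot.dispersal_model <- function(object, ...) {
  df <- tidyr_longer_history(object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "epoch", y = "mean squared error (normalised sigma)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

tidyr_longer_history <- function(history) {
  out <- rbind(
    data.frame(epoch = history$epoch, loss = history$train_loss, set = "train"),
    data.frame(epoch = history$epoch, loss = history$val_loss, set = "validation")
  )
  tibble::as_tibble(out[is.finite(out$loss), ])
}

#' Plot an isolation-by-distance regression
#'
#' @param object An `ibd_regression`.
#' @param ... Unused.
#' @return A ggplot of per-pair genetic statistic against (log) distance
#'   with the fitted least-squares line.
#' @method autoplot ibd_regression
#' @export
autoplot.ibd_regression <- function(object, ...) {
  pts <- object$points[object$points$distance > 0, ]
  if (object$dimension == "2D") {
    pts$xval <- log(pts$distance)
    xlab <- "log geographic distance"
  } else {
    pts$xval <- pts$distance
    xlab <- "geographic distance"
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$xval, y = .data$a_hat)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(x = xlab, y = "pairwise statistic (a-hat)") +
    ggplot2::theme_minimal()
}

#' Plot predicted against true sigma
#'
#' @param predictions A tibble from [predict.dispersal_model()] with
#'   `sigma_true` and `sigma_hat` columns.
#' @return A ggplot with the identity line for reference.
#' @export
plot_predictions <- function(predictions) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$sigma_true, y = .data$sigma_hat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "true sigma", y = "estimated sigma") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
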