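#' Fit a mental-engagement ConvNet classifier
#'
#' The main fitting function: builds the requested fusion network, z-scores
#' every input channel with training-set statistics, carves a seeded
#' stratified validation split to monitor early stopping, and trains with
#' Adam on the categorical cross-entropy. Segments are 2D arrays
#' (window samples x channels); the data-level network consumes them as
#' one array, the feature-level network routes each sensor group through
#' its own branch.
#'
#' @param segments a [segment_set] containing both classes.
#' @param arch,sensors,... forwarded to [model_spec()]; alternatively pass
#'   a ready [model_spec] via `spec`.
#' @param spec optional [model_spec]; overrides `arch`/`sensors`/`...`.
#' @param verbose print per-epoch losses.
#' @return an object of class `engagement_net` with elements `net`,
#'   `spec`, `scaling` (per-channel mean/sd), `history` (per-epoch
#'   losses), `best_epoch` and `levels` (class coding).
#' @export
engagement_net <- function(segments, arch = "data_fusion",
                           sensors = "eeg+spr+ecg", ...,
                           spec = NULL, verbose = FALSE) {
  stopifnot(inherits(segments, "segment_set"))
  if (is.null(spec))
    spec <- model_spec(arch = arch, sensors = sensors,
                       window_samples = dim(segments$data)[2], ...)
  y <- segments$label
  if (length(unique(y)) < 2)
    stop("training error: both classes must be present in the training set")
  if (dim(segments$data)[2] != spec$window_samples)
    stop("shape error: segment window does not match spec$window_samples")

  x <- aperm(segments$data, c(2, 1, 3))   # [win, N, 8]
  scaling <- channel_scaling(x)
  x <- apply_scaling(x, scaling)

  set.seed(spec$seed)
  n <- dim(x)[2]
  val_idx <- integer(0)
  if (spec$val_fraction > 0 && n >= 10) {
    for (cl in unique(y)) {
      ii <- which(y == cl)
      k <- max(1L, round(spec$val_fraction * length(ii)))
      val_idx <- c(val_idx, sample(ii, k))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  net <- build_network(spec)
  set.seed(spec$seed + 1L)   # shuffling / dropout substream
  fit <- net_train_loop(net,
                        x[, tr_idx, , drop = FALSE], y[tr_idx], spec,
                        xval = if (length(val_idx))
                          x[, val_idx, , drop = FALSE] else NULL,
                        yval = y[val_idx], verbose = verbose)
  structure(list(net = fit$net, spec = spec, scaling = scaling,
                 history = fit$history, best_epoch = fit$best_epoch,
                 n_train = length(tr_idx), n_val = length(val_idx),
                 levels = c(high_engagement = 0L, low_engagement = 1L)),
            class = "engagement_net")
}

channel_scaling <- function(x) {
  mu <- numeric(dim(x)[3]); sd_ <- numeric(dim(x)[3])
  for (c in seq_len(dim(x)[3])) {
    mu[c] <- mean(x[, , c])
    sd_[c] <- stats::sd(x[, , c])
    if (sd_[c] == 0 || !is.finite(sd_[c])) sd_[c] <- 1
  }
  list(mean = mu, sd = sd_)
}

apply_scaling <- function(x, scaling) {
  for (c in seq_len(dim(x)[3]))
    x[, , c] <- (x[, , c] - scaling$mean[c]) / scaling$sd[c]
  x
}

#' @export
print.engagement_net <- function(x, ...) {
  cat(sprintf("Mental-engagement ConvNet (%s, sensors: %s)\n",
              x$spec$arch, x$spec$sensors))
  cat(sprintf("  %s trainable parameters, window %d samples\n",
              format(count_trainable_parameters(x$net), big.mark = ","),
              x$spec$window_samples))
  cat(sprintf("  trained on %d segments (%d held out for monitoring), best epoch %d\n",
              x$n_train, x$n_val, x$best_epoch))
  invisible(x)
}

#' @export
summary.engagement_net <- function(object, ...) {
  ops <- all_ops(object$net)
  rows <- lapply(ops, function(op) {
    np <- sum(vapply(c("W", "b", "gamma", "beta"),
                     function(f) length(op[[f]]), 1L))
    data.frame(layer = op$type, params = np)
  })
  tab <- do.call(rbind, rows)
  out <- list(spec = object$spec, layers = tab,
              total_params = count_trainable_parameters(object$net),
              history = object$history)
  class(out) <- "summary.engagement_net"
  out
}

#' @export
print.summary.engagement_net <- function(x, ...) {
  cat(sprintf("%s / %s: %s trainable parameters\n", x$spec$arch,
              x$spec$sensors, format(x$total_params, big.mark = ",")))
  print(x$layers, row.names = FALSE)
  invisible(x)
}

#' Predict engagement classes for new segments
#'
#' @param object a fitted [engagement_net].
#' @param newdata a [segment_set] (or an array segments x window x 8).
#' @param type `"class"` for hard labels (0 high / 1 low engagement, ties
#'   resolved toward the lower class index) or `"prob"` for the softmax
#'   probabilities (rows sum to 1).
#' @param ... unused.
#' @return integer labels or a probability matrix.
#' @export
predict.engagement_net <- function(object, newdata, type = c("class", "prob"),
                                   ...) {
  type <- match.arg(type)
  dat <- if (inherits(newdata, "segment_set")) newdata$data else newdata
  if (length(dim(dat)) != 3 || dim(dat)[2] != object$spec$window_samples)
    stop("shape error: newdata segments do not match the fitted window")
  x <- aperm(dat, c(2, 1, 3))
  x <- apply_scaling(x, object$scaling)
  p <- net_predict_prob(object$net, x, object$spec$batch_size)
  colnames(p) <- names(object$levels)
  if (type == "prob") return(p)
  as.integer(p[, 2] > p[, 1])   # ties go to class 0
}

#' @export
coef.engagement_net <- function(object, ...) {
  ops <- all_ops(object$net)
  out <- list()
  for (i in seq_along(ops)) {
    op <- ops[[i]]
    for (f in c("W", "b", "gamma", "beta")) {
      if (!is.null(op[[f]]))
        out[[sprintf("op%02d_%s_%s", i, op$type, f)]] <- op[[f]]
    }
  }
  out
}

#' @export
plot.engagement_net <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", col = "steelblue",
                 xlab = "epoch", ylab = "loss",
                 ylim = range(c(h$train_loss, h$val_loss)),
                 main = "training history", ...)
  graphics::lines(h$epoch, h$val_loss, col = "firebrick")
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "monitored"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
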