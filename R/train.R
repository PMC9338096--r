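#' Training configuration
#'
#' Mean-squared-error minimization on normalized contact positions with
#' Adam. The optimizer defaults are the standard ones for this task:
#' initial learning rate 1e-4, first momentum 0.9, second momentum 0.999.
#' There is no learning-rate schedule, early stopping or augmentation;
#' training runs for `epochs` epochs and the weights from the epoch with
#' the minimum validation loss are kept. L2 regularization enters through
#' the model spec (a per-layer weight penalty in the loss), not through
#' the optimizer.
#'
#' @param epochs Number of epochs.
#' @param batch_size Mini-batch size (default 32).
#' @param lr Initial Adam learning rate.
#' @param beta1,beta2 Adam first/second momentum.
#' @param val_fraction Fraction of curves held out for validation when
#'   [train_model()] is asked to split internally.
#' @param seed Integer seed for shuffling (weight initialization is seeded
#'   at model construction).
#' @return A list of class `fp_train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, lr = 1e-4,
                         beta1 = 0.9, beta2 = 0.999, val_fraction = 0.3,
                         seed = 0L) {
  if (lr <= 0) stop_fp("lr must be positive", class = "fp_validation_error")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop_fp("val_fraction must lie in (0, 1)", class = "fp_validation_error")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 loss = "mse"),
            class = "fp_train_config")
}

#' Random train/validation split
#'
#' Disjoint, exhaustive and reproducible under `seed`. The training side
#' gets `round(n * (1 - val_fraction))` curves, the validation side the
#' rest.
#'
#' @param curves List of curves.
#' @param val_fraction Fraction held out for validation, in (0, 1).
#' @param seed Integer seed.
#' @return A list with `train`, `val` and the index vectors `idx_train`,
#'   `idx_val`.
#' @export
split_dataset <- function(curves, val_fraction, seed = 0L) {
  n <- length(curves)
  if (n < 2L) stop_fp("need at least 2 curves to split", class = "fp_validation_error")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop_fp("val_fraction must lie in (0, 1)", class = "fp_validation_error")
  n_train <- round(n * (1 - val_fraction))
  if (n_train < 1L || n_train > n - 1L)
    stop_fp("val_fraction = %g leaves an empty split side for n = %d",
            val_fraction, n, class = "fp_validation_error")
  perm <- with_seed(seed, sample.int(n))
  idx_train <- sort(perm[seq_len(n_train)])
  idx_val <- sort(perm[(n_train + 1L):n])
  list(train = curves[idx_train], val = curves[idx_val],
       idx_train = idx_train, idx_val = idx_val)
}

as_xy <- function(data, L) {
  if (is.list(data) && !is.null(data$x) && !is.null(data$y))
    return(data[c("x", "y", "transforms", "zc")])
  prepare_dataset(data, L)
}

#' Train a contact-point regression network
#'
#' Runs `cfg$epochs` epochs of mini-batch MSE minimization with Adam on
#' the normalized signals and labels, recording the training and
#' validation loss per epoch, and returns the model with the weights of
#' the epoch whose validation loss was minimal. Batch normalization
#' layers use batch statistics (and update running averages) during
#' training and running statistics for the per-epoch validation loss and
#' all later inference. Validation curves never contribute gradients.
#' Fully seeded: given the same platform, model seed and `cfg$seed`, the
#' run is deterministic.
#'
#' @param model An untrained (or warm) `fp_model`.
#' @param train_data,val_data Lists of [labeled_curve()]s, or prepared
#'   lists as returned by [prepare_dataset()].
#' @param cfg A [train_config()].
#' @param keep_last Also keep the final-epoch weights in the returned
#'   object (`$weights_last`).
#' @param verbose Print one line per `verbose` epochs (0 = silent).
#' @return An object of class `fp_fit`: `model` (best-epoch weights),
#'   `history` (data frame: epoch, train_mse, val_mse), `best_epoch`,
#'   `config`, and the validation errors in nm at the best epoch.
#' @export
train_model <- function(model, train_data, val_data, cfg = train_config(),
                        keep_last = FALSE, verbose = 0L) {
  stopifnot(inherits(model, "fp_model"), inherits(cfg, "fp_train_config"))
  tr <- as_xy(train_data, model$input_length)
  va <- as_xy(val_data, model$input_length)
  if (anyNA(tr$y) || anyNA(va$y))
    stop_fp("all training and validation curves must be labeled",
            class = "fp_validation_error")
  n <- nrow(tr$x)
  refs <- param_refs(model$layers)
  st <- adam_init(refs)
  hist_train <- hist_val <- numeric(cfg$epochs)
  best <- Inf; best_epoch <- NA_integer_; best_w <- NULL
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      bl <- numeric(0)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        ix <- perm[start:min(start + cfg$batch_size - 1L, n)]
        xb <- tr$x[ix, , drop = FALSE]
        yb <- tr$y[ix]
        B <- nrow(xb); L <- ncol(xb)
        x0 <- matrix(as.vector(t(xb)), B * L, 1L)
        fw <- seq_forward(model$layers, x0, B, L, training = TRUE)
        pred <- drop(fw$out)
        loss <- mean((pred - yb)^2)
        if (!is.finite(loss))
          stop_fp("training diverged (non-finite loss) at epoch %d", ep,
                  class = "fp_diverged_error")
        bl <- c(bl, loss)
        dout <- matrix(2 * (pred - yb) / B, B, 1L)
        seq_backward(model$layers, fw$caches, dout, B)
        st <- adam_step(refs, st, cfg$lr, cfg$beta1, cfg$beta2)
      }
      hist_train[ep] <- mean(bl)
      vp <- model_predict_norm(model, va$x)
      hist_val[ep] <- mean((vp - va$y)^2)
      if (!is.finite(hist_val[ep]))
        stop_fp("training diverged (non-finite validation loss) at epoch %d",
                ep, class = "fp_diverged_error")
      if (hist_val[ep] < best) {
        best <- hist_val[ep]
        best_epoch <- ep
        best_w <- get_weights(model)
      }
      if (verbose > 0L && ep %% verbose == 0L)
        message(sprintf("epoch %4d  train mse %.3e  val mse %.3e", ep,
                        hist_train[ep], hist_val[ep]))
    }
  })
  weights_last <- if (keep_last) get_weights(model) else NULL
  set_weights(model, best_w)
  # validation errors in physical units at the best epoch
  vp <- model_predict_norm(model, va$x)
  zc_pred <- vapply(seq_along(vp), function(i)
    as.numeric(decode_prediction(vp[i], va$transforms[[i]])), numeric(1))
  structure(list(model = model,
                 history = data.frame(epoch = seq_len(cfg$epochs),
                                      train_mse = hist_train,
                                      val_mse = hist_val),
                 best_epoch = best_epoch, config = cfg,
                 val_zc = va$zc, val_zc_pred = zc_pred,
                 weights_last = weights_last),
            class = "fp_fit")
}

#' @export
print.fp_fit <- function(x, ...) {
  err <- x$val_zc - x$val_zc_pred
  cat(sprintf("<trained %s>\n", x$model$arch))
  cat(sprintf("  epochs: %d, best epoch: %d (val mse %.4e)\n",
              nrow(x$history), x$best_epoch, min(x$history$val_mse)))
  cat(sprintf("  validation zc - zc_pred: %.3f +/- %.3f nm (n = %d)\n",
              mean(err), stats::sd(err), length(err)))
  invisible(x)
}

#' @export
summary.fp_fit <- function(object, ...) {
  err <- object$val_zc - object$val_zc_pred
  out <- list(arch = object$model$arch,
              n_params = n_params(object$model),
              epochs = nrow(object$history),
              best_epoch = object$best_epoch,
              best_val_mse = min(object$history$val_mse),
              val_mean_error_nm = mean(err),
              val_sd_error_nm = stats::sd(err),
              val_mean_abs_error_nm = mean(abs(err)),
              n_val = length(err))
  class(out) <- "summary.fp_fit"
  out
}

#' @export
print.summary.fp_fit <- function(x, ...) {
  cat(sprintf("Trained %s (%s parameters)\n", x$arch,
              format(x$n_params, big.mark = ",")))
  cat(sprintf("  %d epochs, best epoch %d, best validation mse %.4e\n",
              x$epochs, x$best_epoch, x$best_val_mse))
  cat(sprintf("  validation zc - zc_pred: mean %.3f nm, sd %.3f nm, mean |err| %.3f nm (n = %d)\n",
              x$val_mean_error_nm, x$val_sd_error_nm, x$val_mean_abs_error_nm,
              x$n_val))
  invisible(x)
}

#' @export
plot.fp_fit <- function(x, log = "y", ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_mse, h$val_mse), type = "l",
                    lty = 1, col = c(1, 2), xlab = "epoch", ylab = "mse loss",
                    log = log, ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), col = c(1, 2), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Predict contact points from a fitted model
#'
#' @param object An `fp_fit`.
#' @param newdata A single curve or a list of curves.
#' @param ... Unused.
#' @return Numeric vector of predicted contact positions (nm) with an
#'   `"out_of_range"` attribute flagging extrapolated predictions.
#' @export
predict.fp_fit <- function(object, newdata, ...) {
  predict_contact(object, newdata)
}

#' @export
residuals.fp_fit <- function(object, ...) {
  object$val_zc - object$val_zc_pred
}
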