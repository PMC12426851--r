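#' Model configuration
#'
#' @param variant `"independent"` (the fully-independent ForeSIIN: one GRU
#'   and one head per feature, combined additively), `"shared_head"`
#'   (per-feature GRUs, one shared head), or `"pooled_gru"` (a conventional
#'   GRU over the pooled 40-dimensional input).
#' @param hidden Hidden state size per recurrent branch (default 8 for the
#'   per-feature variants; 32 is a sensible pooled default).
#' @param head Width of the single hidden layer in each head.
#' @param lambda Branch-loss weight of the composite loss (independent
#'   variant only); 0 reduces to plain cross-entropy on the combined logit.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param restarts Independent training restarts from different
#'   initializations; the fit with the best validation loss wins (default 2
#'   for the independent variant, guarding against initializations that
#'   strand the optimizer in its early plateau; 1 elsewhere).
#' @param seed Seed controlling initialization and batch shuffling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(variant = c("independent", "shared_head", "pooled_gru"),
                         hidden = NULL, head = NULL, lambda = 1,
                         lr = 0.01, batch_size = 64L, max_epochs = 150L,
                         patience = 25L, restarts = NULL, seed = 1L) {
  variant <- match.arg(variant)
  hidden <- hidden %||% if (variant == "pooled_gru") 32L else 8L
  head <- head %||% if (variant == "pooled_gru") 16L else 8L
  restarts <- restarts %||% if (variant == "independent") 2L else 1L
  stopifnot(hidden >= 1, head >= 1, lambda >= 0, patience >= 1,
            batch_size >= 1, max_epochs >= 1, lr > 0, restarts >= 1)
  structure(list(variant = variant, hidden = as.integer(hidden),
                 head = as.integer(head), lambda = lambda, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "model_config")
}

variant_code <- function(variant)
  match(variant, c("independent", "shared_head", "pooled_gru")) - 1L

#' Initialize model parameters
#'
#' Recurrent and head weights are uniform on `[-1/sqrt(h), 1/sqrt(h)]`
#' (biases included); the final combining weights of the independent variant
#' start small (`+-0.05`) and its bias at the empty-model value 0, so the
#' initial prediction is near 0.5. The update-gate bias of every GRU starts
#' at +2.5 (gate ~0.92), a chrono-style initialization that gives the
#' recurrence a memory horizon spanning the 24-month window from the first
#' step — with a neutral gate the final state would only reflect the last
#' couple of months, and gradients through earlier observations vanish.
#' Deterministic given `config$seed`.
#'
#' @param config A [model_config()].
#' @param n_features Number of features m (default 40).
#' @return An object of class `foresiin_params` holding the flat parameter
#'   vector and its dimensions.
#' @export
init_params <- function(config, n_features = 40L) {
  m <- as.integer(n_features)
  h <- config$hidden; k <- config$head
  vc <- variant_code(config$variant)
  P <- fsn_param_count(vc, h, k, m)
  gate_bias <- 2.5
  par <- with_seed(stage_seed(config$seed, 5L), {
    s <- 1 / sqrt(h)
    p <- runif(P, -s, s)
    # bz sits after Wr/Wz/Wc (3hd), Ur/Uz/Uc (3h^2) and br (h) in each block
    bz_at <- function(block_off, d) block_off + 3 * h * d + 3 * h * h + h
    if (vc == 2L) {
      p[bz_at(0L, m) + 1:h] <- p[bz_at(0L, m) + 1:h] + gate_bias
    } else {
      gru1 <- 6 * h + 3 * h * h
      stride <- if (vc == 0L) gru1 + k * h + 2 * k + 1 else gru1
      for (j in seq_len(m) - 1L)
        p[bz_at(j * stride, 1L) + 1:h] <-
          p[bz_at(j * stride, 1L) + 1:h] + gate_bias
    }
    if (vc == 0L) {
      tail_idx <- (P - m):P  # combining weights + bias
      p[tail_idx] <- runif(m + 1L, -0.05, 0.05)
      p[P] <- 0
    }
    p
  })
  structure(list(par = par, config = config, m = m), class = "foresiin_params")
}

#' @export
print.foresiin_params <- function(x, ...) {
  cat(sprintf("<foresiin_params> variant=%s, m=%d, hidden=%d, %d parameters\n",
              x$config$variant, x$m, x$config$hidden, length(x$par)))
  invisible(x)
}

# Coerce sequences to the (T, m, n) tensor the C++ core expects.
# Accepts a summarized_cohort (scaled), an n x T x m array, or a T x m matrix.
as_input_tensor <- function(x, m_expected) {
  if (inherits(x, "summarized_cohort")) x <- x$values
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  d <- dim(x)
  if (is.null(d) || length(d) != 3L)
    stop("dimension error: sequences must be an n x T x m array")
  if (d[3] != m_expected || d[2] < 1L)
    stop(sprintf("dimension error: sequences are %d x %d x %d, model expects %d features",
                 d[1], d[2], d[3], m_expected))
  aperm(x, c(2, 3, 1))  # (T, m, n)
}

#' Run the model forward
#'
#' @param params A `foresiin_params` (initialized or fitted).
#' @param x Scaled/imputed sequences: a `summarized_cohort` after
#'   [scale_and_impute()], an n x T x m array, or a single T x m matrix.
#' @return A `risk_output`: list with `logit` (z), `score` (`sigmoid(z)`),
#'   and, for variants with independent heads, `effects` (n x m matrix of
#'   per-feature contributions `e_j = w_j u_j` with `z = b + sum_j e_j`) and
#'   `branch` (head outputs `u_j`).
#' @export
forward <- function(params, x) {
  tx <- as_input_tensor(x, params$m)
  d <- dim(tx)
  res <- fsn_apply(params$par, as.numeric(tx), as.integer(d),
                   variant_code(params$config$variant),
                   params$config$hidden, params$config$head,
                   NULL, params$config$lambda, FALSE)
  out <- list(logit = res$logit, score = plogis(res$logit),
              effects = res$effects, branch = res$branch)
  if (!is.null(out$effects))
    colnames(out$effects) <- colnames(out$branch) <-
      dimnames(if (inherits(x, "summarized_cohort")) x$values else x)[[3]]
  structure(out, class = "risk_output")
}

#' Predict risk scores
#'
#' Evaluation-mode forward pass; scores are uncalibrated probabilities of a
#' stroke within one year of AF onset. Deterministic and order-invariant.
#'
#' @param object A `foresiin_params`.
#' @param x Sequences as in [forward()].
#' @param ... Unused.
#' @return A `risk_output` (see [forward()]).
#' @export
predict.foresiin_params <- function(object, x, ...) forward(object, x)

#' Composite training loss
#'
#' `L = BCE(sigmoid(z), y) + lambda * mean_j BCE(sigmoid(u_j), y)`, averaged
#' over patients: each branch output `u_j` is treated as its own
#' sub-classifier and trained against the shared label — the only channel
#' through which branches communicate. `lambda = 0` reduces to plain binary
#' cross-entropy on the combined logit. Variants without per-feature heads
#' use the plain term only.
#'
#' @param output A `risk_output` from [forward()].
#' @param labels 0/1 labels.
#' @param lambda Branch-loss weight.
#' @return Scalar loss.
#' @export
composite_loss <- function(output, labels, lambda = 1) {
  if (!all(labels %in% c(0, 1)))
    stop("validation error: labels must be 0 or 1")
  bce <- function(z, y) mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
  l <- bce(output$logit, labels)
  if (lambda > 0 && !is.null(output$branch)) {
    lb <- mean(vapply(seq_len(ncol(output$branch)), function(j)
      bce(output$branch[, j], labels), numeric(1)))
    l <- l + lambda * lb
  }
  l
}

#' Train a model with mini-batch Adam and early stopping
#'
#' Minimizes the composite loss on the (down-sampled) training set with the
#' Adam optimizer, monitoring the validation loss of the combined prediction
#' (the plain cross-entropy term; the per-branch terms act as a training
#' regularizer, and their calibration to the down-sampled class prior would
#' otherwise mask genuine improvements in the prediction) after every epoch.
#' Training stops when the validation loss has not improved for `patience`
#' epochs (or at `max_epochs`), and the parameters of the best validation
#' epoch are returned. Fully seeded: identical seeds give identical
#' histories.
#'
#' @param params Initial `foresiin_params` from [init_params()].
#' @param x_train,y_train Training sequences (n x T x m array or scaled
#'   `summarized_cohort`) and 0/1 labels.
#' @param x_val,y_val Validation sequences and labels.
#' @param config Optional [model_config()] override (defaults to the one in
#'   `params`).
#' @return List with `params` (fitted, at the best validation epoch) and
#'   `history` (`train_history`: per-epoch losses, best epoch, stopping
#'   reason).
#' @export
train_model <- function(params, x_train, y_train, x_val, y_val,
                        config = params$config) {
  fits <- vector("list", config$restarts)
  for (r in seq_len(config$restarts)) {
    if (r == 1L) {
      par_r <- params
      cfg_r <- config
    } else {
      # fresh initialization and batch stream per restart
      cfg_r <- config
      cfg_r$seed <- stage_seed(config$seed, 100L + r)
      par_r <- init_params(cfg_r, params$m)
      cfg_r$restarts <- 1L
    }
    fits[[r]] <- train_once(par_r, x_train, y_train, x_val, y_val, cfg_r)
  }
  winner <- which.min(vapply(fits, function(f) min(f$history$val_loss),
                             numeric(1)))
  fit <- fits[[winner]]
  fit$history$restart <- winner
  fit$params$config <- config
  fit
}

train_once <- function(params, x_train, y_train, x_val, y_val, config) {
  tx <- as_input_tensor(x_train, params$m)
  vx <- as_input_tensor(x_val, params$m)
  stopifnot(dim(tx)[3] == length(y_train), dim(vx)[3] == length(y_val))
  vc <- variant_code(config$variant)
  h <- config$hidden; k <- config$head
  n <- dim(tx)[3]
  par <- params$par
  mu <- numeric(length(par)); vv <- numeric(length(par))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  vx_num <- as.numeric(vx); vdim <- as.integer(dim(vx))
  tloss <- vloss <- numeric(0)
  best <- Inf; best_par <- par; best_epoch <- 0L
  reason <- "max_epochs"

  with_seed(stage_seed(config$seed, 6L), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        xb <- tx[, , b, drop = FALSE]
        res <- fsn_apply(par, as.numeric(xb), as.integer(dim(xb)), vc, h, k,
                         as.numeric(y_train[b]), config$lambda, TRUE)
        if (!is.finite(res$loss))
          stop("non-finite training loss at epoch ", epoch,
               "; try a smaller learning rate")
        g <- res$grad
        step <- step + 1L
        mu <- b1 * mu + (1 - b1) * g
        vv <- b2 * vv + (1 - b2) * g^2
        mhat <- mu / (1 - b1^step)
        vhat <- vv / (1 - b2^step)
        par <- par - config$lr * mhat / (sqrt(vhat) + eps)
        ep_loss <- ep_loss + res$loss * length(b)
      }
      tloss[epoch] <- ep_loss / n
      vres <- fsn_apply(par, vx_num, vdim, vc, h, k,
                        as.numeric(y_val), 0, FALSE)
      vloss[epoch] <- vres$loss
      if (vres$loss < best - 1e-9) {
        best <- vres$loss; best_par <- par; best_epoch <- epoch
      } else if (epoch - best_epoch >= config$patience) {
        reason <- "early_stopping"
        break
      }
    }
  })

  fitted <- params
  fitted$par <- best_par
  fitted$config <- config
  history <- structure(list(train_loss = tloss, val_loss = vloss,
                            best_epoch = best_epoch,
                            stopped_after = length(vloss),
                            reason = reason),
                       class = "train_history")
  list(params = fitted, history = history)
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("<train_history> %d epochs (%s), best validation loss %.4f at epoch %d\n",
              x$stopped_after, x$reason, min(x$val_loss), x$best_epoch))
  invisible(x)
}

#' Save / load fitted parameters
#'
#' The archive is a single RDS file holding the flat parameter vector, the
#' model configuration and the feature count.
#'
#' @param params A `foresiin_params`.
#' @param path File path.
#' @return `path` (write) or the restored `foresiin_params` (read).
#' @export
save_params <- function(params, path) {
  saveRDS(unclass(params), path)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  structure(readRDS(path), class = "foresiin_params")
}
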