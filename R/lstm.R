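#' Recurrent classifier configuration
#'
#' Three-layer many-to-one recurrent network: a linear input map, one LSTM
#' layer (50 hidden units, dropout 0.4 applied to the final hidden state
#' during training), and a linear softmax output over the two outcome
#' classes. Trained with the Adam optimizer on cross-entropy loss; model
#' selection uses validation accuracy with early stopping.
#'
#' @param hidden_dim LSTM hidden (and input-embedding) dimension.
#' @param dropout Dropout probability on the final hidden state in training.
#' @param learning_rate Adam step size.
#' @param max_epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @return An object of class `rnn_config`.
#' @export
rnn_config <- function(hidden_dim = 50L, dropout = 0.4, learning_rate = 0.01,
                       max_epochs = 60L, batch_size = 128L, patience = 10L,
                       seed = 1L) {
  if (dropout < 0 || dropout >= 1) {
    abort("`dropout` must lie in [0, 1).", class = "icbtri_config_error")
  }
  structure(
    list(hidden_dim = as.integer(hidden_dim), dropout = dropout,
         learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         seed = as.integer(seed)),
    class = "rnn_config"
  )
}

bias_add <- function(m, v) m + rep(v, each = nrow(m))
sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(d, hidden_dim) {
  H <- hidden_dim
  u <- function(nr, nc, r) matrix(runif(nr * nc, -r, r), nr, nc)
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1  # forget-gate bias at 1 eases gradient flow
  list(
    We = u(d, H, 1 / sqrt(d)), be = numeric(H),
    Wx = u(H, 4L * H, 1 / sqrt(H)), Wh = u(H, 4L * H, 1 / sqrt(H)), b = b,
    Wo = u(H, 2L, 1 / sqrt(H)), bo = numeric(2L)
  )
}

## Forward pass over a padded batch. x: B x T x d, lengths: B.
## Hidden/cell states are held through padded steps so the state after step T
## is each sequence's state at its own last valid step.
lstm_forward <- function(params, x, lengths, keep_cache = FALSE) {
  B <- dim(x)[1L]; T_ <- dim(x)[2L]; d <- dim(x)[3L]
  H <- ncol(params$We)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", T_) else NULL
  for (t in seq_len(T_)) {
    xt <- matrix(x[, t, ], B, d)
    m <- as.numeric(lengths >= t)
    e <- bias_add(xt %*% params$We, params$be)
    z <- bias_add(e %*% params$Wx + h %*% params$Wh, params$b)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    o <- sigmoid(z[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    if (keep_cache) {
      cache[[t]] <- list(xt = xt, e = e, i = i, f = f, o = o, g = g,
                         c_prev = cc, tc = tc, h_prev = h, m = m)
    }
    cc <- m * c_new + (1 - m) * cc
    h <- m * h_new + (1 - m) * h
  }
  list(h = h, cache = cache)
}

lstm_loss_grad <- function(params, x, lengths, y, dropout_mask = NULL) {
  B <- dim(x)[1L]
  fwd <- lstm_forward(params, x, lengths, keep_cache = TRUE)
  h_final <- fwd$h
  hd <- if (is.null(dropout_mask)) h_final else h_final * dropout_mask
  logits <- bias_add(hd %*% params$Wo, params$bo)
  logits <- logits - apply(logits, 1L, max)
  p <- exp(logits); p <- p / rowSums(p)
  loss <- -mean(log(pmax(p[cbind(seq_len(B), y + 1L)], 1e-12)))

  Y <- matrix(0, B, 2L); Y[cbind(seq_len(B), y + 1L)] <- 1
  dlogits <- (p - Y) / B
  g <- list(We = params$We * 0, be = params$be * 0, Wx = params$Wx * 0,
            Wh = params$Wh * 0, b = params$b * 0,
            Wo = crossprod(hd, dlogits), bo = colSums(dlogits))
  dh <- tcrossprod(dlogits, params$Wo)
  if (!is.null(dropout_mask)) dh <- dh * dropout_mask
  H <- ncol(params$We)
  dc <- matrix(0, B, H)
  for (t in rev(seq_along(fwd$cache))) {
    cc <- fwd$cache[[t]]
    m <- cc$m
    do_ <- dh * cc$tc
    dc_tot <- dc + (dh * cc$o) * (1 - cc$tc^2)
    di <- dc_tot * cc$g
    dg <- dc_tot * cc$i
    df <- dc_tot * cc$c_prev
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2)) * m
    g$Wx <- g$Wx + crossprod(cc$e, dz)
    g$Wh <- g$Wh + crossprod(cc$h_prev, dz)
    g$b <- g$b + colSums(dz)
    de <- tcrossprod(dz, params$Wx)
    g$We <- g$We + crossprod(cc$xt, de)
    g$be <- g$be + colSums(de)
    dh <- tcrossprod(dz, params$Wh) + (1 - m) * dh
    dc <- m * (dc_tot * cc$f) + (1 - m) * dc
  }
  list(loss = loss, grads = g, prob = p[, 2L])
}

adam_init <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Feature standardization fitted on training sequences (valid steps only).
## Interaction-count dimensions are log1p-transformed first.
fit_scaler <- function(x, lengths, log_counts) {
  d <- dim(x)[3L]
  valid <- matrix(FALSE, dim(x)[1L], dim(x)[2L])
  for (t in seq_len(dim(x)[2L])) valid[, t] <- lengths >= t
  mu <- numeric(d); sdv <- numeric(d)
  for (j in seq_len(d)) {
    v <- x[, , j][valid]
    if (log_counts) v <- log1p(v)
    mu[j] <- mean(v)
    sdv[j] <- max(sd(v), 1e-6)
  }
  list(mu = mu, sd = sdv, log_counts = log_counts)
}

apply_scaler <- function(x, scaler) {
  d <- dim(x)[3L]
  for (j in seq_len(d)) {
    v <- x[, , j]
    if (scaler$log_counts) v <- log1p(v)
    x[, , j] <- (v - scaler$mu[j]) / scaler$sd[j]
  }
  x
}

#' Train the recurrent reliable-improvement classifier
#'
#' Trains the many-to-one LSTM on prefix-augmented sequences (each client
#' contributes one example per observed review, all sharing the client's
#' end-of-treatment label), selects the epoch with the best validation
#' accuracy, and stops early when no improvement is seen for
#' `config$patience` epochs. Training is deterministic given the
#' configuration seed.
#'
#' @param train,validation `icbt_cohort` objects.
#' @param labels Label tibble from [label_cohort()] covering both cohorts.
#' @param feature_set One of `"Q"`, `"Qc"`, `"I"`, `"I+Q"`.
#' @param target_instrument `"phq9"` or `"gad7"` (one model per instrument).
#' @param config An [rnn_config()].
#' @return An object of class `icbt_rnn` with the learned parameters,
#'   feature scaler, training history and configuration.
#' @export
train_rnn <- function(train, validation, labels, feature_set = "Q",
                      target_instrument = "phq9", config = rnn_config()) {
  if (length(train) == 0L) {
    abort("empty training set.", class = "icbtri_config_error")
  }
  tr <- build_sequence_dataset(train, labels, feature_set, target_instrument)
  va <- build_sequence_dataset(validation, labels, feature_set,
                               target_instrument)
  if (va$dim != tr$dim) {
    abort("feature dimension mismatch between train and validation.",
          class = "icbtri_config_error")
  }
  log_counts <- feature_set %in% c("I", "I+Q")
  scaler <- fit_scaler(tr$x, tr$lengths, log_counts)
  xtr <- apply_scaler(tr$x, scaler)
  xva <- apply_scaler(va$x, scaler)

  withr::local_seed(config$seed)
  params <- lstm_init(tr$dim, config$hidden_dim)
  opt <- adam_init(params)
  n <- length(tr$y)
  keep <- 1 - config$dropout
  best <- list(acc = -Inf, params = params, epoch = 0L)
  history <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                            val_accuracy = numeric())
  stale <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    losses <- numeric(0L)
    for (start in seq(1L, n, by = config$batch_size)) {
      bi <- idx[start:min(start + config$batch_size - 1L, n)]
      xb <- xtr[bi, , , drop = FALSE]
      mask <- if (config$dropout > 0) {
        matrix(rbinom(length(bi) * config$hidden_dim, 1L, keep),
               length(bi), config$hidden_dim) / keep
      } else {
        NULL
      }
      res <- lstm_loss_grad(params, xb, tr$lengths[bi], tr$y[bi], mask)
      if (!is.finite(res$loss)) {
        abort("training diverged (non-finite loss).",
              class = "icbtri_training_error", history = history)
      }
      losses <- c(losses, res$loss)
      upd <- adam_step(params, res$grads, opt, config$learning_rate)
      params <- upd$params
      opt <- upd$state
    }
    val_prob <- lstm_forward(params, xva, va$lengths)$h
    val_prob <- rnn_scores(params, val_prob)
    val_acc <- mean((val_prob >= 0.5) == (va$y == 1L))
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = epoch, train_loss = mean(losses), val_accuracy = val_acc
    ))
    if (val_acc > best$acc + 1e-9) {
      best <- list(acc = val_acc, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  structure(
    list(params = best$params, scaler = scaler, feature_set = feature_set,
         target_instrument = match_instrument(target_instrument),
         config = config, history = history, best_epoch = best$epoch,
         val_accuracy = best$acc),
    class = "icbt_rnn"
  )
}

rnn_scores <- function(params, h) {
  logits <- bias_add(h %*% params$Wo, params$bo)
  logits <- logits - apply(logits, 1L, max)
  p <- exp(logits)
  (p / rowSums(p))[, 2L]
}

#' @export
print.icbt_rnn <- function(x, ...) {
  cat(sprintf(
    "<icbt_rnn %s/%s: hidden %d, best epoch %d, val accuracy %.3f>\n",
    x$feature_set, x$target_instrument, x$config$hidden_dim, x$best_epoch,
    x$val_accuracy
  ))
  invisible(x)
}

rnn_predict_batch <- function(model, x, lengths) {
  x <- apply_scaler(x, model$scaler)
  h <- lstm_forward(model$params, x, lengths)$h
  rnn_scores(model$params, h)
}
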