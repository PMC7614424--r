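# Forward/backward passes and the Adam training loop for qc_model.
# Convolution and pooling kernels live in src/convnet.cpp; activations,
# the head and the optimiser are orchestrated here.

relu_ <- function(x) {
  x[x < 0] <- 0
  x
}

# Forward through the five blocks. x: (H, W, C, N). Returns the N x F
# feature matrix after global average pooling, plus caches for backward.
forward_backbone <- function(model, x, want_cache = FALSE) {
  spec <- model$spec
  nconv <- length(model$params$conv)
  caches <- if (want_cache) vector("list", nconv) else NULL
  pools <- if (want_cache) vector("list", 5L) else NULL
  li <- 0L
  for (b in seq_len(5L)) {
    for (j in seq_len(spec$convs_per_block[b])) {
      li <- li + 1L
      lay <- model$params$conv[[li]]
      if (want_cache) caches[[li]] <- list(x = x)
      x <- conv3x3_forward(x, lay$W, lay$b)
      x <- relu_(x)
      if (want_cache) caches[[li]]$mask <- x > 0
    }
    p <- maxpool2_forward(x)
    if (want_cache) pools[[b]] <- list(idx = p$idx, in_dim = dim(x))
    x <- p$y
  }
  d <- dim(x)
  feat <- t(matrix(colMeans(matrix(x, nrow = d[1] * d[2])), d[3], d[4]))
  list(feat = feat, caches = caches, pools = pools, pooled_dim = d)
}

head_forward <- function(model, feat) {
  out <- feat %*% model$params$head$W +
    matrix(model$params$head$b, nrow(feat), length(model$params$head$b),
           byrow = TRUE)
  if (model$head$activation == "relu") out <- relu_(out)
  out
}

# Full forward; returns output matrix (N x outputs) and caches.
model_forward <- function(model, x, want_cache = FALSE) {
  fb <- forward_backbone(model, x, want_cache)
  out <- head_forward(model, fb$feat)
  c(fb, list(out = out))
}

# Backward from dOut (N x outputs). Returns gradients for trainable
# parameters only (frozen blocks get NULL). Backpropagation stops below the
# lowest trainable convolution.
model_backward <- function(model, fw, dout) {
  head <- model$params$head
  if (model$head$activation == "relu") dout <- dout * (fw$out > 0)
  grads <- list(
    head = list(W = crossprod(fw$feat, dout), b = colSums(dout)),
    conv = vector("list", length(model$params$conv))
  )
  k <- model$freeze$trainable_last_k_blocks
  if (k == 0L) return(grads)
  min_block <- 6L - k
  blocks <- vapply(model$params$conv, `[[`, integer(1), "block")
  min_li <- min(which(blocks >= min_block))
  # through global average pooling
  d <- fw$pooled_dim
  spatial <- d[1] * d[2]
  dfeat <- dout %*% t(head$W)                       # N x C
  dx <- array(rep(as.vector(t(dfeat)), each = spatial) / spatial, dim = d)
  li <- length(model$params$conv)
  for (b in 5L:1L) {
    dx <- maxpool2_backward(dx, fw$pools[[b]]$idx, fw$pools[[b]]$in_dim)
    for (j in rev(seq_len(model$spec$convs_per_block[b]))) {
      dx <- dx * fw$caches[[li]]$mask
      need_dw <- b >= min_block
      need_dx <- li > min_li
      if (!need_dw && !need_dx) return(grads)
      bw <- conv3x3_backward(fw$caches[[li]]$x, model$params$conv[[li]]$W,
                             dx, need_dx, need_dw)
      if (need_dw) grads$conv[[li]] <- list(W = bw$dW, b = bw$db)
      if (!need_dx) return(grads)
      dx <- bw$dx
      li <- li - 1L
    }
  }
  grads
}

# ---- Adam ------------------------------------------------------------------

adam_new <- function() list(t = 0L, m = list(), v = list())

adam_update <- function(theta, g, st, key, lr, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  if (is.null(st$m[[key]])) {
    st$m[[key]] <- theta * 0
    st$v[[key]] <- theta * 0
  }
  st$m[[key]] <- b1 * st$m[[key]] + (1 - b1) * g
  st$v[[key]] <- b2 * st$v[[key]] + (1 - b2) * g^2
  mhat <- st$m[[key]] / (1 - b1^t)
  vhat <- st$v[[key]] / (1 - b2^t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

apply_gradients <- function(model, grads, st, lr) {
  st$t <- st$t + 1L
  t <- st$t
  for (li in seq_along(grads$conv)) {
    g <- grads$conv[[li]]
    if (is.null(g)) next
    up <- adam_update(model$params$conv[[li]]$W, g$W, st,
                      paste0("cW", li), lr, t)
    model$params$conv[[li]]$W <- up$theta; st <- up$state
    up <- adam_update(model$params$conv[[li]]$b, as.numeric(g$b), st,
                      paste0("cb", li), lr, t)
    model$params$conv[[li]]$b <- up$theta; st <- up$state
  }
  up <- adam_update(model$params$head$W, grads$head$W, st, "hW", lr, t)
  model$params$head$W <- up$theta; st <- up$state
  up <- adam_update(model$params$head$b, grads$head$b, st, "hb", lr, t)
  model$params$head$b <- up$theta; st <- up$state
  list(model = model, state = st)
}

# ---- training --------------------------------------------------------------

#' Training configuration
#'
#' Optimisation protocol: Adam, mean-squared-error loss, batch size 10, and
#' best-validation-loss checkpoint selection. The default learning rate is
#' 1e-4 (1e-3 is the high-rate baseline). `max_epochs` defaults to a
#' desk-scale 50; raise it (e.g. to 1000) for full-scale runs.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size Minibatch size (>= 1; default 10).
#' @param max_epochs Maximum training epochs.
#' @param seed Seed controlling initial shuffling and batch order.
#' @param verbose Print per-epoch losses.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 10L,
                         max_epochs = 50L, seed = 1L, verbose = FALSE) {
  stopifnot_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  structure(
    list(optimizer = "adam", loss = "mse", learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "train_config"
  )
}

mse_loss <- function(out, y) mean((out - y)^2)

# Batched feature extraction (no gradients); px: (H, W, N) single channel.
backbone_features <- function(model, px, chunk = 256L) {
  n <- dim(px)[3]
  feat <- matrix(0, n, model$spec$widths[5])
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    xb <- batch_three_channel(px[, , i:j, drop = FALSE])
    feat[i:j, ] <- forward_backbone(model, xb)$feat
    i <- j + 1L
  }
  feat
}

#' Predict patch-level outputs
#'
#' @param object A `qc_model`.
#' @param px Patch pixels: a `patch_set`, or an (H, W, N) array of
#'   single-channel patches.
#' @param ... Unused.
#' @return N x outputs matrix of raw head outputs (nonnegative for the
#'   clinical head; not clipped to the 0-3 scale).
#' @export
predict.qc_model <- function(object, px, ...) {
  if (inherits(px, "patch_set")) px <- px$pixels
  feat <- backbone_features(object, px)
  out <- head_forward(object, feat)
  colnames(out) <- if (object$head$kind == "clinical") c("gqr", "pr", "dc")
                   else "dose"
  out
}

#' Train a model with Adam / MSE and checkpoint selection
#'
#' Runs minibatch Adam on the mean-squared-error loss and returns the
#' parameters of the epoch with the lowest validation loss, together with
#' the full loss history. When the freeze policy leaves no convolutional
#' block trainable (head-only training, as in the fully fixed pretext
#' pipelines), features are precomputed once and only the head is
#' optimised, which is exactly equivalent and much faster. Deterministic
#' given `config$seed`.
#'
#' @param model A `qc_model` (with its freeze policy already applied).
#' @param train_data,val_data Lists with `x` (H, W, N patch array) and `y`
#'   (N x outputs target matrix). Train and validation sets must come from
#'   disjoint patients (enforced upstream by [assert_split_hygiene()]).
#' @param config A [train_config()].
#' @return List: `model` (best checkpoint), `history` (data frame of epoch,
#'   train and validation loss), `best_epoch`.
#' @export
train <- function(model, train_data, val_data, config = train_config()) {
  n_tr <- if (length(dim(train_data$x)) == 3L) dim(train_data$x)[3] else 0L
  n_va <- if (length(dim(val_data$x)) == 3L) dim(val_data$x)[3] else 0L
  if (n_tr == 0L) stop("empty training set", call. = FALSE)
  if (n_va == 0L) stop("empty validation set", call. = FALSE)
  y_tr <- as.matrix(train_data$y)
  y_va <- as.matrix(val_data$y)
  if (nrow(y_tr) != n_tr || nrow(y_va) != n_va ||
      ncol(y_tr) != model$head$outputs ||
      ncol(y_va) != model$head$outputs) {
    stop("target matrix does not match patches / head outputs",
         call. = FALSE)
  }
  head_only <- model$freeze$trainable_last_k_blocks == 0L
  lr <- config$learning_rate
  bs <- config$batch_size
  with_seed(config$seed, {
    if (head_only) {
      f_tr <- backbone_features(model, train_data$x)
      f_va <- backbone_features(model, val_data$x)
    } else {
      x_tr <- batch_three_channel(train_data$x)
      x_va <- batch_three_channel(val_data$x)
    }
    st <- adam_new()
    best <- list(loss = Inf, params = model$params, epoch = 0L)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      losses <- c()
      for (start in seq(1L, n_tr, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n_tr)]
        yb <- y_tr[idx, , drop = FALSE]
        if (head_only) {
          fb <- f_tr[idx, , drop = FALSE]
          out <- head_forward(model, fb)
          loss <- mse_loss(out, yb)
          dout <- 2 * (out - yb) / length(out)
          if (model$head$activation == "relu") dout <- dout * (out > 0)
          grads <- list(head = list(W = crossprod(fb, dout),
                                    b = colSums(dout)),
                        conv = list())
        } else {
          xb <- x_tr[, , , idx, drop = FALSE]
          fw <- model_forward(model, xb, want_cache = TRUE)
          loss <- mse_loss(fw$out, yb)
          grads <- model_backward(model, fw,
                                  2 * (fw$out - yb) / length(fw$out))
        }
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss at epoch %d", epoch),
               call. = FALSE)
        }
        losses <- c(losses, loss)
        up <- apply_gradients(model, grads, st, lr)
        model <- up$model
        st <- up$state
      }
      val_out <- if (head_only) head_forward(model, f_va)
                 else predict.qc_model(model, val_data$x)
      val_loss <- mse_loss(val_out, y_va)
      if (!is.finite(val_loss)) {
        stop(sprintf("non-finite validation loss at epoch %d", epoch),
             call. = FALSE)
      }
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = mean(losses),
                                     val_loss = val_loss))
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = model$params, epoch = epoch)
      }
      if (config$verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        mean(losses), val_loss))
      }
    }
    model$params <- best$params
    list(model = model, history = hist, best_epoch = best$epoch)
  })
}
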