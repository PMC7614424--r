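# VGG-style backbone: 5 convolutional blocks (3x3 convs + 2x2 max pool),
# global average pooling, and a single fully connected head.

#' Backbone architecture specification
#'
#' A width-scaled VGG16-shaped feature extractor: five blocks with
#' (2, 2, 3, 3, 3) convolution layers of 3x3 kernels, each block ending in
#' a 2x2 max pool. Channel widths double per block as `base_width *
#' (1, 2, 4, 8, 8)`; `base_width = 64` reproduces the full VGG16 layout,
#' the desk-scale default of 8 keeps training CPU-feasible while preserving
#' the block structure (and hence the freezing semantics).
#'
#' @param n_blocks Number of convolutional blocks; must be 5.
#' @param convs_per_block Convolutions per block (default `c(2,2,3,3,3)`).
#' @param base_width Channels of the first block.
#' @param input_size Square input size in pixels (>= 32).
#' @param input_channels Input channels (3: greyscale patches replicated).
#' @return A `backbone_spec` object.
#' @export
backbone_spec <- function(n_blocks = 5L, convs_per_block = c(2, 2, 3, 3, 3),
                          base_width = 8L, input_size = 32L,
                          input_channels = 3L) {
  if (n_blocks != 5L || length(convs_per_block) != 5L) {
    stop("the backbone has exactly 5 convolutional blocks", call. = FALSE)
  }
  if (input_size < 32L) {
    stop("`input_size` must be >= 32 to survive five pooling stages",
         call. = FALSE)
  }
  if (base_width < 1L) stop("`base_width` must be >= 1", call. = FALSE)
  structure(
    list(n_blocks = 5L, convs_per_block = as.integer(convs_per_block),
         base_width = as.integer(base_width),
         widths = as.integer(base_width * c(1, 2, 4, 8, 8)),
         input_size = as.integer(input_size),
         input_channels = as.integer(input_channels)),
    class = "backbone_spec"
  )
}

#' Regression head specification
#'
#' @param kind `"clinical"` (three outputs — GQR, PR, DC — with ReLU
#'   activation, so predictions are nonnegative) or `"dose"` (single output
#'   for the standardised-dose pretext target; linear by default).
#' @param activation Head activation; defaults to `"relu"` for the clinical
#'   head and `"linear"` for the dose head.
#' @return A `head_spec` object.
#' @export
head_spec <- function(kind = c("clinical", "dose"), activation = NULL) {
  kind <- match.arg(kind)
  if (is.null(activation)) {
    activation <- if (kind == "clinical") "relu" else "linear"
  }
  activation <- match.arg(activation, c("relu", "linear"))
  structure(
    list(kind = kind, outputs = if (kind == "clinical") 3L else 1L,
         activation = activation),
    class = "head_spec"
  )
}

#' Block-freezing policy
#'
#' Transfer learning freezes the first `5 - k` convolutional blocks and
#' trains the last `k` blocks plus the fully connected head. `k = 0` trains
#' only the head; `k = 5` trains everything.
#'
#' @param trainable_last_k_blocks Integer in 0..5.
#' @return A `freeze_policy` object.
#' @export
freeze_policy <- function(trainable_last_k_blocks) {
  k <- as.integer(trainable_last_k_blocks)
  if (is.na(k) || k < 0L || k > 5L) {
    stop("`trainable_last_k_blocks` must be in 0..5", call. = FALSE)
  }
  structure(list(trainable_last_k_blocks = k, head_trainable = TRUE),
            class = "freeze_policy")
}

# Is conv layer belonging to `block` trainable under `policy`?
block_trainable <- function(block, policy) {
  block > 5L - policy$trainable_last_k_blocks
}

#' Build the backbone with a regression head
#'
#' Random initialisation uses He-scaled Gaussian weights for the
#' convolutions and Glorot-scaled weights for the head; the head bias starts
#' at the midpoint of the target scale (1.5 for clinical scores, 0.5 for the
#' unit-scaled dose target) so the rectified outputs are alive from the
#' first step. Initialisation is deterministic given `seed`. `init` may also
#' be an existing `qc_model` used as a checkpoint (its convolutional
#' parameters are copied; shapes must match). ImageNet initialisation is an
#' optional path that requires externally supplied VGG16 weights
#' (`weights_file`); requesting it without weights fails explicitly.
#'
#' @param spec A [backbone_spec()].
#' @param head A [head_spec()].
#' @param init `"random"`, `"imagenet"`, or a `qc_model` checkpoint.
#' @param seed Integer seed for the random draws.
#' @param weights_file Optional path to VGG16 ImageNet weights.
#' @return A `qc_model`: `spec`, `head`, `params` (conv layer list and head
#'   weights), `freeze` (all blocks trainable by default) and `seed`.
#' @export
build_backbone <- function(spec = backbone_spec(), head = head_spec(),
                           init = "random", seed = 1L,
                           weights_file = NULL) {
  if (inherits(init, "qc_model")) {
    model <- init
    ok <- identical(model$spec$widths, spec$widths) &&
      identical(model$spec$convs_per_block, spec$convs_per_block) &&
      model$spec$input_channels == spec$input_channels
    if (!ok) {
      stop(sprintf(
        "checkpoint incompatible with spec: checkpoint widths (%s) vs spec (%s)",
        paste(model$spec$widths, collapse = ","),
        paste(spec$widths, collapse = ",")), call. = FALSE)
    }
    model$spec$input_size <- spec$input_size
    return(replace_head(model, head, seed = seed))
  }
  if (identical(init, "imagenet")) {
    if (is.null(weights_file) || !file.exists(weights_file)) {
      stop(paste("ImageNet initialisation requires a downloaded VGG16",
                 "weights file (`weights_file`); none is available"),
           call. = FALSE)
    }
    stop("loading external VGG16 weight files is not implemented",
         call. = FALSE)
  }
  if (!identical(init, "random")) {
    stop("`init` must be \"random\", \"imagenet\" or a qc_model",
         call. = FALSE)
  }
  params <- with_seed(seed, {
    conv <- list()
    cin <- spec$input_channels
    li <- 0L
    for (b in seq_len(5L)) {
      cout <- spec$widths[b]
      for (j in seq_len(spec$convs_per_block[b])) {
        li <- li + 1L
        fan_in <- 9L * cin
        conv[[li]] <- list(
          W = matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)),
                     nrow = fan_in, ncol = cout),
          b = rep(0, cout),
          block = b
        )
        cin <- cout
      }
    }
    feat_dim <- spec$widths[5]
    list(conv = conv, head = init_head(feat_dim, head))
  })
  structure(
    list(spec = spec, head = head, params = params,
         freeze = freeze_policy(5L), seed = as.integer(seed)),
    class = "qc_model"
  )
}

init_head <- function(feat_dim, head) {
  sdw <- sqrt(2 / (feat_dim + head$outputs))
  bias0 <- if (head$kind == "clinical") 1.5 else 0.5
  list(W = matrix(rnorm(feat_dim * head$outputs, 0, sdw),
                  nrow = feat_dim, ncol = head$outputs),
       b = rep(bias0, head$outputs))
}

#' @export
print.qc_model <- function(x, ...) {
  cat(sprintf(
    "<qc_model> 5-block backbone (base width %d), %s head (%d output%s)\n",
    x$spec$base_width, x$head$kind, x$head$outputs,
    if (x$head$outputs > 1) "s" else ""))
  cat(sprintf("  parameters: %d total, %d trainable (last %d block%s + head)\n",
              n_params(x), n_trainable_params(x),
              x$freeze$trainable_last_k_blocks,
              if (x$freeze$trainable_last_k_blocks == 1) "" else "s"))
  invisible(x)
}

#' Total parameter count
#' @param model A `qc_model`.
#' @return Integer count of all parameters.
#' @export
n_params <- function(model) {
  nc <- sum(vapply(model$params$conv,
                   function(l) length(l$W) + length(l$b), numeric(1)))
  as.integer(nc + length(model$params$head$W) + length(model$params$head$b))
}

#' Trainable parameter count under the current freeze policy
#' @param model A `qc_model`.
#' @return Integer count of trainable parameters.
#' @export
n_trainable_params <- function(model) {
  nc <- sum(vapply(model$params$conv, function(l) {
    if (block_trainable(l$block, model$freeze)) length(l$W) + length(l$b)
    else 0
  }, numeric(1)))
  as.integer(nc + length(model$params$head$W) + length(model$params$head$b))
}

#' Apply a block-freezing policy
#'
#' Marks the first `5 - k` blocks as frozen: their parameters carry a
#' no-update contract and remain bit-identical through any subsequent
#' training.
#'
#' @param model A `qc_model`.
#' @param policy A [freeze_policy()] (or the integer `k` directly).
#' @return The model with the policy attached.
#' @export
apply_freeze <- function(model, policy) {
  if (!inherits(policy, "freeze_policy")) policy <- freeze_policy(policy)
  model$freeze <- policy
  model
}

#' Replace the fully connected head
#'
#' Keeps every convolutional parameter exactly and freshly initialises a new
#' head — the transfer step between the dose-inference pretext model and the
#' clinical scoring model.
#'
#' @param model A `qc_model`.
#' @param new_head A [head_spec()].
#' @param seed Seed for the fresh head initialisation.
#' @return The model with the new head.
#' @export
replace_head <- function(model, new_head, seed = 1L) {
  feat_dim <- model$spec$widths[5]
  model$head <- new_head
  model$params$head <- with_seed(seed, init_head(feat_dim, new_head))
  model
}

# Stable checksum of the convolutional parameters (frozen-weight audits).
conv_checksum <- function(model) {
  v <- unlist(lapply(model$params$conv, function(l) c(l$W, l$b)))
  c(sum = sum(v), sumsq = sum(v^2), n = length(v))
}
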