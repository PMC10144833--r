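# A small feed-forward binary classifier trained with Adam, written in
# base-R matrix arithmetic.  Hidden layers are ReLU with inverted dropout;
# the output layer has two linear units turned into a positive-class
# probability by a max-subtracted softmax.

mlp_init <- function(input_dim, hidden, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- c(input_dim, hidden, 2L)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    bound <- 1 / sqrt(fan_in)
    layers[[l]] <- list(
      W = matrix(stats::runif(fan_in * dims[l + 1], -bound, bound),
                 nrow = fan_in),
      b = stats::runif(dims[l + 1], -bound, bound))
  }
  structure(list(layers = layers, input_dim = input_dim, hidden = hidden),
            class = "csf_mlp")
}

relu <- function(x) pmax(x, 0)

softmax_pos <- function(o) {
  # probability of the positive class (unit 2), max-subtracted for stability
  m <- pmax(o[, 1], o[, 2])
  e1 <- exp(o[, 1] - m); e2 <- exp(o[, 2] - m)
  e2 / (e1 + e2)
}

# forward pass; with cache = TRUE returns activations for backprop
mlp_forward_mat <- function(params, X, dropout = 0, training = FALSE,
                            cache = FALSE) {
  L <- length(params$layers)
  h <- X
  hs <- list(h)
  zs <- list()
  masks <- list()
  for (l in seq_len(L - 1L)) {
    ly <- params$layers[[l]]
    z <- sweep(h %*% ly$W, 2, ly$b, "+")
    h <- relu(z)
    if (training && dropout > 0) {
      m <- matrix(stats::rbinom(length(h), 1, 1 - dropout) / (1 - dropout),
                  nrow = nrow(h))
      h <- h * m
      masks[[l]] <- m
    }
    zs[[l]] <- z
    hs[[l + 1L]] <- h
  }
  out <- params$layers[[L]]
  o <- sweep(h %*% out$W, 2, out$b, "+")
  p <- softmax_pos(o)
  if (!cache) return(p)
  list(p = p, o = o, hs = hs, zs = zs, masks = masks)
}

#' Forward pass of the feed-forward classifier
#'
#' @param params A `csf_mlp` parameter set.
#' @param x Numeric matrix (samples x input_dim) or a single feature
#'   vector.
#' @param dropout Dropout probability, active only when `training = TRUE`.
#' @param training Logical; enables dropout.
#' @return Vector of positive-class probabilities in (0, 1).
#' @export
mlp_forward <- function(params, x, dropout = 0, training = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != params$input_dim) stop("input dimension mismatch")
  mlp_forward_mat(params, x, dropout = dropout, training = training)
}

#' Mean binary cross-entropy
#'
#' Probabilities are clipped to `[eps, 1 - eps]` before taking logs.
#'
#' @param prob Predicted positive-class probabilities.
#' @param y Binary labels.
#' @param eps Clipping epsilon (default 1e-7).
#' @return Non-negative scalar loss.
#' @export
cross_entropy <- function(prob, y, eps = 1e-7) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# one Adam update, in place on the params/opt pair
adam_step <- function(params, grads, opt, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (l in seq_along(params$layers)) {
    for (nm in c("W", "b")) {
      g <- grads[[l]][[nm]]
      opt$m[[l]][[nm]] <- b1 * opt$m[[l]][[nm]] + (1 - b1) * g
      opt$v[[l]][[nm]] <- b2 * opt$v[[l]][[nm]] + (1 - b2) * g^2
      mhat <- opt$m[[l]][[nm]] / (1 - b1^opt$t)
      vhat <- opt$v[[l]][[nm]] / (1 - b2^opt$t)
      params$layers[[l]][[nm]] <- params$layers[[l]][[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, opt = opt)
}

mlp_gradients <- function(params, cache, Y) {
  # Y: n x 2 one-hot; softmax + cross-entropy output gradient
  L <- length(params$layers)
  n <- nrow(Y)
  P <- cbind(1 - cache$p, cache$p)
  delta <- (P - Y) / n
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    h_prev <- cache$hs[[l]]
    grads[[l]] <- list(W = crossprod(h_prev, delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- delta %*% t(params$layers[[l]]$W)
      if (length(cache$masks) >= l - 1L && !is.null(cache$masks[[l - 1L]])) {
        delta <- delta * cache$masks[[l - 1L]]
      }
      delta <- delta * (cache$zs[[l - 1L]] > 0)
    }
  }
  grads
}

#' Train the feed-forward classifier
#'
#' Mini-batch Adam on softmax cross-entropy; fixed epoch count, no early
#' stopping, schedule or weight decay.
#'
#' @param X Numeric matrix (samples x features), already standardized.
#' @param y Binary labels (1 = positive).
#' @param hidden Hidden-layer widths (default `c(128, 128, 128)`).
#' @param dropout Dropout probability (default 0.1).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Training epochs (default 20).
#' @param seed RNG seed pinning initialization, shuffling and dropout.
#' @return A `csf_mlp` with a `loss` attribute (mean training loss per
#'   epoch).
#' @export
mlp_train <- function(X, y, hidden = c(128, 128, 128), dropout = 0.1,
                      batch_size = 32, learning_rate = 0.001, epochs = 20,
                      seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0) stop("empty training data")
  set.seed(seed)
  params <- mlp_init(ncol(X), hidden)
  zero_like <- lapply(params$layers, function(ly) {
    list(W = ly$W * 0, b = ly$b * 0)
  })
  opt <- list(m = zero_like, v = zero_like, t = 0L)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    batch_losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      take <- ord[start:min(start + batch_size - 1, n)]
      Xb <- X[take, , drop = FALSE]
      yb <- y[take]
      cache <- mlp_forward_mat(params, Xb, dropout = dropout,
                               training = TRUE, cache = TRUE)
      Y <- cbind(1 - yb, yb)
      grads <- mlp_gradients(params, cache, Y)
      upd <- adam_step(params, grads, opt, lr = learning_rate)
      params <- upd$params
      opt <- upd$opt
      batch_losses <- c(batch_losses, cross_entropy(cache$p, yb))
    }
    losses[ep] <- mean(batch_losses)
  }
  attr(params, "loss") <- losses
  params
}
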