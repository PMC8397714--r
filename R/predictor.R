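# Property prediction function f(.): a feed-forward network on fingerprint
# vectors (logistic-sigmoid hidden layers, linear output) trained by
# backpropagation with Adam on the mean squared error, with a dropout layer
# after the input and every hidden layer.  Implemented directly with matrix
# operations; training is mini-batched and fully seeded.

#' Training configuration for the neural models
#'
#' Defaults follow the published protocol (Adam, mini-batch 100, dropout
#' 0.5); `hidden` defaults to the desk-scale architecture -- the full-scale
#' settings (5 x 250 for the predictor, 3 x 500 for the decoder, 500
#' epochs) are available by configuration.
#'
#' @param hidden Integer vector of hidden-layer sizes.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param dropout Dropout rate after input and hidden layers.
#' @param weight_decay Decoupled L2 weight decay per update (0 disables).
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(hidden = c(64, 64), epochs = 60, batch_size = 100,
                         lr = 1e-3, dropout = 0.1, weight_decay = 0,
                         seed = 1L) {
  structure(list(hidden = hidden, epochs = epochs, batch_size = batch_size,
                 lr = lr, dropout = dropout, weight_decay = weight_decay,
                 seed = seed),
            class = "train_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(l) {
    fan_in <- sizes[l]
    list(W = matrix(rnorm(fan_in * sizes[l + 1], sd = 1 / sqrt(fan_in)),
                    fan_in, sizes[l + 1]),
         b = numeric(sizes[l + 1]))
  })
}

adam_new <- function(params) {
  list(m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"),
       t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^state$t)
    vhat <- v / (1 - beta2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (l in seq_along(params)) {
    for (nm in names(params[[l]])) {
      r <- upd(params[[l]][[nm]], grads[[l]][[nm]],
               state$m[[l]][[nm]], state$v[[l]][[nm]])
      params[[l]][[nm]] <- r$p
      state$m[[l]][[nm]] <- r$m
      state$v[[l]][[nm]] <- r$v
    }
  }
  list(params = params, state = state)
}

mlp_forward <- function(params, X, dropout = 0, train = FALSE) {
  L <- length(params)
  acts <- vector("list", L + 1)
  masks <- vector("list", L)
  A <- X
  if (train && dropout > 0) {
    m0 <- matrix(rbinom(length(A), 1, 1 - dropout), nrow(A)) / (1 - dropout)
    A <- A * m0
  } else m0 <- NULL
  acts[[1]] <- A
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% params[[l]]$W, 2, params[[l]]$b, "+")
    if (l < L) {
      A <- sigmoid(Z)
      if (train && dropout > 0) {
        masks[[l]] <- matrix(rbinom(length(A), 1, 1 - dropout), nrow(A)) /
          (1 - dropout)
        A <- A * masks[[l]]
      }
    } else {
      A <- Z   # linear output
    }
    acts[[l + 1]] <- A
  }
  list(acts = acts, masks = masks, input_mask = m0, out = A)
}

mlp_backward <- function(params, fwd, Y) {
  L <- length(params)
  n <- nrow(Y)
  grads <- vector("list", L)
  delta <- 2 * (fwd$out - Y) / (n * ncol(Y))   # d MSE / d out
  for (l in rev(seq_len(L))) {
    A_prev <- fwd$acts[[l]]
    grads[[l]] <- list(W = crossprod(A_prev, delta),
                       b = colSums(delta))
    if (l > 1) {
      dA <- delta %*% t(params[[l]]$W)
      if (!is.null(fwd$masks[[l - 1]])) dA <- dA * fwd$masks[[l - 1]]
      A <- fwd$acts[[l]]
      # acts[[l]] is post-dropout sigmoid output; derivative uses it directly
      delta <- dA * A * (1 - A)
    }
  }
  grads
}

pairs_to_matrices <- function(pairs) {
  fps <- do.call(rbind, lapply(pairs, function(p) as.numeric(p[[1]])))
  labs <- lapply(pairs, function(p) unlist(p[[2]]))
  nms <- names(labs[[1]])
  if (is.null(nms)) nms <- paste0("y", seq_along(labs[[1]]))
  if (!all(vapply(labs, function(l) identical(names(l) %||% nms, nms), TRUE))) {
    stopf("train_predictor: inconsistent property names")
  }
  Y <- do.call(rbind, labs)
  colnames(Y) <- nms
  list(X = fps, Y = Y)
}

#' Train the neural property predictor
#'
#' @param pairs List of `(fingerprint, property vector)` pairs: each element
#'   a list whose first component is a numeric fingerprint and second a named
#'   numeric vector/list of property values.
#' @param hyper A [train_config()].
#' @return A `predictor_model` with the fitted parameters, per-epoch training
#'   loss and the label standardization used internally.
#' @export
train_predictor <- function(pairs, hyper = train_config()) {
  if (length(pairs) == 0) stopf("train_predictor: empty dataset")
  mats <- pairs_to_matrices(pairs)
  X <- mats$X; Y <- mats$Y
  y_mu <- colMeans(Y); y_sd <- apply(Y, 2, sd)
  y_sd[y_sd < 1e-12] <- 1
  Ys <- sweep(sweep(Y, 2, y_mu), 2, y_sd, "/")
  n <- nrow(X)
  with_seed(hyper$seed, {
    params <- mlp_init(c(ncol(X), hyper$hidden, ncol(Y)))
    st <- adam_new(params)
    losses <- numeric(hyper$epochs)
    for (ep in seq_len(hyper$epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = hyper$batch_size)) {
        b <- idx[start:min(start + hyper$batch_size - 1, n)]
        fwd <- mlp_forward(params, X[b, , drop = FALSE], hyper$dropout, TRUE)
        Yb <- Ys[b, , drop = FALSE]
        ep_loss <- ep_loss + mean((fwd$out - Yb)^2)
        nb <- nb + 1
        grads <- mlp_backward(params, fwd, Yb)
        r <- adam_step(params, grads, st, hyper$lr)
        params <- r$params; st <- r$state
        if ((hyper$weight_decay %||% 0) > 0) {
          for (l in seq_along(params)) {
            params[[l]]$W <- params[[l]]$W * (1 - hyper$lr * hyper$weight_decay)
          }
        }
      }
      losses[ep] <- ep_loss / nb
    }
    structure(list(params = params, y_mu = y_mu, y_sd = y_sd,
                   property_names = colnames(Y), losses = losses,
                   hyper = hyper, input_dim = ncol(X)),
              class = "predictor_model")
  })
}

#' Predict properties from a fingerprint
#'
#' Deterministic at inference (dropout off).
#'
#' @param object A `predictor_model`.
#' @param fp A fingerprint vector, or a matrix with one fingerprint per row.
#' @param ... Unused.
#' @return Named numeric vector (or matrix) of predicted properties.
#' @export
predict.predictor_model <- function(object, fp, ...) {
  X <- if (is.matrix(fp)) fp else matrix(as.numeric(fp), nrow = 1)
  if (ncol(X) != object$input_dim) {
    stopf("predict: fingerprint length %d, expected %d", ncol(X),
          object$input_dim)
  }
  out <- mlp_forward(object$params, X)$out
  out <- sweep(sweep(out, 2, object$y_sd, "*"), 2, object$y_mu, "+")
  colnames(out) <- object$property_names
  if (nrow(out) == 1) setNames(as.numeric(out), object$property_names) else out
}

#' k-fold cross-validation of the property predictor
#'
#' Each sample appears in exactly one test fold; the correlation (Pearson R)
#' and mean absolute error are computed per property on predictions pooled
#' over folds.
#'
#' @param pairs As in [train_predictor()].
#' @param k Number of folds (default 10).
#' @param hyper A [train_config()].
#' @param seed Fold-assignment seed.
#' @return Data frame with one row per property: `property`, `R`, `MAE`.
#' @export
crossvalidate <- function(pairs, k = 10, hyper = train_config(), seed = 1L) {
  n <- length(pairs)
  if (k < 2) stopf("crossvalidate: k must be >= 2")
  if (k > n) stopf("crossvalidate: k larger than dataset")
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  mats <- pairs_to_matrices(pairs)
  preds <- matrix(NA_real_, n, ncol(mats$Y))
  for (f in seq_len(k)) {
    test <- which(folds == f)
    model <- train_predictor(pairs[-test], hyper)
    preds[test, ] <- predict(model, mats$X[test, , drop = FALSE])
  }
  res <- lapply(seq_len(ncol(mats$Y)), function(j) {
    data.frame(property = colnames(mats$Y)[j],
               R = cor(preds[, j], mats$Y[, j]),
               MAE = mean(abs(preds[, j] - mats$Y[, j])))
  })
  do.call(rbind, res)
}
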