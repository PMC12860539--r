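#' Random Fourier feature map
#'
#' Fixed random sinusoidal embedding used to counter the spectral bias of
#' plain multilayer perceptrons: a frozen matrix `B` (m x d) with entries
#' drawn `Normal(0, 1) * scale`; an input `x` maps to
#' `[sin(2 pi x B'), cos(2 pi x B')]`, a `2 m`-vector bounded in `[-1, 1]`.
#' One Fourier dimension is used per input dimension by default
#' (`m = d`).
#'
#' @param d Input dimension (126 for the standard encoding).
#' @param scale Gaussian scale hyperparameter `s`.
#' @param m Number of Fourier features; defaults to `d`.
#' @param seed Integer seed for drawing `B` (the map is frozen after
#'   initialization). The global RNG state is left untouched.
#' @return Object of class `fourier_map` with fields `B`, `scale`, `m`,
#'   `d`, `seed`.
#' @export
fourier_map <- function(d, scale, m = d, seed = 1) {
  stopifnot(d >= 1, m >= 1, scale > 0)
  B <- with_preserved_rng(seed, matrix(stats::rnorm(m * d), m, d) * scale)
  structure(list(B = B, scale = scale, m = as.integer(m), d = as.integer(d),
                 seed = as.integer(seed)),
            class = "fourier_map")
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Apply a Fourier feature map
#'
#' @param X Matrix (n x d) or a single length-`d` vector.
#' @param map A [fourier_map()].
#' @return Matrix n x `2 m`: `[sin(proj), cos(proj)]` with
#'   `proj = 2 pi X B'`; every entry lies in `[-1, 1]`.
#' @export
fourier_features <- function(X, map) {
  stopifnot(inherits(map, "fourier_map"))
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != map$d)
    stop(sprintf("input has %d columns but the map expects %d",
                 ncol(X), map$d))
  proj <- (2 * pi) * (X %*% t(map$B))
  cbind(sin(proj), cos(proj))
}

# --- z-score standardization ------------------------------------------------

zscore_fit <- function(M) {
  center <- colMeans(M)
  scale <- apply(M, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1  # constant columns pass through
  list(center = center, scale = scale)
}
zscore_apply <- function(M, z) sweep(sweep(M, 2, z$center), 2, z$scale, "/")
zscore_invert <- function(M, z) sweep(sweep(M, 2, z$scale, "*"), 2, z$center, "+")

# Accept a needle_dataset (train part) or a bare list(X, Y).
training_matrices <- function(data) {
  if (inherits(data, "needle_dataset")) data <- data$train
  stopifnot(is.matrix(data$X), is.matrix(data$Y),
            nrow(data$X) == nrow(data$Y))
  data
}

# Glorot-uniform initial weights for a fully connected stack.
glorot_init <- function(sizes, seed) {
  with_preserved_rng(seed, {
    lapply(seq_len(length(sizes) - 1), function(l) {
      fan_in <- sizes[l]; fan_out <- sizes[l + 1]
      b <- sqrt(6 / (fan_in + fan_out))
      list(W = matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out),
           b = numeric(fan_out))
    })
  })
}

new_surrogate <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "needle_surrogate")
}

#' Ordinary least squares surrogate (baseline)
#'
#' Linear regression from the 126-dim encoded input to the 48 nodal
#' deflections, fit on z-scored inputs and outputs. Deterministic.
#'
#' @param data A `needle_dataset` (its training part is used) or a list
#'   with matrices `X` (n x 126) and `Y` (n x 48).
#' @return A `needle_surrogate` of kind `"ols"`.
#' @export
train_ols <- function(data) {
  tr <- training_matrices(data)
  if (nrow(tr$X) <= ncol(tr$X))
    stop("OLS needs more samples than input dimensions")
  zx <- zscore_fit(tr$X); zy <- zscore_fit(tr$Y)
  Xs <- cbind(1, zscore_apply(tr$X, zx))
  Ys <- zscore_apply(tr$Y, zy)
  fit <- stats::lm.fit(Xs, Ys)
  if (fit$rank < ncol(Xs)) {
    warning("rank-deficient design (rank ", fit$rank, " of ", ncol(Xs),
            "); pivoted least-squares solution used")
    fit$coefficients[is.na(fit$coefficients)] <- 0
  }
  new_surrogate("ols", coef = fit$coefficients, x_std = zx, y_std = zy,
                meta = list(n_train = nrow(tr$X)))
}

#' Multilayer perceptron surrogate
#'
#' Two hidden layers of 48 rectified-linear units trained with Adam on
#' z-scored inputs and outputs. Defaults follow the common reference MLP
#' regressor: learning rate 1e-3, minibatches of 200, L2 penalty 1e-4,
#' at most 200 epochs with early stopping once the training loss stops
#' improving by more than `tol` for `n_iter_no_change` epochs.
#'
#' @param data As in [train_ols()].
#' @param seed Seed for weight initialization and minibatch shuffling.
#' @param hidden Hidden layer widths.
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size; `0` trains full batch.
#' @param l2 L2 penalty weight.
#' @param tol,n_iter_no_change Early-stopping rule; `n_iter_no_change = 0`
#'   disables it.
#' @return A `needle_surrogate` of kind `"mlp"`.
#' @export
train_mlp <- function(data, seed = 1, hidden = c(48, 48), lr = 1e-3,
                      epochs = 200, batch_size = 200, l2 = 1e-4,
                      tol = 1e-4, n_iter_no_change = 10) {
  tr <- training_matrices(data)
  zx <- zscore_fit(tr$X); zy <- zscore_fit(tr$Y)
  Xs <- zscore_apply(tr$X, zx)
  Ys <- zscore_apply(tr$Y, zy)
  net <- fit_net(Xs, Ys, hidden, lr, epochs, batch_size, l2, tol,
                 n_iter_no_change, seed)
  if (net$diverged) stop("MLP training diverged (loss not finite) at lr = ", lr)
  new_surrogate("mlp", weights = net$weights, x_std = zx, y_std = zy,
                meta = list(lr = lr, epochs = epochs, seed = seed,
                            batch_size = batch_size, l2 = l2,
                            activation = "relu",
                            n_epochs = net$n_epochs, loss = net$loss))
}

#' Fourier-feature neural network surrogate
#'
#' The MLP architecture of [train_mlp()] preceded by a frozen random
#' Fourier feature map ([fourier_map()]). Raw inputs are fed to the map
#' un-standardized (the sinusoids bound them to `[-1, 1]`); outputs are
#' z-scored. Trained full batch with Adam for a fixed number of epochs.
#'
#' @param data As in [train_ols()].
#' @param lr Adam learning rate (grid-search optimum: 0.005).
#' @param scale Gaussian scale of the Fourier map (optimum: 0.2).
#' @param epochs Training epochs (fixed; no early stopping).
#' @param seed Seed for the Fourier map and weight initialization.
#' @param hidden Hidden layer widths.
#' @param m Fourier features per input; defaults to the input dimension.
#' @param l2 L2 penalty weight (0: plain mean-squared-error training).
#' @return A `needle_surrogate` of kind `"ffnn"`.
#' @export
train_ffnn <- function(data, lr = 0.005, scale = 0.2, epochs = 500,
                       seed = 1, hidden = c(48, 48), m = NULL, l2 = 0) {
  stopifnot(lr > 0, scale > 0)
  tr <- training_matrices(data)
  d <- ncol(tr$X)
  map <- fourier_map(d = d, scale = scale, m = if (is.null(m)) d else m,
                     seed = seed)
  Xf <- fourier_features(tr$X, map)
  zy <- zscore_fit(tr$Y)
  Ys <- zscore_apply(tr$Y, zy)
  net <- fit_net(Xf, Ys, hidden, lr, epochs, batch_size = 0, l2 = l2,
                 tol = 0, n_iter_no_change = 0, seed = seed,
                 single_precision = TRUE)
  if (net$diverged)
    stop("FFNN training diverged (loss not finite) at lr = ", lr)
  new_surrogate("ffnn", weights = net$weights, fourier = map, y_std = zy,
                meta = list(lr = lr, scale = scale, epochs = epochs,
                            seed = seed, activation = "relu",
                            n_epochs = net$n_epochs, loss = net$loss))
}

# Shared trainer behind the MLP and FFNN: Glorot init + compiled Adam loop.
# single_precision mirrors GPU-framework float32 training (FFNN); the MLP
# trains in float64 like the reference CPU implementation.
fit_net <- function(X, Y, hidden, lr, epochs, batch_size, l2, tol,
                    n_iter_no_change, seed, single_precision = FALSE) {
  sizes <- c(ncol(X), hidden, ncol(Y))
  w0 <- glorot_init(sizes, seed)
  res <- cpp_train_mlp(X, Y,
                       w0[[1]]$W, rbind(w0[[1]]$b),
                       w0[[2]]$W, rbind(w0[[2]]$b),
                       w0[[3]]$W, rbind(w0[[3]]$b),
                       lr = lr, max_epochs = as.integer(epochs),
                       batch_size = as.integer(batch_size), l2 = l2,
                       tol = tol,
                       n_iter_no_change = as.integer(n_iter_no_change),
                       shuffle_seed = as.integer(seed),
                       single_precision = single_precision)
  list(weights = res[c("W1", "b1", "W2", "b2", "W3", "b3")],
       loss = as.numeric(res$loss), n_epochs = res$n_epochs,
       diverged = isTRUE(res$diverged))
}

#' @export
print.needle_surrogate <- function(x, ...) {
  cat(sprintf("<needle_surrogate> %s\n", toupper(x$kind)))
  if (!is.null(x$meta$lr))
    cat(sprintf("  lr %g, %s epochs run, final loss %.3g\n", x$meta$lr,
                x$meta$n_epochs, utils::tail(x$meta$loss, 1)))
  if (!is.null(x$fourier))
    cat(sprintf("  Fourier map: m = %d, scale = %g, seed = %d\n",
                x$fourier$m, x$fourier$scale, x$fourier$seed))
  invisible(x)
}

#' Predict nodal deflections from encoded inputs
#'
#' @param object A `needle_surrogate`.
#' @param newdata Matrix (n x 126) of encoded inputs, a single 126-vector,
#'   or a list/`needle_dataset` part holding `X`.
#' @param ... Ignored.
#' @return Matrix n x 48 of predicted nodal deflections, mm.
#' @export
predict.needle_surrogate <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata
       else if (is.numeric(newdata)) matrix(newdata, nrow = 1)
       else if (!is.null(newdata$X)) newdata$X
       else if (inherits(newdata, "needle_dataset")) newdata$val$X
       else stop("cannot extract an input matrix from newdata")
  Ys <- switch(object$kind,
    ols = cbind(1, zscore_apply(X, object$x_std)) %*% object$coef,
    mlp = {
      w <- object$weights
      cpp_mlp_forward(zscore_apply(X, object$x_std),
                      w$W1, w$b1, w$W2, w$b2, w$W3, w$b3)
    },
    ffnn = {
      w <- object$weights
      cpp_mlp_forward(fourier_features(X, object$fourier),
                      w$W1, w$b1, w$W2, w$b2, w$W3, w$b3)
    },
    stop("unknown surrogate kind: ", object$kind))
  zscore_invert(Ys, object$y_std)
}
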