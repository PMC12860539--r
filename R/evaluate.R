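#' Evaluate a surrogate against simulator ground truth
#'
#' Computes signed errors (prediction minus simulator deflection, mm) and
#' mean absolute error over a validation set, optionally restricted to
#' one insertion depth. Per-sample MAE averages the absolute error over
#' all 48 nodes (`scope = "all"`) or takes the tip node alone
#' (`scope = "tip"`); the aggregate MAE is the mean of per-sample MAEs.
#'
#' The signed-error summary is aggregated per trajectory (each validation
#' trajectory contributes one mean signed error), so the reported
#' standard error reflects independent insertions rather than the
#' correlated per-node or per-depth errors within one insertion.
#'
#' @param model A `needle_surrogate`.
#' @param data A `needle_dataset` (its validation part) or a list with
#'   `X`, `Y`, `trajectory`, `depth`.
#' @param depth Insertion depth (mm) to evaluate at, or `NULL` to pool
#'   all depths.
#' @param scope `"all"` (48-node MAE) or `"tip"` (tip node only).
#' @return Object of class `surrogate_eval`: `mae` (mm), `mae_per_sample`,
#'   `signed_mean`, `signed_se` (trajectory-level), `n`, `errors`
#'   (n x 48 signed error matrix), `depth`, `scope`.
#' @export
evaluate_surrogate <- function(model, data, depth = 65, scope = c("all", "tip")) {
  scope <- match.arg(scope)
  part <- if (inherits(data, "needle_dataset")) data$val else data
  if (is.null(part)) stop("dataset has no validation part")
  keep <- if (is.null(depth)) seq_len(nrow(part$X)) else which(part$depth == depth)
  if (!length(keep))
    stop("no validation samples at depth ", depth, " mm")
  X <- part$X[keep, , drop = FALSE]
  Y <- part$Y[keep, , drop = FALSE]
  pred <- predict(model, X)
  err <- pred - Y
  mae_per_sample <- if (scope == "all") rowMeans(abs(err))
                    else abs(err[, ncol(err)])
  signed_per_sample <- if (scope == "all") rowMeans(err) else err[, ncol(err)]
  traj_mean <- tapply(signed_per_sample, part$trajectory[keep], mean)
  structure(list(
    depth = depth, scope = scope, n = length(keep),
    mae = mean(mae_per_sample),
    mae_per_sample = as.numeric(mae_per_sample),
    signed_mean = mean(traj_mean),
    signed_se = stats::sd(traj_mean) / sqrt(length(traj_mean)),
    n_trajectories = length(traj_mean),
    errors = err), class = "surrogate_eval")
}

#' @export
print.surrogate_eval <- function(x, ...) {
  cat(sprintf("<surrogate_eval> %s-node scope, %s, n = %d\n", x$scope,
              if (is.null(x$depth)) "all depths"
              else sprintf("depth %g mm", x$depth), x$n))
  cat(sprintf("  MAE %.4f mm; signed error %.4f +/- %.4f mm (SE, %d trajectories)\n",
              x$mae, x$signed_mean, x$signed_se, x$n_trajectories))
  invisible(x)
}

#' Absolute-error distribution along the needle
#'
#' Histogram of absolute prediction error per node (distance from the
#' needle base), binned at a fixed width, for validation samples at one
#' insertion depth. Counts above `clip` are clipped for display, as the
#' near-base bins otherwise dwarf the rest of the distribution.
#'
#' @param model A `needle_surrogate`.
#' @param data As in [evaluate_surrogate()].
#' @param depth Insertion depth, mm (default: deepest trained depth 120
#'   analog is up to the caller).
#' @param bin Histogram bin width, mm (default 0.01).
#' @param clip Optional count ceiling per bin.
#' @return Data frame with columns `node`, `position_mm`, `bin_lower_mm`,
#'   `count`.
#' @export
error_profile <- function(model, data, depth = 120, bin = 0.01, clip = NULL) {
  ev <- evaluate_surrogate(model, data, depth = depth, scope = "all")
  abs_err <- abs(ev$errors)
  needle <- if (inherits(data, "needle_dataset")) data$needle else needle_spec()
  out <- do.call(rbind, lapply(seq_len(ncol(abs_err)), function(j) {
    b <- floor(abs_err[, j] / bin) * bin
    tab <- table(b)
    data.frame(node = j, position_mm = needle$node_positions[j],
               bin_lower_mm = as.numeric(names(tab)),
               count = as.integer(tab))
  }))
  if (!is.null(clip)) out$count <- pmin(out$count, clip)
  rownames(out) <- NULL
  out
}

#' Grid search over FFNN learning rate and Fourier scale
#'
#' Trains one FFNN per `(lr, scale)` grid point on 80% of the training
#' trajectories and scores validation MAE at `depth` on the held-out 20%
#' (tuning split by trajectory). A diverged cell scores `Inf` and the
#' search continues. The reference full-scale grid is 10 learning rates
#' log-spaced in `[1e-5, 1e-2]` by 10 scales linearly spaced in
#' `[0.01, 1]`.
#'
#' @param data A `needle_dataset`.
#' @param lr_grid,scale_grid Numeric grids.
#' @param depth Scoring depth, mm.
#' @param epochs Training epochs per cell.
#' @param seed Seed for the tuning split and each cell's training.
#' @param tune_frac Fraction of training trajectories held out for tuning.
#' @return List with `best` (named `lr`, `scale`), `table` (data frame
#'   `lr`, `scale`, `mae`) and `depth`.
#' @export
grid_search_ffnn <- function(data,
                             lr_grid = 10^seq(log10(1e-2), log10(1e-5),
                                              length.out = 10),
                             scale_grid = seq(0.01, 1, length.out = 10),
                             depth = 65, epochs = 500, seed = 1,
                             tune_frac = 0.2) {
  stopifnot(inherits(data, "needle_dataset"),
            length(lr_grid) >= 1, length(scale_grid) >= 1)
  tr <- data$train
  ids <- unique(tr$trajectory)
  tune_ids <- with_preserved_rng(seed,
    sample(ids, max(1, round(tune_frac * length(ids)))))
  in_tune <- tr$trajectory %in% tune_ids
  fit_part <- list(X = tr$X[!in_tune, , drop = FALSE],
                   Y = tr$Y[!in_tune, , drop = FALSE])
  tune_part <- list(X = tr$X[in_tune, , drop = FALSE],
                    Y = tr$Y[in_tune, , drop = FALSE],
                    trajectory = tr$trajectory[in_tune],
                    depth = tr$depth[in_tune])
  grid <- expand.grid(lr = lr_grid, scale = scale_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$mae <- vapply(seq_len(nrow(grid)), function(i) {
    tryCatch({
      m <- train_ffnn(fit_part, lr = grid$lr[i], scale = grid$scale[i],
                      epochs = epochs, seed = seed)
      evaluate_surrogate(m, tune_part, depth = depth)$mae
    }, error = function(e) Inf)
  }, numeric(1))
  best <- grid[which.min(grid$mae), ]
  list(best = c(lr = best$lr, scale = best$scale), table = grid,
       depth = depth)
}
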