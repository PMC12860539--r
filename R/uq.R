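#' Truncated-normal prior on layered tissue moduli
#'
#' Each tissue layer's elastic modulus is modeled as
#' `TruncNormal(mu, sigma)` with lower truncation fixed at 0 so no
#' sampled tissue has a negative modulus. Layer geometry follows
#' [layered_anatomy()]: `length(mu) - 1` increasing integer boundaries.
#'
#' A packaged example for the clinical transperineal setting uses
#' literature means of 0.043 MPa for prostate and 0.0103 MPa for muscle
#' with a wide 0.08 MPa standard deviation; see
#' `system.file("extdata", "clinical_prior.yaml", package = "needleuq")`.
#'
#' @param mu Per-layer prior means, MPa.
#' @param sigma Per-layer prior standard deviations, MPa (>= 0).
#' @param boundaries Layer transition depths, mm.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(mu, sigma, boundaries = numeric(0)) {
  mu <- as.numeric(mu); sigma <- as.numeric(sigma)
  if (length(sigma) == 1) sigma <- rep(sigma, length(mu))
  if (length(sigma) != length(mu))
    stop("mu and sigma must have one value per layer")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (any(mu < 0)) stop("mu must be non-negative")
  geometry <- layered_anatomy(moduli = mu, boundaries = boundaries)
  structure(list(mu = mu, sigma = sigma, lower = 0,
                 boundaries = geometry$boundaries,
                 n_layers = geometry$n_layers),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec> %d layer(s), TruncNormal(mu, sigma) on [0, Inf)\n",
              x$n_layers))
  lo <- c(0, x$boundaries); hi <- c(x$boundaries, TISSUE_DEPTH_MM)
  for (j in seq_len(x$n_layers))
    cat(sprintf("  %3g-%3g mm : mu %.4g, sigma %.4g MPa\n",
                lo[j], hi[j], x$mu[j], x$sigma[j]))
  invisible(x)
}

#' Draw tissue-property vectors from a prior
#'
#' Independent draws per layer from the zero-truncated normal, via the
#' inverse-CDF transform `x = mu + sigma * qnorm(u)` with `u` uniform on
#' `[pnorm(-mu/sigma), 1]`. A degenerate layer (`sigma = 0`) always
#' returns `mu`.
#'
#' @param prior A [prior_spec()].
#' @param n Number of draws.
#' @param seed Optional integer seed (global RNG state preserved).
#' @return Matrix `n` x `n_layers` of non-negative moduli, MPa.
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "prior_spec"), n >= 1)
  draw <- function() {
    out <- matrix(0, n, prior$n_layers)
    for (j in seq_len(prior$n_layers)) {
      mu <- prior$mu[j]; sg <- prior$sigma[j]
      if (sg == 0) {
        out[, j] <- mu
      } else {
        p0 <- stats::pnorm(0, mean = mu, sd = sg)
        u <- stats::runif(n, p0, 1)
        out[, j] <- pmax(0, stats::qnorm(u, mean = mu, sd = sg))
      }
    }
    out
  }
  if (is.null(seed)) draw() else with_preserved_rng(seed, draw())
}

#' Empirical confidence band over needle-shape samples
#'
#' Per-node empirical quantiles of a Monte Carlo sample of nodal
#' deflections: lower and upper at `(1 - level) / 2` and
#' `1 - (1 - level) / 2`, plus the median. Bands widen monotonically with
#' `level` and nest across levels.
#'
#' @param samples Matrix n_samples x n_nodes of deflections, mm.
#' @param level Band coverage level in (0, 1).
#' @return Data frame with columns `node`, `lower`, `median`, `upper`.
#' @export
confidence_band <- function(samples, level = 0.95) {
  if (is.null(dim(samples)) || nrow(samples) < 2)
    stop("need at least 2 samples to form a band")
  stopifnot(level > 0, level < 1)
  a <- (1 - level) / 2
  q <- apply(samples, 2, function(col) {
    # constant ensembles collapse exactly (no interpolation round-off)
    if (min(col) == max(col)) rep(col[1], 3)
    else stats::quantile(col, probs = c(a, 0.5, 1 - a), names = FALSE)
  })
  data.frame(node = seq_len(ncol(samples)),
             lower = q[1, ], median = q[2, ], upper = q[3, ])
}

#' Monte Carlo uncertainty quantification of needle deflection
#'
#' Propagates a tissue-property prior through a trained surrogate:
#' sample `n` property vectors from the per-layer prior, expand each into
#' a per-millimetre profile on the prior's layer geometry, batch-predict
#' the 48 nodal deflections at the requested insertion depth, and
#' summarize the ensemble as per-node confidence bands.
#'
#' Direct sampling is the default since the demonstrated priors are
#' independent across layers; `sampler` also accepts a function
#' `function(prior, n)` returning an `n x n_layers` matrix, so chain-based
#' samplers for non-independent priors plug in without changing anything
#' downstream.
#'
#' @param prior A [prior_spec()] (carries the layer geometry).
#' @param depth Insertion depth to predict at, mm.
#' @param model A trained `needle_surrogate`.
#' @param n Number of Monte Carlo samples (default 2000).
#' @param seed Integer seed.
#' @param level Band coverage level.
#' @param sampler `"direct"` or a function `(prior, n) -> matrix`.
#' @return Object of class `needle_uq`: `samples` (n x 48, mm), `draws`
#'   (n x n_layers, MPa), `band` (per-node lower/median/upper),
#'   `tip_band_width` (mm), plus the settings.
#' @export
run_uq <- function(prior, depth, model, n = 2000, seed = 1, level = 0.95,
                   sampler = "direct") {
  stopifnot(inherits(prior, "prior_spec"),
            inherits(model, "needle_surrogate"),
            depth >= 1, depth <= TISSUE_DEPTH_MM)
  if (n < 2 / (1 - level))
    warning(sprintf("n = %d is small for a %.0f%% band; need at least %.0f",
                    n, 100 * level, 2 / (1 - level)))
  draws <- if (is.function(sampler)) sampler(prior, n)
           else if (identical(sampler, "direct")) sample_prior(prior, n, seed)
           else stop("sampler must be \"direct\" or a function(prior, n)")
  stopifnot(nrow(draws) == n, ncol(draws) == prior$n_layers)

  hi <- c(prior$boundaries, TISSUE_DEPTH_MM)
  layer_of_mm <- findInterval(seq_len(TISSUE_DEPTH_MM), hi + 0.5) + 1L
  X <- cbind(draws[, layer_of_mm, drop = FALSE], depth)
  if (all(draws == rep(draws[1, ], each = n))) {
    # degenerate ensemble: predict once so the collapse is bit-exact
    samples <- predict(model, X[1, , drop = FALSE])[rep(1L, n), , drop = FALSE]
  } else {
    samples <- predict(model, X)
  }
  band <- confidence_band(samples, level)
  structure(list(samples = samples, draws = draws, band = band,
                 tip_band_width = band$upper[nrow(band)] -
                   band$lower[nrow(band)],
                 level = level, n = n, seed = seed, depth = depth,
                 sampler = if (is.function(sampler)) "custom" else sampler,
                 prior = prior),
            class = "needle_uq")
}

#' @export
print.needle_uq <- function(x, ...) {
  cat(sprintf("<needle_uq> %d samples (%s), depth %g mm, %.0f%% band\n",
              x$n, x$sampler, x$depth, 100 * x$level))
  cat(sprintf("  tip: median %.3f mm, band [%.3f, %.3f] (width %.3f mm)\n",
              x$band$median[nrow(x$band)], x$band$lower[nrow(x$band)],
              x$band$upper[nrow(x$band)], x$tip_band_width))
  invisible(x)
}

#' Plot a needle-shape confidence band
#'
#' Median predicted needle path with the shaded Monte Carlo band, against
#' axial position along the needle.
#'
#' @param x A `needle_uq`.
#' @param needle A [needle_spec()] for axial node positions.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.needle_uq <- function(x, needle = needle_spec(), ...) {
  pos <- needle$node_positions
  graphics::plot(pos, x$band$median, type = "n",
                 ylim = range(x$band$lower, x$band$upper),
                 xlab = "axial position (mm)", ylab = "deflection (mm)", ...)
  graphics::polygon(c(pos, rev(pos)), c(x$band$lower, rev(x$band$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(pos, x$band$median, lwd = 2, col = "steelblue4")
  invisible(x)
}
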