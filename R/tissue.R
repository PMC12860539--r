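#' Per-millimetre tissue elastic modulus profile
#'
#' A `tissue_profile` holds the elastic modulus of the tissue column the
#' needle traverses, sampled once per millimetre of depth. Entry `i`
#' governs the depth interval `(i - 1, i]` mm, so `modulus[d]` is the
#' modulus seen by the needle tip at integer insertion depth `d`.
#'
#' @param modulus Numeric vector of 125 non-negative elastic moduli, MPa.
#' @return Object of class `tissue_profile` (a numeric vector with class
#'   attribute).
#' @seealso [layered_anatomy()], [anatomy_to_profile()]
#' @export
tissue_profile <- function(modulus) {
  modulus <- as.numeric(modulus)
  if (length(modulus) != TISSUE_DEPTH_MM)
    stop(sprintf("a tissue profile must have exactly %d per-mm values, got %d",
                 TISSUE_DEPTH_MM, length(modulus)))
  if (anyNA(modulus) || any(modulus < 0))
    stop("tissue moduli must be non-negative and finite")
  structure(modulus, class = "tissue_profile")
}

#' @export
print.tissue_profile <- function(x, ...) {
  cat(sprintf("<tissue_profile> %d mm, modulus range [%.4g, %.4g] MPa\n",
              length(x), min(x), max(x)))
  invisible(x)
}

#' Layered tissue anatomy
#'
#' A piecewise-constant description of the tissue column: `n_layers`
#' homogeneous layers separated at integer transition depths. Layer `j`
#' spans depths `(boundaries[j-1], boundaries[j]]` with `boundaries[0] = 0`
#' and the last boundary implicitly 125 mm.
#'
#' @param moduli Elastic modulus of each layer, MPa (one per layer).
#' @param boundaries Increasing integer transition depths strictly inside
#'   `(0, 125)`; length `length(moduli) - 1`. Omit for a single layer.
#' @return Object of class `layered_anatomy`.
#' @examples
#' a <- layered_anatomy(moduli = c(0.1, 0.05), boundaries = 60)
#' profile <- anatomy_to_profile(a)
#' @export
layered_anatomy <- function(moduli, boundaries = numeric(0)) {
  moduli <- as.numeric(moduli)
  boundaries <- as.numeric(boundaries)
  n <- length(moduli)
  if (n < 1 || n > 10)
    stop("an anatomy has between 1 and 10 layers")
  if (length(boundaries) != n - 1)
    stop("need exactly one fewer boundary than layers")
  if (n > 1) {
    if (any(diff(boundaries) <= 0) ||
        boundaries[1] <= 0 || boundaries[n - 1] >= TISSUE_DEPTH_MM)
      stop("boundaries must be strictly increasing within (0, 125)")
  }
  if (any(moduli < 0)) stop("layer moduli must be non-negative")
  structure(list(n_layers = n, boundaries = boundaries, moduli = moduli),
            class = "layered_anatomy")
}

#' @export
print.layered_anatomy <- function(x, ...) {
  cat(sprintf("<layered_anatomy> %d layer(s)\n", x$n_layers))
  lo <- c(0, x$boundaries)
  hi <- c(x$boundaries, TISSUE_DEPTH_MM)
  for (j in seq_len(x$n_layers))
    cat(sprintf("  %3g-%3g mm : %.4g MPa\n", lo[j], hi[j], x$moduli[j]))
  invisible(x)
}

#' Expand a layered anatomy into a per-millimetre profile
#'
#' @param a A [layered_anatomy()].
#' @return A [tissue_profile()]: 125 values, entry `d` equal to the
#'   modulus of the layer containing depth `d`.
#' @export
anatomy_to_profile <- function(a) {
  stopifnot(inherits(a, "layered_anatomy"))
  hi <- c(a$boundaries, TISSUE_DEPTH_MM)
  depth <- seq_len(TISSUE_DEPTH_MM)
  layer <- findInterval(depth, hi + 0.5) + 1L  # depth d in layer j iff d <= hi[j]
  tissue_profile(a$moduli[layer])
}

#' Recover layer structure from a per-millimetre profile
#'
#' Inverse of [anatomy_to_profile()] for piecewise-constant profiles:
#' consecutive runs of equal modulus become layers.
#'
#' @param profile A [tissue_profile()].
#' @return A [layered_anatomy()] (only if the run count is at most 10).
#' @export
profile_to_anatomy <- function(profile) {
  stopifnot(inherits(profile, "tissue_profile"))
  r <- rle(as.numeric(profile))
  layered_anatomy(moduli = r$values,
                  boundaries = cumsum(r$lengths)[-length(r$lengths)])
}

#' Sample a random layered anatomy
#'
#' Draws an anatomy from the generative scheme used to build surrogate
#' training data: the layer count is uniform on 1..10, the `n - 1`
#' transition depths are drawn uniformly without replacement from the
#' interior integer depths 1..124 and sorted, and each layer modulus is
#' uniform on `modulus_range` (default 0 to 0.2 MPa, the range over which
#' the simulator produces realistic soft-tissue responses).
#'
#' Uses the R random number generator; call `set.seed()` for
#' reproducibility.
#'
#' @param n_layers Optional fixed layer count (1..10); sampled if `NULL`.
#' @param modulus_range Length-2 numeric, MPa.
#' @return A [layered_anatomy()].
#' @export
sample_anatomy <- function(n_layers = NULL, modulus_range = c(0, 0.2)) {
  if (is.null(n_layers)) n_layers <- sample.int(10L, 1L)
  stopifnot(n_layers >= 1, n_layers <= 10)
  boundaries <- if (n_layers > 1)
    sort(sample(seq_len(TISSUE_DEPTH_MM - 1L), n_layers - 1L))
  else numeric(0)
  moduli <- stats::runif(n_layers, modulus_range[1], modulus_range[2])
  layered_anatomy(moduli = moduli, boundaries = boundaries)
}
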