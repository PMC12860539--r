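#' Save a trained surrogate to JSON
#'
#' Serializes weights, standardization statistics and (for the FFNN) the
#' Fourier map at full numeric precision, with a metadata block, into a
#' single JSON file that [load_surrogate()] restores exactly.
#'
#' @param model A `needle_surrogate`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_surrogate <- function(model, path) {
  stopifnot(inherits(model, "needle_surrogate"))
  obj <- list(format = "needleuq-surrogate", format_version = 1L,
              kind = model$kind, meta = model$meta)
  if (!is.null(model$coef)) obj$coef <- model$coef
  if (!is.null(model$weights))
    obj$weights <- lapply(model$weights, function(w) {
      if (is.matrix(w)) w else as.numeric(w)
    })
  if (!is.null(model$x_std)) obj$x_std <- model$x_std
  obj$y_std <- model$y_std
  if (!is.null(model$fourier))
    obj$fourier <- list(B = model$fourier$B, scale = model$fourier$scale,
                        m = model$fourier$m, d = model$fourier$d,
                        seed = model$fourier$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a surrogate saved with [save_surrogate()]
#'
#' @param path JSON file path.
#' @return A `needle_surrogate`.
#' @export
load_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "needleuq-surrogate"))
    stop(path, " is not a saved needleuq surrogate")
  as_num <- function(v) lapply(v, function(x) {
    if (is.matrix(x)) x else as.numeric(x)
  })
  model <- list(kind = obj$kind, meta = obj$meta)
  if (!is.null(obj$coef)) model$coef <- obj$coef
  if (!is.null(obj$weights)) {
    w <- obj$weights
    w$b1 <- rbind(as.numeric(w$b1)); w$b2 <- rbind(as.numeric(w$b2))
    w$b3 <- rbind(as.numeric(w$b3))
    model$weights <- w
  }
  if (!is.null(obj$x_std)) model$x_std <- as_num(obj$x_std)
  model$y_std <- as_num(obj$y_std)
  if (!is.null(obj$fourier))
    model$fourier <- structure(
      list(B = obj$fourier$B, scale = obj$fourier$scale,
           m = as.integer(obj$fourier$m), d = as.integer(obj$fourier$d),
           seed = as.integer(obj$fourier$seed)),
      class = "fourier_map")
  structure(model, class = "needle_surrogate")
}

#' Write a UQ result as tab-separated band summary
#'
#' @param uq A `needle_uq`.
#' @param path Output file path.
#' @param needle A [needle_spec()] for axial positions.
#' @return `path`, invisibly.
#' @export
write_uq_band <- function(uq, path, needle = needle_spec()) {
  stopifnot(inherits(uq, "needle_uq"))
  band <- uq$band
  band$position_mm <- needle$node_positions[band$node]
  utils::write.table(band[, c("node", "position_mm", "lower", "median",
                              "upper")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
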