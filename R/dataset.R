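#' Encode a (profile, depth) pair as a surrogate input vector
#'
#' The supervised-learning input is a 126-vector: the 125 per-millimetre
#' tissue moduli followed by the insertion depth in mm. The target is the
#' 48-vector of nodal deflections at that depth.
#'
#' @param profile A [tissue_profile()].
#' @param depth Insertion depth, mm.
#' @return Numeric vector of length 126.
#' @export
encode_input <- function(profile, depth) {
  stopifnot(inherits(profile, "tissue_profile"),
            depth >= 1, depth <= TISSUE_DEPTH_MM)
  c(as.numeric(profile), depth)
}

#' Generate a simulator-backed surrogate training dataset
#'
#' Samples random layered anatomies (see [sample_anatomy()]), simulates
#' each insertion to 125 mm, and emits one encoded sample per integer
#' depth in `depths` (default 1 to 124). The train/validation split is by
#' trajectory: a validation anatomy never appears in training.
#'
#' @param n_train,n_val Number of training / validation trajectories.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @param depths Integer depths at which samples are emitted.
#' @param needle A [needle_spec()].
#' @param t_ref,bevel_direction Passed to [simulate_insertion()].
#' @param modulus_range Passed to [sample_anatomy()].
#' @return Object of class `needle_dataset`: lists `train` and `val`,
#'   each with matrix `X` (`n * length(depths)` x 126), matrix `Y`
#'   (same rows x 48, mm), integer vectors `trajectory` and `depth`
#'   (row metadata), the sampled `anatomies` and `n_failed` (count of
#'   trajectories whose simulation failed and was skipped, normally 0);
#'   plus `depths`, `seed` and the needle.
#' @export
generate_dataset <- function(n_train = 1000, n_val = 2000, seed = 1,
                             depths = 1:124, needle = needle_spec(),
                             t_ref = 1, bevel_direction = 1,
                             modulus_range = c(0, 0.2)) {
  stopifnot(n_train >= 1, n_val >= 0,
            all(depths >= 1), all(depths <= TISSUE_DEPTH_MM))
  depths <- as.integer(depths)
  set.seed(seed)
  build <- function(n) {
    anatomies <- replicate(n, sample_anatomy(modulus_range = modulus_range),
                           simplify = FALSE)
    nx <- n * length(depths)
    X <- matrix(0, nx, TISSUE_DEPTH_MM + 1L)
    Y <- matrix(0, nx, needle$n_nodes)
    failed <- integer(0)
    for (i in seq_len(n)) {
      profile <- anatomy_to_profile(anatomies[[i]])
      traj <- tryCatch(
        simulate_insertion(needle, profile, TISSUE_DEPTH_MM,
                           bevel_direction = bevel_direction,
                           t_ref = t_ref, record_springs = FALSE),
        error = function(e) {
          message("trajectory ", i, " failed and was skipped: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(traj)) { failed <- c(failed, i); next }
      rows <- (i - 1L) * length(depths) + seq_along(depths)
      X[rows, seq_len(TISSUE_DEPTH_MM)] <-
        matrix(as.numeric(profile), length(depths), TISSUE_DEPTH_MM,
               byrow = TRUE)
      X[rows, TISSUE_DEPTH_MM + 1L] <- depths
      Y[rows, ] <- traj$W[depths, , drop = FALSE]
    }
    trajectory <- rep(seq_len(n), each = length(depths))
    depth <- rep(depths, n)
    if (length(failed)) {
      warning(length(failed), " of ", n, " trajectories failed to simulate",
              " and were skipped")
      keep <- !(trajectory %in% failed)
      X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
      trajectory <- trajectory[keep]; depth <- depth[keep]
      anatomies <- anatomies[-failed]
    }
    list(X = X, Y = Y, trajectory = trajectory, depth = depth,
         anatomies = anatomies, n_failed = length(failed))
  }
  train <- build(n_train)
  val <- if (n_val > 0) build(n_val) else NULL
  structure(list(train = train, val = val, depths = depths, seed = seed,
                 needle = needle, t_ref = t_ref,
                 bevel_direction = bevel_direction),
            class = "needle_dataset")
}

#' @export
print.needle_dataset <- function(x, ...) {
  cat(sprintf(
    "<needle_dataset> %d train / %d validation trajectories, %d depths, seed %d\n",
    max(x$train$trajectory), if (is.null(x$val)) 0 else max(x$val$trajectory),
    length(x$depths), x$seed))
  cat(sprintf("  train: %d samples of 126 -> %d\n",
              nrow(x$train$X), ncol(x$train$Y)))
  invisible(x)
}

#' Write a dataset to disk as delimited text plus a manifest
#'
#' Writes `train_X.csv`, `train_Y.csv` (and `val_*` when present) with a
#' leading `trajectory` and `depth` column, and `manifest.json` recording
#' the seed, sizes and generator settings.
#'
#' @param dataset A `needle_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "needle_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump <- function(part, name) {
    if (is.null(part)) return(NULL)
    xd <- data.frame(trajectory = part$trajectory, depth = part$depth,
                     part$X, check.names = FALSE)
    yd <- data.frame(trajectory = part$trajectory, depth = part$depth,
                     part$Y, check.names = FALSE)
    utils::write.csv(xd, file.path(dir, paste0(name, "_X.csv")),
                     row.names = FALSE)
    utils::write.csv(yd, file.path(dir, paste0(name, "_Y.csv")),
                     row.names = FALSE)
  }
  dump(dataset$train, "train")
  dump(dataset$val, "val")
  manifest <- list(
    seed = dataset$seed,
    n_train = max(dataset$train$trajectory),
    n_val = if (is.null(dataset$val)) 0L else max(dataset$val$trajectory),
    depths = dataset$depths,
    t_ref = dataset$t_ref,
    bevel_direction = dataset$bevel_direction,
    needle = dataset$needle[c("length", "outer_diameter", "inner_diameter",
                              "elastic_modulus", "bevel_angle", "n_elements")],
    version = as.character(utils::packageVersion("needleuq")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
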