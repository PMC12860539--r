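#' Default pipeline configuration
#'
#' Returns the fully resolved default configuration used by
#' [run_pipeline()]; supply overrides as a nested list (or a YAML file of
#' the same shape). Dataset sizes default to the desk-scale profile of
#' 1000 training and 2000 validation trajectories; the full-scale study
#' profile (10 000 / 40 000) is obtained by overriding `dataset`.
#'
#' @param overrides Nested list merged over the defaults.
#' @return A named list.
#' @export
default_config <- function(overrides = list()) {
  base <- list(
    seed = 1L,
    output_dir = "needleuq-run",
    stages = c("gen-data", "train", "evaluate", "uq"),
    needle = list(),
    simulate = list(anatomy = list(moduli = 0.05, boundaries = numeric(0)),
                    depth = 125L),
    dataset = list(n_train = 1000L, n_val = 2000L, t_ref = 1,
                   write_csv = FALSE),
    train = list(models = c("ols", "mlp", "ffnn"),
                 mlp = list(lr = 1e-3, epochs = 200L, batch_size = 200L),
                 ffnn = list(lr = 0.005, scale = 0.2, epochs = 500L)),
    evaluate = list(depth = 65L, scope = "all"),
    uq = list(prior = list(mu = c(0.0103, 0.043, 0.0103),
                           sigma = c(0.08, 0.08, 0.08),
                           boundaries = c(40, 80)),
              depth = 100L, n = 2000L, level = 0.95, model = "ffnn"))
  modifyList(base, overrides, keep.null = TRUE)
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  default_config(config)
}

#' Run the simulation-to-UQ pipeline
#'
#' Orchestrates the package end to end: `simulate` (single configured
#' anatomy to a trajectory table), `gen-data` (seeded dataset),
#' `train` (any of OLS / MLP / FFNN), `evaluate` (MAE table at the
#' configured depth) and `uq` (confidence band under the configured
#' prior, using the trained FFNN). Stages run in that order; a stage
#' whose upstream artifact is missing stops with an error naming the
#' stage to run first. Every run writes its resolved configuration
#' (`config.yaml`) beside its outputs, so artifacts are reproducible
#' from the run directory alone.
#'
#' @param config Nested list of overrides over [default_config()], or a
#'   YAML file path.
#' @param stages Character vector of stages to run; defaults to
#'   `config$stages`.
#' @return Invisibly, a list with the in-memory artifacts produced:
#'   `trajectory`, `dataset`, `models`, `mae_table`, `uq`, and
#'   `output_dir`.
#' @export
run_pipeline <- function(config = list(), stages = NULL) {
  cfg <- read_config(config)
  stages <- if (is.null(stages)) cfg$stages else stages
  known <- c("simulate", "gen-data", "train", "evaluate", "uq")
  if (length(bad <- setdiff(stages, known)))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(cfg$output_dir, "config.yaml"))
  needle <- do.call(needle_spec, cfg$needle)
  art <- list(output_dir = cfg$output_dir)

  if ("simulate" %in% stages) {
    a <- layered_anatomy(moduli = unlist(cfg$simulate$anatomy$moduli),
                         boundaries = unlist(cfg$simulate$anatomy$boundaries))
    traj <- simulate_insertion(needle, anatomy_to_profile(a),
                               cfg$simulate$depth, t_ref = cfg$dataset$t_ref)
    write_trajectory(traj, file.path(cfg$output_dir, "trajectory.tsv"))
    art$trajectory <- traj
    message("simulate: trajectory.tsv written (tip deflection ",
            sprintf("%.3f", traj$tip$tip_deflection[cfg$simulate$depth]),
            " mm)")
  }

  if ("gen-data" %in% stages) {
    art$dataset <- generate_dataset(n_train = cfg$dataset$n_train,
                                    n_val = cfg$dataset$n_val,
                                    seed = cfg$seed, needle = needle,
                                    t_ref = cfg$dataset$t_ref)
    if (isTRUE(cfg$dataset$write_csv))
      write_dataset(art$dataset, file.path(cfg$output_dir, "dataset"))
    message("gen-data: ", nrow(art$dataset$train$X), " training samples")
  }

  if ("train" %in% stages) {
    if (is.null(art$dataset))
      stop("train needs a dataset; run the gen-data stage first")
    art$models <- list()
    for (m in cfg$train$models) {
      art$models[[m]] <- switch(m,
        ols = train_ols(art$dataset),
        mlp = do.call(train_mlp, c(list(art$dataset, seed = cfg$seed),
                                   cfg$train$mlp)),
        ffnn = do.call(train_ffnn, c(list(art$dataset, seed = cfg$seed),
                                     cfg$train$ffnn)),
        stop("unknown model kind: ", m))
      save_surrogate(art$models[[m]],
                     file.path(cfg$output_dir, paste0(m, ".json")))
      message("train: ", m, " trained and saved")
    }
  }

  if ("evaluate" %in% stages) {
    if (is.null(art$models))
      stop("evaluate needs trained models; run the train stage first")
    rows <- lapply(names(art$models), function(m) {
      ev <- evaluate_surrogate(art$models[[m]], art$dataset,
                               depth = cfg$evaluate$depth,
                               scope = cfg$evaluate$scope)
      data.frame(model = m, depth_mm = cfg$evaluate$depth,
                 scope = cfg$evaluate$scope, mae_mm = ev$mae,
                 signed_mean_mm = ev$signed_mean,
                 signed_se_mm = ev$signed_se, n = ev$n)
    })
    art$mae_table <- do.call(rbind, rows)
    utils::write.csv(art$mae_table,
                     file.path(cfg$output_dir, "mae_table.csv"),
                     row.names = FALSE)
    message("evaluate: MAE table written")
  }

  if ("uq" %in% stages) {
    mdl <- art$models[[cfg$uq$model]]
    if (is.null(mdl))
      stop("uq needs a trained ", cfg$uq$model, "; run the train stage first")
    prior <- prior_spec(mu = unlist(cfg$uq$prior$mu),
                        sigma = unlist(cfg$uq$prior$sigma),
                        boundaries = unlist(cfg$uq$prior$boundaries))
    art$uq <- run_uq(prior, depth = cfg$uq$depth, model = mdl,
                     n = cfg$uq$n, seed = cfg$seed, level = cfg$uq$level)
    write_uq_band(art$uq, file.path(cfg$output_dir, "uq_band.tsv"), needle)
    message(sprintf("uq: tip band width %.3f mm at depth %g mm",
                    art$uq$tip_band_width, cfg$uq$depth))
  }

  invisible(art)
}
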