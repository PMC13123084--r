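#' Read and validate a pipeline configuration file
#'
#' The configuration is a versioned YAML document with top-level keys
#' `version`, `seed`, `out_dir`, `stages` and optional blocks `simulate`,
#' `windows` and `train`. Unknown top-level keys are rejected so typos
#' fail loudly. The parsed configuration round-trips through
#' [yaml::write_yaml()].
#'
#' @param path Path to a YAML file.
#' @return A named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg A named list with the same structure as the YAML document.
#' @export
validate_pipeline_config <- function(cfg) {
  known <- c("version", "seed", "out_dir", "stages", "simulate", "windows",
             "train")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$version)) stop("config must declare a version",
                                 call. = FALSE)
  all_stages <- c("simulate", "bouts", "features", "train", "optimize",
                  "report")
  cfg$stages <- if (is.null(cfg$stages)) all_stages else unlist(cfg$stages)
  bad <- setdiff(cfg$stages, all_stages)
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg$seed <- as.integer(if (is.null(cfg$seed)) 1L else cfg$seed)
  cfg$out_dir <- if (is.null(cfg$out_dir)) "boutwin_out" else cfg$out_dir
  defaults <- list(
    simulate = list(preset = "default_study", n_subjects = NULL,
                    duration_samples = NULL),
    windows = list(grid = default_window_grid()),
    train = list(folds = 3, iterations = 10, smote = TRUE, smote_k = 5,
                 nrounds = 50)
  )
  for (block in names(defaults)) {
    cfg[[block]] <- utils::modifyList(defaults[[block]],
                                      as.list(cfg[[block]]))
  }
  structure(cfg, class = "pipeline_config")
}

sim_config_from_pipeline <- function(cfg) {
  preset <- cfg$simulate$preset
  args <- list(seed = cfg$seed)
  if (!is.null(cfg$simulate$n_subjects)) {
    args$n_subjects <- cfg$simulate$n_subjects
  }
  if (!is.null(cfg$simulate$duration_samples)) {
    args$duration_samples <- cfg$simulate$duration_samples
  }
  maker <- switch(preset,
                  default_study = default_study_config,
                  two_gait_demo = two_gait_demo_config,
                  stop("unknown simulate preset: ", preset, call. = FALSE))
  do.call(maker, args)
}

write_stage_csv <- function(df, path) {
  df <- dplyr::select(df, !dplyr::where(is.list))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the bout-window analysis pipeline from a configuration
#'
#' Executes the requested stages in order (simulate, bouts, features,
#' train, optimize, report), writing every intermediate artefact as CSV
#' under `out_dir` and a `manifest.yaml` recording the configuration hash,
#' the seed and the files each stage produced. A stage whose artefacts
#' already exist under the same configuration hash is skipped unless
#' `force = TRUE`.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @param out_dir Override the configured output directory.
#' @param seed Override the configured master seed.
#' @param force Re-run stages even when up-to-date artefacts exist.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a named list of artefact paths per executed stage.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         force = FALSE, quiet = FALSE) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else
    validate_pipeline_config(unclass(config))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])

  manifest_path <- file.path(cfg$out_dir, "manifest.yaml")
  manifest <- if (file.exists(manifest_path)) {
    read_manifest(manifest_path)
  } else {
    list(config_hash = cfg_hash, seed = cfg$seed, stages = list())
  }
  if (!identical(manifest$config_hash, cfg_hash)) {
    manifest <- list(config_hash = cfg_hash, seed = cfg$seed, stages = list())
  }
  say <- function(...) if (!quiet) message(...)
  stage_done <- function(stage, files) {
    !force && !is.null(manifest$stages[[stage]]) &&
      all(file.exists(unlist(files)))
  }

  artefacts <- list()
  state <- new.env(parent = emptyenv())

  get_recordings <- function() {
    if (!is.null(state$recordings)) return(state$recordings)
    rec_dir <- file.path(cfg$out_dir, "recordings")
    files <- sort(list.files(rec_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0) {
      stop("no recordings available; run the simulate stage first or place ",
           "recording CSVs under ", rec_dir, call. = FALSE)
    }
    state$recordings <- purrr::map(files, read_recording)
    state$recordings
  }

  for (stage in cfg$stages) {
    t0 <- Sys.time()
    files <- switch(stage,
      simulate = {
        rec_dir <- file.path(cfg$out_dir, "recordings")
        sim <- sim_config_from_pipeline(cfg)
        paths <- file.path(rec_dir,
                           sprintf("subj%02d.csv", seq_len(sim$n_subjects)))
        if (stage_done(stage, paths)) {
          say("simulate: up to date, skipping")
        } else {
          dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
          recs <- simulate_study(sim)
          purrr::walk2(recs, paths, write_recording)
          state$recordings <- recs
        }
        paths
      },
      bouts = {
        path <- file.path(cfg$out_dir, "bout_stats.csv")
        if (stage_done(stage, path)) {
          say("bouts: up to date, skipping")
        } else {
          stats <- study_bout_stats(get_recordings(),
                                    sample_rate_hz = 50)
          write_stage_csv(stats, path)
          state$bout_stats <- stats
        }
        path
      },
      features = {
        grid <- cfg$windows$grid
        paths <- file.path(cfg$out_dir, sprintf("features_w%03d.csv", grid))
        if (stage_done(stage, paths)) {
          say("features: up to date, skipping")
        } else {
          recs <- get_recordings()
          purrr::walk2(grid, paths, function(w, p) {
            write_stage_csv(extract_features(recs, size = w), p)
          })
        }
        paths
      },
      train = {
        path <- file.path(cfg$out_dir, "experiment.csv")
        if (stage_done(stage, path)) {
          say("train: up to date, skipping")
        } else {
          exp_tbl <- run_experiment(
            get_recordings(),
            window_grid = cfg$windows$grid,
            n_folds = cfg$train$folds,
            n_iterations = cfg$train$iterations,
            classifier = classifier_gbt(nrounds = cfg$train$nrounds),
            smote = isTRUE(cfg$train$smote),
            smote_k = cfg$train$smote_k,
            seed = cfg$seed)
          write_stage_csv(exp_tbl, path)
          state$experiment <- exp_tbl
        }
        path
      },
      optimize = {
        path <- file.path(cfg$out_dir, "window_optima.csv")
        if (stage_done(stage, path)) {
          say("optimize: up to date, skipping")
        } else {
          exp_tbl <- state$experiment %||%
            read_experiment_csv(file.path(cfg$out_dir, "experiment.csv"),
                                cfg$windows$grid)
          bstats <- state$bout_stats %||%
            tibble::as_tibble(utils::read.csv(
              file.path(cfg$out_dir, "bout_stats.csv")))
          optima <- optimise_windows(exp_tbl, bstats,
                                     grid = cfg$windows$grid)
          write_stage_csv(optima, path)
          state$optima <- optima
        }
        path
      },
      report = {
        path <- file.path(cfg$out_dir, "bout_comparison.csv")
        if (stage_done(stage, path)) {
          say("report: up to date, skipping")
        } else {
          exp_tbl <- state$experiment %||%
            read_experiment_csv(file.path(cfg$out_dir, "experiment.csv"),
                                cfg$windows$grid)
          optima <- state$optima
          if (is.null(optima)) {
            opt_df <- tibble::as_tibble(utils::read.csv(
              file.path(cfg$out_dir, "window_optima.csv")))
            optima <- structure(opt_df,
                                window_grid = as.integer(cfg$windows$grid),
                                class = c("window_optima",
                                          class(tibble::tibble())))
          }
          write_stage_csv(bout_vs_nonbout_report(exp_tbl, optima), path)
        }
        path
      }
    )
    manifest$stages[[stage]] <- list(
      files = as.list(unlist(files)),
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      2),
      seed = cfg$seed
    )
    artefacts[[stage]] <- files
    say(stage, ": done (",
        manifest$stages[[stage]]$seconds, " s)")
  }
  write_manifest(manifest, manifest_path)
  invisible(artefacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_experiment_csv <- function(path, grid) {
  if (!file.exists(path)) {
    stop("experiment table not found: ", path, call. = FALSE)
  }
  df <- tibble::as_tibble(utils::read.csv(path))
  structure(df, window_grid = as.integer(grid),
            class = c("experiment_table", class(tibble::tibble())))
}

# Minimal JSON writing/reading for the manifest (flat, known structure),
# via yaml's JSON-compatible subset to avoid an extra dependency.
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

read_manifest <- function(path) {
  yaml::read_yaml(path)
}
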