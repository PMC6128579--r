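#' Load and validate a pipeline configuration
#'
#' The pipeline is configured by one YAML file with sections `geometry`,
#' `shadowing`, `ensemble`, `fusion`, `synthetic`, `split` and
#' `evaluation`; every key has a default (the packaged
#' `default_config.yaml`) and unknown sections or keys are rejected with a
#' message listing all offenders.
#'
#' @param path YAML file, or `NULL` for the packaged defaults.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                          package = "cowsense",
                                          mustWork = TRUE))
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  bad <- character()
  for (sec in names(user)) {
    if (!sec %in% names(defaults)) {
      bad <- c(bad, sec)
      next
    }
    for (k in names(user[[sec]])) {
      if (!k %in% names(defaults[[sec]])) bad <- c(bad, paste0(sec, ".", k))
    }
  }
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  cfg <- defaults
  for (sec in names(user)) {
    cfg[[sec]] <- utils::modifyList(cfg[[sec]], user[[sec]])
  }
  # construct and validate the typed components once
  cfg_geometry(cfg); cfg_shadowing(cfg); cfg_fusion(cfg)
  if (!cfg$ensemble$feature_mode %in% c("raw", "summary")) {
    stop("ensemble.feature_mode must be 'raw' or 'summary'")
  }
  structure(cfg, class = "run_config")
}

cfg_geometry <- function(cfg) {
  g <- cfg$geometry
  barn_geometry(
    length_m = g$length_m, width_m = g$width_m,
    sensors = if (!is.null(g$sensors)) do.call(rbind, g$sensors),
    reference = if (!is.null(g$reference)) unlist(g$reference),
    headlock = if (!is.null(g$headlock)) do.call(rbind, g$headlock),
    S = g$S
  )
}

cfg_shadowing <- function(cfg) {
  s <- cfg$shadowing
  shadowing_params(P0 = s$P0, d0 = s$d0, n = s$exponent, sigma = s$sigma)
}

cfg_fusion <- function(cfg) {
  f <- cfg$fusion
  fusion_config(eps1 = f$eps1, eps2 = f$eps2,
                body_length = f$body_length, error_max = f$error_max,
                area_width = cfg$geometry$width_m)
}

cfg_simulation <- function(cfg, seed) {
  simulation_config(
    n_per_class = cfg$synthetic$n_per_class,
    geometry = cfg_geometry(cfg),
    shadowing = cfg_shadowing(cfg),
    feeding_overlap_amp = cfg$synthetic$feeding_overlap_amp,
    n_tags = cfg$synthetic$n_tags,
    seed = seed
  )
}

config_hash <- function(cfg) {
  txt <- yaml::as.yaml(unclass(cfg))
  codes <- utf8ToInt(txt)
  sprintf("%08x", sum(codes * (seq_along(codes) %% 97 + 1)) %% 4294967291)
}

stage_log <- function(stage, cfg, seed) {
  message(sprintf("[cowsense %s] config %s seed %s", stage,
                  config_hash(cfg), format(seed)))
}

require_files <- function(...) {
  paths <- c(...)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         " (run the earlier pipeline stages first)")
  }
  invisible(paths)
}

#' File-based pipeline stages
#'
#' Each stage is a pure function of its input files, the configuration and
#' the seed, reading and writing conventional file names inside `dir`:
#'
#' * `cmd_simulate`: `sensor_log.csv`, `observations.csv`, `truth.csv`;
#' * `cmd_train`: 60/40 episode split (`split.csv`) and the boosted model
#'   (`model.json`), trained on the >5 s-filtered training episodes;
#' * `cmd_predict`: first-stage 7-class predictions for the test episodes
#'   (`first_stage.csv`);
#' * `cmd_locate`: per-second position estimates and headlock distances
#'   (`positions.csv`);
#' * `cmd_fuse`: evidence-fused final labels for the test episodes
#'   (`fused.csv`), using the mean estimated headlock distance over each
#'   episode's classification window;
#' * `cmd_evaluate`: per-class metric tables with bootstrap SDs
#'   (`metrics_stage1.csv`, `metrics_fused.csv`) and plain-text confusion
#'   matrices (`confusion_stage1.txt`, `confusion_fused.txt`).
#'
#' @param cfg a [read_run_config()] result.
#' @param dir working directory of the run.
#' @param seed integer seed; every stochastic step derives from it.
#' @return Each stage invisibly returns the paths it wrote;
#'   `cmd_evaluate` returns the two metric data.frames.
#' @export
cmd_simulate <- function(cfg, dir, seed = 1) {
  stage_log("simulate", cfg, seed)
  generate_dataset(cfg_simulation(cfg, seed), dir)
}

#' @rdname cmd_simulate
#' @export
cmd_train <- function(cfg, dir, seed = 1) {
  stage_log("train", cfg, seed)
  require_files(file.path(dir, "sensor_log.csv"),
                file.path(dir, "observations.csv"))
  log <- read_sensor_log(file.path(dir, "sensor_log.csv"))
  episodes <- read_labeled_observations(file.path(dir, "observations.csv"))
  obs <- observations_from_log(log, episodes)
  kept <- filter_observations(obs)
  split <- split_train_test(kept, train_frac = cfg$split$train_frac,
                            seed = derive_seed(seed, 7L))
  feats <- featurize_observations(kept[split$train],
                                  mode = cfg$ensemble$feature_mode)
  model <- fit_adaboost(
    feats$x, feats$y, L = cfg$ensemble$L,
    weak_learner = list(type = cfg$ensemble$weak_learner,
                        size = cfg$ensemble$hidden_units,
                        maxit = cfg$ensemble$maxit),
    seed = derive_seed(seed, 8L)
  )
  save_ensemble(model, file.path(dir, "model.json"))
  kept_meta <- data.frame(
    tag_id = vapply(kept, function(o) o$tag_id, character(1)),
    start = vapply(kept, function(o) o$samples$timestamp[1], numeric(1)),
    end = vapply(kept, function(o) o$samples$timestamp[o$duration],
                 numeric(1)),
    label = vapply(kept, function(o) o$label, character(1))
  )
  kept_meta$role <- "test"
  kept_meta$role[split$train] <- "train"
  utils::write.csv(kept_meta, file.path(dir, "split.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(file.path(dir, c("model.json", "split.csv")))
}

#' @rdname cmd_simulate
#' @export
cmd_predict <- function(cfg, dir, seed = 1) {
  stage_log("predict", cfg, seed)
  require_files(file.path(dir, "sensor_log.csv"),
                file.path(dir, "model.json"), file.path(dir, "split.csv"))
  log <- read_sensor_log(file.path(dir, "sensor_log.csv"))
  split <- utils::read.csv(file.path(dir, "split.csv"),
                           colClasses = c(tag_id = "character"))
  test <- split[split$role == "test", ]
  obs <- observations_from_log(log, test)
  feats <- featurize_observations(obs, mode = cfg$ensemble$feature_mode)
  model <- load_ensemble(file.path(dir, "model.json"))
  out <- test[, c("tag_id", "start", "end", "label")]
  out$predicted <- predict(model, feats$x)
  utils::write.csv(out, file.path(dir, "first_stage.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(file.path(dir, "first_stage.csv"))
}

#' @rdname cmd_simulate
#' @export
cmd_locate <- function(cfg, dir, seed = 1) {
  stage_log("locate", cfg, seed)
  require_files(file.path(dir, "sensor_log.csv"))
  log <- read_sensor_log(file.path(dir, "sensor_log.csv"))
  geometry <- cfg_geometry(cfg)
  grid <- build_grid(geometry)
  params <- cfg_shadowing(cfg)
  ranging <- shadowing_params(P0 = params$P0, d0 = params$d0,
                              n = params$n, sigma = 0)
  delta <- 0
  f <- cfg$shadowing$reference_measured
  if (!is.null(f)) {
    e <- vertex_sensor_distances(matrix(geometry$reference, ncol = 2),
                                 geometry$sensors)[1, ]
    delta <- correction_coefficient(e, unlist(f))
  }
  pos <- locate_positions(log, grid, ranging, delta)
  utils::write.csv(pos, file.path(dir, "positions.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(file.path(dir, "positions.csv"))
}

#' @rdname cmd_simulate
#' @export
cmd_fuse <- function(cfg, dir, seed = 1) {
  stage_log("fuse", cfg, seed)
  require_files(file.path(dir, "first_stage.csv"),
                file.path(dir, "positions.csv"))
  first <- utils::read.csv(file.path(dir, "first_stage.csv"),
                           colClasses = c(tag_id = "character"))
  pos <- utils::read.csv(file.path(dir, "positions.csv"),
                         colClasses = c(tag_id = "character"))
  d_head <- window_mean_dhead(first, pos)
  fused <- reclassify(first$predicted, d_head, cfg_fusion(cfg))
  out <- cbind(first[, c("tag_id", "start", "end", "label")], fused)
  utils::write.csv(out, file.path(dir, "fused.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(file.path(dir, "fused.csv"))
}

# Mean estimated headlock distance over each episode's centered 6 s
# classification window (averaging the per-second estimates damps the
# per-second localization noise).
window_mean_dhead <- function(episodes, positions, window_len = 6) {
  vapply(seq_len(nrow(episodes)), function(i) {
    e <- episodes[i, ]
    n <- e$end - e$start + 1
    ws <- e$start + floor((n - window_len) / 2)
    rows <- positions$tag_id == e$tag_id &
      positions$timestamp >= ws & positions$timestamp < ws + window_len
    if (!any(rows)) return(NA_real_)
    mean(positions$d_head[rows])
  }, numeric(1))
}

#' @rdname cmd_simulate
#' @export
cmd_evaluate <- function(cfg, dir, seed = 1) {
  stage_log("evaluate", cfg, seed)
  require_files(file.path(dir, "first_stage.csv"),
                file.path(dir, "fused.csv"))
  first <- utils::read.csv(file.path(dir, "first_stage.csv"),
                           colClasses = c(tag_id = "character"))
  fused <- utils::read.csv(file.path(dir, "fused.csv"),
                           colClasses = c(tag_id = "character"))
  B <- cfg$evaluation$bootstrap_B
  m1 <- metrics_report(first$label, first$predicted, B = B,
                       seed = derive_seed(seed, 21L))
  utils::write.csv(m1, file.path(dir, "metrics_stage1.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(format_confusion(confusion_matrix(first$label,
                                               first$predicted)),
             file.path(dir, "confusion_stage1.txt"))
  # fused stage: the feeding/standing re-classification subset
  sub <- fused[fused$first_stage_label %in% confusable_pair() &
                 fused$label %in% confusable_pair(), ]
  m2 <- NULL
  if (nrow(sub)) {
    cm2 <- confusion_matrix(sub$label, sub$final_label,
                            classes = confusable_pair())
    writeLines(format_confusion(cm2), file.path(dir, "confusion_fused.txt"))
    m2 <- metrics_report(sub$label, sub$final_label,
                         classes = confusable_pair(),
                         exclude_uncertain = TRUE, B = B,
                         seed = derive_seed(seed, 22L))
    utils::write.csv(m2, file.path(dir, "metrics_fused.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(list(stage1 = m1, fused = m2))
}

#' Run the whole pipeline in one call
#'
#' `simulate -> train -> predict -> locate -> fuse -> evaluate` on a fresh
#' synthetic dataset.
#'
#' @inheritParams cmd_simulate
#' @return The [cmd_evaluate()] result, invisibly.
#' @export
run_pipeline <- function(cfg = read_run_config(), dir = tempfile("cowrun"),
                         seed = 1) {
  cmd_simulate(cfg, dir, seed)
  cmd_train(cfg, dir, seed)
  cmd_predict(cfg, dir, seed)
  cmd_locate(cfg, dir, seed)
  cmd_fuse(cfg, dir, seed)
  cmd_evaluate(cfg, dir, seed)
}
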