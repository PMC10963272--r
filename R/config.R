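# Experiment orchestration: run configurations, hierarchical seeding, and
# run manifests. Every experiment is a pure function of (config, seed): the
# manifest records the config, derived stage seeds and output checksums so a
# run can be reproduced byte-for-byte.

GENMEM_EXPERIMENTS <- c("stimuli", "consolidate", "sweep", "boundary",
                        "drm", "carmichael", "lesion")

#' Derive independent per-stage seeds from a parent seed
#'
#' `child_k = ((seed mod (2^31 - 1)) * 21493 + 7919 * k + 11) mod (2^31 - 1)`
#' for stage index `k`; every derived seed is a valid 32-bit seed.
#'
#' @param seed Parent integer seed.
#' @param stages Character vector of stage names.
#' @return Named list of integer seeds, one per stage.
#' @export
seed_everything <- function(seed, stages = c("stimuli", "mhn", "vae",
                                             "experiment")) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  base <- as.numeric(seed) %% (2^31 - 1)
  out <- lapply(seq_along(stages), function(k) {
    as.integer((base * 21493 + 7919 * k + 11) %% (2^31 - 1))
  })
  names(out) <- stages
  out
}

#' Build a run configuration
#'
#' @param experiment One of `r paste(GENMEM_EXPERIMENTS, collapse = ", ")`.
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory for run artifacts.
#' @param n_scenes Number of scenes stored in the MHN.
#' @param n_replay Replay samples used to train the VAE.
#' @param beta MHN inverse temperature.
#' @param latent_dim VAE latent dimension.
#' @param max_epochs VAE training epochs.
#' @param corrupt_fraction Cue corruption fraction.
#' @param thresholds Threshold grid for the extended-model sweep.
#' @param ... Additional experiment-specific entries kept verbatim.
#' @return A list of class `run_config`.
#' @export
run_config <- function(experiment, seed = 1L, out_dir = tempfile("genmem_run"),
                       n_scenes = 1000L, n_replay = 1000L, beta = 20,
                       latent_dim = 20L, max_epochs = 20L,
                       corrupt_fraction = 0.1,
                       thresholds = c(0, 0.05, 0.1, 0.2, 0.4), ...) {
  if (!experiment %in% GENMEM_EXPERIMENTS) {
    stop(sprintf("unknown experiment '%s' (expected one of: %s)", experiment,
                 paste(GENMEM_EXPERIMENTS, collapse = ", ")))
  }
  structure(c(list(experiment = experiment, seed = as.integer(seed),
                   out_dir = out_dir, n_scenes = n_scenes,
                   n_replay = n_replay, beta = beta, latent_dim = latent_dim,
                   max_epochs = max_epochs,
                   corrupt_fraction = corrupt_fraction,
                   thresholds = thresholds),
              list(...)),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

consolidated_system <- function(config, seeds) {
  probes <- scene_probes(config$n_scenes, seed = seeds$stimuli)
  store <- hopfield_store(probes$x, beta = config$beta)
  cfg <- scene_vae_config(max_epochs = config$max_epochs,
                          latent_dim = config$latent_dim)
  run <- consolidate(store, cfg, n_replay = config$n_replay,
                     seed = seeds$vae)
  list(probes = probes, store = store, run = run)
}

#' Execute a configured experiment end-to-end
#'
#' Generates stimuli, stores and consolidates as required by the experiment,
#' writes result tables (CSV) and a summary (JSON) into `config$out_dir`, and
#' returns a manifest recording the config, derived seeds, and a checksum
#' inventory of every output file.
#'
#' @param config A [run_config()].
#' @return A list of class `run_manifest`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- seed_everything(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(experiment = config$experiment, seed = config$seed)

  if (config$experiment == "stimuli") {
    probes <- scene_probes(config$n_scenes, seed = seeds$stimuli)
    utils::write.csv(data.frame(label = probes$labels), file.path(
      config$out_dir, "labels.csv"), row.names = FALSE)
    write_factors_json(probes$factors, file.path(config$out_dir,
                                                 "factors.json"))
    summary$n_scenes <- config$n_scenes
  } else if (config$experiment == "consolidate") {
    sys <- consolidated_system(config, seeds)
    utils::write.csv(sys$run$log, file.path(config$out_dir, "log.csv"),
                     row.names = FALSE)
    summary$final_recon <- sys$run$log$recon[nrow(sys$run$log)]
    summary$final_decoding_accuracy <-
      sys$run$log$decoding_accuracy[nrow(sys$run$log)]
    summary$rho_epoch_accuracy <- spearman_rho(
      sys$run$log$epoch, sys$run$log$decoding_accuracy)
  } else if (config$experiment == "sweep") {
    sys <- consolidated_system(config, seeds)
    set.seed(seeds$experiment)
    n_events <- if (is.null(config$n_events)) 100L else config$n_events
    events <- lapply(sample_factors(n_events, simplify = FALSE), function(f) {
      add_novel_features(render_scene(f), sample_overlay())
    })
    sw <- threshold_sweep(sys$run$vae, events, thresholds = config$thresholds,
                          partial_fraction = config$corrupt_fraction,
                          seed = seeds$experiment + 1L)
    utils::write.csv(sw$rows, file.path(config$out_dir, "sweep.csv"),
                     row.names = FALSE)
    summary$rho_pixels <- sw$rho_pixels
    summary$rho_error <- sw$rho_error
  } else if (config$experiment == "boundary") {
    sys <- consolidated_system(config, seeds)
    n_test <- if (is.null(config$n_test)) 50L else config$n_test
    scenes <- sample_boundary_scenes(n_test, seed = seeds$experiment)
    rep <- boundary_experiment(sys$run$vae, scenes,
                               corrupt_fraction = config$corrupt_fraction,
                               seed = seeds$experiment + 1L)
    utils::write.csv(rep$summary, file.path(config$out_dir, "boundary.csv"),
                     row.names = FALSE)
    summary$median_ratio_zoom_out <-
      rep$summary$median_size_ratio[rep$summary$ratio == min(rep$summary$ratio)]
    summary$median_ratio_zoom_in <-
      rep$summary$median_size_ratio[rep$summary$ratio == max(rep$summary$ratio)]
  } else if (config$experiment == "drm") {
    corpus <- preprocess_corpus(generate_corpus(seed = seeds$stimuli))
    fit <- train_bow_vae(corpus, seed = seeds$vae)
    res <- lure_rate_vs_length(corpus, fit$vae, seed = seeds$experiment)
    utils::write.csv(res$table, file.path(config$out_dir, "lure_rates.csv"),
                     row.names = FALSE)
    summary$rho_length_lure <- res$rho
  } else if (config$experiment == "carmichael") {
    sys <- consolidated_system(config, seeds)
    set.seed(seeds$experiment)
    base <- sample_factors(1L)
    scale <- estimate_latent_scale(sys$run$vae,
                                   lapply(sample_factors(50L,
                                                         simplify = FALSE),
                                          render_scene))
    res <- carmichael_experiment(sys$run$vae, base, latent_scale = scale,
                                 seed = seeds$experiment + 1L)
    summary$cube_bias <- res$cube$dist_to_other - res$cube$dist_to_cued
    summary$sphere_bias <- res$sphere$dist_to_other - res$sphere$dist_to_cued
  } else if (config$experiment == "lesion") {
    sys <- consolidated_system(config, seeds)
    system <- memory_system(sys$store, sys$run$vae, sys$run$readout)
    probe <- scene_probes(100L, seed = seeds$experiment)
    intact <- mean(as.character(system_semantic_recall(system, probe$x)) ==
                     as.character(probe$labels))
    lesioned <- lesion(system, "decoder")
    post <- mean(as.character(system_semantic_recall(lesioned, probe$x)) ==
                   as.character(probe$labels))
    summary$semantic_accuracy_intact <- intact
    summary$semantic_accuracy_decoder_lesion <- post
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  # the stored config omits the output location so identical runs written to
  # different directories produce identical artifacts
  portable <- config
  portable$out_dir <- NULL
  jsonlite::write_json(unclass(portable),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- list.files(config$out_dir, full.names = TRUE)
  manifest <- structure(list(
    config = config, seeds = seeds,
    timestamp = format(Sys.time(), tz = "UTC"),
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files))),
    summary = summary
  ), class = "run_manifest")
  jsonlite::write_json(list(seeds = manifest$seeds,
                            files = manifest$files, summary = summary),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run '%s' (seed %d): %d output files in %s\n",
              x$config$experiment, x$config$seed, nrow(x$files),
              x$config$out_dir))
  invisible(x)
}
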