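#' Default run configuration
#'
#' Full nested configuration of an end-to-end run with the reference
#' full-scale defaults: generator N = 5 on 128^3 VOIs, 200 epochs, batch
#' size 3, learning rate 2e-5, lambda_l1 = 100, six self-supervised
#' iterations, and the digital-phantom defaults of [phantom_spec()] with
#' tagging levels 300/600/900 HU (low/moderate/high; the moderate level is
#' held out of pre-training and drives the self-supervised loop). See the
#' methods vignette for the desk-scale settings used by the package's own
#' experiments.
#'
#' @return nested named list of class `ec_run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    phantom = list(
      grid_shape = c(64L, 32L, 32L), spacing = c(1, 1, 1),
      lumen_radius = 6, wall_thickness = 2, fold_amplitude = 1.2,
      fold_frequency = 0.15, fill_fraction = 0.35,
      tissue_hu = 40, air_hu = -1000, background_hu = -100,
      blur_fwhm = 1.2, noise_sigma = 15,
      pseudo_enhancement_strength = 0, pseudo_enhancement_range = 3,
      tagging_levels = list(low = 300, moderate = 600, high = 900),
      heldout_level = "moderate", n_per_level = 2L),
    voi = list(n_per_volume = 3L, S = 128L),
    generator = list(n_layers = 5L, base_channels = 64L, kernel_size = 4L,
                     use_skip_connections = TRUE, dropout_rate = 0),
    discriminator = list(base_channels = 8L),
    loss = list(lambda_l1 = 100),
    train = list(epochs = 200L, batch_size = 3L, learning_rate = 2e-5,
                 adam_betas = c(0.5, 0.999)),
    selfsup = list(iterations = 6L, initial_ec = "threshold",
                   include_fixed_pairs = TRUE),
    eval = list(enabled = TRUE),
    output_dir = "ecgan-run",
    global_seed = 1L), class = "ec_run_config")
}

#' Desk-scale study configuration
#'
#' The package's own scaled-down study conditions, used by its tests and by
#' `scripts/acceptance.R`: 32^3 VOIs, an N = 3 generator with 8 base
#' channels, 30 epochs per training run at batch size 2 with learning rate
#' 2e-4, three self-supervised iterations, one phantom per tagging level
#' with four VOIs per volume, tagging 300/900 HU for pre-training and the
#' held-out 600 HU level driving the self-supervised loop. See the methods
#' vignette for the rationale behind these sizes.
#'
#' @param seed global seed of the run.
#' @param output_dir artifact directory.
#' @return an `ec_run_config`.
#' @export
desk_config <- function(seed = 1L, output_dir = tempfile("ecgan-desk-")) {
  cfg <- default_run_config()
  cfg$phantom$n_per_level <- 1L
  cfg$voi$S <- 32L
  cfg$voi$n_per_volume <- 4L
  cfg$generator$n_layers <- 3L
  cfg$generator$base_channels <- 8L
  cfg$discriminator$base_channels <- 8L
  cfg$train$epochs <- 30L
  cfg$train$batch_size <- 2L
  cfg$train$learning_rate <- 2e-4
  cfg$selfsup$iterations <- 3L
  cfg$global_seed <- as.integer(seed)
  cfg$output_dir <- output_dir
  cfg
}

merge_strict <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  assert_that(is.list(user), "config section '%s' must be a mapping", path,
              class = "ec_config_error")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop_ec("unknown config key%s: %s", if (length(unknown) > 1) "s" else "",
            paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                   collapse = ", "),
            class = "ec_config_error")
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_strict(defaults[[k]], user[[k]],
                                    paste0(path, ".", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  N <- cfg$generator$n_layers
  S <- cfg$voi$S
  if (S %% 2^N != 0)
    stop_ec("voi.S = %d is not divisible by 2^generator.N = %d", S, 2^N,
            class = "ec_config_error")
  if (S %% 8 != 0 || S / 8 - 2 < 1)
    stop_ec("voi.S = %d is incompatible with the discriminator (need S divisible by 8, S/8 - 2 >= 1)",
            S, class = "ec_config_error")
  assert_that(cfg$selfsup$iterations >= 0,
              "selfsup.iterations must be >= 0",
              class = "ec_config_error")
  assert_that(cfg$phantom$heldout_level %in% names(cfg$phantom$tagging_levels),
              "phantom.heldout_level must name one of phantom.tagging_levels",
              class = "ec_config_error")
  # exercise the component validators on the embedded sub-configs
  run_config_phantom_spec(cfg, cfg$phantom$tagging_levels[[1]], seed = 1L)
  generator_config(N = N, base_channels = cfg$generator$base_channels,
                   kernel_size = cfg$generator$kernel_size,
                   use_skip_connections = cfg$generator$use_skip_connections,
                   dropout_rate = cfg$generator$dropout_rate)
  loss_config(cfg$loss$lambda_l1)
  train_config(epochs = cfg$train$epochs, batch_size = cfg$train$batch_size,
               learning_rate = cfg$train$learning_rate,
               adam_betas = cfg$train$adam_betas)
  invisible(cfg)
}

run_config_phantom_spec <- function(cfg, tagging_hu, seed) {
  p <- cfg$phantom
  phantom_spec(grid_shape = p$grid_shape, spacing = p$spacing,
               lumen_radius = p$lumen_radius,
               wall_thickness = p$wall_thickness,
               fold_amplitude = p$fold_amplitude,
               fold_frequency = p$fold_frequency,
               fill_fraction = p$fill_fraction,
               tagging_hu = tagging_hu, tissue_hu = p$tissue_hu,
               air_hu = p$air_hu, background_hu = p$background_hu,
               blur_fwhm = p$blur_fwhm, noise_sigma = p$noise_sigma,
               pseudo_enhancement_strength = p$pseudo_enhancement_strength,
               pseudo_enhancement_range = p$pseudo_enhancement_range,
               seed = seed)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills every omitted key with the defaults of
#' [default_run_config()], rejects unknown keys (strict mode — silent typos
#' in training configs are costly), and validates cross-field consistency
#' such as the divisibility of the VOI size by `2^N`. An empty file yields
#' the full default configuration.
#'
#' @param path YAML file path.
#' @return an `ec_run_config`.
#' @export
load_config <- function(path) {
  assert_that(file.exists(path), "config file '%s' does not exist", path,
              class = "ec_io_error")
  user <- yaml::read_yaml(path)
  cfg <- merge_strict(default_run_config(), user)
  cfg$phantom$grid_shape <- as.integer(cfg$phantom$grid_shape)
  class(cfg) <- "ec_run_config"
  validate_run_config(cfg)
  cfg
}

#' Write a run configuration to YAML
#'
#' @param cfg an `ec_run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the pipeline end to end
#'
#' Executes the whole study on the digital phantom: simulate registered
#' phantom pairs at the training tagging levels plus the held-out level;
#' compute centerlines from the lumen masks and extract matched VOIs;
#' assemble fixed-truth pairs from the training levels; pre-train; run the
#' self-supervised loop on the held-out level's uncleansed VOIs; evaluate
#' PSNR against the held-out native ground truth after every stage. All
#' stage seeds derive deterministically from `cfg$global_seed`, so a run is
#' bit-reproducible.
#'
#' Artifacts written under `cfg$output_dir`: `psnr_curve.csv` (iteration
#' curve), `loss_history.csv`, `generator.rds` / `discriminator.rds`
#' checkpoints, `config.yaml`, and `manifest.json` (config, derived seeds,
#' versions).
#'
#' @param cfg an `ec_run_config`.
#' @return invisibly, a list with the final `state`, the PSNR `curve` data
#'   frame, the uncleansed-input `baseline` PSNR report, the `eval_pairs`
#'   used for scoring, and the artifact `dir`.
#' @export
run_end_to_end <- function(cfg) {
  validate_run_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  gs <- cfg$global_seed
  levels <- cfg$phantom$tagging_levels
  heldout <- cfg$phantom$heldout_level
  train_levels <- setdiff(names(levels), heldout)
  seeds <- list(train = stage_seed(gs, "train"))

  simulate_level <- function(level) {
    seeds[[paste0("phantom-", level)]] <<- stage_seed(gs, paste0("phantom-", level))
    spec <- run_config_phantom_spec(cfg, levels[[level]],
                                    seed = seeds[[paste0("phantom-", level)]])
    batch_generate(spec, cfg$phantom$n_per_level,
                   base_seed = seeds[[paste0("phantom-", level)]])
  }

  S <- cfg$voi$S
  vois_of <- function(pairs, level) {
    tagged <- list(); native <- list()
    for (i in seq_along(pairs)) {
      pp <- pairs[[i]]
      cl <- compute_centerline(pp$lumen_mask, spacing = pp$native$spacing)
      centers <- sample_positions(cl, cfg$voi$n_per_volume, S,
                                  dim(pp$native$voxels))
      id <- sprintf("%s-%d", level, i)
      tagged <- c(tagged, extract_vois(normalize_hu(pp$tagged, id), centers, S))
      native <- c(native, extract_vois(normalize_hu(pp$native, id), centers, S))
    }
    list(tagged = tagged, native = native)
  }

  fixed_pairs <- list()
  for (lv in train_levels) {
    vv <- vois_of(simulate_level(lv), lv)
    fixed_pairs <- c(fixed_pairs, make_fixed_pairs(vv$tagged, vv$native))
  }
  held <- vois_of(simulate_level(heldout), heldout)
  eval_pairs <- if (isTRUE(cfg$eval$enabled))
    make_fixed_pairs(held$tagged, held$native) else NULL

  gcfg <- generator_config(N = cfg$generator$n_layers,
                           base_channels = cfg$generator$base_channels,
                           kernel_size = cfg$generator$kernel_size,
                           use_skip_connections = cfg$generator$use_skip_connections,
                           dropout_rate = cfg$generator$dropout_rate)
  lcfg <- loss_config(cfg$loss$lambda_l1)
  tcfg <- train_config(epochs = cfg$train$epochs,
                       batch_size = cfg$train$batch_size,
                       learning_rate = cfg$train$learning_rate,
                       adam_betas = cfg$train$adam_betas,
                       seed = seeds$train)
  scfg <- selfsup_config(iterations = cfg$selfsup$iterations,
                         per_iteration_train = tcfg,
                         initial_ec = cfg$selfsup$initial_ec,
                         include_fixed_pairs = cfg$selfsup$include_fixed_pairs)

  state <- run_selfsup(fixed_pairs, held$tagged, scfg, gcfg, lcfg,
                       eval_pairs = eval_pairs,
                       d_base_channels = cfg$discriminator$base_channels)

  # no-op reference: PSNR of the uncleansed input itself against the truth
  baseline <- if (!is.null(eval_pairs))
    evaluate_generator(fn_generator(identity), eval_pairs,
                       label = list(condition = "uncleansed")) else NULL

  curve <- if (length(state$psnr_history) > 0)
    iteration_curve(state$psnr_history) else NULL
  if (!is.null(curve))
    write.csv(curve, file.path(cfg$output_dir, "psnr_curve.csv"),
              row.names = FALSE)
  if (!is.null(state$history))
    write.csv(state$history, file.path(cfg$output_dir, "loss_history.csv"),
              row.names = FALSE)
  save_model(state$G, file.path(cfg$output_dir, "generator.rds"))
  save_model(state$D, file.path(cfg$output_dir, "discriminator.rds"))
  save_config(cfg, file.path(cfg$output_dir, "config.yaml"))
  manifest <- list(config = unclass(cfg), seeds = seeds,
                   r_version = R.version.string,
                   package_version =
                     as.character(utils::packageVersion("ecgan")))
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(state = state, curve = curve, baseline = baseline,
                 eval_pairs = eval_pairs, dir = cfg$output_dir))
}

#' Save / load a network checkpoint
#'
#' Checkpoints store the network's configuration and parameters in a single
#' RDS archive.
#'
#' @param net an `ec_generator` or `ec_discriminator`.
#' @param path file path.
#' @return `path` (save) or the restored network (load).
#' @export
save_model <- function(net, path) {
  assert_that(inherits(net, c("ec_generator", "ec_discriminator")),
              "net must be a generator or discriminator")
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  net <- readRDS(path)
  assert_that(inherits(net, c("ec_generator", "ec_discriminator")),
              "'%s' does not contain a network checkpoint", path,
              class = "ec_io_error")
  net
}
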