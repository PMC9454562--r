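#' Self-supervised loop configuration
#'
#' Settings of the iterative fine-tuning loop: the number of
#' self-supervised iterations `T` (the reference operating point is six
#' iterations with an N = 5 generator), the per-iteration training
#' configuration, the initial-EC method used to seed the first dynamic
#' targets, and whether the fixed-truth pairs stay in the per-iteration
#' training set (they do, by default).
#'
#' @param iterations number of self-supervised iterations T, >= 0.
#' @param per_iteration_train a [train_config()] used for each iteration
#'   (and, by default, for pre-training).
#' @param initial_ec `"threshold"` (default, see
#'   [ec_threshold_initializer()]), `"identity"`, or a VOI-to-VOI function.
#' @param include_fixed_pairs keep fixed-truth pairs in the training set of
#'   every iteration?
#' @return an object of class `ec_selfsup_config`.
#' @export
selfsup_config <- function(iterations = 6L,
                           per_iteration_train = train_config(),
                           initial_ec = "threshold",
                           include_fixed_pairs = TRUE) {
  assert_that(iterations >= 0, "iterations must be >= 0")
  structure(list(iterations = as.integer(iterations),
                 per_iteration_train = per_iteration_train,
                 initial_ec = initial_ec,
                 include_fixed_pairs = isTRUE(include_fixed_pairs)),
            class = "ec_selfsup_config")
}

resolve_initial_ec <- function(spec) {
  if (is.function(spec)) return(spec)
  switch(as.character(spec),
         threshold = ec_threshold_initializer(),
         identity = function(x) x,
         stop_ec("unknown initial_ec method '%s'", spec,
                 class = "ec_config_error"))
}

new_training_state <- function(G, D, fixed_pairs, dynamic_pairs = list(),
                               iteration = 0L, history = NULL,
                               psnr_history = list()) {
  structure(list(iteration = as.integer(iteration), G = G, D = D,
                 fixed_pairs = fixed_pairs, dynamic_pairs = dynamic_pairs,
                 history = history, psnr_history = psnr_history),
            class = "ec_training_state")
}

#' @export
print.ec_training_state <- function(x, ...) {
  cat(sprintf("<training state> iteration %d, %d fixed + %d dynamic pairs\n",
              x$iteration, length(x$fixed_pairs), length(x$dynamic_pairs)))
  invisible(x)
}

#' Supervised pre-training on fixed-truth pairs
#'
#' Builds fresh generator/discriminator networks (weights seeded from
#' `tcfg$seed`) and trains them on the fixed-truth pairs alone — the
#' registered clean/tagged phantom VOIs with known desired output. Returns
#' a training state at iteration 0 with an empty dynamic-pair set.
#'
#' @param fixed_pairs non-empty list of `ec_voi_pair`, all with provenance
#'   `"fixed"`.
#' @param gcfg a [generator_config()].
#' @param tcfg a [train_config()].
#' @param lcfg a [loss_config()].
#' @param d_base_channels discriminator width.
#' @return an `ec_training_state`.
#' @export
pretrain <- function(fixed_pairs, gcfg, tcfg, lcfg, d_base_channels = 8L) {
  assert_that(length(fixed_pairs) >= 1, "fixed_pairs is empty")
  prov <- vapply(fixed_pairs, function(p) p$provenance, character(1))
  assert_that(all(prov == "fixed"),
              "pretrain accepts only fixed-truth pairs")
  S <- dim(fixed_pairs[[1]]$x$values)[1]
  set.seed(stage_seed(tcfg$seed, "init"))
  G <- build_generator(gcfg, S)
  D <- build_discriminator(S, base_channels = d_base_channels)
  res <- train_gan(fixed_pairs, G, D, tcfg, lcfg)
  new_training_state(res$G, res$D, fixed_pairs,
                     history = if (nrow(res$history) > 0)
                       cbind(iteration = 0L, res$history) else NULL)
}

#' Seed the dynamic-truth pairs of a training state
#'
#' Pairs each uncleansed VOI with an initial-EC estimate (see
#' [make_dynamic_pairs()]); these targets are replaced by the generator's
#' own output at the end of every subsequent self-supervised iteration.
#'
#' @param state an `ec_training_state` from [pretrain()].
#' @param uncleansed_vois list of [voi()].
#' @param initial_ec method identifier or function (see
#'   [selfsup_config()]).
#' @return the updated state.
#' @export
seed_dynamic_pairs <- function(state, uncleansed_vois,
                               initial_ec = "threshold") {
  state$dynamic_pairs <-
    make_dynamic_pairs(uncleansed_vois, resolve_initial_ec(initial_ec))
  state
}

#' One self-supervised training iteration
#'
#' Trains the networks on the union of fixed-truth and dynamic-truth pairs
#' for `cfg$per_iteration_train$epochs` epochs (the generator and
#' discriminator weights carry over — fine-tuning continues, nothing is
#' re-initialised), then regenerates every dynamic pair's target as the
#' newly trained generator applied to its input, and increments the
#' iteration counter. Fixed pairs are never touched.
#'
#' @param state an `ec_training_state` with non-empty `dynamic_pairs`.
#' @param cfg a [selfsup_config()].
#' @param lcfg a [loss_config()].
#' @return the updated state.
#' @export
selfsup_iteration <- function(state, cfg, lcfg = loss_config()) {
  assert_that(inherits(state, "ec_training_state"),
              "state must be a training state")
  assert_that(length(state$dynamic_pairs) >= 1,
              "dynamic_pairs is empty; call seed_dynamic_pairs() first")
  it <- state$iteration + 1L
  tcfg <- cfg$per_iteration_train
  tcfg$seed <- stage_seed(tcfg$seed, paste0("selfsup-iter-", it))
  train_set <- if (cfg$include_fixed_pairs)
    c(state$fixed_pairs, state$dynamic_pairs) else state$dynamic_pairs
  state$last_train_size <- length(train_set)
  res <- train_gan(train_set, state$G, state$D, tcfg, lcfg)
  state$G <- res$G
  state$D <- res$D
  state$dynamic_pairs <- lapply(state$dynamic_pairs, function(p) {
    p$y <- apply_generator(state$G, p$x)
    p
  })
  state$iteration <- it
  if (nrow(res$history) > 0)
    state$history <- rbind(state$history, cbind(iteration = it, res$history))
  state
}

#' Run the full self-supervised training scheme
#'
#' Pre-trains on the fixed-truth pairs, seeds dynamic-truth pairs from the
#' uncleansed VOIs via the initial-EC method, then runs `cfg$iterations`
#' self-supervised iterations in which the evolving generator regenerates
#' its own dynamic targets. When `eval_pairs` are supplied, cleansing
#' quality (PSNR of G(x) against the desired output) is recorded after
#' pre-training and after every iteration, giving `iterations + 1` entries.
#' With `iterations = 0` the returned generator is exactly the pre-trained
#' one.
#'
#' @param fixed_pairs fixed-truth pairs for pre-training.
#' @param uncleansed_vois VOIs of the input case to be cleansed.
#' @param cfg a [selfsup_config()].
#' @param gcfg a [generator_config()].
#' @param lcfg a [loss_config()].
#' @param eval_pairs optional evaluation pairs (uncleansed VOI, desired EC
#'   VOI) scored after each stage.
#' @param pretrain_train optional [train_config()] for pre-training;
#'   defaults to `cfg$per_iteration_train`.
#' @param d_base_channels discriminator width.
#' @return the final `ec_training_state`, with `psnr_history` filled when
#'   `eval_pairs` were given.
#' @export
run_selfsup <- function(fixed_pairs, uncleansed_vois, cfg, gcfg,
                        lcfg = loss_config(), eval_pairs = NULL,
                        pretrain_train = NULL, d_base_channels = 8L) {
  tcfg <- pretrain_train %||% cfg$per_iteration_train
  state <- pretrain(fixed_pairs, gcfg, tcfg, lcfg,
                    d_base_channels = d_base_channels)
  if (!is.null(eval_pairs))
    state$psnr_history <- list(
      evaluate_generator(state$G, eval_pairs,
                         label = list(N = gcfg$N, iteration = 0L)))
  if (length(uncleansed_vois) > 0)
    state <- seed_dynamic_pairs(state, uncleansed_vois, cfg$initial_ec)
  for (t in seq_len(cfg$iterations)) {
    state <- selfsup_iteration(state, cfg, lcfg)
    if (!is.null(eval_pairs))
      state$psnr_history[[length(state$psnr_history) + 1L]] <-
        evaluate_generator(state$G, eval_pairs,
                           label = list(N = gcfg$N, iteration = t))
  }
  state
}

#' Apply a generator to a whole volume by overlapping tiles
#'
#' Covers the volume with overlapping S^3 tiles, runs the generator on each
#' and blends the overlapping predictions by cosine-ramp weighted
#' averaging, so tile seams are feathered and the blend weights sum to one
#' at every voxel. Volumes smaller than the tile in any axis are padded by
#' edge replication and cropped back.
#'
#' @param G a generator (trained network or [fn_generator()] mock).
#' @param nvol a [normalized_volume()] (or bare 3D array).
#' @param tile_S tile edge length compatible with `G`.
#' @param overlap voxels of overlap between neighbouring tiles
#'   (`0 <= overlap < tile_S`).
#' @return same type as `nvol` with cleansed values.
#' @export
apply_full_volume <- function(G, nvol, tile_S, overlap = 16L) {
  vals <- if (inherits(nvol, "ec_nvol")) nvol$values else nvol
  assert_that(overlap >= 0 && overlap < tile_S,
              "need 0 <= overlap < tile_S")
  d0 <- dim(vals)
  # pad up to tile size by edge replication if needed
  d <- pmax(d0, tile_S)
  if (any(d > d0)) {
    padded <- array(0, dim = d)
    ix <- clamp(seq_len(d[1]), 1, d0[1])
    iy <- clamp(seq_len(d[2]), 1, d0[2])
    iz <- clamp(seq_len(d[3]), 1, d0[3])
    padded[] <- vals[ix, iy, iz]
    vals <- padded
  }
  step <- tile_S - overlap
  starts_axis <- function(n) {
    s <- seq(1L, max(n - tile_S + 1L, 1L), by = step)
    if (s[length(s)] != n - tile_S + 1L) s <- c(s, n - tile_S + 1L)
    unique(s)
  }
  w1 <- rep(1, tile_S)
  if (overlap > 0) {
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(overlap) - 0.5) / overlap)
    w1[seq_len(overlap)] <- pmin(w1[seq_len(overlap)], ramp)
    w1[tile_S + 1 - seq_len(overlap)] <-
      pmin(w1[tile_S + 1 - seq_len(overlap)], ramp)
  }
  wt <- outer(outer(w1, w1), w1)
  dim(wt) <- c(tile_S, tile_S, tile_S)
  acc <- array(0, dim = d)
  wacc <- array(0, dim = d)
  for (sx in starts_axis(d[1])) for (sy in starts_axis(d[2]))
    for (sz in starts_axis(d[3])) {
      rx <- sx:(sx + tile_S - 1)
      ry <- sy:(sy + tile_S - 1)
      rz <- sz:(sz + tile_S - 1)
      pred <- apply_generator(G, vals[rx, ry, rz])
      acc[rx, ry, rz] <- acc[rx, ry, rz] + pred * wt
      wacc[rx, ry, rz] <- wacc[rx, ry, rz] + wt
    }
  out <- acc / wacc
  out <- out[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
  dim(out) <- d0
  if (inherits(nvol, "ec_nvol"))
    normalized_volume(clamp(out, -1, 1), spacing = nvol$spacing,
                      source_id = nvol$source_id)
  else out
}
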