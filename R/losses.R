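#' Loss configuration
#'
#' Holds the weight `lambda_l1` of the L1 reconstruction term relative to
#' the adversarial term in the generator objective. The default of 100
#' follows the classic image-to-image translation setting.
#'
#' @param lambda_l1 non-negative L1 weight.
#' @return an object of class `ec_loss_config`.
#' @export
loss_config <- function(lambda_l1 = 100) {
  assert_that(lambda_l1 >= 0, "lambda_l1 must be non-negative")
  structure(list(lambda_l1 = lambda_l1), class = "ec_loss_config")
}

#' Training configuration
#'
#' Optimisation hyperparameters for adversarial training. The full-scale
#' reference setting is 200 epochs, batch size 3, Adam with learning rate
#' 2e-5 and betas (0.5, 0.999); all are configurable for desk-scale runs.
#'
#' @param epochs number of passes over the pair set (0 is allowed and
#'   leaves the networks untouched).
#' @param batch_size mini-batch size, >= 1.
#' @param learning_rate Adam step size, > 0.
#' @param adam_betas length-2 numeric, Adam moment decays.
#' @param seed integer seed driving shuffling, dropout and (via
#'   [pretrain()]) weight initialisation.
#' @return an object of class `ec_train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 3L,
                         learning_rate = 2e-5,
                         adam_betas = c(0.5, 0.999), seed = 1L) {
  assert_that(epochs >= 0, "epochs must be >= 0")
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  assert_that(learning_rate > 0, "learning_rate must be > 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 adam_betas = as.numeric(adam_betas),
                 seed = as.integer(seed)),
            class = "ec_train_config")
}

check_scores <- function(s, what) {
  assert_that(all(s > -1e-8) && all(s < 1 + 1e-8),
              "%s scores must lie in (0, 1)", what,
              class = "ec_contract_error")
  clamp(s, 1e-12, 1 - 1e-12)
}

#' Conditional adversarial loss
#'
#' The discriminator objective `E[log D(x, y)] + E[log(1 - D(x, G(x)))]`
#' evaluated as the mean over all patch scores (and batch entries) of
#' `log d_real + log(1 - d_fake)`, clamped away from `log 0`. The
#' discriminator maximises this; its optimum (real scores near 1, fake
#' scores near 0) approaches 0 from below.
#'
#' @param d_real_scores,d_fake_scores numeric vectors/arrays (or lists of
#'   them) of patch scores in (0, 1).
#' @return scalar loss value.
#' @export
adversarial_loss <- function(d_real_scores, d_fake_scores) {
  r <- unlist(d_real_scores, use.names = FALSE)
  f <- unlist(d_fake_scores, use.names = FALSE)
  r <- check_scores(r, "real")
  f <- check_scores(f, "fake")
  mean(log(r)) + mean(log(1 - f))
}

#' L1 reconstruction loss
#'
#' Mean absolute voxel difference between the desired EC volume `y` and the
#' generated volume `G(x)`; this is the term that pulls the generator
#' toward the desired cleansing.
#'
#' @param y,g_x numeric arrays (or [voi()] objects) of identical shape.
#' @return scalar mean absolute difference.
#' @export
l1_loss <- function(y, g_x) {
  yv <- if (inherits(y, "ec_voi")) y$values else y
  gv <- if (inherits(g_x, "ec_voi")) g_x$values else g_x
  assert_that(identical(dim(yv) %||% length(yv), dim(gv) %||% length(gv)),
              "l1_loss: shape mismatch", class = "ec_contract_error")
  mean(abs(yv - gv))
}

#' Generator-side objective
#'
#' Combines the generator's adversarial component with the weighted L1
#' term: `adv + lambda_l1 * l1`. The adversarial component is the
#' non-saturating form `-E[log D(x, G(x))]` as used during training; with
#' `lambda_l1 = 0` the objective reduces to the adversarial component
#' alone.
#'
#' @param adv_component scalar adversarial component.
#' @param l1_component scalar L1 component.
#' @param cfg a [loss_config()].
#' @return scalar objective.
#' @export
generator_objective <- function(adv_component, l1_component, cfg) {
  assert_that(inherits(cfg, "ec_loss_config"), "cfg must be a loss_config")
  adv_component + cfg$lambda_l1 * l1_component
}
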