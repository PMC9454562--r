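#' Adversarial training on VOI pairs
#'
#' Alternating mini-batch training of the 3D GAN: each batch first takes a
#' discriminator step (ascend `E[log D(x,y)] + E[log(1 - D(x,G(x)))]` with
#' G held fixed) and then a generator step (descend the non-saturating
#' adversarial term `-E[log D(x,G(x))]` plus `lambda_l1` times the L1
#' loss). Both networks use Adam; data order is reshuffled every epoch from
#' `tcfg$seed`, so a run is bit-reproducible given the same inputs, config
#' and seed. With `epochs = 0` the networks are returned unchanged.
#'
#' @param pairs non-empty list of VOI pairs (`ec_voi_pair`).
#' @param G a [build_generator()] network.
#' @param D a [build_discriminator()] network.
#' @param tcfg a [train_config()].
#' @param lcfg a [loss_config()].
#' @return list with updated `G`, `D` and `history`, a data frame of
#'   per-epoch mean losses (`d_loss` is the discriminator's maximised
#'   objective, `g_adv` the non-saturating generator term, `g_l1` the L1
#'   term, `g_obj` the combined generator objective).
#' @export
train_gan <- function(pairs, G, D, tcfg, lcfg) {
  assert_that(length(pairs) >= 1, "pair list is empty")
  assert_that(inherits(tcfg, "ec_train_config"), "tcfg must be a train_config")
  assert_that(inherits(lcfg, "ec_loss_config"), "lcfg must be a loss_config")
  empty_hist <- data.frame(epoch = integer(0), d_loss = numeric(0),
                           g_adv = numeric(0), g_l1 = numeric(0),
                           g_obj = numeric(0))
  if (tcfg$epochs == 0)
    return(list(G = G, D = D, history = empty_hist))

  S <- dim(pairs[[1]]$x$values)[1]
  xs <- lapply(pairs, function(p) matrix(as.numeric(p$x$values), nrow = 1))
  ys <- lapply(pairs, function(p) matrix(as.numeric(p$y$values), nrow = 1))
  dims <- dim(pairs[[1]]$x$values)
  V <- prod(dims)

  set.seed(tcfg$seed)
  pG <- get_params(G)
  pD <- get_params(D)
  optG <- adam_init(pG)
  optD <- adam_init(pD)
  lr <- tcfg$learning_rate
  betas <- tcfg$adam_betas
  lam <- lcfg$lambda_l1
  n <- length(pairs)
  hist <- vector("list", tcfg$epochs)

  for (epoch in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
    ep <- c(d_loss = 0, g_adv = 0, g_l1 = 0, g_obj = 0)
    for (batch in batches) {
      B <- length(batch)
      # --- discriminator step (G fixed) ---
      gD <- NULL
      d_obj <- 0
      fakes <- vector("list", B)
      for (bi in seq_len(B)) {
        i <- batch[bi]
        fake <- g_forward(G, xs[[i]], dims, train = TRUE, keep = FALSE)$out
        fakes[[bi]] <- fake
        fr <- d_forward(D, rbind(xs[[i]], ys[[i]]), dims, keep = TRUE)
        ff <- d_forward(D, rbind(xs[[i]], fake), dims, keep = TRUE)
        r <- clamp(fr$out, 1e-12, 1 - 1e-12)
        f <- clamp(ff$out, 1e-12, 1 - 1e-12)
        P <- length(r)
        d_obj <- d_obj + (mean(log(r)) + mean(log(1 - f))) / B
        # gradients of the minimised loss (-objective), averaged over batch
        dreal <- -(1 / (B * P)) / r
        dfake <- (1 / (B * P)) / (1 - f)
        gD <- acc_grads(gD, d_backward(D, fr$cache, dreal)$grads)
        gD <- acc_grads(gD, d_backward(D, ff$cache, dfake)$grads)
      }
      st <- adam_step(pD, gD, optD, lr, betas)
      pD <- st$params; optD <- st$state
      D <- set_params(D, pD)

      # --- generator step (D fixed) ---
      gG <- NULL
      adv_acc <- 0; l1_acc <- 0
      for (bi in seq_len(B)) {
        i <- batch[bi]
        gf <- g_forward(G, xs[[i]], dims, train = TRUE, keep = TRUE)
        fake <- gf$out
        df <- d_forward(D, rbind(xs[[i]], fake), dims, keep = TRUE)
        s <- clamp(df$out, 1e-12, 1 - 1e-12)
        P <- length(s)
        adv <- -mean(log(s))
        l1 <- mean(abs(fake - ys[[i]]))
        adv_acc <- adv_acc + adv / B
        l1_acc <- l1_acc + l1 / B
        ds <- -(1 / (B * P)) / s
        dxd <- d_backward(D, df$cache, ds)$dx
        dfake <- dxd[2, , drop = FALSE] +
          (lam / (B * V)) * sign(fake - ys[[i]])
        gG <- acc_grads(gG, g_backward(G, gf$cache, dfake)$grads)
      }
      st <- adam_step(pG, gG, optG, lr, betas)
      pG <- st$params; optG <- st$state
      G <- set_params(G, pG)

      w <- B / n
      ep <- ep + w * c(d_loss = d_obj, g_adv = adv_acc, g_l1 = l1_acc,
                       g_obj = adv_acc + lam * l1_acc)
    }
    hist[[epoch]] <- data.frame(epoch = epoch, d_loss = ep["d_loss"],
                                g_adv = ep["g_adv"], g_l1 = ep["g_l1"],
                                g_obj = ep["g_obj"], row.names = NULL)
  }
  list(G = G, D = D, history = do.call(rbind, hist))
}
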