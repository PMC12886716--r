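#' Train the registration module alone
#'
#' Isolates the registration-in-the-loop mechanism: with the generator
#' replaced by an identity surrogate (the already-aligned source image),
#' the displacement network is trained on pairs whose targets carry a
#' known smooth misalignment, minimising
#' `lambda_ * Huber(target, source %o% field) + mu * SMTH(field)`.
#' Useful for verifying that the module recovers known distortion fields
#' and for warm-starting full training.
#'
#' @param pairs List of `list(source =, target =)` RGB arrays (or
#'   [multiplex_sample()] objects with `source` taken from a supplied
#'   `sources` list).
#' @param steps Number of Adam updates.
#' @param batch_size Pairs per update.
#' @param lr Learning rate.
#' @param base_width,depth Registration network size.
#' @param coeffs A [loss_coefficients()] (uses `lambda_`, `mu`, `phi`).
#' @param seed Integer seed (initialisation and batch order).
#' @return List with `net` (the trained `registration_net`) and `log`
#'   (per-step data frame of `huber`, `smth`, `total`).
#' @export
fit_registration <- function(pairs, steps = 300L, batch_size = 4L, lr = 1e-3,
                             base_width = 8L, depth = 3L,
                             coeffs = loss_coefficients(), seed = 1L) {
  stopifnot(length(pairs) > 0)
  seeds <- seed_all(seed, c("init", "sampler"))
  net <- with_seed(seeds[["init"]], build_registration(base_width, depth))
  opt <- adam_init(net$params, lr)
  order <- with_seed(seeds[["sampler"]],
                     matrix(sample.int(length(pairs), steps * batch_size,
                                       replace = TRUE), steps))
  log <- data.frame(step = seq_len(steps), huber = NA_real_,
                    smth = NA_real_, total = NA_real_)
  for (t in seq_len(steps)) {
    gR <- NULL
    acc <- c(0, 0, 0)
    for (j in order[t, ]) {
      src <- as_tensor(pairs[[j]]$source)
      tgt <- as_tensor(pairs[[j]]$target)
      rf <- registration_fwd(net, cat_ch(src, tgt))
      warped <- warp(src, rf$field)
      hg <- huber_grad(warped, tgt, coeffs$phi)
      wb <- warp_bwd(src, rf$field, hg)
      nf <- field_scale(rf$field)^2   # SMTH in normalized coordinates
      sg <- smth_grad(rf$field)
      rb <- registration_bwd(net, rf$cache,
                             coeffs$lambda_ * wb$gdy + coeffs$mu * sg$gdy / nf,
                             coeffs$lambda_ * wb$gdx + coeffs$mu * sg$gdx / nf)
      gR <- if (is.null(gR)) rb$gp else tree_add(gR, rb$gp)
      l_h <- huber(tgt, warped, coeffs$phi)
      l_s <- smth(rf$field) / nf
      acc <- acc + c(l_h, l_s, coeffs$lambda_ * l_h + coeffs$mu * l_s)
    }
    upd <- adam_step(net$params, tree_scale(gR, 1 / batch_size), opt)
    net$params <- upd$params; opt <- upd$opt
    log[t, 2:4] <- acc / batch_size
  }
  list(net = net, log = log)
}
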