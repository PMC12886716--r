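#' Training loss coefficients
#'
#' Defaults are the framework's empirical settings: generator weights
#' `alpha = 10` (warped Huber), `beta = 10` (adversarial), `gamma = 1e-4`
#' (total variation); registration weights `lambda_ = 20` (warped Huber)
#' and `mu = 10` (field smoothness); Huber threshold `phi = 1`.
#'
#' @param alpha,beta,gamma Generator-loss weights (default all positive;
#'   zero disables a term, e.g. for ablations).
#' @param lambda_,mu Registration-loss weights.
#' @param phi Huber threshold (> 0).
#' @return A `loss_coefficients` list.
#' @export
loss_coefficients <- function(alpha = 10, beta = 10, gamma = 1e-4,
                              lambda_ = 20, mu = 10, phi = 1) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, lambda_ >= 0, mu >= 0,
            phi > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 lambda_ = lambda_, mu = mu, phi = phi),
            class = "loss_coefficients")
}

#' Huber (smoothed L1) loss
#'
#' Mean over all elements of `d^2 / (2 phi)` where `|d| < phi` and
#' `|d| - phi / 2` otherwise, with `d = a - b`. The two branches meet at
#' `phi / 2`, so the loss is continuous and once-differentiable at the
#' threshold. For multi-channel images the mean runs over every element
#' (per-channel means averaged across channels).
#'
#' @param a,b Arrays of identical shape.
#' @param phi Threshold (> 0).
#' @return Scalar loss.
#' @export
huber <- function(a, b, phi = 1) {
  stopifnot(identical(dim(a), dim(b)) || length(a) == length(b), phi > 0)
  d <- abs(a - b)
  mean(ifelse(d < phi, d^2 / (2 * phi), d - phi / 2))
}

# gradient of huber w.r.t. a (elementwise, already divided by element count)
huber_grad <- function(a, b, phi = 1) {
  d <- a - b
  g <- ifelse(abs(d) < phi, d / phi, sign(d))
  g / length(d)
}

#' Binary cross-entropy from a pre-sigmoid score
#'
#' `-(label * log p + (1 - label) * log(1 - p))` with `p = sigmoid(score)`,
#' computed in log-sum-exp form so large scores never overflow.
#'
#' @param score Raw (pre-sigmoid) discriminator score.
#' @param label 0 or 1.
#' @return Scalar loss.
#' @export
bce_logit <- function(score, label) {
  stopifnot(label %in% c(0, 1))
  max(score, 0) - score * label + log1p(exp(-abs(score)))
}

#' @rdname bce_logit
#' @param prob Probability in (0, 1) (post-sigmoid); convenience form.
#' @export
bce <- function(prob, label) {
  stopifnot(label %in% c(0, 1), prob > 0, prob < 1)
  -(label * log(prob) + (1 - label) * log(1 - prob))
}

bce_logit_grad <- function(score, label) sigmoid(score) - label

#' Total variation of an image
#'
#' Anisotropic TV: the raw sum (not mean) over interior forward differences
#' `|I(n+1,m) - I(n,m)| + |I(n,m+1) - I(n,m)|`, summed over channels. The
#' scale mismatch with the mean-normalised Huber term is intentional; the
#' small generator weight `gamma = 1e-4` compensates.
#'
#' @param image Matrix or array `c(H, W, C)`, at least 2x2.
#' @return Scalar.
#' @export
tv <- function(image) {
  x <- as_tensor(image)
  d <- dim(x)
  stopifnot(d[1] >= 2, d[2] >= 2)
  dv <- x[-1, , , drop = FALSE] - x[-d[1], , , drop = FALSE]
  dh <- x[, -1, , drop = FALSE] - x[, -d[2], , drop = FALSE]
  sum(abs(dv)) + sum(abs(dh))
}

tv_grad <- function(image) {
  x <- as_tensor(image)
  d <- dim(x)
  g <- array(0, d)
  dv <- sign(x[-1, , , drop = FALSE] - x[-d[1], , , drop = FALSE])
  dh <- sign(x[, -1, , drop = FALSE] - x[, -d[2], , drop = FALSE])
  g[-1, , ] <- g[-1, , , drop = FALSE] + dv
  g[-d[1], , ] <- g[-d[1], , , drop = FALSE] - dv
  g[, -1, ] <- g[, -1, , drop = FALSE] + dh
  g[, -d[2], ] <- g[, -d[2], , drop = FALSE] - dh
  g
}

#' Smoothness penalty of a displacement field
#'
#' Mean over the `X * Y` spatial elements of the squared forward
#' differences in both directions, summed over the two field components:
#' `SMTH(T) = (1 / XY) * sum[ (T(x+1,y) - T(x,y))^2 + (T(x,y+1) - T(x,y))^2 ]`.
#'
#' @param field A [displacement_field()].
#' @return Scalar.
#' @export
smth <- function(field) {
  stopifnot(is_displacement_field(field))
  n <- length(field$dy)
  (smth_comp(field$dy) + smth_comp(field$dx)) / n
}

smth_comp <- function(m) {
  d <- dim(m)
  stopifnot(d[1] >= 2, d[2] >= 2)
  sum((m[-1, ] - m[-d[1], ])^2) + sum((m[, -1] - m[, -d[2]])^2)
}

smth_grad <- function(field) {
  n <- length(field$dy)
  list(gdy = smth_grad_comp(field$dy) / n,
       gdx = smth_grad_comp(field$dx) / n)
}

smth_grad_comp <- function(m) {
  d <- dim(m)
  g <- matrix(0, d[1], d[2])
  dv <- m[-1, , drop = FALSE] - m[-d[1], , drop = FALSE]
  dh <- m[, -1, drop = FALSE] - m[, -d[2], drop = FALSE]
  g[-1, ] <- g[-1, , drop = FALSE] + 2 * dv
  g[-d[1], ] <- g[-d[1], , drop = FALSE] - 2 * dv
  g[, -1] <- g[, -1, drop = FALSE] + 2 * dh
  g[, -d[2]] <- g[, -d[2], drop = FALSE] - 2 * dh
  g
}

#' Generator training objective
#'
#' `alpha * Huber(target, warp(g_out, field)) + beta * BCE(score, 1) +
#' gamma * TV(g_out)`, where `field` is the displacement predicted by the
#' registration module for (g_out, target) and `score` is the
#' discriminator's raw score on (g_out, DSM). The warped Huber term is
#' mandatory; training without a field is rejected.
#'
#' @param g_out Generator output, array `c(H, W, 3)`.
#' @param target Ground-truth stained image, same shape.
#' @param d_score Raw (pre-sigmoid) discriminator score on `g_out`.
#' @param field A [displacement_field()] from the registration module.
#' @param coeffs A [loss_coefficients()] object.
#' @return List with `total` and components `huber`, `adv`, `tv`.
#' @export
generator_loss <- function(g_out, target, d_score, field,
                           coeffs = loss_coefficients()) {
  if (is.null(field))
    stop("the warped-Huber term is mandatory: supply a displacement field",
         call. = FALSE)
  warped <- warp(g_out, field)
  l_h <- huber(target, warped, coeffs$phi)
  l_a <- bce_logit(d_score, 1)
  l_t <- tv(g_out)
  list(total = coeffs$alpha * l_h + coeffs$beta * l_a + coeffs$gamma * l_t,
       huber = l_h, adv = l_a, tv = l_t)
}

#' Discriminator training objective
#'
#' `BCE(fake_score, 0) + BCE(real_score, 1)` on raw scores.
#'
#' @param d_fake_score,d_real_score Raw scores on generated / real images.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(d_fake_score, d_real_score) {
  bce_logit(d_fake_score, 0) + bce_logit(d_real_score, 1)
}

#' Registration training objective
#'
#' `lambda_ * Huber(target, warp(g_out, field)) + mu * SMTH(field)`. The
#' smoothness term is evaluated on the displacement expressed in
#' normalized image coordinates (pixels divided by half the shorter
#' side), the units a spatial-transformer sampling grid uses; on
#' pixel-unit fields the same penalty would be inflated by the squared
#' half-side and the objective would always prefer the zero field over
#' recovering a genuine smooth misalignment. Set `normalize_field =
#' FALSE` to penalise the raw pixel-unit field instead.
#'
#' @inheritParams generator_loss
#' @param normalize_field Evaluate SMTH in normalized coordinates.
#' @return List with `total` and components `huber`, `smth`.
#' @export
registration_loss <- function(g_out, target, field,
                              coeffs = loss_coefficients(),
                              normalize_field = TRUE) {
  warped <- warp(g_out, field)
  l_h <- huber(target, warped, coeffs$phi)
  l_s <- smth(field) / if (normalize_field) field_scale(field)^2 else 1
  list(total = coeffs$lambda_ * l_h + coeffs$mu * l_s,
       huber = l_h, smth = l_s)
}

# half the shorter side: pixels -> normalized sampling coordinates
field_scale <- function(field) min(dim(field$dy)) / 2

#' Mean squared error and peak signal-to-noise ratio
#'
#' `mse` is the mean over `W x H` pixels (and channels for RGB) of the
#' squared difference. `psnr` is `10 * log10(max(reference)^2 / MSE)`,
#' with the maximum taken over the histochemical reference image. Identical
#' images give `Inf` (documented sentinel).
#'
#' @param a Virtually stained image.
#' @param b Histochemical reference image, same shape.
#' @return Scalar.
#' @export
mse <- function(a, b) {
  stopifnot(length(a) == length(b))
  mean((a - b)^2)
}

#' @rdname mse
#' @export
psnr <- function(a, b) {
  m <- mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(max(b)^2 / m)
}
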