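test_that("huber matches its closed-form branch values and is symmetric", {
  expect_equal(huber(matrix(1, 3, 3), matrix(1, 3, 3)), 0)
  expect_equal(huber(0.5, 0), 0.125)           # quadratic branch: 0.25 / 2
  expect_equal(huber(2, 0), 1.5)               # linear branch: 2 - 0.5
  a <- rand_img(6, 6, 1, 1); b <- rand_img(6, 6, 1, 2)
  expect_equal(huber(a, b), huber(b, a))
  expect_equal(huber(a, b, 0.3), bf_huber(a, b, 0.3))
})

test_that("huber branches meet continuously at the threshold", {
  phi <- 0.7
  eps <- 1e-9
  below <- huber(phi - eps, 0, phi)
  above <- huber(phi + eps, 0, phi)
  expect_equal(below, phi / 2, tolerance = 1e-8)
  expect_equal(above, phi / 2, tolerance = 1e-8)
})

test_that("binary cross-entropy matches the closed form in both labels", {
  expect_equal(bce(0.5, 1), log(2))
  expect_equal(bce(0.5, 0), log(2))
  expect_equal(bce_logit(0, 1), log(2))
  expect_lt(bce_logit(20, 1), 1e-8)            # perfect-score limit
  for (z in c(-3, -0.4, 0.7, 5)) for (lab in 0:1)
    expect_equal(bce_logit(z, lab), bf_bce(1 / (1 + exp(-z)), lab))
  # stability: huge scores stay finite
  expect_true(is.finite(bce_logit(500, 0)))
  expect_true(is.finite(bce_logit(-500, 1)))
})

test_that("total variation is the raw interior sum, summed over channels", {
  expect_equal(tv(matrix(0.3, 5, 5)), 0)
  expect_equal(tv(matrix(c(0, 0, 1, 1), 2, 2)), 2)
  k <- 6                                        # checkerboard closed form
  cb <- outer(1:k, 1:k, function(i, j) (i + j) %% 2)
  expect_equal(tv(cb), 2 * k * (k - 1))
  x <- rand_img(7, 5, 3, 3)
  expect_equal(tv(x), bf_tv(x))
})

test_that("field smoothness penalty matches brute force and scales quadratically", {
  z <- matrix(0, 4, 4)
  expect_equal(smth(displacement_field(z, z)), 0)
  ramp <- matrix(rep(1:6, 6), 6, 6)             # T(x, y) = x
  f <- displacement_field(ramp, 0 * ramp)
  expect_equal(smth(f), bf_smth(ramp, 0 * ramp))
  set.seed(4)
  dy <- matrix(rnorm(30), 5, 6); dx <- matrix(rnorm(30), 5, 6)
  f1 <- displacement_field(dy, dx)
  expect_equal(smth(f1), bf_smth(dy, dx))
  f2 <- displacement_field(2 * dy, 2 * dx)
  expect_equal(smth(f2), 4 * smth(f1))
})

test_that("psnr and mse follow their printed definitions", {
  b <- rand_img(8, 8, 3, 5)
  a <- b + 0.1
  b[1] <- 1                                     # pin max(reference) = 1
  a <- b + 0.1
  expect_equal(mse(a, b), 0.01)
  expect_equal(psnr(a, b), 20)
  expect_equal(psnr(b, b), Inf)                 # identical-image sentinel
  a2 <- rand_img(8, 8, 3, 6)
  expect_equal(mse(a2, b), bf_mse(a2, b))
  expect_equal(psnr(a2, b), bf_psnr(a2, b))
  expect_equal(psnr(a2 / 2, b / 2), psnr(a2, b))  # scale invariance
})

test_that("generator loss composes its three terms with the framework weights", {
  tgt <- rand_img(16, 16, 3, 7)
  zf <- displacement_field(matrix(0, 16, 16), matrix(0, 16, 16))
  co <- loss_coefficients()
  l <- generator_loss(tgt, tgt, d_score = 0, field = zf, coeffs = co)
  expect_equal(l$huber, 0)
  expect_equal(l$adv, log(2))
  expect_equal(l$total, 10 * 0 + 10 * log(2) + 1e-4 * tv(tgt))
  expect_equal(l$total,
               co$alpha * l$huber + co$beta * l$adv + co$gamma * l$tv,
               tolerance = 1e-12)
  # zeroed coefficients reduce to the warped-Huber term alone
  g <- rand_img(16, 16, 3, 8)
  co0 <- loss_coefficients(beta = 0, gamma = 0)
  l0 <- generator_loss(g, tgt, d_score = 3, field = zf, coeffs = co0)
  expect_equal(l0$total, 10 * huber(tgt, g))
  expect_error(generator_loss(g, tgt, 0, field = NULL), "mandatory")
})

test_that("discriminator loss is the two-term BCE with its symmetries", {
  expect_equal(discriminator_loss(0, 0), 2 * log(2))   # both probs 0.5
  expect_lt(discriminator_loss(-30, 30), 1e-8)         # perfect-D limit
  s1 <- 0.8; s2 <- -1.2
  expect_equal(discriminator_loss(s1, s2),
               bce_logit(s1, 0) + bce_logit(s2, 1))
  # swapping arguments with swapped labels leaves the value unchanged
  expect_equal(discriminator_loss(s1, s2),
               bce_logit(s2, 1) + bce_logit(s1, 0))
})

test_that("registration loss vanishes only for aligned input and zero field", {
  tgt <- rand_img(16, 16, 3, 9)
  zf <- displacement_field(matrix(0, 16, 16), matrix(0, 16, 16))
  l <- registration_loss(tgt, tgt, zf)
  expect_equal(l$total, 0)
  # exact inverse translation on the interior: residual comes only from
  # the replicated border rows
  sh <- tgt; sh[, 1:13, ] <- tgt[, 4:16, ]
  cf <- displacement_field(matrix(0, 16, 16), matrix(3, 16, 16))
  lw <- registration_loss(tgt, sh, cf)
  expect_lt(lw$huber, huber(sh, tgt))
  expect_equal(lw$smth, 0)                      # constant field is smooth
})

test_that("all losses are non-negative on random inputs", {
  set.seed(11)
  for (i in 1:5) {
    a <- rand_img(8, 8, 3, i); b <- rand_img(8, 8, 3, i + 50)
    f <- displacement_field(matrix(rnorm(64), 8), matrix(rnorm(64), 8))
    expect_gte(huber(a, b), 0)
    expect_gte(tv(a), 0)
    expect_gte(smth(f), 0)
    expect_gte(bce_logit(rnorm(1), 1), 0)
    expect_gte(mse(a, b), 0)
  }
})
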