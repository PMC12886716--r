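# Finite-difference verification of every analytic gradient: the loss
# derivatives used directly in training, and full parameter/input
# backward passes of the three networks on small inputs.

ns <- asNamespace("virtmihc")

relerr <- function(a, b) max(abs(a - b)) / max(max(abs(b)), 1e-8)

test_that("loss gradients match central differences on random 8x8 inputs", {
  set.seed(21)
  a <- rand_img(8, 8, 3, 21); b <- rand_img(8, 8, 3, 22)
  g <- ns$huber_grad(a, b, 0.4)
  gn <- num_grad(function(v) huber(array(v, dim(a)), b, 0.4), as.vector(a))
  expect_lt(relerr(as.vector(g), gn), 1e-4)

  for (lab in 0:1) {
    z <- 0.37
    gn <- num_grad(function(v) bce_logit(v, lab), z)
    expect_lt(abs(ns$bce_logit_grad(z, lab) - gn), 1e-6)
  }

  g <- ns$tv_grad(a)
  gn <- num_grad(function(v) tv(array(v, dim(a))), as.vector(a))
  expect_lt(relerr(as.vector(g), gn), 1e-4)

  dy <- matrix(rnorm(64), 8); dx <- matrix(rnorm(64), 8)
  sg <- ns$smth_grad(displacement_field(dy, dx))
  gn <- num_grad(function(v) smth(displacement_field(matrix(v, 8), dx)),
                 as.vector(dy))
  expect_lt(relerr(as.vector(sg$gdy), gn), 1e-4)
})

test_that("convolution backward matches finite differences", {
  set.seed(22)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  p <- ns$conv_init(2, 3)
  y <- ns$conv_fwd(p, x)
  b <- ns$conv_bwd(p, x, cos(y))
  loss <- function(v) sum(sin(ns$conv_fwd(p, array(v, dim(x)))))
  expect_lt(relerr(as.vector(b$gx), num_grad(loss, as.vector(x))), 1e-5)
  lossw <- function(v) {
    p2 <- p; p2$w <- matrix(v, nrow(p$w))
    sum(sin(ns$conv_fwd(p2, x)))
  }
  expect_lt(relerr(as.vector(b$gw), num_grad(lossw, as.vector(p$w))), 1e-5)
})

test_that("warp backward matches finite differences in image and field", {
  set.seed(23)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  # non-integer offsets keep the bilinear kernel away from its kinks
  f <- displacement_field(matrix(runif(64, -1.3, 1.3) + 0.01, 8),
                          matrix(runif(64, -1.3, 1.3) + 0.01, 8))
  y <- warp(x, f)
  b <- ns$warp_bwd(x, f, cos(y))
  loss_x <- function(v) sum(sin(warp(array(v, dim(x)), f)))
  expect_lt(relerr(as.vector(b$gx), num_grad(loss_x, as.vector(x))), 1e-5)
  loss_dy <- function(v) sum(sin(warp(x, displacement_field(matrix(v, 8), f$dx))))
  expect_lt(relerr(as.vector(b$gdy), num_grad(loss_dy, as.vector(f$dy))), 1e-5)
})

# --- full-network gradient checks on subsampled parameters -----------------

flat_params <- function(p) ns$tree_unlist(p)

unflat_params <- function(p, v) {
  i <- 0
  rec <- function(p) {
    if (ns$is_param_leaf(p)) {
      nw <- length(p$w); nb <- length(p$b)
      p$w[] <- v[i + seq_len(nw)]; i <<- i + nw
      p$b[] <- v[i + seq_len(nb)]; i <<- i + nb
      return(p)
    }
    for (j in seq_along(p)) p[[j]] <- rec(p[[j]])
    p
  }
  rec(p)
}

flat_grads <- function(p, g) {
  if (ns$is_param_leaf(p)) return(c(as.vector(g$gw), g$gb))
  out <- c()
  for (i in seq_along(p)) out <- c(out, flat_grads(p[[i]], g[[ns$tree_key(p, i)]]))
  out
}

check_param_grads <- function(params, analytic, lossfun, n = 25, tol = 1e-4) {
  th <- flat_params(params)
  ga <- flat_grads(params, analytic)
  expect_equal(length(th), length(ga))
  idx <- sort(sample(length(th), min(n, length(th))))
  eps <- 1e-6
  gn <- vapply(idx, function(i) {
    tp <- th; tp[i] <- tp[i] + eps
    lp <- lossfun(unflat_params(params, tp))
    tp[i] <- th[i] - eps
    lm <- lossfun(unflat_params(params, tp))
    (lp - lm) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(ga[idx] - gn)) / max(max(abs(gn)), 1e-6), tol)
}

test_that("generator parameter gradients verify against finite differences", {
  set.seed(24)
  G <- build_generator(4L, depth = 2L)
  x <- array(runif(16 * 16 * 5), c(16, 16, 5))
  r <- ns$generator_fwd(G, x)
  gb <- ns$generator_bwd(G, r$cache, cos(r$y))
  check_param_grads(G$params, gb$gp, function(pp) {
    net <- G; net$params <- pp
    sum(sin(ns$generator_fwd(net, x)$y))
  })
})

test_that("registration parameter gradients verify against finite differences", {
  set.seed(25)
  R <- build_registration(4L, depth = 2L)
  R$params$out <- ns$conv_init(4L, 2L)   # move off the zero-initialised head
  x <- array(runif(16 * 16 * 6), c(16, 16, 6))
  r <- ns$registration_fwd(R, x)
  gb <- ns$registration_bwd(R, r$cache, cos(r$field$dy), cos(r$field$dx))
  check_param_grads(R$params, gb$gp, function(pp) {
    net <- R; net$params <- pp
    f <- ns$registration_fwd(net, x)$field
    sum(sin(f$dy)) + sum(sin(f$dx))
  })
})

test_that("discriminator parameter and input gradients verify", {
  set.seed(26)
  D <- build_discriminator(4L, n_blocks = 2L)
  x <- array(runif(8 * 8 * 4), c(8, 8, 4))
  r <- ns$discriminator_fwd(D, x)
  gb <- ns$discriminator_bwd(D, r$cache, 1)
  check_param_grads(D$params, gb$gp, function(pp) {
    net <- D; net$params <- pp
    ns$discriminator_fwd(net, x)$score
  })
  gn <- num_grad(function(v) ns$discriminator_fwd(D, array(v, dim(x)))$score,
                 as.vector(x))
  expect_lt(relerr(as.vector(gb$gx), gn), 1e-5)
})
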