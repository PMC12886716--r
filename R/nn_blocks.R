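# Network building blocks with explicit forward/backward, plus the
# parameter-tree utilities (gradient accumulation, Adam). Parameters are
# nested lists whose leaves are list(w, b, ...); gradient trees mirror the
# structure with leaves list(gw, gb).

# --- three-convolution residual block (generator) -------------------------
# main: conv3x3 -> lrelu -> conv3x3 -> lrelu -> conv3x3; skip: conv1x1;
# output: lrelu(main + skip).
# the last convolution of each main path starts at reduced gain so blocks
# begin near their skip path and activations stay O(1) through the depth
# (no normalisation layers anywhere, so initialisation carries the burden)
resblock3_init <- function(cin, cout) {
  list(c1 = conv_init(cin, cout), c2 = conv_init(cout, cout),
       c3 = conv_init(cout, cout, gain = 0.3),
       sk = conv_init(cin, cout, k = 1L, gain = 1))
}

resblock3_fwd <- function(p, x) {
  y1 <- conv_fwd(p$c1, x);  a1 <- lrelu_fwd(y1)
  y2 <- conv_fwd(p$c2, a1$y); a2 <- lrelu_fwd(y2)
  y3 <- conv_fwd(p$c3, a2$y)
  sk <- conv_fwd(p$sk, x)
  ao <- lrelu_fwd(y3 + sk)
  list(y = ao$y, cache = list(x = x, a1 = a1, a2 = a2, ao = ao))
}

resblock3_bwd <- function(p, cache, gy) {
  g <- lrelu_bwd(cache$ao, gy)
  bs <- conv_bwd(p$sk, cache$x, g)
  b3 <- conv_bwd(p$c3, cache$a2$y, g)
  g2 <- lrelu_bwd(cache$a2, b3$gx)
  b2 <- conv_bwd(p$c2, cache$a1$y, g2)
  g1 <- lrelu_bwd(cache$a1, b2$gx)
  b1 <- conv_bwd(p$c1, cache$x, g1)
  list(gp = list(c1 = grad_leaf(b1), c2 = grad_leaf(b2),
                 c3 = grad_leaf(b3), sk = grad_leaf(bs)),
       gx = b1$gx + bs$gx)
}

# --- two-convolution residual block (registration net) --------------------
resblock2_init <- function(cin, cout) {
  list(c1 = conv_init(cin, cout), c2 = conv_init(cout, cout, gain = 0.3),
       sk = conv_init(cin, cout, k = 1L, gain = 1))
}

resblock2_fwd <- function(p, x) {
  y1 <- conv_fwd(p$c1, x); a1 <- lrelu_fwd(y1)
  y2 <- conv_fwd(p$c2, a1$y)
  sk <- conv_fwd(p$sk, x)
  ao <- lrelu_fwd(y2 + sk)
  list(y = ao$y, cache = list(x = x, a1 = a1, ao = ao))
}

resblock2_bwd <- function(p, cache, gy) {
  g <- lrelu_bwd(cache$ao, gy)
  bs <- conv_bwd(p$sk, cache$x, g)
  b2 <- conv_bwd(p$c2, cache$a1$y, g)
  g1 <- lrelu_bwd(cache$a1, b2$gx)
  b1 <- conv_bwd(p$c1, cache$x, g1)
  list(gp = list(c1 = grad_leaf(b1), c2 = grad_leaf(b2), sk = grad_leaf(bs)),
       gx = b1$gx + bs$gx)
}

# --- downsampling residual block (discriminator) ---------------------------
# conv3x3 -> lrelu -> conv3x3 stride 2 (doubling channels); skip conv1x1
# stride 2; output lrelu(main + skip). Halves spatial dims.
dblock_init <- function(cin, cout) {
  list(c1 = conv_init(cin, cin),
       c2 = conv_init(cin, cout, stride = 2L, gain = 0.3),
       sk = conv_init(cin, cout, k = 1L, stride = 2L, pad = 0L, gain = 1))
}

dblock_fwd <- function(p, x) {
  y1 <- conv_fwd(p$c1, x); a1 <- lrelu_fwd(y1)
  y2 <- conv_fwd(p$c2, a1$y)
  sk <- conv_fwd(p$sk, x)
  # stride-2 1x1 with pad 0 on even dims gives the same output size as
  # stride-2 3x3 with pad 1
  ao <- lrelu_fwd(y2 + sk)
  list(y = ao$y, cache = list(x = x, a1 = a1, ao = ao))
}

dblock_bwd <- function(p, cache, gy, want_params = TRUE) {
  g <- lrelu_bwd(cache$ao, gy)
  bs <- conv_bwd(p$sk, cache$x, g, want_params)
  b2 <- conv_bwd(p$c2, cache$a1$y, g, want_params)
  g1 <- lrelu_bwd(cache$a1, b2$gx)
  b1 <- conv_bwd(p$c1, cache$x, g1, want_params)
  list(gp = if (want_params) list(c1 = grad_leaf(b1), c2 = grad_leaf(b2),
                                  sk = grad_leaf(bs)),
       gx = b1$gx + bs$gx)
}

# --- attention gate ---------------------------------------------------------
# Additive gate: a = sigmoid(psi(lrelu(wg(g) + ws(s)))); gated skip = s * a.
# Three convolutions and a sigmoid; psi bias starts at 1 so gates open.
attgate_init <- function(cg, cs, ci = max(cs %/% 2L, 1L)) {
  p <- list(wg = conv_init(cg, ci, k = 1L), ws = conv_init(cs, ci, k = 1L),
            psi = conv_init(ci, 1L, k = 1L))
  p$psi$b[] <- 1
  p
}

attgate_fwd <- function(p, g, s) {
  q <- conv_fwd(p$wg, g) + conv_fwd(p$ws, s)
  aq <- lrelu_fwd(q)
  z <- conv_fwd(p$psi, aq$y)
  a <- sigmoid(z)
  y <- s * as.vector(a)   # broadcast the 1-channel gate over s's channels
  list(y = y, cache = list(g = g, s = s, aq = aq, a = a))
}

attgate_bwd <- function(p, cache, gy) {
  s <- cache$s; a <- cache$a
  gs_direct <- gy * as.vector(a)
  ga <- array(rowSums(matrix(gy * s, ncol = dim(s)[3])), dim(a))
  gz <- sigmoid_bwd(a, ga)
  bp <- conv_bwd(p$psi, cache$aq$y, gz)
  gq <- lrelu_bwd(cache$aq, bp$gx)
  bg <- conv_bwd(p$wg, cache$g, gq)
  bs <- conv_bwd(p$ws, s, gq)
  list(gp = list(wg = grad_leaf(bg), ws = grad_leaf(bs), psi = grad_leaf(bp)),
       gg = bg$gx, gs = gs_direct + bs$gx)
}

# --- dense layer ------------------------------------------------------------
dense_init <- function(cin, cout, gain = sqrt(2)) {
  list(w = matrix(rnorm(cin * cout, sd = gain / sqrt(cin)), cin, cout),
       b = numeric(cout))
}

dense_fwd <- function(p, x) as.vector(crossprod(p$w, x)) + p$b

dense_bwd <- function(p, x, gy) {
  list(gw = outer(x, gy), gb = gy, gx = as.vector(p$w %*% gy))
}

# --- parameter-tree utilities ----------------------------------------------
grad_leaf <- function(b) list(gw = b$gw, gb = b$gb)

is_param_leaf <- function(x) is.list(x) && !is.null(x$w)
is_grad_leaf <- function(x) is.list(x) && !is.null(x$gw)

# aligns the second tree by element name where names exist (sub-lists such
# as the per-level encoder blocks are unnamed and align positionally)
tree_key <- function(x, i) {
  nm <- names(x)[i]
  if (is.null(nm) || !nzchar(nm)) i else nm
}

tree_add <- function(a, b) {
  if (is_grad_leaf(a)) return(list(gw = a$gw + b$gw, gb = a$gb + b$gb))
  for (i in seq_along(a)) a[[i]] <- tree_add(a[[i]], b[[tree_key(a, i)]])
  a
}

tree_scale <- function(a, s) {
  if (is_grad_leaf(a)) return(list(gw = a$gw * s, gb = a$gb * s))
  for (i in seq_along(a)) a[[i]] <- tree_scale(a[[i]], s)
  a
}

tree_zero_like <- function(p) {
  if (is_param_leaf(p)) return(list(gw = p$w * 0, gb = p$b * 0))
  lapply(p, tree_zero_like)
}

# flatten all parameter values to one numeric vector (for change audits)
tree_unlist <- function(p) {
  if (is_param_leaf(p)) return(c(as.vector(p$w), p$b))
  unlist(lapply(p, tree_unlist), use.names = FALSE)
}

# --- Adam -------------------------------------------------------------------
adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zero_mv <- function(p) {
    if (is_param_leaf(p))
      return(list(mw = p$w * 0, vw = p$w * 0, mb = p$b * 0, vb = p$b * 0))
    lapply(p, zero_mv)
  }
  list(mv = zero_mv(params), lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps, t = 0L)
}

adam_step <- function(params, grads, opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  upd <- function(p, g, s) {
    if (is_param_leaf(p)) {
      s$mw <- b1 * s$mw + (1 - b1) * g$gw
      s$vw <- b2 * s$vw + (1 - b2) * g$gw^2
      s$mb <- b1 * s$mb + (1 - b1) * g$gb
      s$vb <- b2 * s$vb + (1 - b2) * g$gb^2
      p$w <- p$w - opt$lr * (s$mw / c1) / (sqrt(s$vw / c2) + opt$eps)
      p$b <- p$b - opt$lr * (s$mb / c1) / (sqrt(s$vb / c2) + opt$eps)
      return(list(p = p, s = s))
    }
    for (i in seq_along(p)) {
      r <- upd(p[[i]], g[[tree_key(p, i)]], s[[i]])
      p[[i]] <- r$p; s[[i]] <- r$s
    }
    list(p = p, s = s)
  }
  r <- upd(params, grads, opt$mv)
  opt$mv <- r$s
  list(params = r$p, opt = opt)
}
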