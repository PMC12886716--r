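#' Build the conditional discriminator
#'
#' A single convolution lifts the 4-channel input (RGB image + DSM channel)
#' to `base_width` channels, followed by a leaky ReLU and five successive
#' residual blocks of two convolutions each; the second convolution of
#' every block uses stride 2, halving the spatial dimensions and doubling
#' the channels. Global average pooling feeds two dense layers that produce
#' one scalar score; the sigmoid that turns it into a probability is
#' applied inside the numerically stable binary cross-entropy (or by
#' [discriminator_prob()]).
#'
#' @param base_width Stem channels (64 full-scale, 16 tiny preset).
#' @param in_channels Image channels + 1 DSM channel.
#' @param n_blocks Number of stride-2 residual blocks.
#' @return A `discriminator_net` parameter object.
#' @export
build_discriminator <- function(base_width = 64L, in_channels = 4L,
                                n_blocks = 5L) {
  stopifnot(base_width >= 4, n_blocks >= 1)
  ch <- base_width * 2L^(seq_len(n_blocks))
  blocks <- vector("list", n_blocks)
  cin <- base_width
  for (i in seq_len(n_blocks)) {
    blocks[[i]] <- dblock_init(cin, ch[i])
    cin <- ch[i]
  }
  structure(list(params = list(stem = conv_init(in_channels, base_width),
                               blocks = blocks,
                               fc1 = dense_init(cin, base_width),
                               # small-gain head: the discriminator starts
                               # near-uninformative so its early gradient
                               # does not drown the pixel-fidelity term
                               fc2 = dense_init(base_width, 1L, gain = 0.01)),
                 base_width = as.integer(base_width),
                 in_channels = as.integer(in_channels),
                 n_blocks = as.integer(n_blocks)),
            class = "discriminator_net")
}

#' @export
print.discriminator_net <- function(x, ...) {
  cat("<discriminator_net>", x$n_blocks, "stride-2 residual blocks, stem",
      x$base_width, "channels |", length(tree_unlist(x$params)),
      "parameters\n")
  invisible(x)
}

discriminator_fwd <- function(net, x) {
  d <- dim(x)
  if (d[3] != net$in_channels)
    stop("discriminator expects ", net$in_channels, " channels, got ", d[3],
         call. = FALSE)
  if (d[1] %% 2L^net$n_blocks != 0 || d[2] %% 2L^net$n_blocks != 0)
    stop("discriminator input dims must be divisible by ", 2L^net$n_blocks,
         call. = FALSE)
  p <- net$params
  s <- conv_fwd(p$stem, x)
  a0 <- lrelu_fwd(s)
  h <- a0$y
  bcaches <- vector("list", net$n_blocks)
  for (i in seq_len(net$n_blocks)) {
    r <- dblock_fwd(p$blocks[[i]], h)
    bcaches[[i]] <- r
    h <- r$y
  }
  npix <- prod(dim(h)[1:2])
  pooled <- colMeans(matrix(h, nrow = npix))    # global average pool
  z1 <- dense_fwd(p$fc1, pooled)
  a1 <- lrelu_fwd(z1)
  z <- dense_fwd(p$fc2, a1$y)
  list(score = z[1],
       cache = list(x = x, a0 = a0, bcaches = bcaches, hdim = dim(h),
                    pooled = pooled, a1 = a1))
}

# backward from d(loss)/d(score); returns parameter grads (unless only the
# input gradient is needed, as in generator updates) and grad w.r.t. x
discriminator_bwd <- function(net, cache, gscore, want_params = TRUE) {
  p <- net$params
  b2 <- dense_bwd(p$fc2, cache$a1$y, gscore)
  g1 <- lrelu_bwd(cache$a1, b2$gx)
  b1 <- dense_bwd(p$fc1, cache$pooled, g1)
  npix <- prod(cache$hdim[1:2])
  gh <- array(rep(b1$gx / npix, each = npix), cache$hdim)
  gblocks <- vector("list", net$n_blocks)
  for (i in rev(seq_len(net$n_blocks))) {
    bb <- dblock_bwd(p$blocks[[i]], cache$bcaches[[i]]$cache, gh, want_params)
    gblocks[[i]] <- bb$gp
    gh <- bb$gx
  }
  g0 <- lrelu_bwd(cache$a0, gh)
  bs <- conv_bwd(p$stem, cache$x, g0, want_params)
  list(gp = if (want_params) list(stem = grad_leaf(bs), blocks = gblocks,
                 fc1 = list(gw = b1$gw, gb = b1$gb),
                 fc2 = list(gw = b2$gw, gb = b2$gb)),
       gx = bs$gx)
}

#' Discriminator probability for an (image, DSM) pair
#'
#' @param net A `discriminator_net`.
#' @param image RGB array `c(H, W, 3)` in `[0, 1]`.
#' @param dsm A DSM object or matrix matching the image's spatial dims.
#' @return Probability in (0, 1) that the input is a real stained image.
#' @export
discriminator_prob <- function(net, image, dsm) {
  m <- if (inherits(dsm, "dsm")) dsm$matrix else dsm
  sigmoid(discriminator_fwd(net, cat_ch(as_tensor(image), as_tensor(m)))$score)
}
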