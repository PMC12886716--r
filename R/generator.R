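#' Build the virtual-staining generator
#'
#' Attention U-Net with a symmetric encoder/decoder. The encoder has four
#' downsampling levels, each a three-convolution residual block with leaky
#' ReLU (slope 0.1) followed by 2x2 max pooling that halves the spatial
#' dimensions while the channel count doubles. Decoder levels upsample by
#' 2x bilinear resizing, gate the corresponding encoder features through an
#' additive attention gate (three convolutions and a sigmoid), concatenate,
#' and apply another residual block. A final residual block and a single
#' convolution reduce the channels to 3 (RGB); a sigmoid maps the output to
#' `[0, 1]` (switchable to linear).
#'
#' Input is the 4 autofluorescence channels plus the constant DSM channel
#' (5 channels total); spatial dimensions must be divisible by 16.
#'
#' @param base_width Channels at the first encoder level (64 for the
#'   full-scale preset, 8 for the tiny CPU preset).
#' @param in_channels Input channels (AF 4 + DSM 1).
#' @param depth Number of downsampling levels.
#' @param activation `"sigmoid"` (default) or `"linear"` output mapping.
#' @return A `generator_net` parameter object.
#' @export
build_generator <- function(base_width = 64L, in_channels = 5L, depth = 4L,
                            activation = c("sigmoid", "linear")) {
  stopifnot(base_width >= 4, depth >= 1)
  activation <- match.arg(activation)
  ch <- base_width * 2L^(seq_len(depth) - 1L)
  enc <- vector("list", depth)
  cin <- in_channels
  for (l in seq_len(depth)) {
    enc[[l]] <- resblock3_init(cin, ch[l])
    cin <- ch[l]
  }
  bott <- resblock3_init(ch[depth], 2L * ch[depth])
  att <- dec <- vector("list", depth)
  cprev <- 2L * ch[depth]
  for (l in rev(seq_len(depth))) {
    att[[l]] <- attgate_init(cprev, ch[l])
    dec[[l]] <- resblock3_init(cprev + ch[l], ch[l])
    cprev <- ch[l]
  }
  out <- conv_init(ch[1], 3L, gain = 0.02)
  # start at the brightfield mean (mostly-white tissue images) so early
  # training is not dominated by a uniform push toward white
  out$b[] <- if (activation == "sigmoid") 1.4 else 0.8
  structure(list(params = list(enc = enc, bott = bott, att = att, dec = dec,
                               final = resblock3_init(ch[1], ch[1]),
                               out = out),
                 base_width = as.integer(base_width),
                 in_channels = as.integer(in_channels),
                 depth = as.integer(depth), activation = activation),
            class = "generator_net")
}

#' @export
print.generator_net <- function(x, ...) {
  cat("<generator_net> attention U-Net: depth", x$depth, "base width",
      x$base_width, "|", x$in_channels, "-> 3 channels |",
      length(tree_unlist(x$params)), "parameters\n")
  invisible(x)
}

generator_check_dims <- function(net, x) {
  d <- dim(x)
  div <- 2L^net$depth
  if (d[3] != net$in_channels)
    stop("generator expects ", net$in_channels, " input channels, got ", d[3],
         call. = FALSE)
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop("generator input dims must be divisible by ", div, call. = FALSE)
}

generator_fwd <- function(net, x) {
  generator_check_dims(net, x)
  p <- net$params
  depth <- net$depth
  skips <- pools <- vector("list", depth)
  h <- x
  for (l in seq_len(depth)) {
    r <- resblock3_fwd(p$enc[[l]], h)
    skips[[l]] <- r
    pl <- maxpool_fwd(r$y)
    pools[[l]] <- pl
    h <- pl$y
  }
  bott <- resblock3_fwd(p$bott, h)
  h <- bott$y
  ups <- gates <- decs <- vector("list", depth)
  for (l in rev(seq_len(depth))) {
    u <- up2_fwd(h)
    ups[[l]] <- dim(h)[1:2]
    g <- attgate_fwd(p$att[[l]], u, skips[[l]]$y)
    gates[[l]] <- g
    r <- resblock3_fwd(p$dec[[l]], cat_ch(u, g$y))
    decs[[l]] <- list(r = r, u_ch = dim(u)[3])
    h <- r$y
  }
  fin <- resblock3_fwd(p$final, h)
  z <- conv_fwd(p$out, fin$y)
  y <- if (net$activation == "sigmoid") sigmoid(z) else z
  list(y = y,
       cache = list(skips = skips, pools = pools, bott = bott, ups = ups,
                    gates = gates, decs = decs, fin = fin, y = y))
}

generator_bwd <- function(net, cache, gy) {
  p <- net$params
  depth <- net$depth
  gz <- if (net$activation == "sigmoid") sigmoid_bwd(cache$y, gy) else gy
  bo <- conv_bwd(p$out, cache$fin$y, gz)
  bf <- resblock3_bwd(p$final, cache$fin$cache, bo$gx)
  gp <- list(final = bf$gp, out = grad_leaf(bo),
             enc = vector("list", depth), att = vector("list", depth),
             dec = vector("list", depth))
  gh <- bf$gx
  gskip <- vector("list", depth)   # gradients flowing into encoder skips
  for (l in seq_len(depth)) {
    dc <- cache$decs[[l]]
    bd <- resblock3_bwd(p$dec[[l]], dc$r$cache, gh)
    gp$dec[[l]] <- bd$gp
    parts <- split_ch(bd$gx, c(dc$u_ch, dim(cache$gates[[l]]$cache$s)[3]))
    ba <- attgate_bwd(p$att[[l]], cache$gates[[l]]$cache, parts[[2]])
    gp$att[[l]] <- ba$gp
    gu <- parts[[1]] + ba$gg
    gskip[[l]] <- ba$gs
    gh <- up2_bwd(gu, cache$ups[[l]][1], cache$ups[[l]][2])
  }
  bb <- resblock3_bwd(p$bott, cache$bott$cache, gh)
  gp$bott <- bb$gp
  gh <- bb$gx
  gx <- NULL
  for (l in rev(seq_len(depth))) {
    d <- dim(cache$skips[[l]]$y)
    gpool <- maxpool_bwd(cache$pools[[l]], gh, d[1], d[2])
    be <- resblock3_bwd(p$enc[[l]], cache$skips[[l]]$cache,
                        gpool + gskip[[l]])
    gp$enc[[l]] <- be$gp
    gh <- be$gx
  }
  list(gp = gp, gx = gh)
}
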