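#' Build the registration module
#'
#' U-Net-style displacement estimator used only during training. It takes
#' the generator output concatenated with the target image (6 channels) and
#' predicts the two normal components (row, column) of a per-pixel
#' displacement field. The encoder/decoder has `depth` paired levels, each
#' integrated with a two-convolution residual block; at the deepest point a
#' convolution doubles the feature channels, three consecutive residual
#' blocks refine the features, and another convolution halves the channels
#' before the upsampling path. A final convolution condenses the features
#' to 2 channels; it is zero-initialised so training starts at the identity
#' field.
#'
#' The full-scale preset uses `depth = 7` (inputs divisible by 128, e.g.
#' the 512-pixel training crops); the tiny preset reduces depth to fit
#' small phantoms.
#'
#' @param base_width Channels at the first level.
#' @param depth Encoder/decoder pair count (7 full-scale, 3 tiny).
#' @param in_channels Input channels (generator output 3 + target 3).
#' @return A `registration_net` parameter object.
#' @export
build_registration <- function(base_width = 16L, depth = 7L,
                               in_channels = 6L) {
  stopifnot(base_width >= 4, depth >= 1)
  ch <- base_width * 2L^(seq_len(depth) - 1L)
  enc <- vector("list", depth)
  cin <- in_channels
  for (l in seq_len(depth)) {
    enc[[l]] <- resblock2_init(cin, ch[l])
    cin <- ch[l]
  }
  cd <- ch[depth]
  bott <- list(up = conv_init(cd, 2L * cd),
               r1 = resblock2_init(2L * cd, 2L * cd),
               r2 = resblock2_init(2L * cd, 2L * cd),
               r3 = resblock2_init(2L * cd, 2L * cd),
               down = conv_init(2L * cd, cd))
  dec <- vector("list", depth)
  cprev <- cd
  for (l in rev(seq_len(depth))) {
    dec[[l]] <- resblock2_init(cprev + ch[l], ch[l])
    cprev <- ch[l]
  }
  structure(list(params = list(enc = enc, bott = bott, dec = dec,
                               out = conv_init(ch[1], 2L, zero = TRUE)),
                 base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 in_channels = as.integer(in_channels)),
            class = "registration_net")
}

#' @export
print.registration_net <- function(x, ...) {
  cat("<registration_net> depth", x$depth, "base width", x$base_width, "|",
      x$in_channels, "-> 2 channels |", length(tree_unlist(x$params)),
      "parameters\n")
  invisible(x)
}

registration_check_dims <- function(net, x) {
  d <- dim(x)
  div <- 2L^net$depth
  if (d[3] != net$in_channels)
    stop("registration net expects ", net$in_channels, " channels, got ",
         d[3], call. = FALSE)
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop("registration input dims must be divisible by ", div, call. = FALSE)
}

registration_fwd <- function(net, x) {
  registration_check_dims(net, x)
  p <- net$params
  depth <- net$depth
  skips <- pools <- vector("list", depth)
  h <- x
  for (l in seq_len(depth)) {
    r <- resblock2_fwd(p$enc[[l]], h)
    skips[[l]] <- r
    pl <- maxpool_fwd(r$y)
    pools[[l]] <- pl
    h <- pl$y
  }
  bu <- conv_fwd(p$bott$up, h); bua <- lrelu_fwd(bu)
  r1 <- resblock2_fwd(p$bott$r1, bua$y)
  r2 <- resblock2_fwd(p$bott$r2, r1$y)
  r3 <- resblock2_fwd(p$bott$r3, r2$y)
  bd <- conv_fwd(p$bott$down, r3$y); bda <- lrelu_fwd(bd)
  h2 <- bda$y
  ups <- decs <- vector("list", depth)
  for (l in rev(seq_len(depth))) {
    u <- up2_fwd(h2)
    ups[[l]] <- dim(h2)[1:2]
    r <- resblock2_fwd(p$dec[[l]], cat_ch(u, skips[[l]]$y))
    decs[[l]] <- list(r = r, u_ch = dim(u)[3])
    h2 <- r$y
  }
  z <- conv_fwd(p$out, h2)
  field <- displacement_field(z[, , 1], z[, , 2])
  list(field = field,
       cache = list(x = x, skips = skips, pools = pools, bott_in = h,
                    bua = bua, r1 = r1, r2 = r2, r3 = r3, bda = bda,
                    ups = ups, decs = decs, h2 = h2))
}

# backward from gradients on the field (gdy, gdx); returns parameter grads
registration_bwd <- function(net, cache, gdy, gdx) {
  p <- net$params
  depth <- net$depth
  gz <- array(c(gdy, gdx), c(dim(gdy), 2L))
  bo <- conv_bwd(p$out, cache$h2, gz)
  gp <- list(enc = vector("list", depth), dec = vector("list", depth),
             out = grad_leaf(bo))
  gh <- bo$gx
  gskip <- vector("list", depth)
  for (l in seq_len(depth)) {
    dc <- cache$decs[[l]]
    bd <- resblock2_bwd(p$dec[[l]], dc$r$cache, gh)
    gp$dec[[l]] <- bd$gp
    parts <- split_ch(bd$gx, c(dc$u_ch, dim(cache$skips[[l]]$y)[3]))
    gskip[[l]] <- parts[[2]]
    gh <- up2_bwd(parts[[1]], cache$ups[[l]][1], cache$ups[[l]][2])
  }
  gbd <- lrelu_bwd(cache$bda, gh)
  bdc <- conv_bwd(p$bott$down, cache$r3$y, gbd)
  b3 <- resblock2_bwd(p$bott$r3, cache$r3$cache, bdc$gx)
  b2 <- resblock2_bwd(p$bott$r2, cache$r2$cache, b3$gx)
  b1 <- resblock2_bwd(p$bott$r1, cache$r1$cache, b2$gx)
  gbu <- lrelu_bwd(cache$bua, b1$gx)
  buc <- conv_bwd(p$bott$up, cache$bott_in, gbu)
  gp$bott <- list(up = grad_leaf(buc), r1 = b1$gp, r2 = b2$gp, r3 = b3$gp,
                  down = grad_leaf(bdc))
  gh <- buc$gx
  for (l in rev(seq_len(depth))) {
    d <- dim(cache$skips[[l]]$y)
    gpool <- maxpool_bwd(cache$pools[[l]], gh, d[1], d[2])
    be <- resblock2_bwd(p$enc[[l]], cache$skips[[l]]$cache,
                        gpool + gskip[[l]])
    gp$enc[[l]] <- be$gp
    gh <- be$gx
  }
  list(gp = gp, gx = gh)
}

#' Predict the displacement field aligning a generated image to its target
#'
#' @param net A `registration_net`.
#' @param generated,target RGB arrays `c(H, W, 3)`.
#' @return A [displacement_field()].
#' @export
predict_displacement <- function(net, generated, target) {
  registration_fwd(net, cat_ch(as_tensor(generated),
                               as_tensor(target)))$field
}
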