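# Thin R wrappers over the compiled primitives plus the elementwise ops.
# A "tensor" is a numeric array dim c(H, W, C). Each op has fwd/bwd; fwd
# returns list(y, cache) where needed.

conv_init <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                      gain = sqrt(2), zero = FALSE) {
  fan_in <- k * k * cin
  w <- if (zero) matrix(0, fan_in, cout) else
    matrix(rnorm(fan_in * cout, sd = gain / sqrt(fan_in)), fan_in, cout)
  list(w = w, b = numeric(cout), k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
}

conv_fwd <- function(p, x) {
  cpp_conv2d_fwd(x, p$w, p$b, p$k, p$stride, p$pad)
}

conv_bwd <- function(p, x, gy, want_params = TRUE) {
  cpp_conv2d_bwd(x, p$w, gy, p$k, p$stride, p$pad, want_params)
}

lrelu_fwd <- function(x, slope = 0.1) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  list(y = x, neg = neg)
}

lrelu_bwd <- function(cache, gy, slope = 0.1) {
  gy[cache$neg] <- slope * gy[cache$neg]
  gy
}

sigmoid <- function(x) 1 / (1 + exp(-x))

sigmoid_bwd <- function(y, gy) gy * y * (1 - y)

maxpool_fwd <- function(x) cpp_maxpool2_fwd(x)

maxpool_bwd <- function(cache, gy, H, W) cpp_maxpool2_bwd(cache$idx, gy, H, W)

up2_fwd <- function(x) cpp_up2_fwd(x)

up2_bwd <- function(gy, H, W) cpp_up2_bwd(gy, H, W)

#' Warp an image along a displacement field
#'
#' Gather-semantics resampling: `out(r, c) = image(r + dy(r, c), c + dx(r, c))`
#' by bilinear interpolation, with border replication for out-of-bounds
#' sample positions. This is the warp operator used to align the generator
#' output with an imperfectly registered target before the pixel-wise loss.
#'
#' @param image Array `c(H, W, C)` (a matrix is treated as one channel).
#' @param field Displacement field: list with matrices `dy`, `dx` in pixel
#'   units (row offset, column offset), each `H x W`.
#' @return Warped array with the dimensions of `image`.
#' @examples
#' img <- array(runif(16 * 16 * 3), c(16, 16, 3))
#' zero <- displacement_field(matrix(0, 16, 16), matrix(0, 16, 16))
#' identical(warp(img, zero), img)
#' @export
warp <- function(image, field) {
  image <- as_tensor(image)
  stopifnot(is_displacement_field(field))
  if (!all(dim(field$dy) == dim(image)[1:2])) {
    stop("field dimensions ", paste(dim(field$dy), collapse = "x"),
         " do not match image ", paste(dim(image)[1:2], collapse = "x"),
         call. = FALSE)
  }
  cpp_warp_fwd(image, field$dy, field$dx)
}

warp_bwd <- function(image, field, gy) {
  cpp_warp_bwd(image, field$dy, field$dx, gy)
}

#' Construct a displacement field
#'
#' @param dy,dx Matrices of per-pixel row/column offsets in pixels.
#' @return Object of class `displacement_field`.
#' @export
displacement_field <- function(dy, dx) {
  stopifnot(is.matrix(dy), is.matrix(dx), all(dim(dy) == dim(dx)),
            all(is.finite(dy)), all(is.finite(dx)))
  structure(list(dy = dy, dx = dx), class = "displacement_field")
}

#' @rdname displacement_field
#' @param x Object to test.
#' @export
is_displacement_field <- function(x) inherits(x, "displacement_field")

as_tensor <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x
}

# concatenate along the channel axis
cat_ch <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])[1:2]
  array(unlist(xs, use.names = FALSE),
        c(d, sum(vapply(xs, function(x) dim(x)[3], numeric(1)))))
}

split_ch <- function(x, sizes) {
  out <- vector("list", length(sizes))
  at <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- x[, , at + seq_len(sizes[i]), drop = FALSE]
    at <- at + sizes[i]
  }
  out
}

# Gaussian smoothing of a matrix via the replicate-padded convolution
# primitive; kernel support 2*ceil(2.5*sigma) + 1, no size constraint.
gauss_smooth <- function(m, sigma) {
  k <- 2L * as.integer(ceiling(2.5 * sigma)) + 1L
  g <- gaussian_kernel(k, sigma)
  drop(cpp_conv2d_fwd(array(m, c(dim(m), 1L)), matrix(as.vector(g)), 0,
                      k, 1L, (k - 1L) %/% 2L)[, , 1])
}
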