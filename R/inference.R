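#' Plan a tiled traversal of a large field
#'
#' Tiles of side `tile_size` (divisible by 16, the generator's spatial
#' divisibility) cover the field with `overlap` pixels of overlap; tile
#' outputs are blended with raised-cosine feather weights normalised to
#' sum to one at every pixel. Fields smaller than one tile are zero-padded
#' to a single tile and cropped back.
#'
#' @param dims Field dimensions `c(H, W)`.
#' @param tile_size Tile side in pixels.
#' @param overlap Overlap between neighbouring tiles (>= 0).
#' @return A `tiling_plan` with tile origins and the feather weight.
#' @export
tiling_plan <- function(dims, tile_size = 64L, overlap = 16L) {
  stopifnot(tile_size %% 16L == 0L, overlap >= 0L, overlap < tile_size)
  starts <- function(n) {
    if (n <= tile_size) return(1L)
    s <- seq(1L, n - tile_size + 1L, by = tile_size - overlap)
    if (s[length(s)] + tile_size - 1L < n) s <- c(s, n - tile_size + 1L)
    s
  }
  ramp <- function(n, ov) {
    w <- rep(1, n)
    if (ov > 0) {
      r <- 0.5 - 0.5 * cos(pi * (seq_len(ov) - 0.5) / ov)   # in (0, 1)
      w[seq_len(ov)] <- r
      w[n + 1L - seq_len(ov)] <- r
    }
    w
  }
  wt <- outer(ramp(tile_size, overlap), ramp(tile_size, overlap))
  structure(list(dims = as.integer(dims), tile_size = as.integer(tile_size),
                 overlap = as.integer(overlap),
                 ys = starts(dims[1]), xs = starts(dims[2]), weight = wt),
            class = "tiling_plan")
}

#' Virtually stain an AF field
#'
#' Applies the trained generator tile by tile with the DSM of the
#' requested stain, feather-blending tile overlaps. Deterministic; output
#' spatial dimensions equal the input's.
#'
#' @param af_field AF array `c(H, W, 4)` of arbitrary size.
#' @param stain_class `"he"`, `"erg"` or `"panck"`.
#' @param bundle A trained `model_bundle` (or `vmihc_model`).
#' @param plan Optional [tiling_plan()]; defaults to 64-px tiles with
#'   16-px overlap.
#' @return Virtually stained RGB array `c(H, W, 3)`.
#' @export
stain_field <- function(af_field, stain_class, bundle, plan = NULL) {
  if (inherits(bundle, "vmihc_model")) bundle <- bundle$bundle
  af_field <- as_tensor(af_field)
  if (dim(af_field)[3] != 4L)
    stop("AF field must have 4 channels (DAPI, FITC, TxRed, Cy5)",
         call. = FALSE)
  stain_class <- check_stain(stain_class)
  d <- dim(af_field)
  if (is.null(plan)) plan <- tiling_plan(d[1:2])
  ts <- plan$tile_size
  padded <- d[1] < ts || d[2] < ts
  if (padded) {
    big <- array(0, c(max(d[1], ts), max(d[2], ts), 4L))
    big[seq_len(d[1]), seq_len(d[2]), ] <- af_field
    af_field <- big
    plan <- tiling_plan(dim(big)[1:2], ts, plan$overlap)
  }
  code <- DSM_CODES[[stain_class]]
  dsm_tile <- matrix(code, ts, ts)
  acc <- array(0, c(dim(af_field)[1:2], 3L))
  wacc <- matrix(0, dim(af_field)[1], dim(af_field)[2])
  for (y0 in plan$ys) for (x0 in plan$xs) {
    ry <- y0:(y0 + ts - 1L); rx <- x0:(x0 + ts - 1L)
    tile <- af_field[ry, rx, , drop = FALSE]
    out <- generator_fwd(bundle$G, cat_ch(tile, as_tensor(dsm_tile)))$y
    for (c in 1:3)
      acc[ry, rx, c] <- acc[ry, rx, c] + out[, , c] * plan$weight
    wacc[ry, rx] <- wacc[ry, rx] + plan$weight
  }
  for (c in 1:3) acc[, , c] <- acc[, , c] / wacc
  if (padded) acc <- acc[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
  pmin(pmax(acc, 0), 1)   # brightfield RGB range
}

#' Generate all three stains from one AF field
#'
#' One AF input, three co-registered outputs (H&E, ERG, PanCK) on the
#' identical pixel grid and tile decomposition — the multiplexing use
#' case that serial physical sections cannot provide.
#'
#' @inheritParams stain_field
#' @return Named list of RGB arrays `he`, `erg`, `panck`.
#' @export
stain_multiplex <- function(af_field, bundle, plan = NULL) {
  out <- lapply(STAIN_CLASSES, function(s)
    stain_field(af_field, s, bundle, plan))
  names(out) <- STAIN_CLASSES
  out
}

#' Predict method for trained virtual staining models
#'
#' @param object A `vmihc_model`.
#' @param af_field AF array `c(H, W, 4)`.
#' @param stains `"all"` or a subset of stain classes.
#' @param plan Optional [tiling_plan()].
#' @param ... Unused.
#' @return Named list of RGB arrays (single array if one stain requested).
#' @export
predict.vmihc_model <- function(object, af_field, stains = "all",
                                plan = NULL, ...) {
  if (identical(stains, "all")) return(stain_multiplex(af_field, object, plan))
  stains <- vapply(stains, check_stain, character(1))
  out <- lapply(stains, function(s) stain_field(af_field, s, object, plan))
  names(out) <- stains
  if (length(out) == 1L) out[[1L]] else out
}
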