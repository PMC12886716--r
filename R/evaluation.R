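#' Colour deconvolution of a stained RGB image
#'
#' Inverts the Beer-Lambert mixture: optical density
#' `OD(x) = -log10(rgb(x))` (zero-intensity pixels clamped by `eps` before
#' the log), per-stain concentrations `OD %*% solve(vectors)`. Negative
#' concentrations are returned raw; clamping happens only at mask-building
#' time in [dab_mask()].
#'
#' @param rgb RGB array `c(H, W, 3)` in `(0, 1]`.
#' @param vectors Stain OD matrix from [stain_vectors()] (rows unit-norm,
#'   invertible).
#' @param eps Clamp for zero intensities; the default is the 8-bit
#'   quantization floor (1/255), bounding optical density at ~2.4 so that
#'   isolated near-black pixels cannot produce unbounded concentrations.
#' @return Array `c(H, W, n_stains)` of concentration maps, stain names on
#'   the third dimension.
#' @export
color_deconvolve <- function(rgb, vectors = stain_vectors(),
                             eps = 1 / 255) {
  rgb <- as_tensor(rgb)
  stopifnot(dim(rgb)[3] == 3L, nrow(vectors) == 3L)
  if (abs(det(vectors)) < 1e-8)
    stop("stain vector matrix is singular", call. = FALSE)
  d <- dim(rgb)
  od <- -log10(pmax(matrix(rgb, ncol = 3L), eps))
  conc <- od %*% solve(vectors)
  out <- array(conc, c(d[1], d[2], nrow(vectors)))
  dimnames(out) <- list(NULL, NULL, rownames(vectors))
  out
}

# forward remix for round-trip checks: concentrations -> RGB
color_reconstruct <- function(conc, vectors = stain_vectors()) {
  d <- dim(conc)
  od <- matrix(conc, ncol = d[3]) %*% vectors
  array(10^(-od), c(d[1], d[2], 3L))
}

#' DAB-positive binary mask
#'
#' Otsu's threshold on the DAB concentration map followed by morphological
#' dilation then erosion (closing) with a disc structuring element.
#' Negative concentrations are clamped to zero before thresholding. A
#' constant map yields an empty mask with a warning (Otsu undefined).
#'
#' @param dab_map Matrix of DAB concentrations.
#' @param radius Disc radius of the structuring element.
#' @return Logical mask.
#' @export
dab_mask <- function(dab_map, radius = 2L) {
  stopifnot(all(is.finite(dab_map)))
  m <- pmax(dab_map, 0)
  hi <- max(m)
  if (hi - min(m) < 1e-12) {
    warning("constant DAB map: Otsu threshold undefined, returning empty mask")
    return(matrix(FALSE, nrow(m), ncol(m)))
  }
  thr <- EBImage::otsu(m / hi, range = c(0, 1)) * hi
  mask_closing(m > thr, radius = radius)
}

#' Nuclei statistics of a binary mask
#'
#' Connected-component count and mean component area (pixels^2) under the
#' configured connectivity (8 by default). An empty mask reports count 0
#' and `NA` mean area.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return A `nuclei_stats` list: `count`, `mean_area`, `areas`.
#' @export
erg_nuclei_stats <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  lab <- cpp_label_components(matrix(as.integer(mask), nrow(mask)),
                              as.integer(connectivity))
  n <- max(lab)
  areas <- if (n > 0) as.numeric(tabulate(lab[lab > 0], nbins = n)) else
    numeric(0)
  structure(list(count = n,
                 mean_area = if (n > 0) mean(areas) else NA_real_,
                 areas = areas), class = "nuclei_stats")
}

#' @export
print.nuclei_stats <- function(x, ...) {
  cat("<nuclei_stats>", x$count, "components, mean area",
      if (is.na(x$mean_area)) "NA" else round(x$mean_area, 1), "px^2\n")
  invisible(x)
}

#' Down-sampled intersection over union
#'
#' Both masks are mean-pooled over non-overlapping `factor x factor`
#' blocks (zero-padded to a multiple of `factor`), re-binarised at
#' `> bin_thresh`, and compared as
#' `sum(M_vs * M_hs) / sum(min(M_vs + M_hs, 1))`. Robust to small
#' misalignments. Two empty masks compare as 1 (documented sentinel).
#'
#' @param mask_vs,mask_hs Logical or 0/1 matrices of identical dims.
#' @param factor Down-sampling factor.
#' @param bin_thresh Binarisation threshold on the pooled masks.
#' @return Scalar in `[0, 1]`.
#' @export
d_iou <- function(mask_vs, mask_hs, factor = 8L, bin_thresh = 0.01) {
  stopifnot(all(dim(mask_vs) == dim(mask_hs)))
  p1 <- block_mean(mask_vs * 1, factor) > bin_thresh
  p2 <- block_mean(mask_hs * 1, factor) > bin_thresh
  den <- sum(pmin(p1 + p2, 1))
  if (den == 0) return(1)
  sum(p1 * p2) / den
}

block_mean <- function(m, f) {
  h <- nrow(m); w <- ncol(m)
  H <- f * ceiling(h / f); W <- f * ceiling(w / f)
  if (H != h || W != w) {
    p <- matrix(0, H, W); p[seq_len(h), seq_len(w)] <- m; m <- p
  }
  # mean over f x f blocks via two reshapes
  m1 <- array(m, c(f, H / f, W))
  s1 <- apply(m1, c(2, 3), sum)
  m2 <- array(t(s1), c(f, W / f, H / f))
  t(apply(m2, c(2, 3), sum)) / f^2
}

#' Structural similarity index
#'
#' Standard windowed SSIM on luminance: Gaussian window (default 11 px,
#' sigma 1.5), stabilising constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2` with
#' `K = (0.01, 0.03)` and dynamic range `L = 1` for images in `[0, 1]`;
#' the SSIM map is averaged over valid window positions. RGB inputs are
#' converted with Rec. 601 luminance weights.
#'
#' @param a,b Images of identical dims (matrix or `c(H, W, C)` array).
#' @param window Window side (odd).
#' @param sigma Gaussian window sigma.
#' @param K Stabilising constants `c(K1, K2)`.
#' @param L Dynamic range.
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b, window = 11L, sigma = 1.5, K = c(0.01, 0.03), L = 1) {
  a <- to_luminance(a); b <- to_luminance(b)
  stopifnot(all(dim(a) == dim(b)), min(dim(a)) >= window)
  g <- gaussian_kernel(window, sigma)
  C1 <- (K[1] * L)^2; C2 <- (K[2] * L)^2
  f <- function(x) drop(cpp_conv2d_fwd(array(x, c(dim(x), 1L)),
                                       matrix(as.vector(g)), 0,
                                       as.integer(window), 1L, 0L)[, , 1])
  mua <- f(a); mub <- f(b)
  saa <- f(a * a) - mua^2; sbb <- f(b * b) - mub^2
  sab <- f(a * b) - mua * mub
  mean(((2 * mua * mub + C1) * (2 * sab + C2)) /
         ((mua^2 + mub^2 + C1) * (saa + sbb + C2)))
}

to_luminance <- function(x) {
  if (is.matrix(x)) return(x)
  x <- as_tensor(x)
  if (dim(x)[3] == 1L) return(x[, , 1])
  0.2989 * x[, , 1] + 0.5870 * x[, , 2] + 0.1140 * x[, , 3]
}

gaussian_kernel <- function(n, sigma) {
  r <- seq_len(n) - (n + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Perceptual distance between images
#'
#' Layer-weighted mean squared distance between unit-normalised feature
#' maps from a pluggable extractor. The default [identity_extractor()]
#' uses the image itself as its single feature map, degenerating to a
#' normalised MSE; a learned multi-layer extractor can be plugged in where
#' pretrained weights are available. With `extractor = NULL` the metric is
#' reported as `NA` (absent), never silently substituted.
#'
#' @param a,b Images of identical dims.
#' @param extractor Function mapping an image to a list of feature arrays,
#'   or `NULL`.
#' @param weights Optional per-layer weights (default uniform).
#' @return Scalar distance (0 for identical inputs), or `NA` if no
#'   extractor is available.
#' @export
perceptual_distance <- function(a, b, extractor = identity_extractor(),
                                weights = NULL) {
  if (is.null(extractor)) return(NA_real_)
  fa <- extractor(as_tensor(a)); fb <- extractor(as_tensor(b))
  stopifnot(length(fa) == length(fb))
  if (is.null(weights)) weights <- rep(1 / length(fa), length(fa))
  d <- 0
  for (l in seq_along(fa)) {
    na <- unit_normalize(fa[[l]]); nb <- unit_normalize(fb[[l]])
    d <- d + weights[l] * mean((na - nb)^2)
  }
  d
}

# channel-unit normalisation per pixel (LPIPS-style)
unit_normalize <- function(x, eps = 1e-10) {
  d <- dim(x)
  m <- matrix(x, ncol = d[3])
  n <- sqrt(rowSums(m^2)) + eps
  array(m / n, d)
}

#' @rdname perceptual_distance
#' @export
identity_extractor <- function() function(img) list(img)

#' Paired two-tailed t test
#'
#' Standard paired t on the per-pair differences. Identical lists give
#' statistic 0 and p 1; a constant nonzero difference (zero variance)
#' gives a signed infinite statistic with p 0 (sentinels for the
#' degenerate cases the textbook formula cannot express).
#'
#' @param values_vs,values_hs Equal-length numeric vectors (>= 2).
#' @return List with `statistic` and `p`.
#' @export
paired_t <- function(values_vs, values_hs) {
  stopifnot(length(values_vs) == length(values_hs), length(values_vs) >= 2)
  d <- values_vs - values_hs
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(statistic = 0, p = 1))
    return(list(statistic = sign(mean(d)) * Inf, p = 0))
  }
  tt <- t.test(values_vs, values_hs, paired = TRUE)
  list(statistic = unname(tt$statistic), p = tt$p.value)
}

#' Evaluate a cohort of virtual/histochemical image pairs
#'
#' Computes PSNR, SSIM and (optional) perceptual distance for every pair;
#' for ERG additionally DAB nuclei statistics on both images with paired t
#' tests on count and mean area; for PanCK the down-sampled IoU between
#' the two DAB masks. Pairs with mismatched dimensions are skipped with a
#' logged reason and counted in the report.
#'
#' @param pairs List of `list(virtual =, reference =)` image pairs, or a
#'   CSV manifest with columns `virtual_path`, `reference_path`.
#' @param stain Stain class of the cohort.
#' @param vectors Stain OD matrix for deconvolution (H-DAB default).
#' @param extractor Perceptual feature extractor or `NULL`.
#' @return An `eval_report`: `rows` (per-pair metrics), `summary`,
#'   `skipped`, `stain`.
#' @export
evaluate_pairs <- function(pairs, stain, vectors = stain_vectors(),
                           extractor = identity_extractor()) {
  stain <- check_stain(stain)
  if (is.character(pairs)) {
    m <- read.csv(pairs, stringsAsFactors = FALSE)
    dirn <- dirname(pairs)
    pairs <- lapply(seq_len(nrow(m)), function(i)
      list(virtual = read_rgb(file.path(dirn, m$virtual_path[i])),
           reference = read_rgb(file.path(dirn, m$reference_path[i]))))
  }
  rows <- list(); skipped <- character(0)
  nuc <- list(vs_count = c(), hs_count = c(), vs_area = c(), hs_area = c())
  for (i in seq_along(pairs)) {
    v <- as_tensor(pairs[[i]]$virtual); r <- as_tensor(pairs[[i]]$reference)
    if (!all(dim(v) == dim(r))) {
      skipped <- c(skipped, sprintf("pair %d: dims %s vs %s", i,
                                    paste(dim(v), collapse = "x"),
                                    paste(dim(r), collapse = "x")))
      next
    }
    row <- data.frame(pair = i, psnr = psnr(v, r), ssim = ssim(v, r),
                      lpips = perceptual_distance(v, r, extractor))
    if (stain == "erg") {
      sv <- erg_nuclei_stats(dab_mask(color_deconvolve(v, vectors)[, , "dab"]))
      sr <- erg_nuclei_stats(dab_mask(color_deconvolve(r, vectors)[, , "dab"]))
      row$nuclei_count_vs <- sv$count; row$nuclei_count_hs <- sr$count
      row$nuclei_area_vs <- sv$mean_area; row$nuclei_area_hs <- sr$mean_area
      nuc$vs_count <- c(nuc$vs_count, sv$count)
      nuc$hs_count <- c(nuc$hs_count, sr$count)
      nuc$vs_area <- c(nuc$vs_area, sv$mean_area)
      nuc$hs_area <- c(nuc$hs_area, sr$mean_area)
    } else if (stain == "panck") {
      mv <- dab_mask(color_deconvolve(v, vectors)[, , "dab"])
      mr <- dab_mask(color_deconvolve(r, vectors)[, , "dab"])
      row$d_iou <- d_iou(mv, mr)
    }
    rows[[length(rows) + 1L]] <- row
  }
  rows <- if (length(rows)) do.call(rbind, rows) else NULL
  summary <- list(n_pairs = length(pairs), n_evaluated = NROW(rows),
                  n_skipped = length(skipped))
  if (!is.null(rows)) {
    summary$psnr_mean <- mean(rows$psnr[is.finite(rows$psnr)])
    summary$ssim_mean <- mean(rows$ssim)
    if (!all(is.na(rows$lpips))) summary$lpips_mean <- mean(rows$lpips)
    if (stain == "erg" && NROW(rows) >= 2) {
      summary$t_count <- paired_t(nuc$vs_count, nuc$hs_count)
      ok <- !is.na(nuc$vs_area) & !is.na(nuc$hs_area)
      if (sum(ok) >= 2)
        summary$t_area <- paired_t(nuc$vs_area[ok], nuc$hs_area[ok])
    }
    if (stain == "panck") summary$d_iou_mean <- mean(rows$d_iou)
  }
  structure(list(rows = rows, summary = summary, skipped = skipped,
                 stain = stain), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$summary
  cat("<eval_report>", x$stain, "|", s$n_evaluated, "pairs evaluated,",
      s$n_skipped, "skipped\n")
  if (!is.null(s$psnr_mean))
    cat(sprintf("  PSNR %.2f dB | SSIM %.4f%s%s\n", s$psnr_mean, s$ssim_mean,
                if (!is.null(s$lpips_mean))
                  sprintf(" | LPIPS %.4f", s$lpips_mean) else "",
                if (!is.null(s$d_iou_mean))
                  sprintf(" | D-IoU %.4f", s$d_iou_mean) else ""))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Per-pair metrics as CSV plus a JSON summary (with the stain-vector
#' matrix recorded in the header for provenance).
#'
#' @param report An [evaluate_pairs()] result.
#' @param dir Output directory.
#' @param vectors Stain vectors to record.
#' @return The directory, invisibly.
#' @export
write_eval_report <- function(report, dir, vectors = stain_vectors()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$rows))
    write.csv(report$rows, file.path(dir, "per_pair.csv"), row.names = FALSE)
  s <- report$summary
  s$stain <- report$stain
  s$stain_vectors <- unclass(round(vectors, 4))
  s$skipped <- report$skipped
  jsonlite::write_json(s, file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
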