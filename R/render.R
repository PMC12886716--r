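#' Stain optical-density vectors
#'
#' Unit RGB optical-density vectors of the classical colour-deconvolution
#' literature: hematoxylin, eosin and DAB, plus an orthogonal residual
#' completing a 3x3 basis. Rows are unit-norm.
#'
#' @param chromogens Character vector naming the first rows; any of
#'   `"hematoxylin"`, `"eosin"`, `"dab"`.
#' @param complete If `TRUE` (default), append a unit residual vector
#'   orthogonal to the first two rows so the matrix is invertible.
#' @return Matrix with one unit OD vector per row.
#' @export
stain_vectors <- function(chromogens = c("hematoxylin", "dab"),
                          complete = TRUE) {
  base <- rbind(hematoxylin = c(0.650, 0.704, 0.286),
                eosin = c(0.072, 0.990, 0.105),
                dab = c(0.268, 0.570, 0.776))
  rows <- base[match(chromogens, rownames(base)), , drop = FALSE]
  if (anyNA(rows)) stop("unknown chromogen; valid: hematoxylin, eosin, dab",
                        call. = FALSE)
  rows <- rows / sqrt(rowSums(rows^2))
  if (complete && nrow(rows) == 2L) {
    res <- pracma_cross(rows[1, ], rows[2, ])
    res <- res / sqrt(sum(res^2))
    rows <- rbind(rows, residual = res)
  }
  rows
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Chromogen recipe: how a stain renders phantom compartments
#'
#' Couples 2-3 unit stain OD vectors with concentration rules mapping
#' phantom regions to per-chromogen concentrations. Regions are the
#' exclusive compartments (`background`, `stroma`, `epithelial_cytoplasm`,
#' `vessel_lumen`, `nucleus`, `endothelial_nucleus`) plus the overlay masks
#' `epithelial_mask` and `endothelial_nuclei` used by the IHC stains; rules
#' over different regions add.
#'
#' Defaults follow the diagnostic staining patterns: H&E puts hematoxylin
#' on nuclei and eosin on cytoplasm/stroma; ERG puts DAB only on
#' endothelial nuclei over a hematoxylin counterstain; PanCK puts DAB only
#' on the epithelial mask (cytoplasmic epithelial labeling).
#'
#' @param stain_class `"he"`, `"erg"` or `"panck"`.
#' @param vectors Stain OD matrix (rows unit-norm); default per class.
#' @param rules Named list: region -> named concentration vector over the
#'   chromogens in `vectors`. All concentrations must be >= 0.
#' @return A `chromogen_recipe`.
#' @export
chromogen_recipe <- function(stain_class, vectors = NULL, rules = NULL) {
  stain_class <- check_stain(stain_class)
  if (is.null(vectors))
    vectors <- switch(stain_class,
      he = stain_vectors(c("hematoxylin", "eosin")),
      erg = ,
      panck = stain_vectors(c("hematoxylin", "dab")))
  if (is.null(rules))
    rules <- switch(stain_class,
      he = list(nucleus = c(hematoxylin = 0.9),
                endothelial_nucleus = c(hematoxylin = 0.9),
                stroma = c(eosin = 0.35),
                epithelial_cytoplasm = c(eosin = 0.55),
                vessel_lumen = c(eosin = 0.12)),
      erg = list(nucleus = c(hematoxylin = 0.7),
                 endothelial_nuclei = c(dab = 1.0),
                 stroma = c(hematoxylin = 0.06),
                 epithelial_cytoplasm = c(hematoxylin = 0.1)),
      panck = list(nucleus = c(hematoxylin = 0.7),
                   endothelial_nucleus = c(hematoxylin = 0.7),
                   epithelial_mask = c(dab = 0.9),
                   stroma = c(hematoxylin = 0.06)))
  for (r in rules)
    if (any(r < 0)) stop("negative concentration in rules", call. = FALSE)
  ok_regions <- c(names(PHANTOM_COMPARTMENTS), "epithelial_mask",
                  "endothelial_nuclei")
  bad <- setdiff(names(rules), ok_regions)
  if (length(bad)) stop("unknown regions in rules: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(stain_class = stain_class, stain_vectors = vectors,
                 concentration_rules = rules), class = "chromogen_recipe")
}

# per-chromogen concentration maps implied by a recipe on a phantom
concentration_maps <- function(phantom, recipe) {
  comp <- phantom_compartments(phantom)
  chrom <- rownames(recipe$stain_vectors)
  chrom <- chrom[chrom != "residual"]
  h <- phantom$height; w <- phantom$width
  maps <- lapply(chrom, function(ch) matrix(0, h, w))
  names(maps) <- chrom
  for (region in names(recipe$concentration_rules)) {
    mask <- switch(region,
      epithelial_mask = phantom$epithelial_mask,
      endothelial_nuclei = phantom$endothelial_nuclei_mask,
      comp == PHANTOM_COMPARTMENTS[[region]])
    rule <- recipe$concentration_rules[[region]]
    for (ch in names(rule)) {
      if (!ch %in% chrom)
        stop("rule references chromogen '", ch, "' absent from the recipe",
             call. = FALSE)
      maps[[ch]][mask] <- maps[[ch]][mask] + rule[[ch]]
    }
  }
  maps
}

#' Render a stained brightfield image from a phantom
#'
#' Beer-Lambert transmission: `rgb = 10^(-sum_k c_k(x) * v_k)` with
#' per-chromogen concentration maps `c_k` and unit OD vectors `v_k`; pure
#' white where all concentrations are zero. Base 10 matches the optical
#' density convention of colour deconvolution, so
#' [color_deconvolve()] recovers the generating concentrations exactly.
#'
#' @param phantom A [generate_phantom()] result.
#' @param recipe A [chromogen_recipe()].
#' @param noise_sd Gaussian noise (fraction of full scale) added to the RGB
#'   image, clipped to `[0, 1]`; 0 gives a noise-free render.
#' @param seed Seed for the noise realisation.
#' @return RGB array `c(H, W, 3)` in `[0, 1]`.
#' @export
render_stain <- function(phantom, recipe, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(recipe, "chromogen_recipe"), noise_sd >= 0)
  maps <- concentration_maps(phantom, recipe)
  v <- recipe$stain_vectors[names(maps), , drop = FALSE]
  od <- matrix(0, phantom$height * phantom$width, 3L)
  for (i in seq_along(maps)) od <- od + outer(as.vector(maps[[i]]), v[i, ])
  rgb <- array(10^(-od), c(phantom$height, phantom$width, 3L))
  if (noise_sd > 0) {
    rgb <- with_seed(derive_seed(seed, "stain_noise"),
                     rgb + array(rnorm(length(rgb), sd = noise_sd), dim(rgb)))
    rgb <- pmin(pmax(rgb, 0), 1)
  }
  rgb
}

#' Default AF channel mixing of the phantom compartments
#'
#' Relative channel intensities (DAPI, FITC, TxRed, Cy5 order) per
#' compartment. Chosen so each tissue structure has distinctive label-free
#' contrast: nuclei dominate DAPI, stroma dominates FITC, epithelial
#' cytoplasm dominates TxRed, vessel lumina dominate Cy5. A linear
#' compartment mixture, not a fluorophore-spectrum model.
#'
#' @return 6x4 matrix, rows named by compartment.
#' @export
default_af_mixing <- function() {
  rbind(background = c(0.00, 0.02, 0.02, 0.02),
        stroma = c(0.10, 0.60, 0.25, 0.15),
        epithelial_cytoplasm = c(0.15, 0.30, 0.70, 0.30),
        vessel_lumen = c(0.05, 0.15, 0.20, 0.80),
        nucleus = c(0.90, 0.20, 0.10, 0.10),
        endothelial_nucleus = c(0.85, 0.25, 0.15, 0.35))
}

#' Render the 4-channel autofluorescence image of a phantom
#'
#' Each channel is the compartment mixing intensity plus an optional smooth
#' multiplicative texture and Gaussian noise, clipped to `[0, 1]`.
#' Deterministic under a fixed seed.
#'
#' @param phantom A [generate_phantom()] result.
#' @param mixing Compartment-by-channel intensity matrix in `[0, 1]`
#'   (rows as in [default_af_mixing()]).
#' @param noise_sd Per-pixel Gaussian noise standard deviation (>= 0).
#' @param texture_amp Amplitude of the smooth (Gaussian-blurred) texture.
#' @param texture_scale Blur sigma of the texture in pixels.
#' @param seed Seed for texture and noise.
#' @return AF array `c(H, W, 4)`, channels DAPI, FITC, TxRed, Cy5.
#' @export
render_af <- function(phantom, mixing = default_af_mixing(), noise_sd = 0.01,
                      texture_amp = 0.03, texture_scale = 8, seed = 1L) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            all(mixing >= 0), all(mixing <= 1), noise_sd >= 0)
  comp <- phantom_compartments(phantom)
  h <- phantom$height; w <- phantom$width
  af <- array(0, c(h, w, 4L))
  for (ch in 1:4) {
    plane <- matrix(mixing[comp + 1L, ch], h, w)
    af[, , ch] <- plane
  }
  if (texture_amp > 0 || noise_sd > 0) {
    af <- with_seed(derive_seed(seed, "af_noise"), {
      for (ch in 1:4) {
        if (texture_amp > 0) {
          tex <- gauss_smooth(matrix(rnorm(h * w), h, w),
                              sigma = texture_scale)
          tex <- tex / max(abs(tex), 1e-12) * texture_amp
          af[, , ch] <- af[, , ch] + tex
        }
        if (noise_sd > 0)
          af[, , ch] <- af[, , ch] + matrix(rnorm(h * w, sd = noise_sd), h, w)
      }
      af
    })
    af <- pmin(pmax(af, 0), 1)
  }
  af
}
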