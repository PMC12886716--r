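#' Construct a co-registered training/inference unit
#'
#' Bundles a 4-channel AF image, its DSM code, the target stained image
#' and the stain class; optionally carries the true displacement field
#' when the target has been synthetically misaligned.
#'
#' @param af AF array `c(H, W, 4)` in `[0, 1]`.
#' @param stain_class `"he"`, `"erg"` or `"panck"`.
#' @param target RGB array `c(H, W, 3)` in `[0, 1]`, same spatial dims.
#' @param true_displacement Optional [displacement_field()].
#' @param id Optional tile identifier.
#' @return A `multiplex_sample`.
#' @export
multiplex_sample <- function(af, stain_class, target,
                             true_displacement = NULL, id = NULL) {
  stain_class <- check_stain(stain_class)
  af <- as_tensor(af); target <- as_tensor(target)
  stopifnot(dim(af)[3] == 4L, dim(target)[3] == 3L,
            all(dim(af)[1:2] == dim(target)[1:2]))
  if (!is.null(true_displacement))
    stopifnot(is_displacement_field(true_displacement),
              all(dim(true_displacement$dy) == dim(af)[1:2]))
  structure(list(af = af, dsm_code = DSM_CODES[[stain_class]],
                 stain_class = stain_class, target = target,
                 true_displacement = true_displacement, id = id),
            class = "multiplex_sample")
}

#' @export
print.multiplex_sample <- function(x, ...) {
  cat("<multiplex_sample>", x$stain_class, "(code", x$dsm_code, ")",
      paste(dim(x$af)[1:2], collapse = "x"),
      if (!is.null(x$true_displacement)) "| misaligned target" else "", "\n")
  invisible(x)
}

#' Generate a smooth random displacement field
#'
#' Gaussian-smoothed white-noise vector field scaled so the largest
#' component magnitude equals `amplitude` pixels. Smoothness (bounded
#' discrete gradients) plus the amplitude cap keep the warp invertible.
#'
#' @param height,width Field dimensions.
#' @param amplitude Maximum displacement in pixels.
#' @param smoothness Gaussian blur sigma in pixels.
#' @param seed Integer seed.
#' @return A [displacement_field()].
#' @export
random_smooth_field <- function(height, width, amplitude, smoothness = 12,
                                seed = 1L) {
  stopifnot(amplitude >= 0, smoothness > 0)
  if (amplitude == 0)
    return(displacement_field(matrix(0, height, width),
                              matrix(0, height, width)))
  with_seed(derive_seed(seed, "misalign"), {
    mk <- function() {
      m <- gauss_smooth(matrix(rnorm(height * width), height, width),
                        sigma = smoothness)
      m / max(abs(m), 1e-12) * amplitude
    }
    displacement_field(mk(), mk())
  })
}

#' Misalign a sample's target by a known smooth field
#'
#' Replaces the target with `target` warped along a smooth random
#' displacement field (emulating staining-induced distortion) and records
#' the field in `true_displacement`. The amplitude is capped at 10% of the
#' shorter image side to guarantee invertibility.
#'
#' @param sample A [multiplex_sample()].
#' @param amplitude Maximum displacement in pixels.
#' @param smoothness Blur sigma of the field.
#' @param seed Integer seed.
#' @return The misaligned `multiplex_sample`.
#' @export
make_misaligned_pair <- function(sample, amplitude, smoothness = 12,
                                 seed = 1L) {
  stopifnot(inherits(sample, "multiplex_sample"))
  d <- dim(sample$af)
  if (amplitude > 0.1 * min(d[1], d[2]))
    stop("amplitude ", amplitude, " exceeds 10% of the image side",
         call. = FALSE)
  fld <- random_smooth_field(d[1], d[2], amplitude, smoothness, seed)
  warped <- if (amplitude == 0) sample$target else warp(sample$target, fld)
  multiplex_sample(sample$af, sample$stain_class, warped,
                   true_displacement = fld, id = sample$id)
}

#' Simulate a cohort of co-registered AF/brightfield pairs
#'
#' For each tile one tissue phantom is generated, its AF image rendered
#' once, and a stained target rendered for each requested stain class, so
#' the three stains share one underlying geometry (the multiplexing study
#' condition). Optionally misaligns the targets by smooth random fields.
#'
#' @param n_tiles Number of phantom tiles.
#' @param size Tile side in pixels.
#' @param stains Stain classes to render per tile.
#' @param spec A [phantom_spec()].
#' @param af_noise_sd AF Gaussian noise level.
#' @param stain_noise_sd Target image noise level.
#' @param misalign_px Misalignment amplitude in pixels (0 = aligned).
#' @param seed Master seed.
#' @return List with `samples` (list of [multiplex_sample()]) and
#'   `phantoms` (ground truth per tile).
#' @export
simulate_cohort <- function(n_tiles, size = 64L,
                            stains = c("he", "erg", "panck"),
                            spec = phantom_spec(), af_noise_sd = 0.01,
                            stain_noise_sd = 0, misalign_px = 0, seed = 1L) {
  stains <- vapply(stains, check_stain, character(1))
  phantoms <- vector("list", n_tiles)
  samples <- list()
  for (i in seq_len(n_tiles)) {
    tile_seed <- derive_seed(seed, paste0("tile", i))
    ph <- generate_phantom(size, size, spec, seed = tile_seed)
    phantoms[[i]] <- ph
    af <- render_af(ph, noise_sd = af_noise_sd, seed = tile_seed)
    for (s in stains) {
      tgt <- render_stain(ph, chromogen_recipe(s),
                          noise_sd = stain_noise_sd, seed = tile_seed)
      sm <- multiplex_sample(af, s, tgt,
                             id = sprintf("tile%03d_%s", i, s))
      if (misalign_px > 0)
        sm <- make_misaligned_pair(sm, misalign_px,
                                   seed = derive_seed(tile_seed, s))
      samples[[length(samples) + 1L]] <- sm
    }
  }
  list(samples = samples, phantoms = phantoms)
}
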