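#' Tissue-phantom generation parameters
#'
#' Counts and size ranges of the structures placed in one phantom tile.
#' Nuclei are random ellipses (axis lengths 4-10 px), vessels are annuli
#' whose lumen boundary is studded with small endothelial nuclei, and
#' epithelial regions are smoothed blobs (unions of discs closed with the
#' evaluation pipeline's default structuring element, so their ground-truth
#' masks are stable under the morphological closing used at analysis time).
#' All structures keep a minimum 6-px clearance between nucleus instances
#' so connected components never merge. Defaults are sized for 64-px
#' tiles (the desk-scale study condition); scale the counts up for larger
#' tiles.
#'
#' @param n_nuclei Regular (non-endothelial) nuclei per tile.
#' @param n_vessels Vessels per tile.
#' @param n_epithelial Epithelial blobs per tile.
#' @param nucleus_axes Range of ellipse axis lengths in pixels.
#' @param vessel_radius Range of vessel outer radii in pixels.
#' @param vessel_wall Wall thickness in pixels (lumen radius = outer - wall).
#' @param endo_per_vessel Endothelial nuclei studding each vessel ring.
#' @param endo_radius Range of endothelial nucleus radii in pixels.
#' @param blob_radius Range of disc radii composing an epithelial blob.
#' @param min_gap Minimum clearance between nucleus instances in pixels.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_nuclei = 6L, n_vessels = 1L, n_epithelial = 1L,
                         nucleus_axes = c(4, 10), vessel_radius = c(7, 9),
                         vessel_wall = 2, endo_per_vessel = 3L,
                         endo_radius = c(1.5, 2), blob_radius = c(5, 8),
                         min_gap = 6) {
  stopifnot(n_nuclei >= 0, n_vessels >= 0, n_epithelial >= 0,
            all(nucleus_axes > 0), all(vessel_radius > 0), vessel_wall > 0,
            endo_per_vessel >= 0, min_gap >= 0)
  structure(list(n_nuclei = as.integer(n_nuclei),
                 n_vessels = as.integer(n_vessels),
                 n_epithelial = as.integer(n_epithelial),
                 nucleus_axes = nucleus_axes, vessel_radius = vessel_radius,
                 vessel_wall = vessel_wall,
                 endo_per_vessel = as.integer(endo_per_vessel),
                 endo_radius = endo_radius, blob_radius = blob_radius,
                 min_gap = min_gap), class = "phantom_spec")
}

# compartment codes used across the package
PHANTOM_CLASSES <- c(background = 0L, stroma = 1L, epithelial_cytoplasm = 2L,
                     vessel_lumen = 3L)
PHANTOM_COMPARTMENTS <- c(background = 0L, stroma = 1L,
                          epithelial_cytoplasm = 2L, vessel_lumen = 3L,
                          nucleus = 4L, endothelial_nucleus = 5L)

ellipse_mask <- function(h, w, cy, cx, a, b, theta) {
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- yy * cos(theta) + xx * sin(theta)
  v <- -yy * sin(theta) + xx * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

disc_mask <- function(h, w, cy, cx, r) ellipse_mask(h, w, cy, cx, r, r, 0)

#' Generate a tissue phantom
#'
#' Builds the latent tissue geometry from which both the AF channels and
#' the stained brightfield targets are rendered: a circular tissue core on
#' background, stromal interior, epithelial blobs, vessels with lumina and
#' endothelial nuclei lining the lumen boundary, and elliptical nuclei.
#' Bit-identical output under the same `(height, width, spec, seed)`.
#'
#' @param height,width Tile dimensions in pixels (>= 64).
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return A `tissue_phantom` with fields `class_map` (integer matrix with
#'   codes background 0, stroma 1, epithelial_cytoplasm 2, vessel_lumen 3),
#'   `nuclei_labels` (integer instance ids, 0 = none), `endothelial_nuclei_mask`,
#'   `epithelial_mask`, `vessel_lumen_mask` (logical matrices), and ground
#'   truth counts in `counts`.
#' @export
generate_phantom <- function(height, width, spec = phantom_spec(), seed = 1L) {
  stopifnot(height >= 64, width >= 64, inherits(spec, "phantom_spec"))
  with_seed(derive_seed(seed, "phantom"), {
    h <- as.integer(height); w <- as.integer(width)
    core_r <- 0.48 * min(h, w)
    cy0 <- (h + 1) / 2; cx0 <- (w + 1) / 2
    core <- disc_mask(h, w, cy0, cx0, core_r)
    class_map <- matrix(PHANTOM_CLASSES[["background"]], h, w)
    class_map[core] <- PHANTOM_CLASSES[["stroma"]]

    # epithelial blobs: unions of discs, then morphological closing so the
    # stored ground truth is a fixed point of the analysis-time closing
    epi <- matrix(FALSE, h, w)
    for (i in seq_len(spec$n_epithelial)) {
      bc <- random_point_in_core(h, w, cy0, cx0, core_r * 0.55)
      blob <- matrix(FALSE, h, w)
      for (k in seq_len(5)) {
        r <- runif(1, spec$blob_radius[1], spec$blob_radius[2])
        off <- runif(2, -spec$blob_radius[2], spec$blob_radius[2])
        blob <- blob | disc_mask(h, w, bc[1] + off[1], bc[2] + off[2], r)
      }
      epi <- epi | blob
    }
    epi <- epi & core
    if (any(epi)) epi <- mask_closing(epi, radius = 2L)
    class_map[epi] <- PHANTOM_CLASSES[["epithelial_cytoplasm"]]

    # vessels: annuli placed away from each other (they may sit inside
    # epithelial regions -- the vascular-invasion configuration)
    lumen <- matrix(FALSE, h, w)
    vessels <- list()
    tries <- 0L
    while (length(vessels) < spec$n_vessels) {
      if ((tries <- tries + 1L) > 200L * max(spec$n_vessels, 1L))
        stop("configuration error: cannot place ", spec$n_vessels,
             " vessels in ", h, "x", w, call. = FALSE)
      rv <- runif(1, spec$vessel_radius[1], spec$vessel_radius[2])
      ctr <- random_point_in_core(h, w, cy0, cx0, core_r - rv - 4)
      ok <- TRUE
      for (v in vessels)
        if (sum((ctr - v$ctr)^2) < (rv + v$r + 2 * spec$min_gap +
                                    2 * max(spec$endo_radius))^2) ok <- FALSE
      if (!ok) next
      vessels[[length(vessels) + 1L]] <- list(ctr = ctr, r = rv)
      lum <- disc_mask(h, w, ctr[1], ctr[2], rv - spec$vessel_wall)
      lumen <- lumen | lum
    }
    class_map[lumen] <- PHANTOM_CLASSES[["vessel_lumen"]]

    # nuclei: regular first, then endothelial; ids in placement order
    labels <- matrix(0L, h, w)
    placed <- list()  # bounding circles (cy, cx, r) for clearance checks
    next_id <- 0L

    place_ellipse <- function(cy, cx, a, b, theta) {
      m <- ellipse_mask(h, w, cy, cx, a, b, theta)
      next_id <<- next_id + 1L
      labels[m] <<- next_id
      placed[[length(placed) + 1L]] <<- c(cy, cx, max(a, b))
      m
    }
    clear_of_nuclei <- function(cy, cx, r) {
      for (p in placed)
        if ((cy - p[1])^2 + (cx - p[2])^2 < (r + p[3] + spec$min_gap)^2)
          return(FALSE)
      TRUE
    }

    tries <- 0L
    n_reg <- 0L
    while (n_reg < spec$n_nuclei) {
      if ((tries <- tries + 1L) > 400L * max(spec$n_nuclei, 1L))
        stop("configuration error: cannot place ", spec$n_nuclei,
             " nuclei in ", h, "x", w, call. = FALSE)
      a <- runif(1, spec$nucleus_axes[1], spec$nucleus_axes[2]) / 2
      b <- runif(1, spec$nucleus_axes[1], spec$nucleus_axes[2]) / 2
      rmax <- max(a, b)
      ctr <- random_point_in_core(h, w, cy0, cx0, core_r - rmax - 2)
      ok <- clear_of_nuclei(ctr[1], ctr[2], rmax)
      for (v in vessels)   # keep regular nuclei off the vessel ring
        if (sum((ctr - v$ctr)^2) < (v$r + rmax + spec$min_gap)^2) ok <- FALSE
      if (!ok) next
      place_ellipse(ctr[1], ctr[2], a, b, runif(1, 0, pi))
      n_reg <- n_reg + 1L
    }

    endo <- matrix(FALSE, h, w)
    for (v in vessels) {
      ring_r <- v$r - spec$vessel_wall + 1   # just outside the lumen edge
      k <- spec$endo_per_vessel
      if (k == 0L) next
      rad <- mean(spec$endo_radius)
      # angular spacing that guarantees the clearance along the ring
      min_dtheta <- (2 * rad + spec$min_gap) / ring_r
      if (k * min_dtheta > 2 * pi)
        stop("configuration error: ", k, " endothelial nuclei do not fit ",
             "on a vessel of radius ", round(v$r, 1), call. = FALSE)
      theta0 <- runif(1, 0, 2 * pi)
      thetas <- theta0 + (seq_len(k) - 1) * (2 * pi / k)
      for (th in thetas) {
        cy <- v$ctr[1] + ring_r * cos(th)
        cx <- v$ctr[2] + ring_r * sin(th)
        r <- runif(1, spec$endo_radius[1], spec$endo_radius[2])
        m <- place_ellipse(cy, cx, r, r * runif(1, 0.7, 1), runif(1, 0, pi))
        endo <- endo | m
      }
    }

    epithelial_mask <- epi | (labels > 0L & epi)   # cytoplasm plus nuclei
    class_map[labels > 0L & class_map == PHANTOM_CLASSES[["epithelial_cytoplasm"]] &
                !epi] <- PHANTOM_CLASSES[["stroma"]]

    structure(list(height = h, width = w, class_map = class_map,
                   nuclei_labels = labels, endothelial_nuclei_mask = endo,
                   epithelial_mask = epithelial_mask,
                   vessel_lumen_mask = lumen, core_mask = core,
                   vessels = vessels, rng_seed = as.integer(seed),
                   spec = spec,
                   counts = list(n_nuclei_total = next_id,
                                 n_regular = n_reg,
                                 n_endothelial = next_id - n_reg,
                                 n_vessels = length(vessels),
                                 n_epithelial = spec$n_epithelial)),
              class = "tissue_phantom")
  })
}

random_point_in_core <- function(h, w, cy0, cx0, rmax) {
  repeat {
    cy <- runif(1, 1, h); cx <- runif(1, 1, w)
    if ((cy - cy0)^2 + (cx - cx0)^2 <= rmax^2) return(c(cy, cx))
  }
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat("<tissue_phantom>", x$height, "x", x$width, "|",
      x$counts$n_nuclei_total, "nuclei (", x$counts$n_endothelial,
      "endothelial ) |", x$counts$n_vessels, "vessels |",
      x$counts$n_epithelial, "epithelial blobs\n")
  invisible(x)
}

# per-pixel compartment map with nuclei overlaid on their background class
phantom_compartments <- function(phantom) {
  comp <- phantom$class_map
  comp[phantom$nuclei_labels > 0L] <- PHANTOM_COMPARTMENTS[["nucleus"]]
  comp[phantom$endothelial_nuclei_mask] <-
    PHANTOM_COMPARTMENTS[["endothelial_nucleus"]]
  comp
}

# morphological closing (dilation then erosion) with a disc brush
mask_closing <- function(mask, radius = 2L) {
  br <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  m <- EBImage::erode(EBImage::dilate(mask * 1, br), br)
  m > 0.5
}
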