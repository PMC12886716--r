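test_that("an empty scene renders as stroma/background with no instances", {
  sp <- phantom_spec(n_nuclei = 0, n_vessels = 0, n_epithelial = 0)
  ph <- generate_phantom(64, 64, sp, seed = 1)
  expect_true(all(ph$class_map %in% c(0L, 1L)))
  expect_true(all(ph$nuclei_labels == 0L))
  expect_false(any(ph$endothelial_nuclei_mask))
  expect_false(any(ph$epithelial_mask))
})

test_that("requested instance counts appear as label ids, and placement is seeded", {
  sp <- phantom_spec(n_nuclei = 8, n_vessels = 0, n_epithelial = 0)
  ph <- generate_phantom(96, 96, sp, seed = 7)
  expect_equal(max(ph$nuclei_labels), 8L)
  expect_equal(ph$counts$n_regular, 8L)
  expect_identical(ph, generate_phantom(96, 96, sp, seed = 7))
  expect_false(identical(ph$nuclei_labels,
                         generate_phantom(96, 96, sp, seed = 8)$nuclei_labels))
})

test_that("phantom invariants hold: endothelial nuclei are labelled instances near lumina", {
  ph <- generate_phantom(96, 96, phantom_spec(n_vessels = 2), seed = 3)
  endo <- ph$endothelial_nuclei_mask
  expect_true(any(endo))
  expect_true(all(ph$nuclei_labels[endo] > 0L))
  # every endothelial nucleus sits within a few pixels of a lumen boundary
  near <- EBImage::dilate(ph$vessel_lumen_mask * 1,
                          EBImage::makeBrush(11, "disc")) > 0.5
  expect_true(all(near[endo]))
  # epithelial mask covers all epithelial-cytoplasm pixels
  expect_true(all(ph$epithelial_mask[ph$class_map == 2L]))
  expect_equal(ph$counts$n_nuclei_total,
               ph$counts$n_regular + ph$counts$n_endothelial)
})

test_that("infeasible structure counts raise a configuration error", {
  expect_error(generate_phantom(64, 64, phantom_spec(n_nuclei = 500), 1),
               "configuration error")
  expect_error(generate_phantom(64, 64, phantom_spec(n_vessels = 40), 1),
               "configuration error")
})

test_that("an empty phantom renders pure white under any recipe", {
  sp <- phantom_spec(n_nuclei = 0, n_vessels = 0, n_epithelial = 0)
  ph <- generate_phantom(64, 64, sp, seed = 1)
  # suppress the stroma wash so no compartment carries any chromogen
  rec <- chromogen_recipe("erg", rules = list(endothelial_nuclei = c(dab = 1)))
  img <- render_stain(ph, rec)
  expect_equal(img, array(1, c(64, 64, 3)))
})

test_that("rendered DAB pixels follow the Beer-Lambert closed form", {
  ph <- generate_phantom(96, 96, phantom_spec(), seed = 5)
  rec <- chromogen_recipe("erg")
  img <- render_stain(ph, rec)
  v <- stain_vectors(c("hematoxylin", "dab"))
  endo <- ph$endothelial_nuclei_mask
  for (ch in 1:3) {
    plane <- img[, , ch]
    expect_equal(unique(round(plane[endo], 12)),
                 unname(round(10^(-1.0 * v["dab", ch]), 12)))
  }
})

test_that("ERG rendering marks exactly the endothelial nuclei as DAB-positive", {
  ph <- generate_phantom(96, 96, phantom_spec(n_vessels = 2), seed = 9)
  img <- render_stain(ph, chromogen_recipe("erg"))
  conc <- color_deconvolve(img, stain_vectors(c("hematoxylin", "dab")))
  expect_identical(dab_mask(conc[, , "dab"]), ph$endothelial_nuclei_mask)
})

test_that("negative concentrations in recipe rules are rejected", {
  expect_error(chromogen_recipe("erg",
                                rules = list(nucleus = c(hematoxylin = -1))),
               "negative concentration")
  expect_error(chromogen_recipe("erg", rules = list(foo = c(dab = 1))),
               "unknown region")
})

test_that("noise-free AF channels are piecewise constant at the mixing values", {
  ph <- generate_phantom(64, 64,
                         phantom_spec(n_nuclei = 0, n_vessels = 0,
                                      n_epithelial = 0), seed = 1)
  mx <- default_af_mixing()
  af <- render_af(ph, mx, noise_sd = 0, texture_amp = 0)
  stroma <- ph$class_map == 1L
  for (ch in 1:4) {
    expect_equal(unique(af[, , ch][stroma]), unname(mx["stroma", ch]))
    expect_equal(unique(af[, , ch][!stroma]),
                 unname(mx["background", ch]))
  }
})

test_that("DAPI contrast separates nuclei from stroma as the mixing specifies", {
  ph <- generate_phantom(96, 96, phantom_spec(), seed = 2)
  af <- render_af(ph, seed = 4)
  nuc <- ph$nuclei_labels > 0
  stroma <- ph$class_map == 1L & !nuc
  expect_gt(mean(af[, , 1][nuc]), mean(af[, , 1][stroma]))
})

test_that("AF seeds change only the noise realisation", {
  ph <- generate_phantom(64, 64, phantom_spec(), seed = 6)
  base <- render_af(ph, noise_sd = 0, texture_amp = 0)
  a1 <- render_af(ph, noise_sd = 0.02, texture_amp = 0, seed = 1)
  a2 <- render_af(ph, noise_sd = 0.02, texture_amp = 0, seed = 2)
  expect_false(identical(a1, a2))
  # identical after noise subtraction (away from the clipping boundary)
  inner <- base > 0.05 & base < 0.95
  n1 <- (a1 - base)[inner]; n2 <- (a2 - base)[inner]
  expect_equal(sd(n1), 0.02, tolerance = 0.01)
  expect_identical(render_af(ph, noise_sd = 0.02, texture_amp = 0, seed = 1),
                   a1)
})

test_that("misalignment fields respect amplitude, smoothness and the zero case", {
  ph <- generate_phantom(64, 64, phantom_spec(), seed = 8)
  s <- multiplex_sample(render_af(ph, seed = 1), "he",
                        render_stain(ph, chromogen_recipe("he")))
  m0 <- make_misaligned_pair(s, amplitude = 0)
  expect_identical(m0$target, s$target)
  expect_true(all(m0$true_displacement$dy == 0))

  m4 <- make_misaligned_pair(s, amplitude = 4, seed = 3)
  expect_equal(max(abs(c(m4$true_displacement$dy, m4$true_displacement$dx))),
               4, tolerance = 1e-9)
  # smooth fields have far lower gradient energy than white noise of the
  # same amplitude
  expect_lt(smth(m4$true_displacement), 4^2 / 4)
  expect_error(make_misaligned_pair(s, amplitude = 10), "10%")
})

test_that("datasets round-trip losslessly through the manifest readers", {
  ph <- generate_phantom(64, 64, phantom_spec(), seed = 10)
  dir <- withr::local_tempdir()
  stains <- c("he", "erg", "panck", "he", "erg")
  samples <- lapply(seq_along(stains), function(i)
    multiplex_sample(render_af(ph, seed = i), stains[i],
                     render_stain(ph, chromogen_recipe(stains[i])),
                     id = sprintf("t%02d_%s_%d", i, stains[i], i)))
  write_dataset(samples, dir, seed = 42)
  m <- load_manifest(dir)
  expect_equal(nrow(m), 5L)
  tb <- table(m$stain)
  expect_equal(as.vector(tb[c("he", "erg", "panck")]), c(2L, 2L, 1L))
  expect_equal(nrow(validate_manifest(m)), 0L)
  back <- read_dataset(dir)
  for (i in seq_along(samples)) {
    expect_identical(back[[i]]$af, virtmihc:::snap16(samples[[i]]$af))
    expect_identical(back[[i]]$target, virtmihc:::snap16(samples[[i]]$target))
    expect_equal(back[[i]]$stain_class, samples[[i]]$stain_class)
  }
})
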