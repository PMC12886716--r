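test_that("colour deconvolution inverts the optical-density mixture", {
  v <- stain_vectors(c("hematoxylin", "dab"))
  white <- array(1, c(4, 4, 3))
  expect_equal(color_deconvolve(white, v),
               array(0, c(4, 4, 3)), ignore_attr = TRUE)
  # known concentrations -> rgb -> recovered concentrations
  set.seed(31)
  conc <- array(runif(8 * 8 * 3, 0, 1.2), c(8, 8, 3))
  rgb <- virtmihc:::color_reconstruct(conc, v)
  back <- color_deconvolve(rgb, v)
  expect_equal(back, conc, tolerance = 1e-9, ignore_attr = TRUE)
  # deconvolve-then-reconstruct reproduces the RGB
  img <- rand_img(6, 6, 3, 32) * 0.9 + 0.05
  expect_equal(virtmihc:::color_reconstruct(color_deconvolve(img, v), v),
               img, tolerance = 1e-9)
  sing <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1))
  expect_error(color_deconvolve(img, sing), "singular")
})

test_that("Otsu-based DAB masking separates a well-split bimodal map", {
  set.seed(33)
  truth <- matrix(FALSE, 48, 48); truth[10:20, 10:20] <- TRUE
  dmap <- matrix(rnorm(48 * 48, 0.1, 0.04), 48, 48)
  dmap[truth] <- rnorm(sum(truth), 0.9, 0.04)      # 5+ sigma separation
  m <- dab_mask(dmap)
  expect_lt(mean(m != truth), 0.01)
  expect_warning(m0 <- dab_mask(matrix(0, 8, 8)), "constant")
  expect_false(any(m0))
  # adding a constant below the mode gap shifts the threshold with it
  expect_equal(dab_mask(dmap + 0.2), m)
})

test_that("nuclei statistics count connected components under 8-connectivity", {
  empty <- matrix(FALSE, 10, 10)
  s <- erg_nuclei_stats(empty)
  expect_equal(s$count, 0L)
  expect_true(is.na(s$mean_area))

  two <- matrix(FALSE, 12, 12)
  two[2:4, 2:4] <- TRUE; two[8:10, 8:10] <- TRUE
  s2 <- erg_nuclei_stats(two)
  expect_equal(s2$count, 2L)
  expect_equal(s2$mean_area, 9)

  # diagonal adjacency merges under 8- but not 4-connectivity
  diagm <- matrix(FALSE, 6, 6); diagm[2, 2] <- TRUE; diagm[3, 3] <- TRUE
  expect_equal(erg_nuclei_stats(diagm, connectivity = 8)$count, 1L)
  expect_equal(erg_nuclei_stats(diagm, connectivity = 4)$count, 2L)

  set.seed(34)
  for (i in 1:3) {
    rnd <- matrix(runif(30 * 30) < 0.25, 30, 30)
    expect_equal(erg_nuclei_stats(rnd)$count, bf_count_components(rnd, 8))
  }
})

test_that("down-sampled IoU follows its block-pooled definition", {
  m <- matrix(FALSE, 16, 16); m[3:10, 3:10] <- TRUE
  expect_equal(d_iou(m, m), 1)
  m2 <- matrix(FALSE, 16, 16); m2[12:16, 12:16] <- TRUE
  m3 <- matrix(FALSE, 16, 16); m3[1:4, 1:4] <- TRUE
  expect_equal(d_iou(m3, m2), 0)
  # one shared and one unshared occupied 8x8 block -> 1/2
  a <- matrix(FALSE, 16, 16); a[1:8, 1:8] <- TRUE
  b <- matrix(FALSE, 16, 16); b[1:8, 1:8] <- TRUE; b[9:16, 9:16] <- TRUE
  expect_equal(d_iou(a, b), 0.5)
  expect_equal(d_iou(matrix(FALSE, 8, 8), matrix(FALSE, 8, 8)), 1)
  set.seed(35)
  for (i in 1:4) {
    x <- matrix(runif(24 * 24) < 0.2, 24, 24)
    y <- matrix(runif(24 * 24) < 0.2, 24, 24)
    v <- d_iou(x, y)
    expect_equal(v, bf_d_iou(x, y))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("d_iou is monotone in shared support and dihedral-invariant", {
  set.seed(36)
  x <- matrix(runif(32 * 32) < 0.15, 32, 32)
  y <- matrix(runif(32 * 32) < 0.15, 32, 32)
  v0 <- d_iou(x, y)
  y2 <- y | x                       # add full shared support
  expect_gte(d_iou(x, y2), v0)
  rot <- function(m) t(m[nrow(m):1, ])
  expect_equal(d_iou(rot(x), rot(y)), v0)
})

test_that("ssim matches a brute-force windowed implementation", {
  a <- rand_img(20, 20, 3, 37); b <- rand_img(20, 20, 3, 38)
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, b), ssim(b, a))
  expect_equal(ssim(a, b), bf_ssim(a, b), tolerance = 1e-9)
  am <- matrix(runif(16 * 16), 16); bm <- matrix(runif(16 * 16), 16)
  expect_equal(ssim(am, bm), bf_ssim(am, bm), tolerance = 1e-9)
  # PSNR/SSIM invariant to simultaneous dihedral transforms
  rot3 <- function(x) { y <- x; for (c in 1:3) y[, , c] <- t(x[, , c][20:1, ]); y }
  expect_equal(ssim(rot3(a), rot3(b)), ssim(a, b), tolerance = 1e-12)
  expect_equal(psnr(rot3(a), rot3(b)), psnr(a, b), tolerance = 1e-12)
})

test_that("perceptual distance degenerates to normalised MSE under identity features", {
  a <- rand_img(12, 12, 3, 39); b <- rand_img(12, 12, 3, 40)
  expect_equal(perceptual_distance(a, a), 0)
  na <- virtmihc:::unit_normalize(a); nb <- virtmihc:::unit_normalize(b)
  expect_equal(perceptual_distance(a, b), mean((na - nb)^2))
  expect_true(is.na(perceptual_distance(a, b, extractor = NULL)))
})

test_that("paired t test matches the textbook formula and its sentinels", {
  x <- c(12, 15, 9, 11, 14)
  y <- c(10, 16, 8, 9, 15)
  r <- paired_t(x, y)
  d <- x - y
  expect_equal(r$statistic, mean(d) / (sd(d) / sqrt(5)))
  expect_equal(r$p, t.test(x, y, paired = TRUE)$p.value)
  same <- paired_t(x, x)
  expect_equal(same$statistic, 0); expect_equal(same$p, 1)
  shifted <- paired_t(x + 2, x)
  expect_equal(shifted$statistic, Inf); expect_equal(shifted$p, 0)
})

test_that("cohort evaluation reports per-pair metrics and skips bad pairs", {
  ph <- generate_phantom(64, 64, phantom_spec(n_vessels = 2), seed = 41)
  erg <- render_stain(ph, chromogen_recipe("erg"))
  pairs <- list(list(virtual = erg, reference = erg),
                list(virtual = erg, reference = erg),
                list(virtual = erg, reference = array(1, c(32, 32, 3))))
  rep <- evaluate_pairs(pairs, "erg")
  expect_equal(rep$summary$n_evaluated, 2L)
  expect_equal(rep$summary$n_skipped, 1L)
  expect_true(all(rep$rows$ssim == 1))
  expect_true(all(is.infinite(rep$rows$psnr)))
  expect_equal(rep$rows$nuclei_count_vs, rep$rows$nuclei_count_hs)
  expect_equal(rep$summary$t_count$statistic, 0)

  pk <- render_stain(ph, chromogen_recipe("panck"))
  repp <- evaluate_pairs(list(list(virtual = pk, reference = pk)), "panck")
  expect_equal(repp$rows$d_iou, 1)

  dir <- withr::local_tempdir()
  write_eval_report(rep, dir)
  expect_true(file.exists(file.path(dir, "per_pair.csv")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$n_evaluated, 2L)
})
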