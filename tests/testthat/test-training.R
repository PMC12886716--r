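# Small co-registered cohort shared across the training tests
local_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- simulate_cohort(2, size = 64, seed = 311)
    coh
  }
})

test_that("balanced sampling is uniform over stains and seed-reproducible", {
  ds <- list(he = as.list(1:40), erg = as.list(1:12), panck = as.list(1:25))
  bb <- balanced_batches(ds, batch_size = 4, n_batches = 2000, seed = 99)
  stains <- unlist(lapply(bb, `[[`, "stain"))
  expect_length(stains, 8000)
  freq <- table(stains) / 8000
  # 99.9% binomial interval around 1/3 for 8,000 draws
  expect_true(all(abs(freq - 1 / 3) <= 0.0174))
  expect_identical(bb, balanced_batches(ds, 4, 2000, seed = 99))
  expect_false(identical(bb[[1]], balanced_batches(ds, 4, 1, seed = 100)[[1]]))
})

test_that("a single-sample stain dataset recurs while stain frequencies stay uniform", {
  ds <- list(he = as.list(1:20), erg = as.list(1), panck = as.list(1:20))
  bb <- balanced_batches(ds, 4, 1500, seed = 5)
  df <- do.call(rbind, bb)
  expect_true(all(df$idx[df$stain == "erg"] == 1L))
  freq <- table(df$stain) / nrow(df)
  expect_true(all(abs(freq - 1 / 3) < 0.03))
  expect_error(balanced_batches(list(he = list(1), erg = list()), 4, 1),
               "empty stain dataset")
})

test_that("augmentation applies one dihedral transform consistently and invertibly", {
  s <- local_cohort()$samples[[1]]
  s <- make_misaligned_pair(s, amplitude = 3, seed = 2)
  expect_identical(virtmihc:::augment_apply(s, 0L)$af, s$af)   # identity
  for (k in 0:7) {
    tr <- virtmihc:::augment_apply(s, k)
    back <- virtmihc:::augment_apply(tr, virtmihc:::dihedral_inverse(k))
    expect_identical(back$af, s$af)
    expect_identical(back$target, s$target)
    expect_equal(back$true_displacement$dy, s$true_displacement$dy)
    expect_equal(back$true_displacement$dx, s$true_displacement$dx)
    # the transformed pair stays warp-consistent: the stored field still
    # maps the (transformed) aligned target onto the misaligned one
  }
  ks <- vapply(1:4000, function(i)
    attr(augment(s, seed = i), "transform"), integer(1))
  freq <- table(factor(ks, levels = 0:7)) / 4000
  expect_true(all(abs(freq - 1 / 8) < 0.025))
  bad <- multiplex_sample(array(0.5, c(64, 48, 4)), "he",
                          array(0.5, c(64, 48, 3)))
  expect_error(augment(bad), "square")
})

test_that("augmentation commutes with warping of the misaligned target", {
  s <- local_cohort()$samples[[2]]
  mis <- make_misaligned_pair(s, amplitude = 3, seed = 7)
  for (k in c(1L, 5L)) {
    tr <- virtmihc:::augment_apply(mis, k)
    # warp the transformed aligned target with the transformed field
    aligned_tr <- virtmihc:::dihedral_image(s$target, k)
    rewarped <- warp(aligned_tr, tr$true_displacement)
    expect_equal(rewarped, tr$target, tolerance = 1e-12)
  }
})

test_that("frozen optimizers leave parameters bit-identical with finite losses", {
  coh <- local_cohort()
  cfg <- train_config("tiny", steps = 4L, seed = 2L,
                      lr_generator = 0, lr_discriminator = 0,
                      lr_registration = 0)
  b0 <- init_bundle(cfg)
  batches <- rep(list(coh$samples[1:2]), 5)
  r <- train_step(b0, batches, cfg$coefficients)
  expect_identical(virtmihc:::tree_unlist(r$bundle$G$params),
                   virtmihc:::tree_unlist(b0$G$params))
  expect_identical(virtmihc:::tree_unlist(r$bundle$D$params),
                   virtmihc:::tree_unlist(b0$D$params))
  expect_true(all(is.finite(unlist(r$records[r$records$kind == "G",
                                             c("l_huber", "l_adv", "l_tv")]))))
})

test_that("the 4:1 schedule isolates gradients per network", {
  coh <- local_cohort()
  cfg <- train_config("tiny", steps = 4L, seed = 3L)
  b0 <- init_bundle(cfg)
  batches <- rep(list(coh$samples[c(1, 4)]), 5)
  ns <- asNamespace("virtmihc")
  # the four generator updates must not touch the discriminator
  r1 <- ns$g_and_r_update(b0, batches[[1]], cfg$coefficients)
  expect_identical(ns$tree_unlist(r1$bundle$D$params),
                   ns$tree_unlist(b0$D$params))
  expect_false(identical(ns$tree_unlist(r1$bundle$G$params),
                         ns$tree_unlist(b0$G$params)))
  expect_false(identical(ns$tree_unlist(r1$bundle$R$params),
                         ns$tree_unlist(b0$R$params)))
  # and the discriminator update must not touch generator or registration
  r2 <- ns$d_update(r1$bundle, batches[[2]], cfg$coefficients)
  expect_identical(ns$tree_unlist(r2$bundle$G$params),
                   ns$tree_unlist(r1$bundle$G$params))
  expect_identical(ns$tree_unlist(r2$bundle$R$params),
                   ns$tree_unlist(r1$bundle$R$params))
  expect_false(identical(ns$tree_unlist(r2$bundle$D$params),
                         ns$tree_unlist(r1$bundle$D$params)))
})

test_that("checkpoints restore bit-identical forward outputs", {
  coh <- local_cohort()
  cfg <- train_config("tiny", steps = 4L, seed = 4L)
  m <- vmihc_train(coh$samples, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  b2 <- load_checkpoint(path)
  af <- coh$samples[[1]]$af
  expect_identical(stain_field(af, "he", b2), stain_field(af, "he", m))
  expect_error(load_checkpoint(withr::local_tempfile(fileext = ".rds",
                                                     lines = "x")),
               "checkpoint|RDS|unknown", ignore.case = TRUE)
})

test_that("resuming from a checkpoint reproduces the uninterrupted loss log bitwise", {
  coh <- local_cohort()
  cfg <- train_config("tiny", steps = 16L, seed = 5L)
  full <- vmihc_train(coh$samples, cfg)
  half <- vmihc_train(coh$samples, train_config("tiny", steps = 8L, seed = 5L))
  resumed <- vmihc_train(coh$samples, cfg, bundle = half$bundle)
  tail_log <- full$log[full$log$step > 8L, ]
  rownames(tail_log) <- NULL
  rl <- resumed$log; rownames(rl) <- NULL
  expect_identical(rl, tail_log)
  expect_identical(virtmihc:::tree_unlist(resumed$bundle$G$params),
                   virtmihc:::tree_unlist(full$bundle$G$params))
})

test_that("zero-step training returns the seeded initialisation unchanged", {
  cfg <- train_config("tiny", steps = 0L, seed = 6L)
  m <- vmihc_train(local_cohort()$samples, cfg)
  b0 <- init_bundle(cfg)
  expect_identical(virtmihc:::tree_unlist(m$bundle$G$params),
                   virtmihc:::tree_unlist(b0$G$params))
  expect_null(m$log)
})

test_that("the in-loop registration module improves training on misaligned targets", {
  # targets carry known 4-px smooth distortions; generators trained with
  # and without the warped-Huber term are compared on held-out tiles with
  # aligned targets, same seeds and budget
  train <- simulate_cohort(3, size = 64, stains = "he", misalign_px = 4,
                           seed = 551)
  held <- simulate_cohort(2, size = 64, stains = "he", seed = 552)
  aligned_huber <- function(model) {
    mean(vapply(held$samples, function(s)
      huber(s$target, stain_field(s$af, "he", model)), numeric(1)))
  }
  with_r <- vmihc_train(train$samples,
                        train_config("tiny", steps = 120L, seed = 9L))
  without_r <- vmihc_train(train$samples,
                           train_config("tiny", steps = 120L, seed = 9L,
                                        use_registration = FALSE))
  expect_lt(aligned_huber(with_r), aligned_huber(without_r))
})
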