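#' Training configuration
#'
#' The `"paper"` preset carries the full-scale settings: Adam learning
#' rates 2e-5 (generator), 2e-6 (discriminator), 2e-6 (registration),
#' batch size 4, four generator updates per discriminator update, 512-px
#' crops, rotations {0, 90, 180, 270} degrees and random flips, generator
#' base width 64 and registration depth 7. The `"tiny"` preset keeps the
#' loss coefficients and the 4:1 schedule but shrinks the networks (base
#' width 8, registration depth 3), uses 64-px tiles and desk-scale
#' learning rates (1e-3/1e-4/1e-4) so training converges within minutes on
#' one CPU.
#'
#' @param preset `"tiny"` or `"paper"`.
#' @param ... Named overrides of any config field.
#' @return A `train_config` list.
#' @export
train_config <- function(preset = c("tiny", "paper"), ...) {
  preset <- match.arg(preset)
  base <- list(
    lr_generator = 2e-5, lr_discriminator = 2e-6, lr_registration = 2e-6,
    batch_size = 4L, g_updates_per_d_update = 4L, crop = 512L,
    rotations = c(0L, 90L, 180L, 270L), flips = TRUE,
    steps = 10000L, seed = 1L, coefficients = loss_coefficients(),
    base_width_g = 64L, base_width_d = 64L, base_width_r = 16L,
    depth_g = 4L, depth_r = 7L, activation = "sigmoid",
    use_registration = TRUE, checkpoint_every = 1000L)
  if (preset == "tiny")
    base <- modifyList(base, list(
      lr_generator = 1e-3, lr_discriminator = 1e-4, lr_registration = 1e-4,
      crop = 64L, steps = 500L, base_width_g = 8L, base_width_d = 16L,
      base_width_r = 8L, depth_r = 3L, checkpoint_every = 250L,
      activation = "linear"))
  cfg <- modifyList(base, list(...))
  stopifnot(cfg$lr_generator >= 0, cfg$lr_discriminator >= 0,
            cfg$lr_registration >= 0, cfg$batch_size >= 1,
            cfg$crop %% 2L^max(cfg$depth_g, cfg$depth_r) == 0)
  cfg$preset <- preset
  structure(cfg, class = "train_config")
}

#' Initialise a model bundle
#'
#' Generator, discriminator and registration networks with seeded weight
#' initialisation, plus one Adam optimizer per network and a step counter.
#'
#' @param config A [train_config()].
#' @return A `model_bundle`.
#' @export
init_bundle <- function(config = train_config("tiny")) {
  seeds <- seed_all(config$seed)
  with_seed(seeds[["init"]], {
    G <- build_generator(config$base_width_g, depth = config$depth_g,
                         activation = config$activation)
    D <- build_discriminator(config$base_width_d)
    R <- build_registration(config$base_width_r, depth = config$depth_r)
    structure(list(G = G, D = D, R = R,
                   opt_g = adam_init(G$params, config$lr_generator),
                   opt_d = adam_init(D$params, config$lr_discriminator),
                   opt_r = adam_init(R$params, config$lr_registration),
                   step = 0L, config = config), class = "model_bundle")
  })
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("<model_bundle> step", x$step, "preset", x$config$preset, "\n")
  print(x$G); print(x$D); print(x$R)
  invisible(x)
}

#' Balanced batch plan over the three stain datasets
#'
#' Every drawn sample's stain class is uniform over the available stains,
#' independently across draws (equal-probability mixing of the H&E, ERG
#' and PanCK datasets regardless of their sizes); within a stain, tiles
#' are drawn uniformly with replacement. Reproducible under `seed`.
#'
#' @param datasets Named list (per stain) of sample lists; all non-empty.
#' @param batch_size Samples per batch.
#' @param n_batches Number of batches to plan.
#' @param seed Integer seed.
#' @return List of data frames with columns `stain`, `idx`.
#' @export
balanced_batches <- function(datasets, batch_size, n_batches, seed = 1L) {
  stains <- names(datasets)
  sizes <- vapply(datasets, length, integer(1))
  if (any(sizes == 0))
    stop("empty stain dataset: ", paste(stains[sizes == 0], collapse = ", "),
         "; the equal-probability contract cannot be met", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_batches), function(b) {
      st <- stains[sample.int(length(stains), batch_size, replace = TRUE)]
      idx <- vapply(st, function(s)
        sample.int(sizes[[s]], 1L), integer(1))
      data.frame(stain = st, idx = idx, stringsAsFactors = FALSE,
                 row.names = NULL)
    })
  })
}

# --- dihedral augmentation --------------------------------------------------

rot_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
flip_v <- function(m) m[nrow(m):1, , drop = FALSE]

apply_planes <- function(x, f) {
  x <- as_tensor(x)
  out <- NULL
  for (c in seq_len(dim(x)[3])) {
    p <- f(x[, , c])
    if (is.null(out)) out <- array(0, c(dim(p), dim(x)[3]))
    out[, , c] <- p
  }
  out
}

# transform index k in 0..7: (k %% 4) clockwise quarter-turns, then a
# vertical flip if k >= 4. Displacement components co-transform.
dihedral_image <- function(x, k) {
  r <- k %% 4L
  for (i in seq_len(r)) x <- apply_planes(x, rot_cw)
  if (k >= 4L) x <- apply_planes(x, flip_v)
  x
}

dihedral_field <- function(field, k) {
  dy <- field$dy; dx <- field$dx
  for (i in seq_len(k %% 4L)) {
    tmp <- rot_cw(dx); dx2 <- -rot_cw(dy)
    dy <- tmp; dx <- dx2
  }
  if (k >= 4L) {
    dy <- -flip_v(dy); dx <- flip_v(dx)
  }
  displacement_field(dy, dx)
}

# pure rotations invert to the complementary rotation; the flip-composed
# transforms (rotate then flip) are involutions
dihedral_inverse <- function(k) if (k < 4L) (4L - k) %% 4L else k

augment_apply <- function(sample, k) {
  fld <- if (is.null(sample$true_displacement)) NULL
         else dihedral_field(sample$true_displacement, k)
  multiplex_sample(dihedral_image(sample$af, k), sample$stain_class,
                   dihedral_image(sample$target, k),
                   true_displacement = fld, id = sample$id)
}

#' Randomly augment a sample with a dihedral transform
#'
#' Samples one of the eight square symmetries (rotations by 0/90/180/270
#' degrees, optionally composed with a flip) uniformly and applies the
#' identical geometric transform to the AF channels, the target, and the
#' true displacement field if present (the constant DSM is unaffected).
#'
#' @param sample A square [multiplex_sample()].
#' @param seed Integer seed.
#' @return Transformed sample; attribute `"transform"` records the index.
#' @export
augment <- function(sample, seed = 1L) {
  d <- dim(sample$af)
  if (d[1] != d[2])
    stop("augmentation requires square crops for 90/270-degree rotations",
         call. = FALSE)
  k <- with_seed(seed, sample.int(8L, 1L) - 1L)
  out <- augment_apply(sample, k)
  attr(out, "transform") <- k
  out
}

# --- training steps ---------------------------------------------------------

# one generator update with the registration module riding along: the
# shared warped-Huber gradient drives R through the field and G through
# the warped image; the adversarial and TV terms touch only G. With the
# registration module disabled (ablation) the Huber term is computed on
# the unwarped output and R is untouched. Returns updated bundle plus
# mean component losses.
g_and_r_update <- function(bundle, batch, coeffs) {
  n <- length(batch)
  use_r <- isTRUE(bundle$config$use_registration)
  gG <- gR <- NULL
  acc <- c(huber = 0, adv = 0, tv = 0, reg = 0, smth = 0)
  for (s in batch) {
    dsm <- make_dsm(s$stain_class, dim(s$af)[1], dim(s$af)[2])
    gfwd <- generator_fwd(bundle$G, gen_input(s$af, dsm))
    g <- gfwd$y
    if (use_r) {
      rfwd <- registration_fwd(bundle$R, cat_ch(g, s$target))
      field <- rfwd$field
      warped <- warp(g, field)
      hg <- huber_grad(warped, s$target, coeffs$phi)
      wb <- warp_bwd(g, field, hg)
      l_h <- huber(s$target, warped, coeffs$phi)
      nf <- field_scale(field)^2      # SMTH in normalized coordinates
      l_s <- smth(field) / nf
      sg <- smth_grad(field)
      # registration: lambda * huber + mu * smth, through the field only
      rb <- registration_bwd(bundle$R, rfwd$cache,
                             coeffs$lambda_ * wb$gdy + coeffs$mu * sg$gdy / nf,
                             coeffs$lambda_ * wb$gdx + coeffs$mu * sg$gdx / nf)
      gR <- if (is.null(gR)) rb$gp else tree_add(gR, rb$gp)
      ghub <- wb$gx
    } else {
      l_h <- huber(s$target, g, coeffs$phi)
      l_s <- 0
      ghub <- huber_grad(g, s$target, coeffs$phi)
    }
    # generator: alpha * huber (through the warp; field constant) +
    # beta * adversarial (through D; D's params untouched) + gamma * TV
    dfwd <- discriminator_fwd(bundle$D, cat_ch(g, as_tensor(dsm$matrix)))
    l_a <- bce_logit(dfwd$score, 1)
    db <- discriminator_bwd(bundle$D, dfwd$cache,
                            coeffs$beta * bce_logit_grad(dfwd$score, 1),
                            want_params = FALSE)
    gout <- coeffs$alpha * ghub +
      db$gx[, , 1:3, drop = FALSE] +
      coeffs$gamma * tv_grad(g)
    gb <- generator_bwd(bundle$G, gfwd$cache, gout)
    gG <- if (is.null(gG)) gb$gp else tree_add(gG, gb$gp)
    acc <- acc + c(l_h, l_a, tv(g), coeffs$lambda_ * l_h + coeffs$mu * l_s,
                   l_s)
  }
  upd <- adam_step(bundle$G$params, tree_scale(gG, 1 / n), bundle$opt_g)
  bundle$G$params <- upd$params; bundle$opt_g <- upd$opt
  if (!is.null(gR)) {
    upd <- adam_step(bundle$R$params, tree_scale(gR, 1 / n), bundle$opt_r)
    bundle$R$params <- upd$params; bundle$opt_r <- upd$opt
  }
  list(bundle = bundle, losses = acc / n)
}

d_update <- function(bundle, batch, coeffs) {
  n <- length(batch)
  gD <- NULL
  loss <- 0
  for (s in batch) {
    dsm <- make_dsm(s$stain_class, dim(s$af)[1], dim(s$af)[2])
    g <- generator_fwd(bundle$G, gen_input(s$af, dsm))$y
    dm <- as_tensor(dsm$matrix)
    fake <- discriminator_fwd(bundle$D, cat_ch(g, dm))
    real <- discriminator_fwd(bundle$D, cat_ch(s$target, dm))
    loss <- loss + discriminator_loss(fake$score, real$score)
    bf <- discriminator_bwd(bundle$D, fake$cache,
                            bce_logit_grad(fake$score, 0))
    br <- discriminator_bwd(bundle$D, real$cache,
                            bce_logit_grad(real$score, 1))
    gi <- tree_add(bf$gp, br$gp)
    gD <- if (is.null(gD)) gi else tree_add(gD, gi)
  }
  upd <- adam_step(bundle$D$params, tree_scale(gD, 1 / n), bundle$opt_d)
  bundle$D$params <- upd$params; bundle$opt_d <- upd$opt
  list(bundle = bundle, loss = loss / n)
}

#' One scheduled training unit
#'
#' Four generator updates (each carrying a registration-module update on
#' its own parameters) followed by one discriminator update, each on its
#' own balanced batch. Each loss's gradients touch only its own network's
#' parameters. Aborts with a diagnostic snapshot on non-finite losses.
#'
#' @param bundle A [init_bundle()] result.
#' @param batches List of `g_updates_per_d_update + 1` batches (lists of
#'   [multiplex_sample()]).
#' @param coeffs A [loss_coefficients()].
#' @return List with the updated `bundle` and a `records` data frame of
#'   per-update component losses.
#' @export
train_step <- function(bundle, batches, coeffs = loss_coefficients()) {
  sched <- bundle$config$g_updates_per_d_update
  stopifnot(length(batches) == sched + 1L)
  records <- vector("list", sched + 1L)
  for (i in seq_len(sched)) {
    r <- g_and_r_update(bundle, batches[[i]], coeffs)
    bundle <- r$bundle
    check_finite_losses(r$losses, bundle$step, batches[[i]])
    records[[i]] <- data.frame(step = bundle$step + i, kind = "G",
                               stain = paste(vapply(batches[[i]],
                                 `[[`, "", "stain_class"), collapse = "/"),
                               l_huber = r$losses[["huber"]],
                               l_adv = r$losses[["adv"]],
                               l_tv = r$losses[["tv"]],
                               l_reg = r$losses[["reg"]],
                               l_smth = r$losses[["smth"]],
                               l_disc = NA_real_)
  }
  rd <- d_update(bundle, batches[[sched + 1L]], coeffs)
  bundle <- rd$bundle
  check_finite_losses(c(disc = rd$loss), bundle$step, batches[[sched + 1L]])
  records[[sched + 1L]] <- data.frame(step = bundle$step + sched,
                                      kind = "D", stain = "",
                                      l_huber = NA_real_, l_adv = NA_real_,
                                      l_tv = NA_real_, l_reg = NA_real_,
                                      l_smth = NA_real_, l_disc = rd$loss)
  bundle$step <- bundle$step + sched
  list(bundle = bundle, records = do.call(rbind, records))
}

check_finite_losses <- function(losses, step, batch) {
  if (all(is.finite(losses))) return(invisible())
  stop("non-finite loss at step ", step, " (stains ",
       paste(vapply(batch, `[[`, "", "stain_class"), collapse = "/"),
       "): ", paste(names(losses), signif(losses, 4), collapse = ", "),
       call. = FALSE)
}

#' Train the virtual multiplexed staining model
#'
#' Mixes the per-stain datasets with equal probability, applies dihedral
#' augmentation, and alternates generator/registration and discriminator
#' updates on the 4:1 schedule until `config$steps` generator updates have
#' run. Fully reproducible under `(config, seed)` on one device; the batch
#' plan and per-sample augmentations are derived deterministically from
#' the master seed, so resuming from a checkpoint continues the identical
#' trajectory.
#'
#' @param data List of [multiplex_sample()] objects, or a dataset
#'   directory written by [write_dataset()].
#' @param config A [train_config()].
#' @param out_dir Optional directory for checkpoints, the loss log and the
#'   serialized config.
#' @param bundle Optional bundle to resume from (e.g. [load_checkpoint()]).
#' @param quiet Suppress progress messages.
#' @return A `vmihc_model`: the trained bundle plus the loss log.
#' @export
vmihc_train <- function(data, config = train_config("tiny"), out_dir = NULL,
                        bundle = NULL, quiet = TRUE) {
  samples <- if (is.character(data)) read_dataset(data) else data
  stopifnot(length(samples) > 0)
  per_stain <- split(samples, vapply(samples, `[[`, "", "stain_class"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(c(paste0("# virtmihc ",
                        as.character(utils::packageVersion("virtmihc"))),
                 paste(names(unclass(config))[1:10], "=",
                       vapply(unclass(config)[1:10], function(v)
                         paste(format(v), collapse = ","), ""))),
               file.path(out_dir, "run_config.txt"))
  }
  if (is.null(bundle)) bundle <- init_bundle(config)
  seeds <- seed_all(config$seed)
  sched <- config$g_updates_per_d_update
  n_units <- ceiling(config$steps / sched)
  # the whole batch plan is a pure function of the seed: resume-safe
  plan <- balanced_batches(per_stain, config$batch_size,
                           n_units * (sched + 1L), seed = seeds[["sampler"]])
  logs <- list()
  unit0 <- bundle$step %/% sched
  for (u in seq_len(n_units)) {
    if (u <= unit0) next   # resuming: earlier units already consumed
    bx <- lapply(seq_len(sched + 1L), function(i) {
      pb <- plan[[(u - 1L) * (sched + 1L) + i]]
      lapply(seq_len(nrow(pb)), function(j) {
        s <- per_stain[[pb$stain[j]]][[pb$idx[j]]]
        augment(s, seed = derive_seed(seeds[["augment"]],
                                      paste(u, i, j, sep = "_")))
      })
    })
    r <- train_step(bundle, bx, config$coefficients)
    bundle <- r$bundle
    logs[[length(logs) + 1L]] <- r$records
    if (!quiet && u %% 10L == 0L)
      message("unit ", u, "/", n_units, " huber=",
              signif(mean(r$records$l_huber, na.rm = TRUE), 4))
    if (!is.null(out_dir) && (bundle$step %% config$checkpoint_every < sched))
      save_checkpoint(bundle, file.path(out_dir,
                                        sprintf("ckpt_%06d.rds", bundle$step)))
  }
  log <- if (length(logs)) do.call(rbind, logs) else NULL
  if (!is.null(out_dir)) {
    save_checkpoint(bundle, file.path(out_dir, "ckpt_final.rds"))
    if (!is.null(log))
      write.csv(log, file.path(out_dir, "loss_log.csv"), row.names = FALSE)
  }
  structure(list(bundle = bundle, config = config, log = log,
                 n_samples = length(samples),
                 stains = names(per_stain)), class = "vmihc_model")
}

#' Save / load a model checkpoint
#'
#' Stores all three networks' parameters, optimizer states, step counter
#' and the config that built them; loading validates that the stored
#' config rebuilds the same architecture. Round-trips restore bit-identical
#' forward outputs.
#'
#' @param bundle A `model_bundle` (or `vmihc_model`).
#' @param path File path (`.rds`).
#' @export
save_checkpoint <- function(bundle, path) {
  if (inherits(bundle, "vmihc_model")) bundle <- bundle$bundle
  stopifnot(inherits(bundle, "model_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: the restored `model_bundle`.
#' @export
load_checkpoint <- function(path) {
  bundle <- readRDS(path)
  if (!inherits(bundle, "model_bundle"))
    stop("not a virtmihc checkpoint: ", path, call. = FALSE)
  cfg <- bundle$config
  ref <- with_seed(1L, build_generator(cfg$base_width_g, depth = cfg$depth_g,
                                       activation = cfg$activation))
  if (length(tree_unlist(ref$params)) !=
      length(tree_unlist(bundle$G$params)))
    stop("checkpoint architecture does not match its stored config",
         call. = FALSE)
  bundle
}

#' @export
print.vmihc_model <- function(x, ...) {
  cat("<vmihc_model> trained", x$bundle$step, "generator steps on",
      x$n_samples, "samples (", paste(x$stains, collapse = ", "), ")\n")
  invisible(x)
}

#' @export
summary.vmihc_model <- function(object, ...) {
  log <- object$log
  cat("Virtual multiplexed staining model\n")
  print(object$bundle)
  if (!is.null(log)) {
    g <- log[log$kind == "G", ]
    half <- g[g$step > max(g$step) / 2, ]
    cat(sprintf("final-half mean losses: huber %.4g | adv %.4g | tv %.4g | reg %.4g\n",
                mean(half$l_huber), mean(half$l_adv), mean(half$l_tv),
                mean(half$l_reg)))
  }
  invisible(object)
}

#' @export
plot.vmihc_model <- function(x, ...) {
  log <- x$log
  if (is.null(log)) stop("no training log to plot", call. = FALSE)
  g <- log[log$kind == "G", ]
  graphics::plot(g$step, g$l_huber, type = "l", log = "y",
                 xlab = "generator step", ylab = "loss",
                 main = "training losses", ...)
  graphics::lines(g$step, g$l_reg / 20, col = "steelblue")
  graphics::legend("topright", c("huber", "reg/20"),
                   col = c("black", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}
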