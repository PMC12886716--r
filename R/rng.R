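#' Derive independent sub-seeds from one master seed
#'
#' Every stochastic component (phantom generation, batch sampling,
#' augmentation, weight initialisation, noise) draws from its own named
#' substream so that consuming randomness in one component never shifts
#' another. Substreams are derived deterministically from the master seed
#' and the component name, keeping all derived seeds below 2^31.
#'
#' @param seed Integer master seed.
#' @param components Character vector of substream names.
#' @return Named integer vector of sub-seeds.
#' @examples
#' seed_all(1, c("phantom", "sampler"))
#' @export
seed_all <- function(seed,
                     components = c("phantom", "sampler", "augment",
                                    "init", "noise", "misalign")) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  seed <- as.integer(seed)
  out <- vapply(components, function(nm) derive_seed(seed, nm), integer(1))
  names(out) <- components
  out
}

#' Derive one named sub-seed
#'
#' Deterministic `(seed, name) -> sub-seed` in `[0, 2^31 - 2]`: a small
#' string hash folded with the master seed. Not cryptographic, just
#' stable — the primitive behind [seed_all()].
#'
#' @param seed Integer master seed.
#' @param name Substream name.
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, name) {
  h <- 5381
  for (k in utf8ToInt(name)) h <- (h * 33 + k) %% 2147483647
  as.integer((h + as.double(seed) * 48271) %% 2147483647)
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so
#' library internals never perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
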