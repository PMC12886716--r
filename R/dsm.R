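#' Construct a digital staining matrix (DSM)
#'
#' The DSM is the conditioning channel concatenated with the AF input: a
#' spatially constant matrix whose value encodes the requested stain,
#' 2 for H&E, 1 for PanCK and -1 for ERG. Codes are fed to the networks
#' raw, not normalised.
#'
#' @param stain_class One of `"he"` (aliases `"h-and-e"`, `"h&e"`),
#'   `"panck"`, `"erg"`.
#' @param height,width Spatial dimensions, matching the paired AF image.
#' @return Object of class `dsm` with fields `matrix`, `code`,
#'   `stain_class`.
#' @examples
#' make_dsm("he", 8, 8)$code        # 2
#' make_dsm("erg", 8, 8)$code       # -1
#' @export
make_dsm <- function(stain_class, height, width) {
  stain_class <- check_stain(stain_class)
  code <- DSM_CODES[[stain_class]]
  structure(list(matrix = matrix(code, height, width), code = code,
                 stain_class = stain_class), class = "dsm")
}

#' @export
print.dsm <- function(x, ...) {
  cat("<dsm>", x$stain_class, "code", x$code, "dims",
      paste(dim(x$matrix), collapse = "x"), "\n")
  invisible(x)
}

#' Map a DSM code back to its stain class
#' @param code One of -1, 1, 2.
#' @return Stain class string.
#' @export
stain_for_code <- function(code) {
  i <- match(code, DSM_CODES)
  if (is.na(i)) stop("unknown DSM code ", code, "; valid codes: ",
                     paste(DSM_CODES, collapse = ", "), call. = FALSE)
  STAIN_CLASSES[i]
}

# generator input tensor: AF channels + DSM channel
gen_input <- function(af, dsm) {
  m <- if (inherits(dsm, "dsm")) dsm$matrix else dsm
  cat_ch(as_tensor(af), as_tensor(m))
}
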