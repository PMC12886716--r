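# Readers/writers and the dataset manifest. Images are stored as 16-bit
# TIFF (AF, targets) and 8-bit PNG (masks); 16-bit values round-trip
# exactly on the k/65535 grid, so writers snap to that grid and return the
# snapped array.

MANIFEST_HEADER <- "# virtmihc manifest v1; af_channels=DAPI,FITC,TxRed,Cy5"

snap16 <- function(x) round(x * 65535) / 65535

#' Read / write a 4-channel AF tile as TIFF
#'
#' Channel order DAPI, FITC, TxRed, Cy5 (declared in the dataset
#' manifest header; images carry no trusted metadata). Written as 16-bit
#' TIFF: values are snapped to the 16-bit grid on write (the snapped array
#' is returned invisibly) and scaled back to `[0, 1]` on read, so a
#' write/read round-trip is exact.
#'
#' @param path File path.
#' @return `read_af_tiff`: AF array `c(H, W, 4)` in `[0, 1]`.
#' @export
read_af_tiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(x)) != 3L || dim(x)[3] != 4L)
    stop("expected a 4-channel AF tile (DAPI, FITC, TxRed, Cy5); got ",
         paste(dim(x), collapse = "x"), " in ", path, call. = FALSE)
  x
}

#' @rdname read_af_tiff
#' @param image AF array `c(H, W, 4)` in `[0, 1]`.
#' @export
write_af_tiff <- function(image, path) {
  image <- as_tensor(image)
  stopifnot(dim(image)[3] == 4L, min(image) >= 0, max(image) <= 1)
  image <- snap16(image)
  tiff::writeTIFF(image, path, bits.per.sample = 16L, compression = "none")
  invisible(image)
}

write_rgb <- function(image, path) {
  image <- snap16(image)
  tiff::writeTIFF(image, path, bits.per.sample = 16L, compression = "none")
  invisible(image)
}

read_rgb <- function(path) {
  x <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("expected an RGB image in ", path, call. = FALSE)
  x
}

write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(mask)
}

read_mask_png <- function(path) png::readPNG(path) > 0.5

#' Write a dataset of multiplex samples to disk
#'
#' AF tiles as 4-channel 16-bit TIFF, targets as 16-bit RGB TIFF, phantom
#' masks (when supplied) as 8-bit PNG, plus a delimited manifest declaring
#' tile id, stain class, DSM code, file paths and seed. Round-trips
#' losslessly through [read_dataset()] (images are snapped to the 16-bit
#' grid at write time).
#'
#' @param samples List of [multiplex_sample()] objects.
#' @param directory Output directory (created if missing).
#' @param phantoms Optional list of phantoms (one per unique tile) whose
#'   endothelial/epithelial masks are written alongside.
#' @param seed Seed recorded in the manifest.
#' @return Path of the manifest file, invisibly.
#' @export
write_dataset <- function(samples, directory, phantoms = NULL, seed = NA) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    id <- if (is.null(s$id)) sprintf("sample%04d", i) else s$id
    af_path <- file.path(directory, paste0(id, "_af.tif"))
    tg_path <- file.path(directory, paste0(id, "_", s$stain_class, ".tif"))
    write_af_tiff(s$af, af_path)
    write_rgb(s$target, tg_path)
    rows[[i]] <- data.frame(id = id, stain = s$stain_class,
                            dsm_code = s$dsm_code,
                            af_path = basename(af_path),
                            target_path = basename(tg_path),
                            seed = seed, stringsAsFactors = FALSE)
  }
  if (!is.null(phantoms)) {
    for (j in seq_along(phantoms)) {
      ph <- phantoms[[j]]
      write_mask_png(ph$endothelial_nuclei_mask,
                     file.path(directory, sprintf("tile%03d_endo_mask.png", j)))
      write_mask_png(ph$epithelial_mask,
                     file.path(directory, sprintf("tile%03d_epi_mask.png", j)))
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(directory, "manifest.csv")
  con <- file(mpath, "w")
  writeLines(MANIFEST_HEADER, con)
  write.csv(manifest, con, row.names = FALSE)
  close(con)
  invisible(mpath)
}

#' Load and validate a dataset manifest
#'
#' @param path Manifest file (or its directory).
#' @return A `manifest` data frame with attribute `directory`.
#' @export
load_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  if (!file.exists(path)) stop("no manifest at ", path, call. = FALSE)
  m <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "stain", "dsm_code", "af_path", "target_path")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  attr(m, "directory") <- dirname(path)
  class(m) <- c("vmihc_manifest", class(m))
  m
}

#' @rdname load_manifest
#' @param manifest A loaded manifest.
#' @return `validate_manifest`: data frame of flagged problems (zero rows
#'   when clean).
#' @export
validate_manifest <- function(manifest) {
  dirn <- attr(manifest, "directory")
  problems <- list()
  flag <- function(row, what) problems[[length(problems) + 1L]] <<-
    data.frame(row = row, problem = what, stringsAsFactors = FALSE)
  if (nrow(manifest) == 0) {
    warning("manifest has zero rows")
    return(data.frame(row = integer(), problem = character()))
  }
  dup <- duplicated(paste(manifest$id, manifest$stain))
  for (i in which(dup)) flag(i, "duplicate id/stain")
  for (i in seq_len(nrow(manifest))) {
    st <- tryCatch(check_stain(manifest$stain[i]), error = function(e) NA)
    if (is.na(st)) { flag(i, "unknown stain class"); next }
    if (DSM_CODES[[st]] != manifest$dsm_code[i])
      flag(i, sprintf("stain/dsm conflict: %s should code %d", st,
                      DSM_CODES[[st]]))
    for (col in c("af_path", "target_path"))
      if (!file.exists(file.path(dirn, manifest[[col]][i])))
        flag(i, paste("missing file:", manifest[[col]][i]))
  }
  if (length(problems)) do.call(rbind, problems)
  else data.frame(row = integer(), problem = character())
}

#' Read a dataset written by [write_dataset()]
#'
#' @param directory Dataset directory containing `manifest.csv`.
#' @return List of [multiplex_sample()] objects.
#' @export
read_dataset <- function(directory) {
  m <- load_manifest(directory)
  v <- validate_manifest(m)
  if (nrow(v)) stop("invalid dataset: ",
                    paste(unique(v$problem), collapse = "; "), call. = FALSE)
  lapply(seq_len(nrow(m)), function(i) {
    multiplex_sample(read_af_tiff(file.path(directory, m$af_path[i])),
                     m$stain[i],
                     read_rgb(file.path(directory, m$target_path[i])),
                     id = m$id[i])
  })
}
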