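# Serialization: images as 8-bit PNG (scaled x255) or exact CSV of flattened
# floats; Hopfield stores as CSV plus a JSON sidecar; factors and corpora as
# JSON/CSV. All formats are plain text or standard PNG so fixtures are
# portable.

#' Write an image as PNG
#'
#' Values are scaled by 255 to 8-bit depth; exact round trips should use
#' [write_image_csv()].
#'
#' @param image H x W x C array in `[0, 1]`.
#' @param path Output file path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clip01(image), target = path)
  invisible(path)
}

#' Read a PNG image
#'
#' @param path PNG file path.
#' @return An H x W x C array in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  img
}

#' Write an image as CSV of flattened floats (exact)
#'
#' One row; a `# dim: H W C` comment records the shape.
#'
#' @param image Image array.
#' @param path Output file path.
#' @export
write_image_csv <- function(image, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dim: %s", paste(dim(image), collapse = " ")), con)
  writeLines(paste(format(flatten_image(image), digits = 17),
                   collapse = ","), con)
  invisible(path)
}

#' Read an image written by [write_image_csv()]
#'
#' @param path CSV file path.
#' @return The image array, bit-exact.
#' @export
read_image_csv <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(sub("# dim: ", "", lines[1]), " ")[[1]])
  unflatten_image(as.numeric(strsplit(lines[2], ",")[[1]]), dims)
}

#' Write a Hopfield store to CSV + JSON sidecar
#'
#' @param store A [hopfield_store()].
#' @param path Base path; writes `<path>.csv` (patterns) and `<path>.json`
#'   (beta, value range, dimensions).
#' @export
write_hopfield_store <- function(store, path) {
  utils::write.table(store$patterns, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(beta = store$beta,
                            value_range = store$value_range,
                            m = nrow(store$patterns),
                            d = ncol(store$patterns)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Hopfield store written by [write_hopfield_store()]
#'
#' @param path Base path used when writing.
#' @return A [hopfield_store()].
#' @export
read_hopfield_store <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  patterns <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(patterns) <- NULL
  hopfield_store(patterns, beta = meta$beta,
                 value_range = unlist(meta$value_range))
}

#' Write corpus word counts as CSV with a vocabulary header
#'
#' @param corpus A `corpus`.
#' @param path Output file path.
#' @export
write_corpus_csv <- function(corpus, path) {
  m <- corpus$counts
  colnames(m) <- corpus$vocabulary
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Write scene factors as JSON
#'
#' @param factors A [scene_factors()] or list of them.
#' @param path Output file path.
#' @export
write_factors_json <- function(factors, path) {
  if (inherits(factors, "scene_factors")) factors <- list(factors)
  jsonlite::write_json(lapply(factors, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read scene factors written by [write_factors_json()]
#'
#' @param path JSON file path.
#' @return A list of [scene_factors()].
#' @export
read_factors_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(f) do.call(scene_factors, f))
}
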