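# Plain-text interchange formats. All intermediate artifacts are text so
# that a full analysis can be archived, diffed and re-run.

#' Write chain codes to a plain-text file
#'
#' One record per spore: a header line
#' `id width height start_row start_col n_moves` (0-based start pixel)
#' followed by one line holding the Freeman direction digits. The format
#' round-trips bit-exactly through [read_chain_codes()].
#'
#' @param chains List of `chain_code` objects (names used as ids).
#' @param path Output file.
#' @param scale_um_per_px Optional scale recorded as a `# scale=` comment.
#' @return Invisibly, `path`.
#' @export
write_chain_codes <- function(chains, path, scale_um_per_px = NULL) {
  if (is.null(names(chains)))
    names(chains) <- sprintf("chain%03d", seq_along(chains))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(scale_um_per_px))
    writeLines(sprintf("# scale=%.17g", scale_um_per_px), con)
  for (id in names(chains)) {
    ch <- chains[[id]]
    stopifnot(inherits(ch, "chain_code"))
    writeLines(sprintf("%s %d %d %d %d %d", id,
                       ch$dims[2L], ch$dims[1L],
                       ch$start[1L] - 1L, ch$start[2L] - 1L,
                       length(ch$directions)), con)
    writeLines(paste(ch$directions, collapse = ""), con)
  }
  invisible(path)
}

#' Read chain codes written by [write_chain_codes()]
#'
#' @param path Input file.
#' @return Named list of `chain_code` objects; a recorded scale is
#'   attached to each.
#' @export
read_chain_codes <- function(path) {
  lines <- readLines(path)
  scale <- NA_real_
  if (length(lines) && startsWith(lines[1L], "# scale=")) {
    scale <- as.numeric(sub("# scale=", "", lines[1L], fixed = TRUE))
    lines <- lines[-1L]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 2L != 0L) stop("malformed chain-code file")
  out <- list()
  for (i in seq(1L, length(lines), by = 2L)) {
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1L]]
    if (length(hdr) != 6L) stop("malformed chain-code header: ", lines[i])
    dirs <- as.integer(strsplit(lines[i + 1L], "")[[1L]])
    if (length(dirs) != as.integer(hdr[6L]) || any(dirs < 0L | dirs > 7L))
      stop("malformed chain-code record: ", hdr[1L])
    ch <- new_chain_code(start = as.integer(hdr[4:5]) + 1L, directions = dirs,
                         dims = as.integer(hdr[c(3L, 2L)]))
    ch$scale_um_per_px <- scale
    out[[hdr[1L]]] <- ch
  }
  out
}

#' Write normalized descriptors to a single text file
#'
#' Header line `n_harmonics=K`; then one line per spore: spore id, image
#' id, and the 4K coefficients in storage order (a_n b_n c_n d_n per
#' harmonic, harmonics ascending), followed by the size scalar.
#'
#' @param nefds Named list of `spore_nefd` (names = spore ids).
#' @param path Output file.
#' @param image_ids Character vector mapping spore id to image id
#'   (recycled "NA" if missing).
#' @return Invisibly, `path`.
#' @export
write_nefd_file <- function(nefds, path, image_ids = NULL) {
  stopifnot(length(nefds) >= 1L)
  H <- unique(vapply(nefds, function(n) n$n_harmonics, 0L))
  if (length(H) != 1L) stop("descriptor sets have differing harmonic counts")
  if (is.null(image_ids)) image_ids <- rep("NA", length(nefds))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("n_harmonics=%d", H), con)
  for (i in seq_along(nefds)) {
    cf <- t(nefds[[i]]$coeffs)          # column-major over (a,b,c,d) quadruples
    writeLines(paste(names(nefds)[i], image_ids[i],
                     paste(sprintf("%.17g", c(cf, nefds[[i]]$size_scalar)),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Read a descriptor file written by [write_nefd_file()]
#'
#' @param path Input file.
#' @return List with `nefds` (named list of `spore_nefd`) and `image_ids`.
#' @export
read_nefd_file <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "n_harmonics="))
    stop("malformed descriptor file: missing n_harmonics header")
  H <- as.integer(sub("n_harmonics=", "", lines[1L], fixed = TRUE))
  lines <- lines[-1L][nzchar(lines[-1L])]
  nefds <- list(); image_ids <- character(0L)
  for (ln in lines) {
    parts <- strsplit(ln, " ", fixed = TRUE)[[1L]]
    if (length(parts) != 2L + 4L * H + 1L)
      stop("malformed descriptor record: ", parts[1L])
    vals <- as.numeric(parts[-(1:2)])
    cf <- matrix(vals[seq_len(4L * H)], ncol = 4L, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
    nefds[[parts[1L]]] <- structure(
      list(n_harmonics = H, coeffs = cf, size_scalar = vals[4L * H + 1L],
           theta = NA_real_, psi = NA_real_, flipped = NA),
      class = "spore_nefd")
    image_ids <- c(image_ids, parts[2L])
  }
  names(image_ids) <- names(nefds)
  list(nefds = nefds, image_ids = image_ids)
}

#' Read a grayscale image file
#'
#' Reads PNG (or TIFF when the tiff package is installed) as a numeric
#' matrix in \[0, 1\]; RGB images are averaged to one channel.
#'
#' @param path Image file (.png, .tif/.tiff).
#' @return Numeric matrix, row 1 = top of the image.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the tiff package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext))
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:3, drop = FALSE], c(1L, 2L), mean)
  arr
}

#' Write a binary image as PNG
#'
#' @param img A [binary_image()].
#' @param path Output .png path.
#' @return Invisibly, `path`.
#' @export
write_binary_image <- function(img, path) {
  stopifnot(inherits(img, "binary_image"))
  png::writePNG(matrix(as.double(img$pixels), nrow(img$pixels)), path)
  invisible(path)
}

#' Read a binary image from a PNG/TIFF file
#'
#' Pixels above 0.5 become foreground.
#'
#' @param path Image file.
#' @param scale_um_per_px Spatial scale to attach.
#' @return A [binary_image()].
#' @export
read_binary_image <- function(path, scale_um_per_px) {
  gray <- read_gray_image(path)
  binary_image(matrix(as.integer(gray > 0.5), nrow(gray), ncol(gray)),
               scale_um_per_px)
}
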