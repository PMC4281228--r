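## File formats: multi-page float TIFF for field images (page order declared
## in a JSON sidecar), 16-bit TIFF for label matrices, CSV feature tables.

#' Write a field image as multi-page TIFF with a JSON sidecar
#'
#' Pages are channels (2-D fields) or, for a single z-stack channel, z
#' planes. TIFF stores normalized unsigned intensities, so pages are
#' min/max-normalized to `[0, 1]` at 32 bits and the sidecar records the
#' original range along with the channel order, pixel size and grid
#' position.
#'
#' @param field A [field_image()].
#' @param path Output `.tif` path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "FieldImage"))
  lo <- min(vapply(field$channels, min, numeric(1)))
  hi <- max(vapply(field$channels, max, numeric(1)))
  if (hi <= lo) hi <- lo + 1
  pages <- list(); order <- character(0)
  for (nm in names(field$channels)) {
    ch <- (field$channels[[nm]] - lo) / (hi - lo)
    if (length(dim(ch)) == 3) {
      for (z in seq_len(dim(ch)[3])) {
        pages[[length(pages) + 1]] <- ch[, , z]
        order <- c(order, sprintf("%s:z%d", nm, z - 1))
      }
    } else {
      pages[[length(pages) + 1]] <- ch
      order <- c(order, nm)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  side <- list(pages = order, fx = field$fx, fy = field$fy,
               pixel_size_um = field$pixel_size, lo = lo, hi = hi)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a field image written by [write_field_tiff()]
#'
#' @param path Path to the `.tif` file (sidecar at `<path>.json`).
#' @return A [field_image()].
#' @export
read_field_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  names(pages) <- side$pages
  chn <- sub(":z[0-9]+$", "", side$pages)
  unscale <- function(m) m * (side$hi - side$lo) + side$lo
  channels <- list()
  for (nm in unique(chn)) {
    idx <- which(chn == nm)
    if (length(idx) == 1 && !grepl(":z", side$pages[idx])) {
      channels[[nm]] <- unscale(pages[[idx]])
    } else {
      d <- dim(pages[[idx[1]]])
      arr <- array(0, c(d[1], d[2], length(idx)))
      for (j in seq_along(idx)) arr[, , j] <- unscale(pages[[idx[j]]])
      channels[[nm]] <- arr
    }
  }
  field_image(channels, side$fx, side$fy, side$pixel_size_um)
}

#' Write a label matrix as 16-bit single-page TIFF
#'
#' @param labels Integer label matrix (max label 65535).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16, reduce = FALSE)
  invisible(path)
}

#' Read a label matrix written by [write_label_tiff()]
#' @param path Path to the TIFF.
#' @return Integer label matrix.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
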