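# File interchange: TIFF images/stacks, JSON ROI and ground-truth sidecars,
# CSV profiles. External annotation coordinates are 0-based with y down
# (image-convention JSON); internally everything is 1-based pixel centers.

#' Read a grayscale TIFF image or stack
#'
#' @param path TIFF file.
#' @return a numeric matrix (single page) or 3D array (y, x, page).
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (length(pages) == 1L) return(pages[[1L]])
  array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
}

#' Write a grayscale image or stack as 32-bit float TIFF
#'
#' @param image matrix or 3D array (y, x, t).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  if (length(dim(image)) == 3L) {
    pages <- lapply(seq_len(dim(image)[3L]), function(t) image[, , t])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    tiff::writeTIFF(image, path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}

#' Read a contour / polyline ROI from JSON
#'
#' Accepts `[[x, y], ...]` vertex lists in 0-based image coordinates
#' (y down) and converts to the package's 1-based convention.
#'
#' @param path JSON file.
#' @return an n x 2 matrix with columns `x`, `y`.
#' @export
read_roi_json <- function(path) {
  v <- jsonlite::fromJSON(path)
  m <- if (is.matrix(v)) v else do.call(rbind, v)
  if (ncol(m) != 2L) stop("ROI JSON must be a list of [x, y] pairs",
                          call. = FALSE)
  cbind(x = m[, 1] + 1, y = m[, 2] + 1)
}

#' Write a contour / polyline ROI to JSON (0-based coordinates)
#'
#' @param points n x 2 matrix of 1-based (x, y) points.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(points, path) {
  m <- unname(as.matrix(points)) - 1
  jsonlite::write_json(m, path, digits = NA)
  invisible(path)
}

#' Write a synthetic embryo as TIFF plus JSON sidecar
#'
#' The image (or stack) goes to `<stem>.tif`; the ground truth, contour
#' (0-based) and annotations to `<stem>.json`.
#'
#' @param embryo a [synthetic_embryo()].
#' @param stem output path without extension.
#' @return the two paths, invisibly.
#' @export
write_embryo <- function(embryo, stem) {
  stopifnot(inherits(embryo, "synthetic_embryo"))
  tif <- paste0(stem, ".tif"); js <- paste0(stem, ".json")
  write_image_tiff(embryo$image, tif)
  side <- list(truth = unclass(embryo$truth),
               contour = if (is.null(embryo$contour)) NULL else
                 unname(as.matrix(embryo$contour)) - 1,
               annotations = embryo$annotations,
               meta = embryo$meta)
  jsonlite::write_json(side, js, digits = NA, auto_unbox = TRUE,
                       null = "null", force = TRUE)
  invisible(c(tif = tif, json = js))
}

#' Write a membrane profile to CSV
#'
#' Columns: `x`, `membrane`, `cytoplasm`, `background`, `normalized`.
#'
#' @param profile a [membrane_profile()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Read a membrane profile from CSV
#'
#' @param path CSV written by [write_profile_csv()].
#' @return a [membrane_profile()].
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  norm <- if ("normalized" %in% names(df) && !all(is.na(df$normalized))) {
    df$normalized
  } else {
    NULL
  }
  membrane_profile(df$x, df$membrane, df$cytoplasm, df$background, norm)
}
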