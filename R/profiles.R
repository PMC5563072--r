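#' Membrane intensity profile
#'
#' A 1D intensity trace along the cell perimeter with local cytoplasm and
#' background context: `x` is normalized arclength in `[0, 1)` (circular),
#' `membrane` the raw membrane signal, `cytoplasm` and `background` local
#' level estimates at each position, and `normalized` the
#' cytoplasm-normalized signal once [normalize_profile()] has been applied.
#'
#' @param x strictly increasing positions in `[0, 1)`.
#' @param membrane,cytoplasm,background numeric vectors, same length as `x`.
#' @param normalized optional normalized signal.
#' @return an object of class `membrane_profile`.
#' @export
membrane_profile <- function(x, membrane, cytoplasm = NULL, background = NULL,
                             normalized = NULL) {
  n <- length(x)
  if (is.null(cytoplasm)) cytoplasm <- rep(NA_real_, n)
  if (is.null(background)) background <- rep(NA_real_, n)
  if (length(membrane) != n || length(cytoplasm) != n ||
      length(background) != n) {
    stop("profile arrays must have equal length", call. = FALSE)
  }
  if (n > 1 && any(diff(x) <= 0)) {
    stop("x must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(membrane))) {
    stop("membrane signal must be finite", call. = FALSE)
  }
  structure(list(x = x, membrane = membrane, cytoplasm = cytoplasm,
                 background = background, normalized = normalized),
            class = "membrane_profile")
}

#' @export
print.membrane_profile <- function(x, ...) {
  cat(sprintf(
    "<membrane_profile> %d samples, membrane %.3g..%.3g%s%s\n",
    length(x$x), min(x$membrane), max(x$membrane),
    if (!is.null(x$normalized)) ", normalized" else "",
    if (isTRUE(attr(x, "aligned"))) ", aligned" else ""))
  invisible(x)
}

#' @export
as.data.frame.membrane_profile <- function(x, ...) {
  data.frame(x = x$x, membrane = x$membrane, cytoplasm = x$cytoplasm,
             background = x$background,
             normalized = if (is.null(x$normalized)) NA_real_ else
               x$normalized)
}

#' Extract and straighten a membrane stripe from a midsection image
#'
#' For each of ~perimeter-in-pixels arclength samples along the (closed)
#' contour, samples the image by bilinear interpolation along the local
#' inward normal at `width` depth positions centered on the contour,
#' producing a straightened arclength-by-depth stripe. Depth runs outside
#' to inside: column 1 is the most exterior sample, column `width` the most
#' interior.
#'
#' @param image numeric matrix (y by x).
#' @param contour n x 2 matrix of (x, y) perimeter points tracing the
#'   membrane, implicitly closed, at least `width/2` pixels from the image
#'   border.
#' @param width stripe depth in pixels (default 60).
#' @param n_arclength number of arclength rows; defaults to the contour
#'   perimeter rounded to whole pixels.
#' @return an object of class `membrane_stripe` with fields `pixels`
#'   (arclength x depth matrix), `arclength_px` (pixels per row),
#'   `contour` (the resampled contour) and `depth_order` (`"outside_in"`).
#' @export
extract_stripe <- function(image, contour, width = 60L, n_arclength = NULL) {
  contour <- as.matrix(contour)
  perim <- contour_perimeter(contour)
  if (is.null(n_arclength)) n_arclength <- max(16L, round(perim))
  pts <- resample_contour(contour, n_arclength)
  nrm <- contour_inward_normals(pts)
  offsets <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = width)
  sx <- outer(pts[, 1], offsets, function(p, o) p) +
    outer(nrm[, 1], offsets)
  sy <- outer(pts[, 2], offsets, function(p, o) p) +
    outer(nrm[, 2], offsets)
  bad <- sx < 1 | sx > ncol(image) | sy < 1 | sy > nrow(image)
  if (any(bad)) {
    i <- which(rowSums(bad) > 0)[1L]
    stop(sprintf(
      "contour too close to the image border: stripe of width %d leaves the image near contour point %d (x=%.1f, y=%.1f)",
      width, i, pts[i, 1], pts[i, 2]), call. = FALSE)
  }
  px <- matrix(bilinear_sample(image, as.vector(sx), as.vector(sy)),
               nrow = n_arclength, ncol = width)
  structure(list(pixels = px, arclength_px = perim / n_arclength,
                 contour = pts, depth_order = "outside_in", width = width),
            class = "membrane_stripe")
}

#' @export
print.membrane_stripe <- function(x, ...) {
  cat(sprintf("<membrane_stripe> %d arclength x %d depth, %.3g px/row\n",
              nrow(x$pixels), ncol(x$pixels), x$arclength_px))
  invisible(x)
}

#' Collapse a membrane stripe to a membrane profile
#'
#' At each arclength position, the membrane signal is the mean of the
#' `top_k` brightest pixels within the central depth band of the stripe
#' (default: central third). Local background and cytoplasm are the means
#' of the outermost and innermost edge bands (default: one sixth of the
#' depth each).
#'
#' @param stripe a [membrane_stripe()].
#' @param top_k number of brightest central pixels to average (default 4).
#' @param central_frac fraction of the depth forming the central membrane
#'   band.
#' @param edge_frac fraction of the depth forming each edge band.
#' @return a [membrane_profile()]; a constant (degenerate) stripe yields a
#'   profile flagged with attribute `"degenerate"` rather than an error.
#' @export
membrane_from_stripe <- function(stripe, top_k = 4L, central_frac = 1 / 3,
                                 edge_frac = 1 / 6) {
  px <- stripe$pixels
  d <- ncol(px); n <- nrow(px)
  lo <- floor(d * (1 - central_frac) / 2) + 1L
  hi <- ceiling(d * (1 + central_frac) / 2)
  central <- px[, lo:hi, drop = FALSE]
  if (top_k > ncol(central)) {
    stop("top_k exceeds the central band depth", call. = FALSE)
  }
  membrane <- apply(central, 1L, function(v) {
    mean(sort(v, decreasing = TRUE)[seq_len(top_k)])
  })
  ne <- max(1L, round(d * edge_frac))
  background <- rowMeans(px[, seq_len(ne), drop = FALSE])
  cytoplasm <- rowMeans(px[, seq(d - ne + 1L, d), drop = FALSE])
  prof <- membrane_profile(x = (seq_len(n) - 1L) / n, membrane = membrane,
                           cytoplasm = cytoplasm, background = background)
  if (diff(range(px)) < .Machine$double.eps^0.5 * max(1, abs(px[1]))) {
    attr(prof, "degenerate") <- TRUE
  }
  attr(prof, "arclength_px") <- stripe$arclength_px
  prof
}

# circular moving average, window forced odd
circular_smooth <- function(v, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window <= 1L) return(v)
  n <- length(v)
  h <- (window - 1L) / 2L
  ext <- c(v[(n - h + 1L):n], v, v[1L:h])
  as.numeric(stats::filter(ext, rep(1 / window, window), sides = 2))[
    (h + 1L):(h + n)]
}

#' Normalize a membrane profile to local cytoplasm and background
#'
#' Subtracts the local background and divides by the background-subtracted
#' local cytoplasm, so that pure cytoplasm maps to 1 and pure background to
#' 0. The local estimates are smoothed with a circular moving average
#' before division to avoid amplifying noise in the denominator. The
#' output is invariant under global affine intensity transforms (positive
#' gain plus offset) of the source image.
#'
#' @param profile a [membrane_profile()].
#' @param smooth_frac smoothing window as a fraction of the perimeter
#'   (default 0.05).
#' @return the profile with `normalized` filled in. Positions where the
#'   smoothed cytoplasm does not exceed the background are masked `NA` with
#'   a warning; an entirely masked profile is an error.
#' @export
normalize_profile <- function(profile, smooth_frac = 0.05) {
  stopifnot(inherits(profile, "membrane_profile"))
  n <- length(profile$x)
  if (any(!is.finite(profile$cytoplasm)) || any(!is.finite(profile$background))) {
    stop("profile lacks cytoplasm/background context", call. = FALSE)
  }
  w <- max(1L, round(n * smooth_frac))
  cyt <- circular_smooth(profile$cytoplasm, w)
  bg <- circular_smooth(profile$background, w)
  denom <- cyt - bg
  bad <- denom <= 0
  if (all(bad)) {
    stop("cytoplasm does not exceed background anywhere; cannot normalize",
         call. = FALSE)
  }
  if (any(bad)) {
    warning(sum(bad), " position(s) with non-positive cytoplasm-background ",
            "difference masked NA")
  }
  norm <- (profile$membrane - bg) / denom
  norm[bad] <- NA_real_
  out <- profile
  out$normalized <- norm
  out
}

#' Anterior cortical intensity ratio
#'
#' Mean grayscale value of a 2-pixel-wide line over the cortical domain,
#' divided by the mean of a nearby cytoplasmic region; values greater than
#' 1 indicate membrane enrichment. The line is sampled by bilinear
#' interpolation at ~0.5 px spacing with perpendicular offsets covering the
#' requested width.
#'
#' @param image numeric matrix.
#' @param line n x 2 matrix of (x, y) polyline vertices.
#' @param roi cytoplasmic region: a logical mask matrix of the image size,
#'   or a rectangle `c(x0, y0, x1, y1)`.
#' @param line_width line width in pixels (default 2).
#' @return the intensity ratio (numeric scalar).
#' @export
anterior_cortical_intensity <- function(image, line, roi, line_width = 2) {
  line <- as.matrix(line)
  if (nrow(line) < 2L) stop("line needs at least 2 vertices", call. = FALSE)
  samp_x <- numeric(0); samp_y <- numeric(0)
  offs <- seq(-(line_width - 1) / 2, (line_width - 1) / 2, length.out =
                max(2L, round(line_width)))
  for (i in seq_len(nrow(line) - 1L)) {
    p <- line[i, ]; q <- line[i + 1L, ]
    len <- sqrt(sum((q - p)^2))
    if (len == 0) next
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / 0.5) + 1L))
    ux <- (q[1] - p[1]) / len; uy <- (q[2] - p[2]) / len
    nx <- -uy; ny <- ux
    for (o in offs) {
      samp_x <- c(samp_x, p[1] + ts * (q[1] - p[1]) + o * nx)
      samp_y <- c(samp_y, p[2] + ts * (q[2] - p[2]) + o * ny)
    }
  }
  if (any(samp_x < 1 | samp_x > ncol(image) |
          samp_y < 1 | samp_y > nrow(image))) {
    stop("line (with width) leaves the image", call. = FALSE)
  }
  line_mean <- mean(bilinear_sample(image, samp_x, samp_y))
  roi_vals <- roi_values(image, roi)
  if (length(roi_vals) == 0L) stop("empty cytoplasm ROI", call. = FALSE)
  m <- mean(roi_vals)
  if (m == 0) stop("cytoplasm ROI has zero mean", call. = FALSE)
  line_mean / m
}

# Pixels of a region given as a logical mask or a rectangle c(x0,y0,x1,y1).
roi_values <- function(image, roi) {
  if (is.matrix(roi) && is.logical(roi)) {
    if (!all(dim(roi) == dim(image))) {
      stop("mask dimensions differ from image", call. = FALSE)
    }
    return(image[roi])
  }
  if (is.numeric(roi) && length(roi) == 4L) {
    x0 <- max(1L, round(roi[1])); y0 <- max(1L, round(roi[2]))
    x1 <- min(ncol(image), round(roi[3])); y1 <- min(nrow(image), round(roi[4]))
    if (x1 < x0 || y1 < y0) return(numeric(0))
    return(as.numeric(image[y0:y1, x0:x1]))
  }
  stop("roi must be a logical mask or c(x0, y0, x1, y1)", call. = FALSE)
}

#' Temporal mean projection of an image stack
#'
#' Per-pixel mean over the frames falling inside a time window, the
#' projection used to reveal directed particle tracks as streaks.
#'
#' @param stack 3D array (y, x, t).
#' @param window_s window duration in seconds (default 180).
#' @param frame_interval seconds per frame.
#' @param start_frame first frame of the window.
#' @return a 2D matrix of per-pixel means.
#' @export
temporal_mean_projection <- function(stack, window_s = 180,
                                     frame_interval = 1, start_frame = 1L) {
  stopifnot(length(dim(stack)) == 3L)
  nt <- dim(stack)[3L]
  if ((nt - start_frame + 1L) * frame_interval < window_s) {
    stop("stack shorter than the projection window", call. = FALSE)
  }
  n_use <- max(1L, floor(window_s / frame_interval))
  frames <- seq(start_frame, length.out = n_use)
  apply(stack[, , frames, drop = FALSE], c(1L, 2L), mean)
}

#' Circularly align a profile so the posterior domain center sits at x = 0
#'
#' Rotates the sample arrays of a circular profile so that the given
#' posterior-domain center maps to position 0 (the canonical orientation:
#' posterior pole at `x = 0`, anterior pole at `x = 0.5`, the posterior
#' domain straddling the origin). Marks the profile as aligned, which
#' [halves_from_profile()] requires.
#'
#' @param profile a [membrane_profile()].
#' @param posterior_center normalized position of the posterior domain
#'   center in the profile's current frame (e.g. from
#'   [domain_metrics()]`$posterior_center`).
#' @return the shifted profile with attribute `"aligned" = TRUE` and the
#'   applied shift in attribute `"shift"`.
#' @export
align_profile <- function(profile, posterior_center) {
  stopifnot(inherits(profile, "membrane_profile"))
  n <- length(profile$x)
  k <- round((posterior_center %% 1) * n) %% n
  rot <- function(v) if (k == 0) v else c(v[(k + 1L):n], v[1L:k])
  out <- profile
  for (f in c("membrane", "cytoplasm", "background")) out[[f]] <- rot(out[[f]])
  if (!is.null(out$normalized)) out$normalized <- rot(out$normalized)
  attr(out, "aligned") <- TRUE
  attr(out, "shift") <- -k / n
  out
}
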