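# Punctum (focus) detection on cortical images, in the band-pass +
# local-maximum + centroid-refinement lineage of classical particle
# tracking, plus the anterior/middle/posterior partition used for
# density-based asymmetry.

# separable convolution with edge-renormalization (kernel mass outside the
# image is excluded rather than zero-padded)
conv_sep <- function(img, kernel) {
  half <- (length(kernel) - 1L) / 2L
  pass <- function(m, along_rows) {
    acc <- matrix(0, nrow(m), ncol(m))
    wgt <- matrix(0, nrow(m), ncol(m))
    n <- if (along_rows) nrow(m) else ncol(m)
    for (j in seq_along(kernel)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      okv <- src >= 1L & src <= n
      if (along_rows) {
        acc[okv, ] <- acc[okv, ] + kernel[j] * m[src[okv], ]
        wgt[okv, ] <- wgt[okv, ] + kernel[j]
      } else {
        acc[, okv] <- acc[, okv] + kernel[j] * m[, src[okv]]
        wgt[, okv] <- wgt[, okv] + kernel[j]
      }
    }
    acc / wgt * sum(kernel)
  }
  pass(pass(img, TRUE), FALSE)
}

# sliding-window maximum over a (2*half+1)^2 square
max_filter <- function(img, half) {
  out <- img
  nr <- nrow(img); nc <- ncol(img)
  pass <- function(m, along_rows) {
    res <- m
    n <- if (along_rows) nr else nc
    for (off in seq(-half, half)) {
      if (off == 0) next
      src <- seq_len(n) + off
      okv <- src >= 1L & src <= n
      if (along_rows) {
        res[okv, ] <- pmax(res[okv, ], m[src[okv], ])
      } else {
        res[, okv] <- pmax(res[, okv], m[, src[okv]])
      }
    }
    res
  }
  pass(pass(img, TRUE), FALSE)
}

# Band-pass: Gaussian smoothing at the noise scale minus a boxcar
# background estimate at the feature scale; negative values clipped to 0.
bandpass_image <- function(image, diameter, noise_sigma = 1) {
  w <- floor(diameter / 2)
  gx <- seq(-w, w)
  gk <- exp(-gx^2 / (4 * noise_sigma^2))
  gk <- gk / sum(gk)
  bk <- rep(1 / (2 * w + 1), 2 * w + 1)
  out <- conv_sep(image, gk) - conv_sep(image, bk)
  out[out < 0] <- 0
  out
}

#' Detect punctate foci on a cortical image
#'
#' Band-pass filters the image (Gaussian smoothing at the noise scale minus
#' a boxcar background at the feature scale), finds local maxima above a
#' threshold, refines each to sub-pixel precision by the intensity-weighted
#' centroid within the feature window, and merges duplicates closer than
#' `diameter / 2` (keeping the brighter). Detection is equivariant under a
#' global intensity gain when the threshold is scaled with it.
#'
#' @param image numeric matrix.
#' @param diameter feature diameter in pixels (odd, >= 3).
#' @param threshold intensity threshold on the band-passed image; `NULL`
#'   selects `mean + 3 sd` of the band-passed image.
#' @param noise_sigma Gaussian smoothing scale (pixels).
#' @return an object of class `foci_set`: data frame `foci` with columns
#'   `x`, `y`, `intensity` (band-passed mass) and the detection parameters.
#' @export
detect_foci <- function(image, diameter = 7L, threshold = NULL,
                        noise_sigma = 1) {
  if (diameter < 3L || diameter %% 2L == 0L) {
    stop("diameter must be odd and >= 3", call. = FALSE)
  }
  w <- floor(diameter / 2)
  bp <- bandpass_image(image, diameter, noise_sigma)
  if (is.null(threshold)) threshold <- mean(bp) + 3 * stats::sd(bp)
  mx <- max_filter(bp, w)
  cand <- which(bp >= mx & bp > threshold, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(new_foci_set(data.frame(x = numeric(0), y = numeric(0),
                                   intensity = numeric(0)),
                        diameter, threshold, noise_sigma))
  }
  doff <- seq(-w, w)
  circ <- outer(doff^2, doff^2, "+") <= w^2   # [dy, dx]
  nr <- nrow(bp); nc <- ncol(bp)
  res <- matrix(0, nrow(cand), 3L)
  for (i in seq_len(nrow(cand))) {
    r0 <- cand[i, 1L]; c0 <- cand[i, 2L]
    rs <- r0 + doff; cs <- c0 + doff
    okr <- rs >= 1L & rs <= nr; okc <- cs >= 1L & cs <= nc
    win <- bp[rs[okr], cs[okc], drop = FALSE] * circ[okr, okc, drop = FALSE]
    mass <- sum(win)
    if (mass <= 0) next
    cy <- sum(rowSums(win) * rs[okr]) / mass
    cx <- sum(colSums(win) * cs[okc]) / mass
    res[i, ] <- c(cx, cy, mass)
  }
  keep <- res[, 3L] > 0
  res <- res[keep, , drop = FALSE]
  # merge duplicates within diameter/2, brightest kept
  ord <- order(res[, 3L], decreasing = TRUE)
  res <- res[ord, , drop = FALSE]
  taken <- logical(nrow(res))
  min_sep2 <- (diameter / 2)^2
  for (i in seq_len(nrow(res))) {
    if (taken[i]) next
    if (i < nrow(res)) {
      later <- (i + 1L):nrow(res)
      d2 <- (res[later, 1L] - res[i, 1L])^2 + (res[later, 2L] - res[i, 2L])^2
      taken[later[d2 < min_sep2]] <- TRUE
    }
  }
  res <- res[!taken, , drop = FALSE]
  new_foci_set(data.frame(x = res[, 1L], y = res[, 2L],
                          intensity = res[, 3L]),
               diameter, threshold, noise_sigma)
}

new_foci_set <- function(df, diameter, threshold, noise_sigma) {
  structure(list(foci = df,
                 detection_params = list(diameter = diameter,
                                         threshold = threshold,
                                         noise_sigma = noise_sigma)),
            class = "foci_set")
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("<foci_set> %d foci (diameter %g, threshold %.3g)\n",
              nrow(x$foci), x$detection_params$diameter,
              x$detection_params$threshold))
  invisible(x)
}

#' Partition an embryo mask into anterior/middle/posterior thirds
#'
#' Each mask pixel is assigned by its projection onto the
#' anterior-to-posterior pole axis: the first third of the pole-to-pole
#' distance is anterior, the last third posterior (projections beyond the
#' poles are clamped into the nearest region). The three regions are
#' disjoint and cover the mask exactly.
#'
#' @param mask logical matrix selecting the embryo pixels.
#' @param axis 2 x 2 matrix: rows are the anterior and posterior pole
#'   `(x, y)` positions.
#' @return an object of class `embryo_partition` with logical `masks`
#'   (`anterior`, `middle`, `posterior`), their pixel `areas`, and the
#'   `axis`.
#' @export
partition_thirds <- function(mask, axis) {
  axis <- as.matrix(axis)
  stopifnot(is.logical(mask), all(dim(axis) == c(2L, 2L)))
  if (!any(mask)) stop("empty embryo mask", call. = FALSE)
  ant <- axis[1L, ]; post <- axis[2L, ]
  u <- post - ant
  len2 <- sum(u^2)
  if (len2 < 1e-12) stop("degenerate pole axis", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  t <- ((idx[, 2L] - ant[1]) * u[1] + (idx[, 1L] - ant[2]) * u[2]) / len2
  region <- findInterval(t, c(1 / 3, 2 / 3)) + 1L    # 1=ant, 2=mid, 3=post
  mk <- function(which_region) {
    m <- mask & FALSE
    m[idx[region == which_region, , drop = FALSE]] <- TRUE
    m
  }
  masks <- list(anterior = mk(1L), middle = mk(2L), posterior = mk(3L))
  structure(list(masks = masks,
                 areas = vapply(masks, sum, numeric(1)),
                 axis = axis),
            class = "embryo_partition")
}

#' @export
print.embryo_partition <- function(x, ...) {
  cat(sprintf("<embryo_partition> areas A/M/P = %d/%d/%d px^2\n",
              x$areas[["anterior"]], x$areas[["middle"]],
              x$areas[["posterior"]]))
  invisible(x)
}

#' Foci density asymmetry inputs
#'
#' Normalizes anterior and posterior focus counts by the area of their
#' third (the middle third is excluded from the comparison) and returns
#' the densities as [asymmetry_inputs()] for [asi_raw()]. An empty focus
#' set yields zero inputs flagged for the ASI-0 convention.
#'
#' @param foci a [detect_foci()] result (or a data frame with `x`, `y`).
#' @param partition an [partition_thirds()] result.
#' @return an [asymmetry_inputs()] of kind `"foci_density"` (per-px^2
#'   densities).
#' @export
foci_density_asi <- function(foci, partition) {
  stopifnot(inherits(partition, "embryo_partition"))
  df <- if (inherits(foci, "foci_set")) foci$foci else as.data.frame(foci)
  if (any(partition$areas[c("anterior", "posterior")] == 0)) {
    stop("anterior/posterior partition areas must be positive",
         call. = FALSE)
  }
  if (!nrow(df)) {
    warning("no foci detected; ASI will be 0 by convention")
    return(asymmetry_inputs(0, 0, "foci_density", zero_ok = TRUE))
  }
  ant <- partition$axis[1L, ]; post <- partition$axis[2L, ]
  u <- post - ant
  t <- ((df$x - ant[1]) * u[1] + (df$y - ant[2]) * u[2]) / sum(u^2)
  n_ant <- sum(t < 1 / 3)
  n_post <- sum(t >= 2 / 3)
  asymmetry_inputs(n_ant / partition$areas[["anterior"]],
                   n_post / partition$areas[["posterior"]],
                   "foci_density", zero_ok = TRUE)
}
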