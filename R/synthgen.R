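#' Generate a synthetic membrane intensity profile
#'
#' Samples the double-boundary erf model
#' `I(x) = a + (b/2)[erf(m(x - c1)) - erf(m(x - c2))]` at `n_points` evenly
#' spaced normalized arclength positions `x = k/n_points`, `k = 0, ...,
#' n_points - 1`, then applies the camera noise model of `truth`. `x` is
#' circular: position 0 and position `1 - 1/n_points` are adjacent on the
#' cell. Cytoplasm and background context are attached as constant local
#' estimates from `truth`.
#'
#' @param truth a [ground_truth()].
#' @param n_points number of perimeter samples (>= 16).
#' @param noise apply the noise model? (`FALSE` gives the closed-form
#'   model values exactly.)
#' @return a [membrane_profile()] with the generating truth attached as
#'   attribute `"truth"`.
#' @export
gen_membrane_profile <- function(truth, n_points = 360L, noise = TRUE) {
  truth <- validate_ground_truth(truth)
  if (n_points < 16L) stop("n_points must be >= 16", call. = FALSE)
  x <- (seq_len(n_points) - 1L) / n_points
  ideal <- double_boundary_model(x, truth$baseline_a, truth$amplitude_b,
                                 truth$slope_m, truth$boundary_c1,
                                 truth$boundary_c2)
  membrane <- ideal
  if (noise && has_noise(truth)) {
    membrane <- withr::with_seed(truth$seed, apply_camera_noise(ideal, truth))
  }
  prof <- membrane_profile(x = x, membrane = membrane,
                           cytoplasm = rep(truth$cytoplasm_level, n_points),
                           background = rep(truth$background_level, n_points))
  attr(prof, "truth") <- truth
  prof
}

#' Render a synthetic midsection embryo image
#'
#' Draws an ellipsoidal cell midsection: exterior pixels at
#' `background_level`, interior at `cytoplasm_level`, and a membrane ring of
#' `ring_width` pixels centered on the elliptical contour whose intensity at
#' arclength `x` equals the double-boundary profile model of `truth`. The
#' contour starts at the rightmost point of the ellipse (the posterior pole,
#' `x = 0`) and runs counter-clockwise; the anterior pole sits at `x = 0.5`.
#'
#' @param truth a [ground_truth()].
#' @param shape image size `c(nrow, ncol)` (y by x pixels).
#' @param semiaxes ellipse semi-axes `c(x, y)` in pixels.
#' @param center ellipse center `c(x, y)`; defaults to the image center.
#' @param ring_width membrane ring thickness in pixels (3-5 typical).
#' @param margin required clearance between the ellipse and the image edge,
#'   in pixels; must accommodate at least half the stripe width used for
#'   extraction.
#' @param n_profile number of arclength samples used to paint the ring.
#' @param noise apply the noise model?
#' @return a [synthetic_embryo()] whose `contour` is the equal-arclength
#'   elliptical contour and whose annotations name the two poles.
#' @export
gen_midsection_image <- function(truth, shape = c(180L, 240L),
                                 semiaxes = c(55, 35), center = NULL,
                                 ring_width = 5, margin = 32,
                                 n_profile = 720L, noise = TRUE) {
  truth <- validate_ground_truth(truth)
  nr <- shape[1]; nc <- shape[2]
  if (is.null(center)) center <- c((nc + 1) / 2, (nr + 1) / 2)
  if (center[1] - semiaxes[1] < 1 + margin ||
      center[1] + semiaxes[1] > nc - margin ||
      center[2] - semiaxes[2] < 1 + margin ||
      center[2] + semiaxes[2] > nr - margin) {
    stop("ellipse does not fit inside the image with a ", margin,
         "-pixel margin", call. = FALSE)
  }
  ec <- ellipse_contour(center, semiaxes, n_profile)
  contour <- ec$points
  xnorm <- (seq_len(n_profile) - 1L) / n_profile
  ring_values <- double_boundary_model(xnorm, truth$baseline_a,
                                       truth$amplitude_b, truth$slope_m,
                                       truth$boundary_c1, truth$boundary_c2)

  X <- matrix(rep(seq_len(nc), each = nr), nrow = nr)
  Y <- matrix(rep(seq_len(nr), times = nc), nrow = nr)
  rn <- sqrt(((X - center[1]) / semiaxes[1])^2 +
             ((Y - center[2]) / semiaxes[2])^2)
  img <- matrix(truth$background_level, nr, nc)
  img[rn <= 1] <- truth$cytoplasm_level

  # membrane ring: assign pixels within ring_width/2 of the contour the
  # profile value of their nearest arclength sample
  half <- ring_width / 2
  band <- which(abs(rn - 1) <= (half + 2) / min(semiaxes))
  if (length(band)) {
    bx <- X[band]; by <- Y[band]
    nearest_d2 <- rep(Inf, length(band))
    nearest_i <- rep(1L, length(band))
    chunk <- 256L
    for (i0 in seq(1L, n_profile, by = chunk)) {
      idx <- i0:min(i0 + chunk - 1L, n_profile)
      d2 <- outer(bx, contour[idx, 1], "-")^2 +
            outer(by, contour[idx, 2], "-")^2
      w <- max.col(-d2, ties.method = "first")
      dmin <- d2[cbind(seq_along(band), w)]
      upd <- dmin < nearest_d2
      nearest_d2[upd] <- dmin[upd]
      nearest_i[upd] <- idx[w[upd]]
    }
    on_ring <- nearest_d2 <= half^2
    img[band[on_ring]] <- ring_values[nearest_i[on_ring]]
  }

  if (noise && has_noise(truth)) {
    img <- withr::with_seed(truth$seed, apply_camera_noise(img, truth))
  }
  synthetic_embryo(
    img, truth, contour = contour,
    annotations = list(
      posterior_pole = c(x = center[1] + semiaxes[1], y = center[2]),
      anterior_pole = c(x = center[1] - semiaxes[1], y = center[2])
    ),
    meta = list(center = center, semiaxes = semiaxes, ring_width = ring_width,
                perimeter_px = ec$perimeter)
  )
}

#' Generate a synthetic cortical-plane image
#'
#' A diffuse membrane signal at `diffuse_level` plus `cluster_count`
#' Gaussian puncta (sd `cluster_sigma`, peak `cluster_amplitude`) at random
#' positions, then camera noise. Positions are drawn uniformly; optional
#' `region_weights` bias the draw across the anterior/middle/posterior
#' thirds of the x axis (anterior on the left), which gives ground truth
#' for density-asymmetry tests. True spot centers are recorded in the
#' annotations.
#'
#' @param truth a [ground_truth()].
#' @param shape image size `c(nrow, ncol)`.
#' @param region_weights length-3 non-negative weights for the
#'   anterior/middle/posterior thirds; `c(1, 1, 1)` is uniform.
#' @param edge_margin keep spot centers at least this many pixels from the
#'   image border.
#' @param noise apply the noise model?
#' @return a [synthetic_embryo()]; `annotations$spots` is a data frame of
#'   true centers (x, y).
#' @export
gen_cortical_image <- function(truth, shape = c(128L, 128L),
                               region_weights = c(1, 1, 1),
                               edge_margin = 0, noise = TRUE) {
  truth <- validate_ground_truth(truth)
  if (truth$cluster_count < 0) stop("cluster_count must be >= 0", call. = FALSE)
  if (length(region_weights) != 3L || any(region_weights < 0) ||
      sum(region_weights) <= 0) {
    stop("region_weights must be 3 non-negative weights", call. = FALSE)
  }
  nr <- shape[1]; nc <- shape[2]
  n <- truth$cluster_count
  draw <- function() {
    lo <- 1 + edge_margin
    thirds <- lo + (nc - 2 * edge_margin - 1) * c(0, 1, 2, 3) / 3
    region <- sample.int(3L, n, replace = TRUE,
                         prob = region_weights / sum(region_weights))
    x <- stats::runif(n, thirds[region], thirds[region + 1L])
    y <- stats::runif(n, lo, nr - edge_margin)
    cbind(x = x, y = y)
  }
  spots <- if (n > 0) withr::with_seed(truth$seed, draw()) else
    cbind(x = numeric(0), y = numeric(0))

  img <- matrix(truth$diffuse_level, nr, nc)
  if (n > 0) {
    s <- truth$cluster_sigma
    rad <- ceiling(5 * s)
    for (k in seq_len(n)) {
      x0 <- spots[k, 1]; y0 <- spots[k, 2]
      cs <- max(1L, floor(x0 - rad)):min(nc, ceiling(x0 + rad))
      rs <- max(1L, floor(y0 - rad)):min(nr, ceiling(y0 + rad))
      gx <- exp(-(cs - x0)^2 / (2 * s^2))
      gy <- exp(-(rs - y0)^2 / (2 * s^2))
      img[rs, cs] <- img[rs, cs] + truth$cluster_amplitude * outer(gy, gx)
    }
  }
  if (noise && has_noise(truth)) {
    # separate stream from the position draw so spot layout is unchanged
    # when noise is toggled
    img <- withr::with_seed(truth$seed + 1L, apply_camera_noise(img, truth))
  }
  synthetic_embryo(img, truth,
                   annotations = list(spots = as.data.frame(spots)),
                   meta = list(region_weights = region_weights))
}

#' Generate a synthetic kymograph with linear particle traces
#'
#' Builds a space-by-time intensity array containing `n_traces` bright
#' linear granule traces moving at `truth$flow_velocity` (um/min, converted
#' through `pixel_size` and `frame_interval`), over a background of
#' `diffuse_level`. Start positions are random under the seed. A trace that
#' would leave the spatial field is truncated and flagged. Exact (sub-pixel)
#' trace endpoints are recorded as [kymo_trace()] objects, so feeding them
#' to [flow_speed_from_trace()] returns the generating velocity exactly.
#'
#' @param truth a [ground_truth()].
#' @param n_traces number of traces.
#' @param duration total time spanned (s); the paper-style default trace
#'   spans about 200 s.
#' @param n_space spatial extent in pixels; defaults to enough to hold a
#'   full-duration trace plus margin.
#' @param noise apply the noise model?
#' @return a [synthetic_embryo()]; `annotations$traces` is a list of
#'   [kymo_trace()], each with a `truncated` attribute.
#' @export
gen_kymograph <- function(truth, n_traces = 12L, duration = 200,
                          n_space = NULL, noise = TRUE) {
  truth <- validate_ground_truth(truth)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  n_time <- floor(duration / truth$frame_interval) + 1L
  v_px_per_frame <- truth$flow_velocity / 60 * truth$frame_interval /
    truth$pixel_size
  travel <- abs(v_px_per_frame) * (n_time - 1L)
  if (is.null(n_space)) n_space <- ceiling(travel) + 60L
  starts <- withr::with_seed(
    truth$seed,
    stats::runif(n_traces, 3, max(3, n_space - 2 - max(0, travel)))
  )
  img <- matrix(truth$diffuse_level, n_space, n_time)
  traces <- vector("list", n_traces)
  for (k in seq_len(n_traces)) {
    pos <- starts[k] + v_px_per_frame * (seq_len(n_time) - 1L)
    inside <- pos >= 1 & pos <= n_space
    last <- if (all(inside)) n_time else which(!inside)[1L] - 1L
    truncated <- last < n_time
    rows <- round(pos[seq_len(last)])
    img[cbind(rows, seq_len(last))] <-
      img[cbind(rows, seq_len(last))] + truth$cluster_amplitude
    tr <- kymo_trace(start_position = pos[1L], start_frame = 1L,
                     end_position = pos[last], end_frame = last,
                     pixel_size = truth$pixel_size,
                     frame_interval = truth$frame_interval)
    attr(tr, "truncated") <- truncated
    traces[[k]] <- tr
  }
  if (noise && has_noise(truth)) {
    img <- withr::with_seed(truth$seed + 1L, apply_camera_noise(img, truth))
  }
  synthetic_embryo(img, truth, annotations = list(traces = traces),
                   meta = list(axis = "space x time",
                               v_px_per_frame = v_px_per_frame))
}

#' Generate a synthetic photobleach-recovery stack
#'
#' A uniform field at `cytoplasm_level`; from `bleach_frame` onward a
#' central 20-pixel-wide stripe (columns, spanning the full height) drops to
#' `bleach_floor` of the pre-bleach level and recovers exponentially toward
#' it with half-time `recovery_halftime`: the normalized stripe intensity at
#' time `dt` after the bleach is `floor + (1 - floor) * (1 - 2^(-dt/h))`.
#'
#' @param truth a [ground_truth()].
#' @param bleach_frame first bleached frame (>= 2, so pre-bleach frames
#'   exist; the default leaves five pre-bleach frames).
#' @param recovery_halftime recovery half-time (s).
#' @param n_frames total frames.
#' @param shape frame size `c(nrow, ncol)`.
#' @param stripe_width bleached stripe width (pixels).
#' @param bleach_floor immediate post-bleach intensity as a fraction of the
#'   pre-bleach level.
#' @param frame_interval acquisition interval (s); recovery was monitored
#'   every 2 s in the assay this emulates.
#' @param noise apply the noise model?
#' @return a [synthetic_embryo()]; `annotations$box` is the central
#'   20 x 100 pixel measurement box `c(x0, y0, x1, y1)` and `meta` records
#'   bleach frame, half-time and frame interval.
#' @export
gen_frap_stack <- function(truth, bleach_frame = 6L, recovery_halftime = 20,
                           n_frames = 80L, shape = c(128L, 64L),
                           stripe_width = 20L, bleach_floor = 0.2,
                           frame_interval = 2, noise = TRUE) {
  truth <- validate_ground_truth(truth)
  if (bleach_frame < 2L) {
    stop("bleach_frame must be >= 2 so pre-bleach frames exist",
         call. = FALSE)
  }
  nr <- shape[1]; nc <- shape[2]
  level <- truth$cytoplasm_level
  cols <- seq(floor((nc - stripe_width) / 2) + 1L, length.out = stripe_width)
  stack <- array(level, dim = c(nr, nc, n_frames))
  for (t in seq(bleach_frame, n_frames)) {
    dt <- (t - bleach_frame) * frame_interval
    frac <- bleach_floor + (1 - bleach_floor) * (1 - 2^(-dt / recovery_halftime))
    stack[, cols, t] <- level * frac
  }
  if (noise && has_noise(truth)) {
    stack <- withr::with_seed(truth$seed, apply_camera_noise(stack, truth))
  }
  # measurement box: the bleached stripe across, 100 px along it
  box_h <- min(100L, nr)
  y0 <- floor((nr - box_h) / 2) + 1L
  synthetic_embryo(stack, truth,
                   annotations = list(box = c(x0 = cols[1L], y0 = y0,
                                              x1 = cols[stripe_width],
                                              y1 = y0 + box_h - 1L)),
                   meta = list(bleach_frame = bleach_frame,
                               recovery_halftime = recovery_halftime,
                               frame_interval = frame_interval,
                               bleach_floor = bleach_floor,
                               stripe_cols = cols))
}
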