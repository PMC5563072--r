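#' Ground-truth parameter record for synthetic embryos
#'
#' Collects every parameter the synthetic-embryo generators need, so that a
#' single record fully determines (together with a seed) all generated
#' images and the ideal value of every downstream measurement. Defaults
#' describe a wild-type-like zygote: a posterior domain covering 40% of the
#' perimeter with steep erf boundaries, membrane brighter than cytoplasm,
#' cytoplasm brighter than background, punctate cortical clusters over a
#' diffuse pool, anterior-directed cortical flow of 7.1 um/min, and a
#' camera noise model of Poisson shot noise plus Gaussian read noise.
#'
#' @param baseline_a membrane profile baseline (AU).
#' @param amplitude_b signed profile amplitude (AU); positive = enriched
#'   inside `[c1, c2]`.
#' @param slope_m boundary steepness (1 / normalized perimeter units).
#' @param boundary_c1,boundary_c2 boundary positions, `0 <= c1 < c2 < 1`.
#' @param cytoplasm_level,background_level interior / exterior intensity
#'   (AU); background must be below cytoplasm.
#' @param cluster_count number of punctate clusters on cortical images.
#' @param cluster_sigma Gaussian spot sd (pixels).
#' @param cluster_amplitude spot peak amplitude (AU).
#' @param diffuse_level diffuse cortical signal level (AU).
#' @param flow_velocity cortical flow speed (um/min).
#' @param pixel_size image scale (um/pixel).
#' @param frame_interval time between frames (s).
#' @param noise_gaussian_sd additive Gaussian read-noise sd (AU); 0 disables.
#' @param poisson_scale photons per AU for shot noise; 0 or `Inf` disables.
#' @param seed integer seed; generators are pure functions of
#'   (truth, shape arguments), so the same record always yields the same
#'   output.
#' @return an object of class `ground_truth` (a validated named list).
#' @examples
#' truth <- ground_truth(amplitude_b = 900, boundary_c1 = 0.3,
#'                       boundary_c2 = 0.7, seed = 42)
#' prof <- gen_membrane_profile(truth, n_points = 128)
#' @export
ground_truth <- function(baseline_a = 550,
                         amplitude_b = 900,
                         slope_m = 30,
                         boundary_c1 = 0.3,
                         boundary_c2 = 0.7,
                         cytoplasm_level = 500,
                         background_level = 100,
                         cluster_count = 50,
                         cluster_sigma = 2,
                         cluster_amplitude = 200,
                         diffuse_level = 300,
                         flow_velocity = 7.1,
                         pixel_size = 0.1,
                         frame_interval = 1,
                         noise_gaussian_sd = 10,
                         poisson_scale = 1,
                         seed = 1L) {
  truth <- list(
    baseline_a = baseline_a, amplitude_b = amplitude_b, slope_m = slope_m,
    boundary_c1 = boundary_c1, boundary_c2 = boundary_c2,
    cytoplasm_level = cytoplasm_level, background_level = background_level,
    cluster_count = cluster_count, cluster_sigma = cluster_sigma,
    cluster_amplitude = cluster_amplitude, diffuse_level = diffuse_level,
    flow_velocity = flow_velocity, pixel_size = pixel_size,
    frame_interval = frame_interval,
    noise_gaussian_sd = noise_gaussian_sd, poisson_scale = poisson_scale,
    seed = as.integer(seed)
  )
  class(truth) <- "ground_truth"
  validate_ground_truth(truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  profile: a=%g b=%g m=%g c1=%g c2=%g\n",
              x$baseline_a, x$amplitude_b, x$slope_m,
              x$boundary_c1, x$boundary_c2))
  cat(sprintf("  levels:  cytoplasm=%g background=%g diffuse=%g\n",
              x$cytoplasm_level, x$background_level, x$diffuse_level))
  cat(sprintf("  clusters: n=%d sigma=%g amplitude=%g\n",
              x$cluster_count, x$cluster_sigma, x$cluster_amplitude))
  cat(sprintf("  kinetics: flow=%g um/min, %g um/px, %g s/frame\n",
              x$flow_velocity, x$pixel_size, x$frame_interval))
  cat(sprintf("  noise: gaussian sd=%g, poisson scale=%g, seed=%d\n",
              x$noise_gaussian_sd, x$poisson_scale, x$seed))
  invisible(x)
}

validate_ground_truth <- function(truth) {
  fail <- function(what) {
    stop("invalid ground_truth: ", what, call. = FALSE)
  }
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (f in c("baseline_a", "amplitude_b", "slope_m", "boundary_c1",
              "boundary_c2", "cytoplasm_level", "background_level",
              "cluster_sigma", "cluster_amplitude", "diffuse_level",
              "flow_velocity", "pixel_size", "frame_interval",
              "noise_gaussian_sd")) {
    if (!num1(truth[[f]])) fail(paste0(f, " must be a finite scalar"))
  }
  if (!(truth$boundary_c1 >= 0 && truth$boundary_c1 < truth$boundary_c2 &&
        truth$boundary_c2 < 1)) {
    fail("boundaries must satisfy 0 <= c1 < c2 < 1")
  }
  if (truth$slope_m <= 0) fail("slope_m must be > 0")
  if (truth$cluster_sigma <= 0) fail("cluster_sigma must be > 0")
  if (truth$pixel_size <= 0) fail("pixel_size must be > 0")
  if (truth$frame_interval <= 0) fail("frame_interval must be > 0")
  if (truth$background_level >= truth$cytoplasm_level) {
    fail("background_level must be below cytoplasm_level")
  }
  if (!is.numeric(truth$cluster_count) || truth$cluster_count < 0 ||
      truth$cluster_count != round(truth$cluster_count)) {
    fail("cluster_count must be a non-negative integer")
  }
  if (truth$noise_gaussian_sd < 0) fail("noise_gaussian_sd must be >= 0")
  if (!is.numeric(truth$poisson_scale) || length(truth$poisson_scale) != 1L ||
      is.na(truth$poisson_scale) || truth$poisson_scale < 0) {
    fail("poisson_scale must be >= 0 (0 or Inf disables shot noise)")
  }
  if (!is.finite(truth$seed)) fail("seed must be an integer")
  truth
}

# Camera noise model: Poisson shot noise on (signal * scale) photons,
# converted back to AU, then additive Gaussian read noise. scale = 0 or Inf
# disables the Poisson component; sd = 0 the Gaussian one. Caller is
# responsible for seeding.
apply_camera_noise <- function(signal, truth) {
  d <- dim(signal)
  out <- as.numeric(signal)
  ps <- truth$poisson_scale
  if (ps > 0 && is.finite(ps)) {
    out <- stats::rpois(length(out), pmax(out, 0) * ps) / ps
  }
  if (truth$noise_gaussian_sd > 0) {
    out <- out + stats::rnorm(length(out), 0, truth$noise_gaussian_sd)
  }
  dim(out) <- d
  out
}

has_noise <- function(truth) {
  (truth$poisson_scale > 0 && is.finite(truth$poisson_scale)) ||
    truth$noise_gaussian_sd > 0
}

#' Synthetic embryo container
#'
#' Bundles a generated image (or stack), the [ground_truth()] record that
#' produced it, the cell contour (ordered x,y pixel coordinates, closed
#' implicitly), and named landmark annotations such as the poles or true
#' spot positions.
#'
#' @param image_or_stack numeric matrix (y by x) or 3D array (y, x, t).
#' @param truth the generating [ground_truth()].
#' @param contour n x 2 matrix of (x, y) perimeter points, or `NULL`.
#' @param annotations named list of landmarks.
#' @param meta named list of generator-specific extras.
#' @return an object of class `synthetic_embryo`.
#' @export
synthetic_embryo <- function(image_or_stack, truth, contour = NULL,
                             annotations = list(), meta = list()) {
  structure(list(image = image_or_stack, truth = truth, contour = contour,
                 annotations = annotations, meta = meta),
            class = "synthetic_embryo")
}

#' @export
print.synthetic_embryo <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<synthetic_embryo> image %s, %s contour, annotations: %s\n",
              paste(d, collapse = "x"),
              if (is.null(x$contour)) "no" else paste0(nrow(x$contour), "-pt"),
              paste(names(x$annotations), collapse = ", ")))
  invisible(x)
}
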