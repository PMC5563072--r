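#' Anterior/posterior measurement pair for asymmetry computation
#'
#' @param A,P non-negative anterior and posterior measurements in the same
#'   units (intensity, area in px^2, or foci density).
#' @param feature_kind one of `"membrane_intensity"`,
#'   `"cytoplasm_intensity"`, `"cell_area"`, `"foci_density"`.
#' @param zero_ok allow `A + P = 0` (used by the foci pipeline, which
#'   defines the ASI of an empty detection as 0 by convention).
#' @return an object of class `asymmetry_inputs`.
#' @export
asymmetry_inputs <- function(A, P,
                             feature_kind = c("membrane_intensity",
                                              "cytoplasm_intensity",
                                              "cell_area", "foci_density"),
                             zero_ok = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (!is.finite(A) || !is.finite(P) || A < 0 || P < 0) {
    stop("A and P must be finite and non-negative", call. = FALSE)
  }
  if (A + P == 0 && !zero_ok) {
    stop("A + P must be positive", call. = FALSE)
  }
  structure(list(A = A, P = P, feature_kind = feature_kind),
            class = "asymmetry_inputs", zero_foci = (A + P == 0))
}

#' Raw asymmetry index
#'
#' `ASI = (A - P) / (2 (A + P))`: 0 for a symmetric feature, +0.5 when the
#' signal is entirely anterior, -0.5 when entirely posterior. Antisymmetric
#' under swapping A and P.
#'
#' @param A anterior measurement (or an [asymmetry_inputs()] object).
#' @param P posterior measurement (ignored when `A` is an
#'   `asymmetry_inputs`).
#' @return the raw ASI, in `[-0.5, 0.5]`. Vectorized over numeric `A`, `P`.
#' @examples
#' asi_raw(3, 1)   # 0.25
#' asi_raw(2, 2)   # 0
#' @export
asi_raw <- function(A, P = NULL) {
  if (inherits(A, "asymmetry_inputs")) {
    if (isTRUE(attr(A, "zero_foci"))) {
      warning("no signal in either half; ASI 0 by convention")
      return(0)
    }
    P <- A$P; A <- A$A
  }
  if (any(!is.finite(A)) || any(!is.finite(P)) || any(A < 0) || any(P < 0)) {
    stop("A and P must be finite and non-negative", call. = FALSE)
  }
  if (any(A + P == 0)) {
    stop("A + P must be positive", call. = FALSE)
  }
  (A - P) / (2 * (A + P))
}

#' Normalize raw ASI values to a control group
#'
#' Divides each raw ASI by the mean raw ASI of the control group, so that 1
#' indicates wild-type asymmetry and 0 complete loss of asymmetry.
#'
#' @param raw_values numeric vector of raw ASI values.
#' @param control_raws numeric vector of control-group raw ASI values
#'   (non-empty, non-zero mean).
#' @return a data frame with columns `raw`, `normalized`,
#'   `control_mean_raw`, `n_control`.
#' @export
asi_normalize <- function(raw_values, control_raws) {
  if (!length(control_raws)) stop("control group is empty", call. = FALSE)
  cm <- mean(control_raws)
  if (cm == 0) stop("control mean ASI is zero; normalization undefined",
                    call. = FALSE)
  data.frame(raw = raw_values, normalized = raw_values / cm,
             control_mean_raw = cm, n_control = length(control_raws))
}

#' Anterior/posterior inputs from an aligned membrane profile
#'
#' Means of the membrane signal over the two cell halves of a profile in
#' the canonical orientation (posterior pole at `x = 0`, anterior pole at
#' `x = 0.5`): anterior half `x` in `[0.25, 0.75)`, posterior half the
#' rest. The profile must have been aligned (see [align_profile()] /
#' [register_profiles()]).
#'
#' @param profile an aligned [membrane_profile()].
#' @param use_normalized use the normalized signal when present.
#' @return an [asymmetry_inputs()] of kind `"membrane_intensity"`.
#' @export
halves_from_profile <- function(profile, use_normalized = TRUE) {
  stopifnot(inherits(profile, "membrane_profile"))
  if (!isTRUE(attr(profile, "aligned")) &&
      !isTRUE(attr(profile, "registered"))) {
    stop("profile is not aligned to the canonical orientation; ",
         "use align_profile() or register_profiles() first", call. = FALSE)
  }
  y <- if (use_normalized && !is.null(profile$normalized)) {
    profile$normalized
  } else {
    profile$membrane
  }
  anterior <- profile$x >= 0.25 & profile$x < 0.75
  A <- mean(y[anterior], na.rm = TRUE)
  P <- mean(y[!anterior], na.rm = TRUE)
  asymmetry_inputs(A, P, "membrane_intensity")
}

#' Anterior/posterior inputs from an image and a pole axis
#'
#' Splits the cell mask by the perpendicular bisector of the
#' anterior-posterior pole axis and measures each half: pixel counts for
#' `compartment = "area"` (px^2), mean intensity within the mask for
#' `"cytoplasm"` or `"membrane"` (for the latter, pass a membrane mask).
#'
#' @param image numeric matrix.
#' @param axis 2 x 2 matrix: rows are the anterior and posterior pole
#'   `(x, y)` positions.
#' @param compartment `"cytoplasm"`, `"membrane"` or `"area"`.
#' @param mask logical matrix selecting the cell (or compartment) pixels.
#' @return an [asymmetry_inputs()].
#' @export
halves_from_image <- function(image, axis,
                              compartment = c("cytoplasm", "membrane",
                                              "area"),
                              mask) {
  compartment <- match.arg(compartment)
  axis <- as.matrix(axis)
  stopifnot(all(dim(axis) == c(2L, 2L)))
  if (!is.logical(mask) || !all(dim(mask) == dim(image))) {
    stop("mask must be a logical matrix matching the image", call. = FALSE)
  }
  ant <- axis[1L, ]; post <- axis[2L, ]
  u <- post - ant
  if (sqrt(sum(u^2)) < 1e-9) stop("degenerate pole axis", call. = FALSE)
  mid <- (ant + post) / 2
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask", call. = FALSE)
  proj <- (idx[, 2L] - mid[1]) * u[1] + (idx[, 1L] - mid[2]) * u[2]
  in_post <- proj > 0
  if (!any(in_post) || all(in_post)) {
    stop("one cell half is empty", call. = FALSE)
  }
  if (compartment == "area") {
    A <- sum(!in_post); P <- sum(in_post)
    return(asymmetry_inputs(A, P, "cell_area"))
  }
  vals <- image[mask]
  kind <- if (compartment == "cytoplasm") "cytoplasm_intensity" else
    "membrane_intensity"
  asymmetry_inputs(mean(vals[!in_post]), mean(vals[in_post]), kind)
}

#' Cluster index: normalized intensity variance within an ROI
#'
#' Background-subtracted pixel values in the ROI are normalized to their
#' mean; the cluster index is the population variance of the normalized
#' values. It is 0 for a uniform (purely diffuse) signal and grows as
#' signal concentrates into puncta, and is invariant under affine intensity
#' transforms provided the supplied background tracks the offset.
#'
#' @param image numeric matrix.
#' @param roi a logical mask or rectangle `c(x0, y0, x1, y1)` (typically
#'   the anterior domain).
#' @param background background level (AU) to subtract.
#' @return the cluster index (dimensionless, >= 0).
#' @export
cluster_index <- function(image, roi, background = 0) {
  v <- roi_values(image, roi) - background
  if (!length(v)) stop("empty ROI", call. = FALSE)
  m <- mean(v)
  if (m <= 0) {
    stop("ROI mean is not positive after background subtraction",
         call. = FALSE)
  }
  w <- v / m
  mean((w - mean(w))^2)
}
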