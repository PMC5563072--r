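#' Depth cross-section of a membrane stripe
#'
#' Projects a straightened stripe along arclength: the depth profile is the
#' mean intensity at each depth position, running from outside (background)
#' across the membrane into the cytoplasm. The profile is then affinely
#' rescaled so that the outer-edge band mean is 0 and the inner-edge band
#' mean is 1; the rescaling is idempotent.
#'
#' @param stripe a [membrane_stripe()] (depth order outside to inside).
#' @param edge_frac fraction of the depth in each normalization edge band.
#' @return an object of class `cross_section` with fields `depth_profile`
#'   and `normalized = TRUE`.
#' @export
cross_section <- function(stripe, edge_frac = 1 / 6) {
  px <- if (inherits(stripe, "membrane_stripe")) stripe$pixels else
    as.matrix(stripe)
  prof <- colMeans(px)
  d <- length(prof)
  ne <- max(1L, round(d * edge_frac))
  out_mean <- mean(prof[seq_len(ne)])
  in_mean <- mean(prof[seq(d - ne + 1L, d)])
  if (abs(in_mean - out_mean) < 1e-12 * max(1, abs(in_mean))) {
    stop("outer and inner edge bands have equal means; cannot normalize",
         call. = FALSE)
  }
  structure(list(depth_profile = (prof - out_mean) / (in_mean - out_mean),
                 normalized = TRUE, edge_frac = edge_frac),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> %d depth samples, range %.3g..%.3g\n",
              length(x$depth_profile), min(x$depth_profile),
              max(x$depth_profile)))
  invisible(x)
}

#' Mean reference cross-section from membrane-free embryos
#'
#' Pointwise mean of cross-sections from embryos with no detectable
#' membrane signal, defining the shape of the outside-to-inside
#' fluorescence step that is subtracted when estimating isolated membrane
#' signal. The per-depth standard deviation is attached as a dispersion
#' report.
#'
#' @param no_membrane_sections list of at least 2 [cross_section()]s of
#'   equal depth.
#' @return a `cross_section` whose `dispersion` field holds the per-depth
#'   sd across inputs.
#' @export
reference_cross_section <- function(no_membrane_sections) {
  if (length(no_membrane_sections) < 2L) {
    stop("need at least 2 membrane-free cross-sections", call. = FALSE)
  }
  profs <- lapply(no_membrane_sections, function(s) {
    stopifnot(inherits(s, "cross_section"))
    s$depth_profile
  })
  d <- unique(vapply(profs, length, integer(1)))
  if (length(d) != 1L) {
    stop("cross-sections have differing depth lengths", call. = FALSE)
  }
  m <- do.call(rbind, profs)
  structure(list(depth_profile = colMeans(m), normalized = TRUE,
                 dispersion = apply(m, 2L, stats::sd)),
            class = "cross_section")
}

#' Total membrane signal by reference subtraction
#'
#' Sum over depth of the difference between an embryo's normalized
#' cross-section and the membrane-free reference; the excess over the plain
#' outside-to-inside step is the membrane signal. The sum runs over the
#' full depth range, negative deviations included.
#'
#' @param section,reference normalized [cross_section()]s of equal depth.
#' @return the total membrane signal (AU, dimensionless after
#'   normalization).
#' @export
total_membrane_signal <- function(section, reference) {
  stopifnot(inherits(section, "cross_section"),
            inherits(reference, "cross_section"))
  if (!isTRUE(section$normalized) || !isTRUE(reference$normalized)) {
    stop("both cross-sections must be normalized", call. = FALSE)
  }
  if (length(section$depth_profile) != length(reference$depth_profile)) {
    stop("depth lengths differ", call. = FALSE)
  }
  sum(section$depth_profile - reference$depth_profile)
}

# membrane signal of a cytoplasm-normalized profile: summed excess over the
# cytoplasm level (1 after normalization)
profile_membrane_signal <- function(profile) {
  stopifnot(inherits(profile, "membrane_profile"))
  if (is.null(profile$normalized)) {
    stop("profile must be cytoplasm-normalized (see normalize_profile)",
         call. = FALSE)
  }
  sum(profile$normalized - 1, na.rm = TRUE)
}

#' PAR-2 membrane retention across a treatment
#'
#' Ratio of total membrane signal after versus before treatment, computed
#' from cytoplasm-normalized membrane profiles (4-pixel stripes in the
#' assay this implements): 1 means full retention, 0 complete clearance to
#' the cytoplasmic level.
#'
#' @param before,after cytoplasm-normalized [membrane_profile()]s of the
#'   same embryo.
#' @return the retention ratio; `NA` with a warning when the
#'   before-treatment signal is zero.
#' @export
par2_retention <- function(before, after) {
  sb <- profile_membrane_signal(before)
  sa <- profile_membrane_signal(after)
  if (abs(sb) <= sqrt(.Machine$double.eps) * length(before$x)) {
    warning("zero membrane signal before treatment; retention undefined")
    return(NA_real_)
  }
  sa / sb
}

#' Kymograph trace endpoints
#'
#' A straight-line granule trajectory on a space-by-time kymograph,
#' recorded by its start and end (position, frame) pairs plus the spatial
#' and temporal calibration.
#'
#' @param start_position,end_position positions (pixels, may be
#'   sub-pixel).
#' @param start_frame,end_frame frame indices (`end_frame > start_frame`).
#' @param pixel_size micrometers per pixel.
#' @param frame_interval seconds per frame.
#' @return an object of class `kymo_trace`.
#' @export
kymo_trace <- function(start_position, start_frame, end_position, end_frame,
                       pixel_size, frame_interval) {
  if (end_frame <= start_frame) {
    stop("end frame must follow start frame", call. = FALSE)
  }
  if (pixel_size <= 0 || frame_interval <= 0) {
    stop("pixel_size and frame_interval must be positive", call. = FALSE)
  }
  structure(list(start = c(position = start_position, frame = start_frame),
                 end = c(position = end_position, frame = end_frame),
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "kymo_trace")
}

#' Cortical flow speed from a kymograph trace
#'
#' Total distance over time from the straight line connecting the start
#' and end positions of the granule:
#' `|dposition| * pixel_size / (dframes * frame_interval)`, reported in
#' micrometers per minute. Invariant under time-reversal of the trace.
#'
#' @param trace a [kymo_trace()].
#' @return flow speed in um/min.
#' @examples
#' tr <- kymo_trace(10, 1, 30, 201, pixel_size = 0.1, frame_interval = 1)
#' flow_speed_from_trace(tr)  # 0.6 um/min
#' @export
flow_speed_from_trace <- function(trace) {
  stopifnot(inherits(trace, "kymo_trace"))
  dp <- abs(trace$end[["position"]] - trace$start[["position"]])
  dt <- (trace$end[["frame"]] - trace$start[["frame"]]) * trace$frame_interval
  dp * trace$pixel_size / dt * 60
}

#' Per-embryo cortical flow speed
#'
#' Mean of the per-trace flow speeds for one embryo; fewer than `min_traces`
#' traces triggers a warning (the assay standard is at least 10 granule
#' trajectories per embryo).
#'
#' @param traces list of [kymo_trace()]s from one embryo.
#' @param min_traces minimum trace count before warning (default 10).
#' @return mean flow speed in um/min.
#' @export
embryo_flow_speed <- function(traces, min_traces = 10L) {
  if (!length(traces)) stop("no traces supplied", call. = FALSE)
  if (length(traces) < min_traces) {
    warning("only ", length(traces), " trace(s); fewer than the ",
            min_traces, " recommended per embryo")
  }
  mean(vapply(traces, flow_speed_from_trace, numeric(1)))
}

#' Photobleach recovery curve from a stack
#'
#' Mean intensity of the measurement box per frame, normalized to the mean
#' of the pre-bleach frames, with an optional single-exponential recovery
#' fit `I(t) = p - (p - f) exp(-k (t - t_bleach))` whose half-time
#' `log(2)/k` summarizes mobility.
#'
#' @param stack 3D array (y, x, t).
#' @param box measurement box `c(x0, y0, x1, y1)` (the assay standard is a
#'   central 20 x 100 pixel box inside the bleached stripe).
#' @param bleach_frame index of the first bleached frame (>= 2).
#' @param frame_interval seconds per frame (default 2).
#' @param fit fit the exponential recovery? (default `TRUE`).
#' @return an object of class `frap_curve` with fields `time` (s, 0 at the
#'   first frame), `intensity`, `normalized`, `bleach_frame`, and when
#'   fitted `halftime` (s), `rate`, `plateau`, `floor`.
#' @export
frap_curve <- function(stack, box, bleach_frame, frame_interval = 2,
                       fit = TRUE) {
  stopifnot(length(dim(stack)) == 3L)
  nr <- dim(stack)[1L]; nc <- dim(stack)[2L]; nt <- dim(stack)[3L]
  x0 <- box[1]; y0 <- box[2]; x1 <- box[3]; y1 <- box[4]
  if (x0 < 1 || y0 < 1 || x1 > nc || y1 > nr || x1 < x0 || y1 < y0) {
    stop("measurement box outside the stack frames", call. = FALSE)
  }
  if (bleach_frame < 2L || bleach_frame > nt) {
    stop("bleach_frame must leave at least one pre-bleach frame",
         call. = FALSE)
  }
  intensity <- vapply(seq_len(nt), function(t) {
    mean(stack[y0:y1, x0:x1, t])
  }, numeric(1))
  pre <- mean(intensity[seq_len(bleach_frame - 1L)])
  if (pre <= 0) stop("non-positive pre-bleach intensity", call. = FALSE)
  normalized <- intensity / pre
  out <- structure(list(time = (seq_len(nt) - 1L) * frame_interval,
                        intensity = intensity, normalized = normalized,
                        bleach_frame = bleach_frame,
                        frame_interval = frame_interval),
                   class = "frap_curve")
  if (fit) {
    post <- seq(bleach_frame, nt)
    tt <- (post - bleach_frame) * frame_interval
    yy <- normalized[post]
    f0 <- yy[1L]
    p0 <- max(yy[length(yy)], f0 + 1e-3)
    k0 <- log(2) / max(tt[length(tt)] / 4, frame_interval)
    ft <- try(minpack.lm::nls.lm(
      par = c(p = p0, f = f0, k = k0),
      fn = function(par) {
        yy - (par[["p"]] - (par[["p"]] - par[["f"]]) * exp(-par[["k"]] * tt))
      },
      lower = c(p = 0, f = 0, k = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
      silent = TRUE)
    if (!inherits(ft, "try-error") && ft$info %in% 1:4) {
      out$rate <- ft$par[["k"]]
      out$halftime <- log(2) / ft$par[["k"]]
      out$plateau <- ft$par[["p"]]
      out$floor <- ft$par[["f"]]
    }
  }
  out
}

#' @export
print.frap_curve <- function(x, ...) {
  cat(sprintf("<frap_curve> %d frames, bleach at %d%s\n",
              length(x$time), x$bleach_frame,
              if (!is.null(x$halftime)) {
                sprintf(", half-time %.3g s", x$halftime)
              } else ""))
  invisible(x)
}
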