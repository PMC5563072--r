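#' Fit a single erf boundary to a profile segment
#'
#' Least-squares fit of `I(x) = a + (b/2) erf(m(x - c))` to one boundary
#' region (typically half of a cortical profile). The segment is first
#' min-max normalized to `[0, 1]` (the convention used when comparing
#' profiles of co-stained markers); the boundary position `c` and slope `m`
#' are unaffected by that affine rescaling. Initialization takes `c` from
#' the half-maximum crossing; if the first fit fails, a multi-start over a
#' coarse grid of `c` values is used.
#'
#' @param x positions (>= 8 samples).
#' @param y intensities at `x`.
#' @param normalize min-max normalize `y` before fitting (default `TRUE`).
#' @param flat_floor if the range of `y` is below this, the segment is
#'   considered flat and the fit returns unconverged with `c` undefined.
#' @return an object of class `single_boundary_fit` with fields
#'   `a`, `b`, `m`, `c`, `rss`, `converged`, `n`.
#' @export
fit_single_boundary <- function(x, y, normalize = TRUE, flat_floor = 1e-8) {
  if (inherits(x, "membrane_profile")) {
    prof <- x
    y <- if (!is.null(prof$normalized)) prof$normalized else prof$membrane
    x <- prof$x
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 8L) stop("need at least 8 samples", call. = FALSE)
  rng <- diff(range(y))
  if (rng < flat_floor) {
    return(new_single_fit(NA, NA, NA, NA, rss = NA_real_, converged = FALSE,
                          n = length(x)))
  }
  if (normalize) y <- (y - min(y)) / rng

  resid_fun <- function(p) {
    y - single_boundary_model(x, p[["a"]], p[["b"]], p[["m"]], p[["c"]])
  }
  rising <- mean(y[x >= stats::quantile(x, 0.75)]) >
    mean(y[x <= stats::quantile(x, 0.25)])
  b0 <- if (rising) 1 else -1
  mid <- (max(y) + min(y)) / 2
  cross <- which(diff(sign(y - mid)) != 0)
  c0 <- if (length(cross)) x[cross[1L]] else stats::median(x)
  xr <- diff(range(x))
  m0 <- 10 / xr

  run <- function(start) {
    fit <- try(minpack.lm::nls.lm(
      par = start, fn = resid_fun,
      lower = c(a = -Inf, b = -Inf, m = 1e-3, c = min(x)),
      upper = c(a = Inf, b = Inf, m = Inf, c = max(x)),
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-14, ptol = 1e-14, gtol = 0)),
      silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    fit
  }
  best <- run(c(a = 0.5, b = b0, m = m0, c = c0))
  best_rss <- if (is.null(best)) Inf else sum(best$fvec^2)
  if (!is.finite(best_rss) || best_rss > 1e-4 * length(x)) {
    for (cg in seq(min(x) + 0.05 * xr, max(x) - 0.05 * xr, length.out = 9L)) {
      for (mg in c(5, 20, 60) / xr) {
        for (bg in c(1, -1)) {
          f <- run(c(a = 0.5, b = bg, m = mg, c = cg))
          if (!is.null(f)) {
            r <- sum(f$fvec^2)
            if (r < best_rss) { best <- f; best_rss <- r }
          }
        }
      }
    }
  }
  if (is.null(best)) {
    return(new_single_fit(NA, NA, NA, NA, NA_real_, FALSE, length(x)))
  }
  p <- best$par
  # canonical sign: keep m > 0, fold any orientation into the sign of b
  new_single_fit(p[["a"]], p[["b"]], p[["m"]], p[["c"]], best_rss,
                 converged = best$info %in% 1:4 && p[["m"]] > 0 &&
                   p[["c"]] >= min(x) && p[["c"]] <= max(x),
                 n = length(x))
}

new_single_fit <- function(a, b, m, c, rss, converged, n) {
  structure(list(a = a, b = b, m = m, c = c, rss = rss,
                 converged = converged, n = n),
            class = "single_boundary_fit")
}

#' @export
print.single_boundary_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<single_boundary_fit> unconverged\n")
  } else {
    cat(sprintf(
      "<single_boundary_fit> a=%.4g b=%.4g m=%.4g c=%.5g (rss=%.3g, n=%d)\n",
      x$a, x$b, x$m, x$c, x$rss, x$n))
  }
  invisible(x)
}

#' Register co-acquired profile pairs on a reference boundary
#'
#' Circularly shifts both channels of each co-acquired profile pair so the
#' reference channel's fitted boundary (inflection point `c`) sits at a
#' common position. Pairs whose reference fit did not converge are excluded
#' and reported.
#'
#' @param reference_fits list of [fit_single_boundary()] results, one per
#'   pair, fitted on the reference channel.
#' @param profile_pairs list of pairs; each pair is a list of two
#'   [membrane_profile()] objects (reference first).
#' @param target common boundary position after registration (default 0.5).
#' @return list with `pairs` (aligned pairs), `shifts` (applied shift per
#'   retained pair), and `excluded` (indices of dropped pairs).
#' @export
register_profiles <- function(reference_fits, profile_pairs, target = 0.5) {
  stopifnot(length(reference_fits) == length(profile_pairs))
  out <- list(); shifts <- numeric(0); excluded <- integer(0)
  for (i in seq_along(profile_pairs)) {
    fit <- reference_fits[[i]]
    if (!isTRUE(fit$converged)) {
      excluded <- c(excluded, i)
      next
    }
    delta <- (target - fit$c) %% 1
    pair <- lapply(profile_pairs[[i]], shift_profile, delta = delta)
    out[[length(out) + 1L]] <- pair
    shifts <- c(shifts, delta)
  }
  if (length(excluded)) {
    message("excluded ", length(excluded),
            " pair(s) with unconverged reference fits: ",
            paste(excluded, collapse = ", "))
  }
  list(pairs = out, shifts = shifts, excluded = excluded)
}

# circular shift of a profile's sample arrays by +delta in x (on-grid)
shift_profile <- function(profile, delta) {
  n <- length(profile$x)
  k <- ((-round(delta * n)) %% n)
  rot <- function(v) if (k == 0) v else c(v[(k + 1L):n], v[1L:k])
  out <- profile
  for (f in c("membrane", "cytoplasm", "background")) out[[f]] <- rot(out[[f]])
  if (!is.null(out$normalized)) out$normalized <- rot(out$normalized)
  attr(out, "registered") <- TRUE
  out
}

#' Signed boundary offset between two markers
#'
#' The difference in fitted boundary position between a marker and the
#' reference, scaled to micrometers: `(c_other - c_ref) * perimeter_um`.
#' With the posterior direction toward increasing `x`, positive values
#' indicate the other marker's boundary lies posterior of the reference
#' (i.e., reduced segregation relative to it). Both fits must come from
#' profiles registered to a common frame.
#'
#' @param fit_ref,fit_other converged [fit_single_boundary()] results in a
#'   common registered frame.
#' @param perimeter_um embryo perimeter in micrometers.
#' @return signed offset in micrometers.
#' @export
boundary_offset <- function(fit_ref, fit_other, perimeter_um) {
  if (!isTRUE(fit_ref$converged) || !isTRUE(fit_other$converged)) {
    stop("both boundary fits must have converged", call. = FALSE)
  }
  if (!is.numeric(perimeter_um) || perimeter_um <= 0) {
    stop("perimeter_um must be positive", call. = FALSE)
  }
  (fit_other$c - fit_ref$c) * perimeter_um
}

#' Fit a double erf boundary (domain) model to a circular profile
#'
#' Least-squares fit of
#' `I(x) = a + (b/2)[erf(m(x - c1)) - erf(m(x - c2))]` to a full circular
#' membrane profile, with `b` signed: positive for a marker enriched inside
#' `[c1, c2]` (posterior-type), negative for one depleted there
#' (anterior-type). Because the data are circular, the fit scans a set of
#' coarse circular phases, fits in each shifted frame (where the domain
#' need not straddle the origin), keeps the lowest-residual solution and
#' maps the boundaries back to the input frame. `c1` is reported in
#' `[0, 1)`; `c2 = c1 + domain width` may exceed 1 when the domain wraps
#' the origin.
#'
#' On circular data the model is nearly sign-degenerate: a domain enriched
#' inside `[c1, c2]` is almost indistinguishable from one depleted in the
#' complementary arc, and noise can decide which representation wins. When
#' the marker polarity is known (posterior markers are enriched, `b > 0`;
#' anterior markers depleted, `b < 0`), fix it with `amplitude_sign`.
#'
#' @param profile a [membrane_profile()] (the `normalized` signal is used
#'   when present, otherwise `membrane`), or a numeric vector of circular
#'   samples.
#' @param n_phases number of coarse circular phases scanned (default 8).
#' @param flat_floor relative range below which the profile is flat and the
#'   fit returns unconverged.
#' @param amplitude_sign `"auto"` (pick by residual), `"positive"`
#'   (posterior-type marker) or `"negative"` (anterior-type marker).
#' @return an object of class `double_boundary_fit` with fields `a`, `b`,
#'   `m`, `c1`, `c2`, `L` (= 1), `rss`, `converged`.
#' @export
fit_double_boundary <- function(profile, n_phases = 8L, flat_floor = 1e-8,
                                amplitude_sign = c("auto", "positive",
                                                   "negative")) {
  amplitude_sign <- match.arg(amplitude_sign)
  if (inherits(profile, "membrane_profile")) {
    y <- if (!is.null(profile$normalized)) profile$normalized else
      profile$membrane
  } else {
    y <- as.numeric(profile)
  }
  ok <- is.finite(y)
  if (any(!ok)) {
    # masked positions: fill by linear interpolation around the circle
    idx <- seq_along(y)
    y[!ok] <- stats::approx(idx[ok], y[ok], xout = idx[!ok],
                            rule = 2)$y
  }
  n <- length(y)
  if (n < 16L) stop("need at least 16 circular samples", call. = FALSE)
  x <- (seq_len(n) - 1L) / n
  rng <- diff(range(y))
  if (rng < flat_floor * max(1, abs(mean(y)))) {
    return(new_double_fit(NA, NA, NA, NA, NA, NA_real_, FALSE))
  }

  thr <- (max(y) + min(y)) / 2
  signs <- switch(amplitude_sign, auto = c(1, -1), positive = 1,
                  negative = -1)
  best <- NULL; best_rss <- Inf; best_shift <- 0
  for (ph in seq_len(n_phases) - 1L) {
    k <- round(ph / n_phases * n) %% n
    ys <- if (k == 0) y else c(y[(k + 1L):n], y[1L:k])
    shift <- k / n                       # x_orig = (x_fit + shift) mod 1
    for (sign_b in signs) {
      inside <- if (sign_b > 0) ys > thr else ys < thr
      r <- rle(inside)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values & starts > 1L & ends < n)
      if (!length(runs)) next
      run <- runs[which.max(r$lengths[runs])]
      c1_0 <- x[starts[run]]; c2_0 <- x[ends[run]]
      if (c2_0 - c1_0 < 2 / n) next
      mu0 <- (c1_0 + c2_0) / 2; h0 <- (c2_0 - c1_0) / 2
      a0 <- if (sign_b > 0) min(ys) + rng * 0.05 else max(ys) - rng * 0.05
      start <- c(a = a0, b = sign_b * rng, m = 8 / max(h0, 0.05),
                 mu = mu0, h = h0)
      fit <- try(minpack.lm::nls.lm(
        par = start,
        fn = function(p) {
          ys - double_boundary_model(x, p[["a"]], p[["b"]], p[["m"]],
                                     p[["mu"]] - p[["h"]],
                                     p[["mu"]] + p[["h"]])
        },
        lower = c(a = -Inf, b = if (sign_b > 0) 0 else -Inf, m = 1e-2,
                  mu = -0.25, h = 1e-4),
        upper = c(a = Inf, b = if (sign_b > 0) Inf else 0, m = Inf,
                  mu = 1.25, h = 0.5),
        control = minpack.lm::nls.lm.control(
          maxiter = 1000, ftol = 1e-14, ptol = 1e-14, gtol = 0)),
        silent = TRUE)
      if (inherits(fit, "try-error")) next
      rss <- sum(fit$fvec^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss; best_shift <- shift }
    }
  }
  if (is.null(best)) {
    return(new_double_fit(NA, NA, NA, NA, NA, NA_real_, FALSE))
  }
  p <- best$par
  size <- 2 * p[["h"]]
  c1 <- (p[["mu"]] - p[["h"]] + best_shift) %% 1
  new_double_fit(p[["a"]], p[["b"]], p[["m"]], c1, c1 + size, best_rss,
                 converged = best$info %in% 1:4 && p[["m"]] > 0 &&
                   size > 0 && size < 1)
}

new_double_fit <- function(a, b, m, c1, c2, rss, converged) {
  structure(list(a = a, b = b, m = m, c1 = c1, c2 = c2, L = 1,
                 rss = rss, converged = converged),
            class = "double_boundary_fit")
}

#' Construct a double-boundary fit record directly
#'
#' Mostly useful for plumbing measured or hypothetical boundary parameters
#' into [domain_metrics()] and friends without running the optimizer.
#'
#' @param a,b,m,c1,c2 model parameters (`c1 <= c2`).
#' @param L profile length (1 for normalized profiles).
#' @param rss residual sum of squares.
#' @param converged convergence flag.
#' @return a `double_boundary_fit`.
#' @export
double_boundary_fit <- function(a, b, m, c1, c2, L = 1, rss = 0,
                                converged = TRUE) {
  if (c2 < c1) stop("c1 must not exceed c2", call. = FALSE)
  structure(list(a = a, b = b, m = m, c1 = c1, c2 = c2, L = L,
                 rss = rss, converged = converged),
            class = "double_boundary_fit")
}

#' @export
print.double_boundary_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<double_boundary_fit> unconverged\n")
  } else {
    cat(sprintf(
      "<double_boundary_fit> a=%.4g b=%.4g m=%.4g c1=%.5g c2=%.5g (rss=%.3g)\n",
      x$a, x$b, x$m, x$c1, x$c2, x$rss))
  }
  invisible(x)
}

#' Domain sizes from a double-boundary fit
#'
#' Posterior domain size `(c2 - c1)/L`, anterior domain size
#' `1 - (c2 - c1)/L`, and the posterior domain center `(c1 + c2)/2`
#' (reported modulo 1). The two sizes sum to 1 exactly.
#'
#' @param fit a converged [fit_double_boundary()] result.
#' @return an object of class `domain_metrics` with fields
#'   `posterior_size`, `anterior_size`, `posterior_center`.
#' @export
domain_metrics <- function(fit) {
  stopifnot(inherits(fit, "double_boundary_fit"))
  if (!isTRUE(fit$converged)) {
    stop("fit did not converge; domain metrics undefined", call. = FALSE)
  }
  post <- (fit$c2 - fit$c1) / fit$L
  structure(list(posterior_size = post, anterior_size = 1 - post,
                 posterior_center = ((fit$c1 + fit$c2) / 2) %% 1),
            class = "domain_metrics")
}

#' @export
print.domain_metrics <- function(x, ...) {
  cat(sprintf(
    "<domain_metrics> posterior %.4g, anterior %.4g, center %.4g\n",
    x$posterior_size, x$anterior_size, x$posterior_center))
  invisible(x)
}

#' Ratio of posterior domain sizes before and after a treatment
#'
#' `after$posterior_size / before$posterior_size` for the same embryo; a
#' value below 1 means the domain shrank.
#'
#' @param before,after [domain_metrics()] of the same embryo at the two
#'   timepoints.
#' @return the size ratio; `NA` with a warning when the before-size is 0.
#' @export
domain_change_ratio <- function(before, after) {
  stopifnot(inherits(before, "domain_metrics"),
            inherits(after, "domain_metrics"))
  if (before$posterior_size == 0) {
    warning("before-treatment posterior domain size is zero; ratio undefined")
    return(NA_real_)
  }
  after$posterior_size / before$posterior_size
}

#' Segregation efficiency of an anterior marker
#'
#' Scored as the relative anterior domain size from a double-boundary fit
#' of an (aligned) anterior-marker profile; smaller anterior domains mean
#' more efficient segregation. Anterior markers are depleted in the
#' posterior domain, so their fitted amplitude `b` is negative; a
#' non-negative `b` triggers a warning.
#'
#' @param fit a converged [fit_double_boundary()] result for an
#'   anterior-marker profile.
#' @return the anterior domain size (fraction of the perimeter).
#' @export
segregation_efficiency <- function(fit) {
  stopifnot(inherits(fit, "double_boundary_fit"))
  if (is.finite(fit$b) && fit$b >= 0) {
    warning("fit amplitude b >= 0: profile does not look like an anterior ",
            "marker (expected depletion inside [c1, c2])")
  }
  domain_metrics(fit)$anterior_size
}

#' Anterior PAR retraction from pole and domain-end annotations
#'
#' Intersects the equatorial line joining the two poles with the line
#' joining the cortical top and bottom ends of the marker domain; the
#' retraction is the distance from that intersection (the posterior domain
#' boundary) to the posterior pole, scaled by the pixel size.
#'
#' @param pole_anterior,pole_posterior pole coordinates `c(x, y)` (pixels).
#' @param domain_end_top,domain_end_bottom cortical domain end coordinates.
#' @param pixel_size micrometers per pixel (default 1: result in pixels).
#' @return retraction distance; if the intersection falls outside the
#'   segment between the poles the value carries attribute
#'   `"outside_axis" = TRUE` and a warning is raised.
#' @export
retraction <- function(pole_anterior, pole_posterior, domain_end_top,
                       domain_end_bottom, pixel_size = 1) {
  pa <- as.numeric(pole_anterior); pp <- as.numeric(pole_posterior)
  hit <- line_intersection(pa, pp, as.numeric(domain_end_top),
                           as.numeric(domain_end_bottom))
  if (is.null(hit)) {
    stop("domain-end line is parallel to the pole axis", call. = FALSE)
  }
  d <- sqrt(sum((hit$point - pp)^2)) * pixel_size
  if (hit$t < 0 || hit$t > 1) {
    warning("domain boundary intersection falls outside the pole segment")
    attr(d, "outside_axis") <- TRUE
  }
  d
}
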