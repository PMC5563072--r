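#' Error-function boundary models
#'
#' Closed-form intensity models for membrane profiles with one or two
#' domain boundaries. `x` is normalized arclength along the cell perimeter
#' (dimensionless, `[0,1)` for a full profile), `c` (or `c1`, `c2`) the
#' boundary position in the same units, `m` the boundary steepness
#' (1/x-units), `a` the baseline and `b` the (signed) amplitude.
#'
#' The single-boundary model is
#' \deqn{I(x) = a + \frac{b}{2}\,\mathrm{erf}(m(x-c))}
#' and the double-boundary (domain) model
#' \deqn{I(x) = a + \frac{b}{2}\left[\mathrm{erf}(m(x-c_1)) -
#'   \mathrm{erf}(m(x-c_2))\right]}
#' so that `b > 0` describes a marker enriched inside `[c1, c2]` and
#' `b < 0` one depleted there.
#'
#' @param x numeric vector of positions.
#' @param a baseline intensity.
#' @param b signed amplitude.
#' @param m boundary steepness (> 0).
#' @param c,c1,c2 boundary positions.
#' @return numeric vector of model intensities at `x`.
#' @examples
#' x <- seq(0, 1, length.out = 201)
#' plot(x, double_boundary_model(x, a = 0.2, b = 1.5, m = 40, c1 = 0.35,
#'                               c2 = 0.75), type = "l")
#' @export
single_boundary_model <- function(x, a, b, m, c) {
  a + (b / 2) * pracma::erf(m * (x - c))
}

#' @rdname single_boundary_model
#' @export
double_boundary_model <- function(x, a, b, m, c1, c2) {
  a + (b / 2) * (pracma::erf(m * (x - c1)) - pracma::erf(m * (x - c2)))
}
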