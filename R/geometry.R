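# Geometry helpers shared by the generators and the stripe extractor.
# Images are matrices indexed [row, col] = [y, x]; a point (x, y) refers to
# the center of pixel image[y, x] (1-based). Contours are n x 2 matrices of
# (x, y) points, implicitly closed.

# Equal-arclength samples on an axis-aligned ellipse, starting at the
# rightmost point (theta = 0) and proceeding counter-clockwise in (x, y).
ellipse_contour <- function(center, semiaxes, n_points, theta_fine = 8192) {
  th <- seq(0, 2 * pi, length.out = theta_fine + 1L)[-(theta_fine + 1L)]
  px <- center[1] + semiaxes[1] * cos(th)
  py <- center[2] + semiaxes[2] * sin(th)
  seg <- sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2)
  s <- c(0, cumsum(seg))            # arclength at each fine vertex (+ closure)
  total <- s[length(s)]
  target <- total * (seq_len(n_points) - 1L) / n_points
  xi <- stats::approx(s, c(px, px[1]), xout = target)$y
  yi <- stats::approx(s, c(py, py[1]), xout = target)$y
  list(points = cbind(x = xi, y = yi), perimeter = total)
}

# Resample a closed polyline contour to n equally spaced arclength points.
resample_contour <- function(contour, n_points) {
  contour <- as.matrix(contour)
  cl <- rbind(contour, contour[1L, , drop = FALSE])
  seg <- sqrt(diff(cl[, 1])^2 + diff(cl[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate contour: zero perimeter", call. = FALSE)
  target <- total * (seq_len(n_points) - 1L) / n_points
  cbind(x = stats::approx(s, cl[, 1], xout = target)$y,
        y = stats::approx(s, cl[, 2], xout = target)$y)
}

contour_perimeter <- function(contour) {
  cl <- rbind(as.matrix(contour), as.matrix(contour)[1L, , drop = FALSE])
  sum(sqrt(diff(cl[, 1])^2 + diff(cl[, 2])^2))
}

# Signed area > 0 for counter-clockwise orientation in (x, y).
contour_signed_area <- function(contour) {
  x <- contour[, 1]; y <- contour[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Inward unit normals of a closed contour (central differences, circular).
contour_inward_normals <- function(contour) {
  n <- nrow(contour)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  tx <- contour[nxt, 1] - contour[prv, 1]
  ty <- contour[nxt, 2] - contour[prv, 2]
  len <- sqrt(tx^2 + ty^2)
  len[len == 0] <- 1
  tx <- tx / len; ty <- ty / len
  # rotate the tangent by 90 deg toward the interior; which rotation is
  # inward depends on the traversal orientation (signed area)
  ccw <- contour_signed_area(contour) > 0
  if (ccw) { nx <- -ty; ny <- tx } else { nx <- ty; ny <- -tx }
  cbind(nx = nx, ny = ny)
}

# Bilinear interpolation of image values at fractional (x, y) positions.
# All points must lie inside [1, ncol] x [1, nrow].
bilinear_sample <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  if (any(x < 1 | x > nc | y < 1 | y > nr)) {
    stop("sample point outside image bounds", call. = FALSE)
  }
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1L)
  i10 <- cbind(y0 + 1L, x0); i11 <- cbind(y0 + 1L, x0 + 1L)
  image[i00] * (1 - fx) * (1 - fy) + image[i01] * fx * (1 - fy) +
    image[i10] * (1 - fx) * fy + image[i11] * fx * fy
}

# Intersection of the infinite lines p1-p2 and q1-q2; returns list(point, t)
# where t is the parameter along p1->p2, or NULL if parallel.
line_intersection <- function(p1, p2, q1, q2) {
  r <- p2 - p1; s <- q2 - q1
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < 1e-12 * max(1, sqrt(sum(r^2)) * sqrt(sum(s^2)))) {
    return(NULL)
  }
  t <- ((q1[1] - p1[1]) * s[2] - (q1[2] - p1[2]) * s[1]) / denom
  list(point = p1 + t * r, t = t)
}
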