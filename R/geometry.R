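# Ellipse geometry shared by the simulator (cell placement, puncta placement)
# and the profile extractor (arc-length sampling along the fitted contour).
# Parametrisation: p(t) = c + R(theta) %*% (a cos t, b sin t), t in [0, 2*pi),
# with t = 0 at the major-axis vertex and t increasing counter-clockwise in
# the mathematical (x right, y up) sense.

#' Construct an ellipse descriptor
#'
#' @param cx,cy center, 0-based pixel coordinates
#' @param a,b semi-major and semi-minor axis lengths in pixels (`a >= b`)
#' @param theta orientation of the major axis from the +x axis, radians in
#'   `[0, pi)`
#' @return a list of class `cq_ellipse`
#' @export
ellipse <- function(cx, cy, a, b, theta = 0) {
  stopifnot(is.finite(cx), is.finite(cy), a > 0, b > 0)
  if (b > a) { tmp <- a; a <- b; b <- tmp; theta <- theta + pi / 2 }
  theta <- theta %% pi
  structure(list(cx = cx, cy = cy, a = a, b = b, theta = theta),
            class = "cq_ellipse")
}

#' Ellipse evaluation helpers
#'
#' `ellipse_point()` and `ellipse_normal()` evaluate contour points and
#' outward unit normals at parameter values `t`; `ellipse_perimeter()`
#' returns the contour length (pixels) and `ellipse_arc_to_t()` maps
#' arc-length positions (pixels, from the major-axis vertex,
#' counter-clockwise) back to parameter values. Used by the simulator to
#' place cortical punctae and by the profile extractor to unwrap the
#' membrane contour.
#'
#' @param ell an [ellipse()]
#' @param t numeric vector of parameter values
#' @param s numeric vector of arc-length positions in pixels
#' @param tab optional precomputed arc table (internal reuse)
#' @return `ellipse_point`/`ellipse_normal`: an `n x 2` matrix of x,y values;
#'   `ellipse_perimeter`: a length (pixels); `ellipse_arc_to_t`: parameter
#'   values
#' @name ellipse-geometry
NULL

#' @rdname ellipse-geometry
#' @export
ellipse_point <- function(ell, t) {
  ct <- cos(t); st <- sin(t)
  co <- cos(ell$theta); so <- sin(ell$theta)
  x <- ell$cx + ell$a * ct * co - ell$b * st * so
  y <- ell$cy + ell$a * ct * so + ell$b * st * co
  cbind(x = x, y = y)
}

#' @rdname ellipse-geometry
#' @export
ellipse_normal <- function(ell, t) {
  ct <- cos(t); st <- sin(t)
  co <- cos(ell$theta); so <- sin(ell$theta)
  # gradient direction of the implicit form, rotated to image frame
  nx0 <- ct / ell$a; ny0 <- st / ell$b
  nx <- nx0 * co - ny0 * so
  ny <- nx0 * so + ny0 * co
  nrm <- sqrt(nx^2 + ny^2)
  cbind(x = nx / nrm, y = ny / nrm)
}

# Cumulative arc-length lookup table over a dense parameter grid.
ellipse_arc_table <- function(ell, n_dense = 4096L) {
  t <- seq(0, 2 * pi, length.out = n_dense + 1L)
  p <- ellipse_point(ell, t)
  seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  list(t = t, s = c(0, cumsum(seg)))
}

#' @rdname ellipse-geometry
#' @export
ellipse_perimeter <- function(ell, tab = NULL) {
  tab <- tab %||% ellipse_arc_table(ell)
  tab$s[length(tab$s)]
}

#' @rdname ellipse-geometry
#' @export
ellipse_arc_to_t <- function(ell, s, tab = NULL) {
  tab <- tab %||% ellipse_arc_table(ell)
  per <- tab$s[length(tab$s)]
  s <- s %% per
  stats::approx(tab$s, tab$t, xout = s, ties = "ordered")$y
}

# Rasterize an ellipse into a logical window of the full field; returns
# a logical matrix of dim `shape` (rows, cols). Pixel centers at integer
# 0-based coordinates.
rasterize_ellipse <- function(ell, shape) {
  nr <- shape[1]; nc <- shape[2]
  # bounding box (generous: semi-major in every direction)
  r <- ell$a + 1
  i0 <- max(1L, floor(ell$cy - r) + 1L); i1 <- min(nr, ceiling(ell$cy + r) + 1L)
  j0 <- max(1L, floor(ell$cx - r) + 1L); j1 <- min(nc, ceiling(ell$cx + r) + 1L)
  out <- matrix(FALSE, nr, nc)
  if (i0 > i1 || j0 > j1) return(out)
  ii <- i0:i1; jj <- j0:j1
  y <- ii - 1; x <- jj - 1
  dx <- outer(rep(1, length(y)), x - ell$cx)
  dy <- outer(y - ell$cy, rep(1, length(x)))
  co <- cos(ell$theta); so <- sin(ell$theta)
  u <- (dx * co + dy * so) / ell$a
  v <- (-dx * so + dy * co) / ell$b
  out[ii, jj] <- (u^2 + v^2) <= 1
  out
}

# Bilinear interpolation of image values at fractional 0-based pixel
# coordinates; points outside the image clamp to the border.
bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  j0 <- pmin(floor(x), nc - 2); i0 <- pmin(floor(y), nr - 2)
  fx <- x - j0; fy <- y - i0
  i0 <- i0 + 1; j0 <- j0 + 1  # to 1-based indices
  v00 <- img[cbind(i0, j0)];     v01 <- img[cbind(i0, j0 + 1)]
  v10 <- img[cbind(i0 + 1, j0)]; v11 <- img[cbind(i0 + 1, j0 + 1)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}
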