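#' Kyphosis angle from flexicurve chord and depth
#'
#' Converts a flexicurve measurement -- chord length `L` between the T1 and
#' T12 contour points and maximal sagittal depth `d` of the dorsal curve --
#' into the thoracic kyphosis angle using the circular-arc chord-sagitta
#' relation
#' \deqn{\theta = 2 \arcsin\!\left(\frac{4 d L}{4 d^2 + L^2}\right)}
#' expressed in degrees. The relation is scale invariant: it depends only on
#' the ratio `d / L`, so `L` and `d` may be in centimetres (flexicurve
#' tracings on millimetric paper) or pixels (digitized silhouettes), as long
#' as both share the same unit.
#'
#' @param L chord length, > 0. Vectorized.
#' @param d curve depth (sagitta), in the same unit as `L`; must satisfy
#'   `0 <= d < L/2`. Beyond `L/2` the arcsin branch of the formula is no
#'   longer monotone and the configuration is anatomically meaningless, so
#'   such values are rejected rather than clamped.
#' @return kyphosis angle(s) in degrees, in `[0, 180)`.
#' @examples
#' kyphosis_angle(L = 32, d = 2.1)   # 29.909 degrees
#' kyphosis_angle(L = 28.5, d = 1.5) # 24.036 degrees
#' @seealso [flexicurve_depth()] for the inverse, [chord_depth_from_contour()]
#'   to obtain (L, d) from a digitized dorsal contour.
#' @export
kyphosis_angle <- function(L, d) {
  if (length(L) != length(d))
    stop("`L` and `d` must have equal length", call. = FALSE)
  if (!all(is.finite(L)) || !all(is.finite(d)))
    stop("`L` and `d` must be finite", call. = FALSE)
  if (any(L <= 0))
    stop("chord length `L` must be positive", call. = FALSE)
  if (any(d < 0))
    stop("depth `d` must be non-negative", call. = FALSE)
  if (any(d >= L / 2))
    stop("depth `d` must be below L/2 (arc-model validity bound)",
         call. = FALSE)
  2 * asin(4 * d * L / (4 * d^2 + L^2)) * 180 / pi
}

#' Flexicurve depth for a prescribed kyphosis angle
#'
#' Inverse of [kyphosis_angle()]: the unique depth `d` in `[0, L/2)` such
#' that a circular arc over a chord of length `L` with sagitta `d` subtends
#' the kyphosis angle `theta`. On the valid branch the angle formula reduces
#' to `theta = 4 * atan(2 d / L)`, giving the closed form
#' `d = (L / 2) * tan(theta / 4)`.
#'
#' @param theta kyphosis angle in degrees, in `[0, 180)`. Vectorized.
#' @param L chord length, > 0.
#' @return depth `d` in the unit of `L`.
#' @examples
#' flexicurve_depth(theta = 24.036, L = 28.5)  # ~1.5
#' @export
flexicurve_depth <- function(theta, L) {
  if (!all(is.finite(theta)) || !all(is.finite(L)))
    stop("`theta` and `L` must be finite", call. = FALSE)
  if (any(theta < 0 | theta >= 180))
    stop("`theta` must lie in [0, 180) degrees", call. = FALSE)
  if (any(L <= 0))
    stop("chord length `L` must be positive", call. = FALSE)
  L / 2 * tan(theta * pi / 180 / 4)
}

#' Chord and depth of a digitized dorsal contour
#'
#' Measures the flexicurve parameters on a digitized back contour: `L` is
#' the Euclidean distance between the T1 and T12 points, and `d` is the
#' maximum perpendicular distance from any contour point to the straight
#' T1--T12 chord. For a contour that is a circular arc this maximum equals
#' the arc's sagitta, matching the arc model behind [kyphosis_angle()].
#' Perpendicular distances below `1e-9` are treated as collinear with the
#' chord and reported as depth 0.
#'
#' @param contour two-column matrix (or data frame) of `(x, y)` contour
#'   points, `y` increasing upward.
#' @param p_t1,p_t12 numeric length-2 vectors `(x, y)`: the chord endpoints
#'   at the T1 and T12 levels.
#' @return list with components `L` and `d` (same unit as the coordinates).
#' @export
chord_depth_from_contour <- function(contour, p_t1, p_t12) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 1L || ncol(contour) != 2L)
    stop("`contour` must be a non-empty two-column (x, y) matrix",
         call. = FALSE)
  if (!is.numeric(p_t1) || !is.numeric(p_t12) ||
      length(p_t1) != 2L || length(p_t12) != 2L)
    stop("chord endpoints must be numeric (x, y) pairs", call. = FALSE)
  v <- p_t12 - p_t1
  L <- sqrt(sum(v^2))
  if (L < .Machine$double.eps)
    stop("degenerate chord: T1 and T12 coincide", call. = FALSE)
  # perpendicular distance of each point to the infinite chord line,
  # |cross((p - p_t1), v)| / |v|
  dx <- contour[, 1] - p_t1[1]
  dy <- contour[, 2] - p_t1[2]
  perp <- abs(dx * v[2] - dy * v[1]) / L
  d <- max(perp)
  if (d < 1e-9) d <- 0
  list(L = L, d = d)
}
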