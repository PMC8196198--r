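# Internal geometry helpers. All coordinates are in nm, boxes orthorhombic,
# positions wrapped into [0, box); intramolecular vectors always use the
# minimum-image displacement so wrapped chains stay intact.

#' @keywords internal
wrap_coords <- function(x, box) {
  for (k in 1:3) x[, k] <- x[, k] %% box[k]
  x
}

# Minimum-image displacement b - a (matrices or vectors), per component.
#' @keywords internal
min_image <- function(a, b, box) {
  d <- b - a
  if (is.matrix(d)) {
    for (k in seq_len(ncol(d))) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  } else {
    d <- d - box[seq_along(d)] * round(d / box[seq_along(d)])
  }
  d
}

# Lateral (xy) minimum-image distance matrix between two sets of points.
#' @keywords internal
lateral_dist <- function(p, q, box) {
  dx <- outer(p[, 1], q[, 1], "-")
  dy <- outer(p[, 2], q[, 2], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  sqrt(dx * dx + dy * dy)
}

#' @keywords internal
unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector cannot be normalized", call. = FALSE)
  v / n
}

# Second Legendre polynomial of cos(alpha).
#' @keywords internal
p2 <- function(cos_alpha) 0.5 * (3 * cos_alpha^2 - 1)

# Rows of `m` normalized to unit length.
#' @keywords internal
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  if (any(n < 1e-12)) stop("zero-length vector cannot be normalized", call. = FALSE)
  m / n
}

# Rotate unit vector(s) `d` (one row per vector) by angle delta about a random
# axis perpendicular to d, azimuth phi. Vectorized over rows.
#' @keywords internal
tilt_about <- function(d, delta, phi) {
  # orthonormal frame per row: e1 any unit vector perp to d, e2 = d x e1
  ref <- matrix(rep(c(1, 0, 0), each = nrow(d)), ncol = 3)
  near_x <- abs(d[, 1]) > 0.9
  ref[near_x, ] <- matrix(rep(c(0, 1, 0), each = sum(near_x)), ncol = 3)
  e1 <- ref - d * rowSums(ref * d)
  e1 <- normalize_rows(e1)
  e2 <- cbind(
    d[, 2] * e1[, 3] - d[, 3] * e1[, 2],
    d[, 3] * e1[, 1] - d[, 1] * e1[, 3],
    d[, 1] * e1[, 2] - d[, 2] * e1[, 1]
  )
  w <- cos(phi) * e1 + sin(phi) * e2
  cos(delta) * d + sin(delta) * w
}

#' @keywords internal
deg2rad <- function(x) x * pi / 180

#' @keywords internal
rad2deg <- function(x) x * 180 / pi

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
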