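#' Toroidal arena geometry
#'
#' Spatial arithmetic on a square arena of side `L` with periodic boundary
#' conditions. Positions are continuous coordinates in `[0, L)`; "pixels" are
#' the unit-square lattice cells used only by the coverage metrics. All
#' pairwise displacements use the minimum-image convention, i.e. the shortest
#' of the nine lattice-shifted copies of the displacement vector.
#'
#' @name toroidal-geometry
NULL

#' Wrap coordinates into the arena
#'
#' Maps coordinates onto `[0, L)` by modular arithmetic, so that the returned
#' point is congruent to the input modulo `L` in each component.
#'
#' @param p Numeric vector of length 2 `(x, y)`, or an `n x 2` matrix of
#'   positions (one row per point).
#' @param L Arena side length (positive scalar).
#' @return Object of the same shape as `p` with every coordinate in `[0, L)`.
#' @examples
#' wrap_position(c(201.5, -0.5), 200) # c(1.5, 199.5)
#' @export
wrap_position <- function(p, L) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  if (!all(is.finite(p))) stop("non-finite coordinate in `p`", call. = FALSE)
  p - floor(p / L) * L
}

#' Minimum-image displacement between two positions
#'
#' The displacement from `a` to `b` on the torus, with each component reduced
#' into the half-open interval `[-L/2, L/2)`. `a + torus_delta(a, b, L)` is
#' congruent to `b` modulo `L`. At exactly half the arena the tie is broken
#' toward `-L/2`, which makes the convention deterministic.
#'
#' @param a,b Length-2 numeric vectors or `n x 2` matrices of wrapped
#'   positions. If one argument is a matrix and the other a vector, the
#'   vector is recycled row-wise.
#' @param L Arena side length.
#' @return Displacement(s), same shape as the wider of `a` and `b`.
#' @examples
#' torus_delta(c(0, 0), c(199, 0), 200) # c(-1, 0): wrap-around is shorter
#' @export
torus_delta <- function(a, b, L) {
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("non-finite coordinate", call. = FALSE)
  }
  d <- b - a
  d - floor(d / L + 0.5) * L
}

#' Minimum-image distance
#'
#' Euclidean norm of [torus_delta()]. Symmetric, and never larger than
#' `L * sqrt(2) / 2` (half the arena diagonal).
#'
#' @inheritParams torus_delta
#' @return Scalar distance, or a vector of distances for matrix input.
#' @export
torus_distance <- function(a, b, L) {
  d <- torus_delta(a, b, L)
  if (is.matrix(d)) sqrt(rowSums(d * d)) else sqrt(sum(d * d))
}

#' Normalize a heading angle to [0, 360) degrees
#'
#' Idempotent: `normalize_heading(normalize_heading(x))` equals
#' `normalize_heading(x)`.
#'
#' @param theta Angle(s) in degrees.
#' @return Angle(s) in `[0, 360)`.
#' @export
normalize_heading <- function(theta) {
  theta - floor(theta / 360) * 360
}

#' Convert a heading to a unit vector
#'
#' @param theta Heading(s) in degrees (0 = +x, 90 = +y, counter-clockwise).
#' @return For a scalar, `c(cos, sin)`; for a vector of headings, an
#'   `n x 2` matrix of unit vectors.
#' @export
heading_to_unit <- function(theta) {
  if (!all(is.finite(theta))) stop("non-finite heading", call. = FALSE)
  r <- theta * pi / 180
  if (length(theta) == 1L) c(cos(r), sin(r)) else cbind(cos(r), sin(r))
}

#' Convert a displacement vector to a heading in degrees
#'
#' @param v Length-2 numeric vector (or `n x 2` matrix).
#' @return Heading(s) in `[0, 360)`.
#' @export
unit_to_heading <- function(v) {
  if (is.matrix(v)) {
    normalize_heading(atan2(v[, 2], v[, 1]) * 180 / pi)
  } else {
    normalize_heading(atan2(v[2], v[1]) * 180 / pi)
  }
}

# Pairwise minimum-image distance matrix for row-position matrices.
# Plain O(n^2) double loop: n is ten in practice and the loop mirrors the
# C++ engine's summation order exactly, which keeps the two paths
# bit-comparable.
torus_distance_matrix <- function(pos, L) {
  n <- nrow(pos)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- pos[j, 1] - pos[i, 1]
      dx <- dx - floor(dx / L + 0.5) * L
      dy <- pos[j, 2] - pos[i, 2]
      dy <- dy - floor(dy / L + 0.5) * L
      m[i, j] <- sqrt(dx * dx + dy * dy)
    }
  }
  m
}
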