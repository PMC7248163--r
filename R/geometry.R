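# Minimal 3D geometry: Euclidean distance, oriented plane construction,
# signed point-to-plane distance. The plane orientation is fixed by an
# explicit left-side witness landmark rather than any axis convention, so
# "left = positive" is well defined in an arbitrary rigid frame.

# triangle area below this (mm^2) is treated as collinear; landmark scale is
# ~10-100 mm so this sits far below placement noise
COLLINEAR_TOL <- 1e-6
PLANE_WITNESS_TOL <- 1e-9

#' Euclidean distance between two points
#'
#' @param a,b numeric xyz vectors in mm.
#' @return distance in mm.
#' @export
#' @examples
#' point_distance(c(0, 0, 0), c(3, 4, 0))  # 5
point_distance <- function(a, b) {
  stopifnot(length(a) == 3L, length(b) == 3L)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    validation_error("point_distance: points must be finite")
  sqrt(sum((a - b)^2))
}

#' Oriented plane through three points
#'
#' Constructs the plane containing \code{p1}, \code{p2}, \code{p3} with its
#' unit normal oriented toward \code{left_witness} (so that the witness has a
#' non-negative signed distance). If the left witness lies on the plane within
#' tolerance, orientation falls back to \code{fallback_witness}.
#'
#' @param p1,p2,p3 defining points (non-collinear), xyz in mm.
#' @param left_witness a point on the anatomical left, used to orient the
#'   normal; conventionally Z(L).
#' @param fallback_witness optional second witness (conventionally Po(L)).
#' @return an object of class \code{reference_plane}: list with unit
#'   \code{normal} and scalar \code{offset} such that the signed distance of a
#'   point \code{p} is \code{sum(normal * p) + offset}.
#' @export
plane_from_points <- function(p1, p2, p3, left_witness,
                              fallback_witness = NULL) {
  v1 <- p2 - p1
  v2 <- p3 - p1
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  area <- sqrt(sum(n^2)) / 2
  if (area < COLLINEAR_TOL)
    validation_error("degenerate reference plane: defining points are collinear")
  n <- n / sqrt(sum(n^2))
  offset <- -sum(n * p1)
  sd_w <- sum(n * left_witness) + offset
  if (abs(sd_w) < PLANE_WITNESS_TOL) {
    if (is.null(fallback_witness))
      validation_error("plane orientation ambiguous: witness lies on the plane")
    sd_w <- sum(n * fallback_witness) + offset
    if (abs(sd_w) < PLANE_WITNESS_TOL)
      validation_error("plane orientation ambiguous: all witnesses coplanar with the reference plane")
  }
  if (sd_w < 0) {
    n <- -n
    offset <- -offset
  }
  structure(list(normal = n, offset = offset), class = "reference_plane")
}

#' Signed perpendicular distance from a point to a plane
#'
#' Positive on the side of the left witness that oriented the plane.
#'
#' @param plane a \code{reference_plane}.
#' @param p numeric xyz vector in mm.
#' @return signed distance in mm.
#' @export
signed_plane_distance <- function(plane, p) {
  stopifnot(inherits(plane, "reference_plane"), length(p) == 3L)
  sum(plane$normal * p) + plane$offset
}

#' Midsagittal reference plane of a landmark set
#'
#' The plane through nasion, sella and MidZ (midpoint of the two Z points),
#' oriented so the anatomical left (witness Z(L), falling back to Po(L) if
#' Z(L) is coplanar) has positive signed distance.
#'
#' @param set a \code{landmark_set}.
#' @return a \code{reference_plane}.
#' @export
#' @examples
#' pl <- midsagittal_plane(skull_template())
#' signed_plane_distance(pl, c(6, 70, -100))  # +6, on the left
midsagittal_plane <- function(set) {
  plane_from_points(get_point(set, "N"), get_point(set, "S"),
                    derive_midz(set),
                    left_witness = get_point(set, "Z", "L"),
                    fallback_witness = get_point(set, "Po", "L"))
}
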