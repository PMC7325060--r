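# Hexagonal lattice geometry: axial site addressing (pointy-top), adjacency,
# physical distances under the pixel-to-micron scaling factor, and shortest
# paths. Axial coordinates (q, r) are 0-based; a site lies on the N x N grid
# when 0 <= q < N and 0 <= r < N. Centroid layout: x = delta * (q + r/2),
# y = delta * (sqrt(3)/2) * r, so adjacent centroids are exactly delta apart.

# the six axial neighbour offsets (pointy-top orientation)
HEX_OFFSETS <- cbind(
  q = c(1L, -1L, 0L, 0L, 1L, -1L),
  r = c(0L, 0L, 1L, -1L, -1L, 1L)
)

#' Pixel-to-micron scaling factor
#'
#' One lattice step corresponds to one tumour cell diameter. A span of 500
#' micrometres holds 24 aligned tumour cells, giving delta = 500/24 = 20.83
#' micrometres per lattice step.
#'
#' @return The scaling factor in micrometres per lattice step.
#' @export
#' @examples
#' hex_delta() # 20.83 um
hex_delta <- function() 500 / 24

#' In-grid axial neighbours of a lattice site
#'
#' @param q,r Integer axial coordinates (0-based) of the site.
#' @param n Grid side length; the grid spans coordinates `0 .. n - 1`.
#' @return A tibble with columns `q` and `r`, one row per in-grid neighbour.
#'   Interior sites have exactly six neighbours.
#' @export
#' @examples
#' hex_neighbors(5, 5, 11)  # interior: 6 rows
#' hex_neighbors(0, 0, 11)  # corner: clipped
hex_neighbors <- function(q, r, n) {
  stopifnot(length(q) == 1, length(r) == 1)
  if (q < 0 || r < 0 || q >= n || r >= n) {
    abort(sprintf("site (%d, %d) is off the %d x %d grid", q, r, n, n))
  }
  nq <- q + HEX_OFFSETS[, "q"]
  nr <- r + HEX_OFFSETS[, "r"]
  keep <- nq >= 0 & nq < n & nr >= 0 & nr < n
  tibble(q = as.integer(nq[keep]), r = as.integer(nr[keep]))
}

#' Centroid coordinates of lattice sites
#'
#' @param q,r Axial coordinates (vectorised).
#' @param delta Lattice spacing in micrometres.
#' @return A tibble with columns `x` and `y` in micrometres.
#' @export
hex_centroid <- function(q, r, delta = hex_delta()) {
  tibble(x = delta * (q + r / 2), y = delta * (sqrt(3) / 2) * r)
}

#' Euclidean distance between hexagon centroids
#'
#' @param q1,r1,q2,r2 Axial coordinates of the two sites (vectorised).
#' @param delta Lattice spacing in micrometres.
#' @param n Optional grid side; when given, coordinates are checked to lie
#'   on the grid.
#' @return Distance(s) in micrometres. Adjacent sites are exactly `delta`
#'   apart; 24 steps along one lattice axis span 500 micrometres.
#' @export
#' @examples
#' physical_distance(0, 0, 1, 0)   # 20.83
#' physical_distance(0, 0, 24, 0)  # 500
physical_distance <- function(q1, r1, q2, r2, delta = hex_delta(), n = NULL) {
  if (!is.null(n)) {
    if (any(c(q1, q2, r1, r2) < 0) || any(c(q1, q2, r1, r2) >= n)) {
      abort("coordinates are off the grid")
    }
  }
  dx <- (q2 + r2 / 2) - (q1 + r1 / 2)
  dy <- (sqrt(3) / 2) * (r2 - r1)
  delta * sqrt(dx^2 + dy^2)
}

#' Hex graph distance (lattice steps) between two sites
#'
#' @inheritParams physical_distance
#' @return Integer number of lattice steps.
#' @export
hex_graph_distance <- function(q1, r1, q2, r2) {
  dq <- q2 - q1
  dr <- r2 - r1
  as.integer((abs(dq) + abs(dr) + abs(dq + dr)) / 2)
}

#' Minimum distance from a site to the bone
#'
#' Minimum Euclidean centroid distance between the site and any bone site of
#' the lattice state. Internally an interface-restricted scan is used; it is
#' exact because the nearest bone site always has a non-bone neighbour.
#'
#' @param state A `lattice_state`.
#' @param q,r Axial coordinates of the query site.
#' @param delta Lattice spacing in micrometres.
#' @return Distance in micrometres.
#' @export
min_distance_to_bone <- function(state, q, r, delta = hex_delta()) {
  label <- state_label(state)
  n <- nrow(label)
  if (q < 0 || r < 0 || q >= n || r >= n) abort("query site is off the grid")
  if (!any(label == LBL_BONE)) abort("state contains no bone sites")
  delta * cpp_min_distance_to_bone(label, q, r)
}

#' Minimum distance path to the nearest target site
#'
#' Shortest path in lattice steps (breadth-first-search distance) from a site
#' to the nearest site matching the target predicate. When several shortest
#' paths exist, one is chosen uniformly at random from R's RNG, so a fixed
#' seed gives a reproducible path.
#'
#' @param state A `lattice_state`.
#' @param q,r Axial coordinates of the origin site.
#' @param target `"bone"` or `"non_tumour"`.
#' @return A tibble of `q`, `r` rows from the origin to the target site
#'   (inclusive); the path length in steps is `nrow(.) - 1`.
#' @export
minimum_distance_path <- function(state, q, r, target = c("bone", "non_tumour")) {
  target <- match.arg(target)
  label <- state_label(state)
  n <- nrow(label)
  if (q < 0 || r < 0 || q >= n || r >= n) abort("origin site is off the grid")
  kind <- if (target == "bone") 0L else 1L
  path <- cpp_min_distance_path(label, q, r, kind)
  if (nrow(path) == 0) abort("no reachable target site")
  tibble(q = path[, 1], r = path[, 2])
}
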