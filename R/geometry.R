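# Planar computational geometry for membrane traces.
#
# All public functions operate on coordinates in nanometres (conversion from
# pixels happens exactly once, when a profile is scaled at analysis time).
# Traces are n x 2 matrices of (x, y) vertices; y increases downward (image
# convention), which is irrelevant for Euclidean distances.

#' Coerce and validate a vertex matrix
#'
#' @param xy An n x 2 numeric matrix (or coercible data.frame) of vertices.
#' @param min_vertices Minimum number of vertices required.
#' @return A numeric matrix with consecutive duplicate vertices collapsed.
#' @keywords internal
#' @noRd
as_vertices <- function(xy, min_vertices = 1L) {
  if (is.data.frame(xy)) xy <- as.matrix(xy)
  if (is.numeric(xy) && is.null(dim(xy)) && length(xy) == 2L) {
    xy <- matrix(xy, ncol = 2L)
  }
  if (!is.matrix(xy) || ncol(xy) != 2L || !is.numeric(xy)) {
    stop("vertices must be an n x 2 numeric matrix", call. = FALSE)
  }
  if (anyNA(xy)) stop("vertices contain missing values", call. = FALSE)
  n <- nrow(xy)
  if (n > 1L) {
    dup <- c(FALSE, rowSums(abs(xy[-1L, , drop = FALSE] -
                                  xy[-n, , drop = FALSE])) == 0)
    if (any(dup)) xy <- xy[!dup, , drop = FALSE]
  }
  if (nrow(xy) < min_vertices) {
    stop(sprintf("polyline needs >= %d distinct vertices", min_vertices),
         call. = FALSE)
  }
  xy
}

# close a contour by appending the first vertex if needed
close_ring <- function(xy) {
  if (any(xy[1L, ] != xy[nrow(xy), ])) xy <- rbind(xy, xy[1L, ])
  xy
}

#' Minimum distance from a point to a polyline
#'
#' Computes the minimum Euclidean distance from a point to any segment of an
#' open polyline by perpendicular projection onto each segment (clamped to the
#' segment ends). The trace is treated as a continuous curve, so the result
#' does not depend on how densely the membrane was traced. A vertex-only mode
#' (distance to the traced vertices, ignoring the connecting segments) is
#' provided for cross-validation against legacy outputs.
#'
#' @param p Numeric length-2 point (x, y), in nm.
#' @param line n x 2 matrix of polyline vertices, in nm.
#' @param closed Treat the polyline as a closed ring.
#' @param vertex_only If `TRUE`, measure to vertices instead of segments.
#' @return Minimum distance in nm (non-negative scalar).
#' @examples
#' point_polyline_distance(c(0, 5), rbind(c(0, 0), c(10, 0)))  # 5
#' @export
point_polyline_distance <- function(p, line, closed = FALSE,
                                    vertex_only = FALSE) {
  stopifnot(is.numeric(p), length(p) == 2L, !anyNA(p))
  xy <- as_vertices(line)
  if (nrow(xy) == 1L) {
    warning("degenerate single-point polyline; distance measured to the point")
    return(sqrt(sum((p - xy[1L, ])^2)))
  }
  if (closed) xy <- close_ring(xy)
  if (vertex_only) {
    return(sqrt(min((xy[, 1L] - p[1L])^2 + (xy[, 2L] - p[2L])^2)))
  }
  n <- nrow(xy)
  ax <- xy[-n, 1L]; ay <- xy[-n, 2L]
  dx <- xy[-1L, 1L] - ax; dy <- xy[-1L, 2L] - ay
  len2 <- dx * dx + dy * dy
  t <- ((p[1L] - ax) * dx + (p[2L] - ay) * dy) / len2
  t[!is.finite(t)] <- 0
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx - p[1L]
  qy <- ay + t * dy - p[2L]
  sqrt(min(qx * qx + qy * qy))
}

#' Edge distance from a vesicle to a membrane trace
#'
#' Distance from the outer edge of a vesicle to a membrane: the centre-to-trace
#' minimum distance minus the vesicle radius, floored at zero. A zero edge
#' distance is the geometric definition of a docked vesicle; small overlaps
#' between the circle and the trace (tracing thickness) therefore read as 0
#' rather than as a negative distance.
#'
#' @param center Numeric length-2 vesicle centre (x, y) in nm.
#' @param radius Vesicle radius in nm (> 0).
#' @param line Membrane polyline, n x 2 matrix in nm.
#' @param closed,vertex_only Passed to [point_polyline_distance()].
#' @return Edge distance in nm, `>= 0`.
#' @examples
#' vesicle_edge_distance(c(0, 25), 20, rbind(c(-50, 0), c(50, 0)))  # 5
#' vesicle_edge_distance(c(0, 15), 20, rbind(c(-50, 0), c(50, 0)))  # 0 (docked)
#' @export
vesicle_edge_distance <- function(center, radius, line, closed = FALSE,
                                  vertex_only = FALSE) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0)
  max(0, point_polyline_distance(center, line, closed = closed,
                                 vertex_only = vertex_only) - radius)
}

#' Minimum distance between two polylines
#'
#' Minimum over all segment pairs of the inter-segment distance; 0 if the
#' traces intersect. Used for organelle contours (endosomes, multivesicular
#' bodies) against the plasma or active-zone membrane: many distances from the
#' organelle membrane to the synaptic membrane are evaluated and the minimum
#' reported. For two non-crossing segments the minimum is always attained at a
#' vertex of one of them, so the computation reduces to vertex-to-segment
#' projections in both directions after an intersection test.
#'
#' @param a,b n x 2 vertex matrices in nm.
#' @param closed_a,closed_b Treat `a` / `b` as closed contours.
#' @return Minimum distance in nm (0 when the traces cross or touch).
#' @export
contour_polyline_distance <- function(a, b, closed_a = TRUE,
                                      closed_b = FALSE) {
  av <- as_vertices(a, 2L)
  bv <- as_vertices(b, 2L)
  xs <- polyline_intersections(av, bv, closed_a = closed_a,
                               closed_b = closed_b)
  if (xs$count > 0L) return(0)
  ar <- if (closed_a) close_ring(av) else av
  br <- if (closed_b) close_ring(bv) else bv
  d1 <- min(vapply(seq_len(nrow(av)), function(i)
    point_polyline_distance(av[i, ], br), numeric(1L)))
  d2 <- min(vapply(seq_len(nrow(bv)), function(i)
    point_polyline_distance(bv[i, ], ar), numeric(1L)))
  min(d1, d2)
}

#' Polyline length and contour area
#'
#' `polyline_length()` sums the segment lengths of a trace (the 1-D surface
#' length of a membrane in a section). `contour_area()` computes the enclosed
#' 2-D area of a closed contour by the shoelace formula; a self-intersecting
#' contour still returns the shoelace value, with a warning, since the traced
#' membranes occasionally cross themselves by a pixel.
#'
#' @param line n x 2 vertex matrix in nm.
#' @param closed For `polyline_length()`, include the closing segment.
#' @return Length in nm, or area in nm^2.
#' @examples
#' polyline_length(rbind(c(0, 0), c(3, 4)))              # 5
#' contour_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
polyline_length <- function(line, closed = FALSE) {
  xy <- as_vertices(line, 2L)
  if (closed) xy <- close_ring(xy)
  sum(sqrt(rowSums((xy[-1L, , drop = FALSE] -
                      xy[-nrow(xy), , drop = FALSE])^2)))
}

#' @rdname polyline_length
#' @param check_simple Warn when the contour self-intersects.
#' @export
contour_area <- function(line, check_simple = TRUE) {
  xy <- as_vertices(line, 3L)
  if (check_simple && self_intersects(xy)) {
    warning("self-intersecting contour; area computed by the shoelace formula")
  }
  x <- xy[, 1L]; y <- xy[, 2L]
  n <- nrow(xy)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# does a closed ring cross itself (non-adjacent segment pairs)?
self_intersects <- function(xy) {
  r <- close_ring(xy)
  n <- nrow(r) - 1L
  if (n < 4L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    js <- seq.int(i + 2L, jmax)
    if (length(js) == 0L) next
    hit <- seg_seg_hit(r[i, ], r[i + 1L, ], r[js, , drop = FALSE],
                       r[js + 1L, , drop = FALSE])
    if (any(hit$cross)) return(TRUE)
  }
  FALSE
}

# vectorised segment intersection: segment (p, q) against segments (a_k, b_k);
# returns transversal/touching crossings with intersection coordinates
seg_seg_hit <- function(p, q, a, b, tol = 1e-9) {
  r <- q - p
  sx <- b[, 1L] - a[, 1L]; sy <- b[, 2L] - a[, 2L]
  denom <- r[1L] * sy - r[2L] * sx
  qpx <- a[, 1L] - p[1L]; qpy <- a[, 2L] - p[2L]
  scale <- max(1, abs(p), abs(q), abs(a), abs(b))
  t <- (qpx * sy - qpy * sx) / denom
  u <- (qpx * r[2L] - qpy * r[1L]) / denom
  ok <- abs(denom) > tol * scale &
    t >= -tol & t <= 1 + tol & u >= -tol & u <= 1 + tol
  ok[is.na(ok)] <- FALSE
  list(cross = ok,
       x = p[1L] + t[ok] * r[1L],
       y = p[2L] + t[ok] * r[2L])
}

#' Count intersection points of two polylines
#'
#' Counts transversal segment-segment intersection points between two traces
#' (parallel overlaps are not counted; coincident crossing points are counted
#' once). This supports the membrane-pit location rule: a pit whose trace
#' overlaps the active-zone trace at two points lies within the active zone.
#'
#' @param a,b n x 2 vertex matrices.
#' @param closed_a,closed_b Treat `a` / `b` as closed.
#' @param tol Relative tolerance for coincident-point deduplication.
#' @return A list with `count` and an n x 2 matrix `points`.
#' @export
polyline_intersections <- function(a, b, closed_a = FALSE, closed_b = FALSE,
                                   tol = 1e-7) {
  av <- as_vertices(a, 2L)
  bv <- as_vertices(b, 2L)
  if (closed_a) av <- close_ring(av)
  if (closed_b) bv <- close_ring(bv)
  na <- nrow(av) - 1L
  bs <- bv[-nrow(bv), , drop = FALSE]
  be <- bv[-1L, , drop = FALSE]
  px <- numeric(0L); py <- numeric(0L)
  for (i in seq_len(na)) {
    hit <- seg_seg_hit(av[i, ], av[i + 1L, ], bs, be)
    if (any(hit$cross)) {
      px <- c(px, hit$x); py <- c(py, hit$y)
    }
  }
  if (length(px) == 0L) {
    return(list(count = 0L, points = matrix(numeric(0L), ncol = 2L)))
  }
  scale <- max(1, abs(px), abs(py))
  key <- paste(round(px / (scale * tol)), round(py / (scale * tol)))
  keep <- !duplicated(key)
  list(count = sum(keep), points = cbind(x = px[keep], y = py[keep]))
}

#' Shape metrics of a membrane pit
#'
#' A pit is an inward deflection of the plasma membrane traced as an open
#' polyline. Its base chord is the segment joining the two trace endpoints.
#' The metrics are: `base_width`, the chord length; `depth`, the maximum
#' perpendicular distance from the chord to the trace (the pit height);
#' `fwhm_diameter`, the width of the pit measured parallel to the chord at
#' half the depth, with linear interpolation between the half-depth crossings
#' (the outermost pair when the profile crosses half depth more than twice);
#' and `arc_length`, the traced membrane length. Measuring the diameter at
#' full-width half-maximum makes it robust to how far down the neck the
#' annotator traced, and measuring parallel to the chord (not the image axes)
#' makes all metrics rotation invariant.
#'
#' @param line Open polyline of the pit, n x 2 matrix in nm, `>= 3` vertices.
#' @return An object of class `pit_metrics`: list with `depth`, `base_width`,
#'   `fwhm_diameter`, `arc_length`, all in nm.
#' @examples
#' pit_metrics(rbind(c(0, 0), c(10, 10), c(20, 0)))
#' @export
pit_metrics <- function(line) {
  xy <- as_vertices(line, 3L)
  p0 <- xy[1L, ]; p1 <- xy[nrow(xy), ]
  chord <- p1 - p0
  L <- sqrt(sum(chord^2))
  if (L == 0) stop("pit endpoints coincide; base chord undefined", call. = FALSE)
  u_hat <- chord / L
  n_hat <- c(-u_hat[2L], u_hat[1L])
  rel <- sweep(xy, 2L, p0)
  u <- rel %*% u_hat
  h <- rel %*% n_hat
  side <- sign(h[which.max(abs(h))])
  h <- h * side
  depth <- max(h)
  scale <- max(L, abs(h))
  if (depth <= 1e-9 * scale) stop("flat pit: trace lies on its base chord",
                                  call. = FALSE)
  half <- depth / 2
  crossings <- numeric(0L)
  for (i in seq_len(nrow(xy) - 1L)) {
    h1 <- h[i]; h2 <- h[i + 1L]
    if ((h1 - half) * (h2 - half) < 0) {
      crossings <- c(crossings, u[i] + (half - h1) / (h2 - h1) * (u[i + 1L] - u[i]))
    } else if (h1 == half) {
      crossings <- c(crossings, u[i])
    }
  }
  if (h[nrow(xy)] == half) crossings <- c(crossings, u[nrow(xy)])
  fwhm <- if (length(crossings) >= 2L) max(crossings) - min(crossings) else NA_real_
  structure(list(depth = depth, base_width = L, fwhm_diameter = fwhm,
                 arc_length = polyline_length(xy)),
            class = "pit_metrics")
}

#' @export
print.pit_metrics <- function(x, ...) {
  cat(sprintf(
    "pit: depth %.2f nm, base %.2f nm, FWHM %.2f nm, arc %.2f nm\n",
    x$depth, x$base_width, x$fwhm_diameter, x$arc_length))
  invisible(x)
}
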