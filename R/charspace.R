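## Characteristic-space analysis: per-window acceleration summaries in the
## (a_max, a_avg) plane, cluster polygons, and the boundary-intersection
## region-overlap test.
##
## Clusters of different exercises occupy separate regions of the
## characteristic space; whether two cluster polygons overlap is decided by
## testing their boundary segments for intersection (slope / intersection
## formulas with strict interval containment), extended with a
## vertex-containment test so that a region fully inside another is not
## missed.

#' Per-window characteristic points
#'
#' For each window, the maximum and the mean of one acceleration component
#' over its 200 samples.
#'
#' @param windows a `motion_windows` object.
#' @param axis `"ax"`, `"ay"` or `"az"` (default; the plane shown for the
#'   published clusters is the z-axis).
#' @return data frame with columns `a_max`, `a_avg`, `label`.
#' @export
char_points <- function(windows, axis = c("az", "ax", "ay")) {
  axis <- match.arg(axis)
  if (!length(windows)) stop_contract("char_points requires windows")
  k <- match(axis, c("ax", "ay", "az"))
  rows <- ((k - 1L) * windows$ticks + 1L):(k * windows$ticks)
  block <- windows$values[rows, , drop = FALSE]
  data.frame(a_max = apply(block, 2L, max),
             a_avg = colMeans(block),
             label = windows$label)
}

#' Cluster region polygon
#'
#' @param vertices two-column matrix (or data frame) of ordered polygon
#'   vertices in the `(a_max, a_avg)` plane; at least 3, non-degenerate.
#' @param label exercise label (optional).
#' @return an object of class `cluster_region`.
#' @export
cluster_region <- function(vertices, label = NA) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L || ncol(v) != 2L)
    stop_contract("a cluster region needs >= 3 two-dimensional vertices")
  area2 <- sum(v[, 1] * v[c(2:nrow(v), 1), 2] - v[c(2:nrow(v), 1), 1] * v[, 2])
  if (abs(area2) < 1e-12)
    stop_contract("degenerate (zero-area) cluster region")
  structure(list(vertices = v, label = label), class = "cluster_region")
}

#' Convex-hull cluster region of labelled characteristic points
#'
#' Hull construction is plumbing around the published eyeballed clusters:
#' the region of one exercise is the convex hull of its points.
#'
#' @param points data frame from [char_points()].
#' @param label exercise whose points form the region.
#' @return a [cluster_region()].
#' @export
hull_region <- function(points, label) {
  p <- points[points$label == label, c("a_max", "a_avg")]
  if (nrow(p) < 3L) stop_contract("need >= 3 points for a hull region")
  h <- grDevices::chull(p$a_max, p$a_avg)
  cluster_region(as.matrix(p[h, ]), label = label)
}

#' Intersection point of two boundary segments
#'
#' Implements the slope / intersection-point formulas for the supporting
#' lines of segments `(p_i, p_j)` and `(p_m, p_n)`, returning the point
#' only when it lies strictly inside both segments' coordinate intervals
#' (the containment conditions, applied after normalizing each interval to
#' min/max order so descending-coordinate segments work).  A vertical
#' segment (infinite slope) is handled by the general two-line form rather
#' than an error; parallel segments return `NULL`.
#'
#' @param p_i,p_j,p_m,p_n numeric 2-vectors, segment endpoints; endpoints
#'   of a segment must be distinct.
#' @return the intersection point `c(x0, y0)`, or `NULL`.
#' @export
segment_intersection <- function(p_i, p_j, p_m, p_n) {
  if (all(p_i == p_j) || all(p_m == p_n))
    stop_contract("segment endpoints must be distinct")
  d1 <- p_j - p_i
  d2 <- p_n - p_m
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-14) return(NULL)        # equal slopes: parallel
  ## general two-line form (reduces to the slope formulas when both
  ## slopes exist): p_i + s*d1 = p_m + u*d2
  s <- ((p_m[1] - p_i[1]) * d2[2] - (p_m[2] - p_i[2]) * d2[1]) / den
  pt <- p_i + s * d1
  inside <- function(a, b, v) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    ok <- TRUE
    for (k in 1:2) {
      if (hi[k] - lo[k] > 1e-12) ok <- ok && (pt[k] > lo[k] && pt[k] < hi[k])
      else ok <- ok && (abs(pt[k] - lo[k]) <= 1e-12)  # degenerate interval
    }
    ok
  }
  if (inside(p_i, p_j) && inside(p_m, p_n)) pt else NULL
}

## Strict point-in-polygon by ray casting; boundary points count as outside.
point_in_polygon <- function(pt, vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  n <- nrow(vertices)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    ## on-edge check
    d <- c(x[j] - x[i], y[j] - y[i])
    w <- c(pt[1] - x[i], pt[2] - y[i])
    cr <- d[1] * w[2] - d[2] * w[1]
    if (abs(cr) < 1e-12 &&
        pt[1] >= min(x[i], x[j]) - 1e-12 && pt[1] <= max(x[i], x[j]) + 1e-12 &&
        pt[2] >= min(y[i], y[j]) - 1e-12 && pt[2] <= max(y[i], y[j]) + 1e-12)
      return(FALSE)
    if ((y[i] > pt[2]) != (y[j] > pt[2])) {
      xi <- x[i] + (pt[2] - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
      if (pt[1] < xi) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Do two cluster regions overlap?
#'
#' `TRUE` iff any pair of boundary segments intersects (per
#' [segment_intersection()]), or one polygon's vertex or centroid lies
#' strictly inside the other.  The containment extension catches full
#' containment (and coincident regions, whose boundaries are parallel
#' everywhere), which a boundary-only test would miss.
#'
#' @param a,b [cluster_region()] objects.
#' @return logical.
#' @export
regions_overlap <- function(a, b) {
  if (!inherits(a, "cluster_region") || !inherits(b, "cluster_region"))
    stop_contract("regions_overlap expects cluster_region objects")
  va <- a$vertices; vb <- b$vertices
  ea <- cbind(seq_len(nrow(va)), c(2:nrow(va), 1L))
  eb <- cbind(seq_len(nrow(vb)), c(2:nrow(vb), 1L))
  for (i in seq_len(nrow(ea))) {
    for (j in seq_len(nrow(eb))) {
      pt <- segment_intersection(va[ea[i, 1], ], va[ea[i, 2], ],
                                 vb[eb[j, 1], ], vb[eb[j, 2], ])
      if (!is.null(pt)) return(TRUE)
    }
  }
  for (i in seq_len(nrow(va)))
    if (point_in_polygon(va[i, ], vb)) return(TRUE)
  for (j in seq_len(nrow(vb)))
    if (point_in_polygon(vb[j, ], va)) return(TRUE)
  point_in_polygon(colMeans(va), vb) || point_in_polygon(colMeans(vb), va)
}

#' Export regions / characteristic points
#'
#' @param points data frame from [char_points()].
#' @param region a [cluster_region()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_char_points <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_char_points
#' @export
write_region <- function(region, path) {
  jsonlite::write_json(list(label = region$label,
                            vertices = apply(region$vertices, 1L, c,
                                             simplify = FALSE)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
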