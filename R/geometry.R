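# Internal planar polygon utilities. Polygons are n x 2 matrices of vertex
# coordinates (columns x, y), stored counter-clockwise, first vertex not
# repeated at the end.

#' Signed area of a polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param v An n x 2 numeric matrix of vertices (x, y), n >= 3.
#' @return Signed area in squared coordinate units.
#' @keywords internal
#' @noRd
signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' @noRd
polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(v))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Area-integral second moments about the centroid; returns the 2x2
# covariance matrix of the uniform distribution over the polygon interior.
#' @noRd
polygon_covariance <- function(v) {
  c0 <- polygon_centroid(v)
  x <- v[, 1] - c0[1]; y <- v[, 2] - c0[2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  ixx <- sum(cr * (x^2 + x * xn + xn^2)) / 12
  iyy <- sum(cr * (y^2 + y * yn + yn^2)) / 12
  ixy <- sum(cr * (2 * x * y + x * yn + xn * y + 2 * xn * yn)) / 24
  matrix(c(ixx, ixy, ixy, iyy), 2, 2) / a
}

# Segment-intersection test for polygon simplicity. O(n^2); cells have few
# vertices so this is never a bottleneck.
#' @noRd
is_simple_polygon <- function(v) {
  n <- nrow(v)
  if (n < 3) return(FALSE)
  seg <- function(i) rbind(v[i, ], v[if (i == n) 1 else i + 1, ])
  orient <- function(p, q, r) {
    (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  }
  intersects <- function(a, b) {
    d1 <- orient(b[1, ], b[2, ], a[1, ])
    d2 <- orient(b[1, ], b[2, ], a[2, ])
    d3 <- orient(a[1, ], a[2, ], b[1, ])
    d4 <- orient(a[1, ], a[2, ], b[2, ])
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (j > n) next
      if (intersects(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

# Split a polygon by the infinite line through `point` with direction `dir`.
# Assumes the line crosses the boundary at exactly two edges (true for
# convex and mildly non-convex cells); returns NULL when it does not.
# Each half keeps the original vertex indices it contains; the two new
# vertices are appended with index NA and their coordinates + host edges
# reported so callers can register them as shared junctions.
#' @noRd
split_polygon_by_line <- function(v, point, dir, min_fatness = 0.1) {
  n <- nrow(v)
  nrm <- c(-dir[2], dir[1])
  s <- (v[, 1] - point[1]) * nrm[1] + (v[, 2] - point[2]) * nrm[2]
  scale <- max(abs(s), 1e-12)
  if (any(abs(s) < 1e-9 * scale)) return(NULL)   # vertex on line: caller jitters
  sn <- c(s[-1], s[1])
  cross_idx <- which(s * sn < 0)
  if (length(cross_idx) != 2) return(NULL)
  cuts <- lapply(cross_idx, function(i) {
    j <- if (i == n) 1 else i + 1
    t <- s[i] / (s[i] - s[j])
    list(edge = c(i, j), t = t, pt = v[i, ] + t * (v[j, ] - v[i, ]))
  })
  # refuse cuts grazing an existing junction: slivers destabilise later steps
  if (any(vapply(cuts, function(cu) cu$t < 0.05 || cu$t > 0.95, logical(1)))) {
    return(NULL)
  }
  build_side <- function(positive) {
    idx <- integer(0); pts <- NULL
    for (i in seq_len(n)) {
      if ((s[i] > 0) == positive) {
        idx <- c(idx, i); pts <- rbind(pts, v[i, ])
      }
      ci <- which(cross_idx == i)
      if (length(ci) == 1) {
        idx <- c(idx, -ci)   # negative marks cut point ci
        pts <- rbind(pts, cuts[[ci]]$pt)
      }
    }
    list(idx = idx, pts = pts)
  }
  a <- build_side(TRUE); b <- build_side(FALSE)
  if (nrow(a$pts) < 3 || nrow(b$pts) < 3) return(NULL)
  tot <- abs(signed_area(v))
  fatness <- function(p) {
    n <- nrow(p)
    e2 <- max(rowSums((p[c(2:n, 1), , drop = FALSE] - p)^2))
    abs(signed_area(p)) / e2
  }
  # refuse grossly unequal splits and sliver daughters (thin polygons are
  # numerically fragile under later smooth deformation)
  if (abs(signed_area(a$pts)) < 0.05 * tot ||
      abs(signed_area(b$pts)) < 0.05 * tot ||
      fatness(a$pts) < min_fatness || fatness(b$pts) < min_fatness) {
    return(NULL)
  }
  list(halves = list(a, b), cuts = cuts)
}

#' @noRd
point_on_segment <- function(p, a, b, tol = 1e-9) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(FALSE)
  t <- sum((p - a) * ab) / len2
  if (t < -tol || t > 1 + tol) return(FALSE)
  perp <- p - (a + t * ab)
  sqrt(sum(perp^2)) < tol * max(1, sqrt(len2))
}
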