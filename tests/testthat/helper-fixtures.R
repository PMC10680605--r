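# Hand-built micro-tissues used across the test files.

# Unit-square cell grid: two rows of quads sharing junctions, like
# make_initial_tissue(grid, jitter = 0) but fully explicit.
square_cell <- function(label, x0, y0, size = 1, jids) {
  cell_polygon(label,
               rbind(c(x0, y0), c(x0 + size, y0),
                     c(x0 + size, y0 + size), c(x0, y0 + size)),
               jids)
}

# 1 x 2 tissue: cells 1 (left) and 2 (right) sharing junctions 2 and 5.
two_cell_snapshot <- function(time_h = 0) {
  tissue_snapshot(list(
    square_cell(1, 0, 0, 1, c(1, 2, 5, 4)),
    square_cell(2, 1, 0, 1, c(2, 3, 6, 5))
  ), time_h)
}

# Three unit cells in a row (labels 1, 2, 3), shared junctions on shared
# walls, centroids one unit apart.
chain_snapshot <- function(time_h = 0) {
  tissue_snapshot(list(
    square_cell(1, 0, 0, 1, c(1, 2, 12, 11)),
    square_cell(2, 1, 0, 1, c(2, 3, 13, 12)),
    square_cell(3, 2, 0, 1, c(3, 4, 14, 13))
  ), time_h)
}

# A minimal 2-snapshot series: cell 1 persists, cell 2 divides into 3, 4.
# Later cells are uniformly scaled by sqrt(2) in both axes (area x2).
division_series <- function() {
  early <- two_cell_snapshot(0)
  k <- sqrt(2)
  late <- tissue_snapshot(list(
    cell_polygon(1, k * rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                 c(1, 2, 5, 4)),
    cell_polygon(3, k * rbind(c(1, 0), c(1.5, 0), c(1.5, 1), c(1, 1)),
                 c(2, 7, 8, 5)),
    cell_polygon(4, k * rbind(c(1.5, 0), c(2, 0), c(2, 1), c(1.5, 1)),
                 c(7, 3, 6, 8))
  ), 24)
  tissue_series(list(early, late),
                list(parent_map(c(1, 3, 4), c(1, 2, 2), 0, 24)))
}

# Closed polygon approximating a circle.
circle_contour <- function(r = 1, n = 256, centre = c(0, 0), phase = 0) {
  th <- phase + seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

# A blob-like smooth closed contour with low-order radial harmonics, so
# shapes have a well-defined principal axis.
blob_contour <- function(n = 256, amp = c(0.25, 0.1), phase = c(0, 1),
                         elong = 1.6) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- 1 + amp[1] * cos(2 * th + phase[1]) + amp[2] * cos(3 * th + phase[2])
  cbind(r * cos(th), elong * r * sin(th))
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
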