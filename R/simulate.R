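# Synthetic growing-tissue simulator.
#
# The simulator instantiates the spatiotemporal-averaging picture of sepal
# growth: a basipetal band of fast areal growth sweeps from the distal tip
# toward the proximal base over successive 24 h steps, on top of which each
# cell draws multiplicative log-normal growth noise with a controllable
# spatial correlation length and AR(1) temporal persistence. Resampled noise
# (persistence 0) averages out over the series, wild-type style; persistent,
# spatially coarse noise accumulates into patchy cumulative growth,
# ftsh4 style. Division is threshold-triggered and modulated by a rate
# factor kappa that leaves growth untouched (the central premise being that
# changing division does not change growth); a fixed fraction of starting
# cells are never-dividing giant cells.

#' Simulation configuration
#'
#' @param n_steps Number of 24 h growth steps (default 5, i.e. 6 snapshots).
#' @param grid `c(n_rows, n_cols)` of the initial cell lattice; rows run
#'   along the proximal-distal (y) axis.
#' @param spacing Lattice pitch in um. The default 10 um gives 100 um^2
#'   starting cells, matching typical early sepal epidermal cell areas.
#' @param jitter Vertex jitter as a fraction of `spacing`.
#' @param band_peak Peak excess areal growth per step at the band centre
#'   (dimensionless; 1 means growth ratio up to 2 at the centre).
#' @param band_width Gaussian half-width of the band, in cell rows.
#' @param band_speed Rows per step the band centre moves tip -> base.
#' @param noise_sd SD of the zero-mean Gaussian log-growth noise.
#' @param corr_len Spatial correlation length of the noise, in cell
#'   diameters (1 = near-independent cells, larger = patchy).
#' @param persistence AR(1) temporal autocorrelation rho of the noise in
#'   `[0, 1]`: 0 resamples every step (wild-type-like), near 1 keeps each
#'   cell's anomaly for the whole series (ftsh4-like).
#' @param pd_bias Fraction beta of each cell's log-area growth realised
#'   along the proximal-distal axis (0.5 = isotropic).
#' @param kappa Division-rate modifier: cells divide when area exceeds
#'   `a_div / kappa`, so kappa < 1 suppresses division (LGO-overexpression
#'   -like) and kappa > 1 promotes it (lgo-like).
#' @param p_giant Probability a starting cell is a never-dividing giant.
#' @param a_div Division area threshold in um^2 at kappa = 1.
#' @param kernel_bw Bandwidth of the vertex-displacement smoothing kernel,
#'   in cell diameters (numerical smoothness parameter).
#' @param seed RNG seed for the single simulation stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_steps = 5,
                       grid = c(12, 10),
                       spacing = 10,
                       jitter = 0.15,
                       band_peak = 1,
                       band_width = 1.5,
                       band_speed = 2,
                       noise_sd = 0.3,
                       corr_len = 1,
                       persistence = 0,
                       pd_bias = 0.6,
                       kappa = 1,
                       p_giant = 0.1,
                       a_div = 200,
                       kernel_bw = 1.75,
                       seed = 1) {
  cfg <- list(n_steps = n_steps, grid = as.integer(grid), spacing = spacing,
              jitter = jitter, band_peak = band_peak, band_width = band_width,
              band_speed = band_speed, noise_sd = noise_sd,
              corr_len = corr_len, persistence = persistence,
              pd_bias = pd_bias, kappa = kappa, p_giant = p_giant,
              a_div = a_div, kernel_bw = kernel_bw, seed = seed)
  stopifnot(length(cfg$grid) == 2, all(cfg$grid >= 2),
            cfg$n_steps >= 1, cfg$jitter >= 0, cfg$band_peak >= 0,
            cfg$band_width > 0, cfg$noise_sd >= 0, cfg$corr_len > 0,
            cfg$persistence >= 0, cfg$persistence <= 1,
            cfg$pd_bias >= 0, cfg$pd_bias <= 1, cfg$kappa > 0,
            cfg$p_giant >= 0, cfg$p_giant <= 1, cfg$a_div > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_steps, "steps,", x$grid[1], "x", x$grid[2],
      "start grid, rho =", x$persistence, ", L =", x$corr_len,
      ", kappa =", x$kappa, ", seed =", x$seed, "\n")
  invisible(x)
}

#' Build the initial jittered cell lattice
#'
#' Tessellates a rectangle into `n_rows` x `n_cols` quadrilateral cells with
#' shared junction identifiers on shared corners. Interior lattice nodes are
#' jittered in both coordinates, boundary nodes only along their edge, and
#' corners stay fixed, so the cells always tile the rectangle exactly. If
#' the jitter inverts a cell the whole tessellation is retried at half the
#' jitter, with a warning.
#'
#' @param grid `c(n_rows, n_cols)`, both >= 2.
#' @param jitter Fraction of the lattice spacing.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param spacing Lattice pitch in um.
#' @return A [tissue_snapshot()] at `time_h = 0`.
#' @export
make_initial_tissue <- function(grid, jitter = 0, seed = NULL, spacing = 10) {
  stopifnot(length(grid) == 2, all(grid >= 2))
  if (!is.null(seed)) set.seed(seed)
  nr <- grid[1]; nc <- grid[2]
  for (attempt in 1:6) {
    nodes <- node_lattice(nr, nc, spacing, jitter)
    cells <- vector("list", nr * nc)
    ok <- TRUE
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        jid <- c(node_id(r, c, nc), node_id(r, c + 1, nc),
                 node_id(r + 1, c + 1, nc), node_id(r + 1, c, nc))
        v <- nodes[jid, , drop = FALSE]
        if (signed_area(v) <= 0 || !is_simple_polygon(v)) { ok <- FALSE; break }
        cells[[(r - 1) * nc + c]] <-
          cell_polygon((r - 1) * nc + c, v, jid)
      }
      if (!ok) break
    }
    if (ok) return(tissue_snapshot(cells, 0))
    warning("jitter ", jitter, " inverted a cell; retrying at ", jitter / 2,
            call. = FALSE)
    jitter <- jitter / 2
  }
  stop("could not build a valid initial tissue", call. = FALSE)
}

#' @noRd
node_id <- function(r, c, nc) (r - 1L) * (nc + 1L) + c

#' @noRd
node_lattice <- function(nr, nc, spacing, jitter) {
  gx <- rep(0:nc, times = nr + 1) * spacing
  gy <- rep(0:nr, each = nc + 1) * spacing
  n <- length(gx)
  dx <- stats::runif(n, -0.5, 0.5) * jitter * spacing
  dy <- stats::runif(n, -0.5, 0.5) * jitter * spacing
  on_left <- gx == 0; on_right <- gx == nc * spacing
  on_bot <- gy == 0; on_top <- gy == nr * spacing
  dx[on_left | on_right] <- 0
  dy[on_bot | on_top] <- 0
  cbind(gx + dx, gy + dy)
}

#' Sample one step's per-cell growth field
#'
#' The target areal growth ratio of cell c at step t is
#' `g = (1 + A * exp(-(row - mu_t)^2 / (2 sigma^2))) * exp(eps)`, where
#' `row` is the cell centroid's position along the proximal-distal axis in
#' units of initial cell rows, `mu_t = n_rows - band_speed * t` moves
#' basipetally, and `eps` is a zero-mean Gaussian log-noise field with
#' marginal SD `noise_sd`, spatial correlation length `corr_len` cell
#' diameters and AR(1) temporal persistence `rho`
#' (`eps_t = rho * eps_{t-1} + sqrt(1 - rho^2) * eta_t`).
#'
#' @param snapshot Current [tissue_snapshot()].
#' @param config A [sim_config()].
#' @param step 0-based step index.
#' @param prev_noise Named numeric vector of the previous step's noise,
#'   already mapped onto this snapshot's labels (daughters inherit their
#'   parent's value), or `NULL` for the first step.
#' @return A list with named vectors `g` (target ratios), `noise` (the new
#'   eps state) and `band` (the deterministic band factor).
#' @export
sample_growth_field <- function(snapshot, config, step, prev_noise = NULL) {
  cen <- cell_centroids(snapshot)
  labs <- as.character(cen$label)
  nr <- config$grid[1]
  yr <- range(cen$y)
  row_pos <- if (yr[2] > yr[1]) (cen$y - yr[1]) / (yr[2] - yr[1]) * nr else 0
  mu <- nr - config$band_speed * step
  band <- 1 + config$band_peak *
    exp(-(row_pos - mu)^2 / (2 * config$band_width^2))

  n <- nrow(cen)
  if (config$noise_sd > 0) {
    # smoothing iid noise with a Gaussian kernel of bandwidth l yields a
    # field whose correlation function is exp(-d^2 / (4 l^2)); taking
    # l = corr_len / sqrt(2) cell diameters makes corr_len the field's
    # actual correlation length: corr(d) = exp(-d^2 / (2 corr_len^2))
    ell <- config$corr_len / sqrt(2) * sqrt(stats::median(cen$area))
    d2 <- outer(cen$x, cen$x, "-")^2 + outer(cen$y, cen$y, "-")^2
    k <- exp(-d2 / (2 * ell^2))
    w <- k / sqrt(rowSums(k^2))
    eta <- as.numeric(w %*% stats::rnorm(n)) * config$noise_sd
  } else {
    eta <- numeric(n)
  }
  rho <- config$persistence
  if (!is.null(prev_noise) && rho > 0) {
    prev <- prev_noise[labs]
    prev[is.na(prev)] <- 0
    eps <- rho * prev + sqrt(1 - rho^2) * eta
  } else {
    eps <- eta
  }
  g <- band * exp(eps)
  names(g) <- labs; names(eps) <- labs; names(band) <- labs
  list(g = g, noise = eps, band = band)
}

# Kernel-interpolated log-stretch field evaluated at arbitrary points.
# centers: cell centroids; lv: per-cell log stretch; bw in um.
#' @noRd
kernel_field <- function(px, py, cx, cy, lv, bw) {
  d2 <- outer(px, cx, "-")^2 + outer(py, cy, "-")^2
  w <- exp(-d2 / (2 * bw^2))
  as.numeric((w %*% lv) / rowSums(w))
}

#' Grow and divide a tissue for one step
#'
#' Vertices are displaced by a smooth map whose local stretch approximates
#' each cell's target areal growth ratio, with fraction `pd_bias` of the
#' log-area growth realised along the proximal-distal (y) axis. The per-axis
#' log stretches are kernel-interpolated from cell centroids and integrated
#' coordinate-wise, so shared junctions move once and the tessellation stays
#' crack-free; exact per-cell realisation is not attempted (the realised
#' ratio tracks the target with a median relative error well under 5% for
#' smooth fields). After growth, every non-giant cell whose area exceeds
#' `a_div / kappa` divides once along the shortest wall through its centroid
#' perpendicular to its longest principal axis (with a +/-5 degree plane
#' jitter); daughters receive fresh labels and the two cut junctions are
#' inserted into the abutting neighbour walls.
#'
#' @param snapshot Current [tissue_snapshot()].
#' @param field Output of [sample_growth_field()].
#' @param config A [sim_config()].
#' @param giant Integer labels of never-dividing giant cells.
#' @param next_time Time in hours of the produced snapshot.
#' @return A list with the next [tissue_snapshot()] and the interval's
#'   [parent_map()].
#' @export
step_tissue <- function(snapshot, field, config, giant = integer(),
                        next_time = snapshot$time_h + 24) {
  cen <- cell_centroids(snapshot)
  g <- field$g[as.character(cen$label)]
  if (any(!is.finite(g) | g <= 0)) stop("growth field must be positive finite")
  bw <- config$kernel_bw * sqrt(stats::median(cen$area))

  # unique junction table
  jid <- unlist(lapply(snapshot$cells, function(c) c$junction_ids))
  jxy <- do.call(rbind, lapply(snapshot$cells, function(c) c$vertices))
  keep <- !duplicated(jid)
  jid <- jid[keep]; jxy <- jxy[keep, , drop = FALSE]

  # fixed-point refinement: the correction passes through the same
  # smoothing kernel, so growth structure coarser than the kernel scale is
  # realised accurately while sub-kernel-scale fluctuations remain
  # mechanically filtered by the shared-wall coupling
  lg <- log(g)
  cell_idx <- lapply(snapshot$cells, function(c) match(c$junction_ids, jid))
  cell_area <- function(xy) {
    vapply(cell_idx, function(ix) signed_area(xy[ix, , drop = FALSE]),
           numeric(1))
  }
  base_xy <- new_xy <- displace_junctions(jxy, cen, lg, 1 - config$pd_bias, bw)
  for (it in 1:6) {
    realized <- cell_area(new_xy) / cen$area
    realized[!is.finite(realized) | realized <= 0] <- NA
    delta <- log(g) - log(realized)
    delta[is.na(delta)] <- 0
    # damped update with the cumulative correction clamped: structure the
    # kernel cannot express (sub-kernel scales need unbounded
    # amplification) is left filtered rather than chased
    lg <- log(g) + pmin(pmax(lg + 0.8 * delta - log(g), -0.35), 0.35)
    new_xy <- displace_junctions(jxy, cen, lg, 1 - config$pd_bias, bw)
  }
  # the damped correction can rarely still fold a sliver cell; the
  # uncorrected map has a strictly positive Jacobian, so fall back to it
  if (min(cell_area(new_xy)) <= 0) new_xy <- base_xy
  # near-collinear wall vertices can poke through a thin cell under the
  # curved map: straighten them in place (a junction move, so the tiling
  # stays consistent)
  new_xy <- untangle_junctions(snapshot, jid, new_xy)
  ok <- min(cell_area(new_xy)) > 0 &&
    all(vapply(snapshot$cells, function(c) {
      is_simple_polygon(new_xy[match(c$junction_ids, jid), , drop = FALSE])
    }, logical(1)))
  if (!ok) {
    # last resort: a global affine stretch can neither fold nor tangle
    sx <- exp(mean((1 - config$pd_bias) * log(g)))
    sy <- exp(mean(config$pd_bias * log(g)))
    x0 <- min(jxy[, 1]); y0 <- min(jxy[, 2])
    new_xy <- cbind(x0 + (jxy[, 1] - x0) * sx, y0 + (jxy[, 2] - y0) * sy)
  }
  pos <- function(ids) new_xy[match(ids, jid), , drop = FALSE]

  grown <- lapply(snapshot$cells, function(c) {
    v <- pos(c$junction_ids)
    if (signed_area(v) <= 0) {
      stop("polygon inversion at cell ", c$label, " during growth step",
           call. = FALSE)
    }
    list(label = c$label, vertices = v, junction_ids = c$junction_ids)
  })

  # division pass
  next_jid <- max(jid) + 1L
  next_lab <- max(cen$label) + 1L
  labels_now <- vapply(grown, function(c) c$label, integer(1))
  areas <- vapply(grown, function(c) signed_area(c$vertices), numeric(1))
  thr <- config$a_div / config$kappa
  to_divide <- labels_now[areas > thr & !(labels_now %in% giant)]
  to_divide <- sort(to_divide)

  work <- grown
  names(work) <- labels_now
  child <- integer(); parent <- integer()

  # junction-id -> cell-name index so cut points are registered on the
  # abutting neighbour walls without scanning every cell per division
  jindex <- new.env(parent = emptyenv())
  for (nm in names(work)) {
    for (j in work[[nm]]$junction_ids) {
      key <- as.character(j)
      jindex[[key]] <- c(jindex[[key]], nm)
    }
  }

  for (lab in to_divide) {
    cl <- work[[as.character(lab)]]
    res <- try_split(cl$vertices)
    if (is.null(res)) next   # degenerate geometry: skip this division
    ids1 <- next_jid; ids2 <- next_jid + 1L; next_jid <- next_jid + 2L
    halves <- lapply(res$halves, function(h) {
      jids <- ifelse(h$idx > 0, cl$junction_ids[pmax(h$idx, 1)],
                     c(ids1, ids2)[pmax(-h$idx, 1)])
      list(vertices = h$pts, junction_ids = as.integer(jids))
    })
    for (ci in 1:2) {
      e <- res$cuts[[ci]]$edge
      pair <- cl$junction_ids[e]
      newid <- c(ids1, ids2)[ci]
      cand <- setdiff(intersect(jindex[[as.character(pair[1])]],
                                jindex[[as.character(pair[2])]]),
                      as.character(lab))
      for (nm in cand) {
        upd <- insert_junction_one(work[[nm]], pair, newid,
                                   res$cuts[[ci]]$pt)
        if (!is.null(upd)) {
          work[[nm]] <- upd
          key <- as.character(newid)
          jindex[[key]] <- c(jindex[[key]], nm)
        }
      }
    }
    d1 <- next_lab; d2 <- next_lab + 1L; next_lab <- next_lab + 2L
    work[[as.character(lab)]] <- NULL
    work[[as.character(d1)]] <- c(halves[[1]], list(label = d1))
    work[[as.character(d2)]] <- c(halves[[2]], list(label = d2))
    for (di in c(d1, d2)) {
      dc <- work[[as.character(di)]]
      for (j in dc$junction_ids) {
        key <- as.character(j)
        jindex[[key]] <- c(setdiff(jindex[[key]], as.character(lab)),
                           as.character(di))
      }
    }
    child <- c(child, d1, d2); parent <- c(parent, lab, lab)
  }

  cells <- lapply(work, function(c) {
    cell_polygon(c$label, c$vertices, c$junction_ids)
  })
  snap <- tissue_snapshot(unname(cells), next_time)
  undivided <- setdiff(labels_now, parent)
  pm <- parent_map(c(undivided, child), c(undivided, parent),
                   snapshot$time_h, next_time)
  list(snapshot = snap, parent_map = pm)
}

# Smooth growth map of the form x' = F(x), y' = G(x, y). The x-stretch
# F'(x) is the column-mean medial-lateral log stretch (1-d kernel over
# centroid x); the y-stretch is whatever remains of the local interpolated
# log areal growth, so the Jacobian F'(x) * dG/dy equals the interpolated
# per-cell growth field exactly: positive everywhere, hence the map never
# folds, and realised cell areas track their targets up to kernel
# interpolation error.
#' @noRd
displace_junctions <- function(jxy, cen, lg, frac_x, bw, m = 8) {
  u <- seq(0, 1, length.out = m)
  tw <- c(0.5, rep(1, m - 2), 0.5) / (m - 1)     # trapezoid weights
  x0 <- min(jxy[, 1]); y0 <- min(jxy[, 2])
  nv <- nrow(jxy)
  lx <- frac_x * lg                              # per-cell ML log stretch

  # x' = x0 + int_x0^x exp(Lx(s)) ds, Lx = 1-d kernel interp over centroid x
  sx <- x0 + outer(jxy[, 1] - x0, u)
  px <- as.numeric(sx)
  wx <- exp(-outer(px, cen$x, "-")^2 / (2 * bw^2))
  fx <- exp(as.numeric((wx %*% lx) / rowSums(wx)))
  newx <- x0 + (jxy[, 1] - x0) * as.numeric(matrix(fx, nv, m) %*% tw)

  # y' = y0 + int_y0^y exp(Lg(x, t) - Lx(x)) dt with Lg the 2-d kernel
  # interpolation of the full log areal growth
  sy <- y0 + outer(jxy[, 2] - y0, u)
  px2 <- rep(jxy[, 1], times = m); py2 <- as.numeric(sy)
  lg2 <- kernel_field(px2, py2, cen$x, cen$y, lg, bw)
  wx2 <- exp(-outer(jxy[, 1], cen$x, "-")^2 / (2 * bw^2))
  lx2 <- as.numeric((wx2 %*% lx) / rowSums(wx2))
  gy <- exp(matrix(lg2, nv, m) - lx2)
  newy <- y0 + (jxy[, 2] - y0) * as.numeric(gy %*% tw)

  matrix(c(newx, newy), ncol = 2)
}

# Division wall: through the centroid, perpendicular to the longest
# principal axis of the cell's area covariance, +/- 5 degrees of jitter.
#' @noRd
try_split <- function(v, tries = 6) {
  ctr <- polygon_centroid(v)
  ev <- eigen(polygon_covariance(v), symmetric = TRUE)
  minor <- ev$vectors[, 2]                         # wall runs along minor axis
  base_ang <- atan2(minor[2], minor[1])
  # already-thin cells may divide into daughters not much thinner than
  # themselves; cutting across the long axis is what rescues them
  n <- nrow(v)
  e2 <- max(rowSums((v[c(2:n, 1), , drop = FALSE] - v)^2))
  parent_fat <- abs(signed_area(v)) / e2
  min_fat <- min(0.1, 0.8 * parent_fat)
  for (i in seq_len(tries)) {
    ang <- base_ang + stats::runif(1, -5, 5) * pi / 180
    res <- split_polygon_by_line(v, ctr, c(cos(ang), sin(ang)),
                                 min_fatness = min_fat)
    if (!is.null(res)) return(res)
  }
  NULL
}

# Straighten near-collinear wall vertices of any non-simple cell by
# projecting them onto the segment between their wall neighbours. Junction
# moves apply to every cell sharing the junction, so the tessellation stays
# crack-free. A few passes suffice; cells that stay tangled are handled by
# the caller's affine fallback.
#' @noRd
untangle_junctions <- function(snapshot, jid, new_xy, passes = 3) {
  for (p in seq_len(passes)) {
    moved <- FALSE
    for (c in snapshot$cells) {
      ix <- match(c$junction_ids, jid)
      v <- new_xy[ix, , drop = FALSE]
      if (is_simple_polygon(v) && signed_area(v) > 0) next
      n <- nrow(v)
      for (i in seq_len(n)) {
        a <- v[if (i == 1) n else i - 1, ]
        b <- v[if (i == n) 1 else i + 1, ]
        ab <- b - a
        len2 <- sum(ab^2)
        if (len2 == 0) next
        t <- sum((v[i, ] - a) * ab) / len2
        if (t <= 0 || t >= 1) next
        proj <- a + t * ab
        d <- sqrt(sum((v[i, ] - proj)^2))
        if (d < 0.1 * sqrt(len2)) {          # near-collinear poke-through
          new_xy[ix[i], ] <- proj
          v[i, ] <- proj
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  new_xy
}

# Insert a new junction (id, pt) into one cell if it has a wall running
# between the two junctions in `pair`; NULL if it does not.
#' @noRd
insert_junction_one <- function(c, pair, id, pt) {
  jd <- c$junction_ids
  n <- length(jd)
  nxt <- c(jd[-1], jd[1])
  hit <- which((jd == pair[1] & nxt == pair[2]) |
                 (jd == pair[2] & nxt == pair[1]))
  if (length(hit) != 1) return(NULL)
  i <- hit
  c$junction_ids <- append(jd, id, after = i)
  c$vertices <- rbind(c$vertices[seq_len(i), , drop = FALSE], pt,
                      if (i < n) c$vertices[(i + 1):n, , drop = FALSE])
  c
}

#' Simulate a full tissue time series
#'
#' Runs `n_steps` growth + division steps from a jittered initial lattice,
#' producing snapshots every 24 h with consistent parent maps. Giant-cell
#' fate is assigned once at t = 0 with probability `p_giant`; the noise
#' state is propagated through lineages (daughters inherit their parent's
#' log-growth anomaly). All randomness comes from one stream seeded with
#' `config$seed`, so runs are reproducible.
#'
#' @param config A [sim_config()].
#' @return A [tissue_series()] with attributes `giant_labels` and `config`.
#' @export
simulate_series <- function(config = sim_config()) {
  set.seed(config$seed)
  snap <- make_initial_tissue(config$grid, config$jitter, seed = NULL,
                              spacing = config$spacing)
  labs0 <- cell_labels(snap)
  giant <- labs0[stats::runif(length(labs0)) < config$p_giant]

  snapshots <- list(snap)
  intervals <- list()
  noise <- NULL
  for (t in seq_len(config$n_steps) - 1L) {
    field <- sample_growth_field(snap, config, t, prev_noise = noise)
    res <- step_tissue(snap, field, config, giant = giant,
                       next_time = 24 * (t + 1))
    pm <- res$parent_map
    # daughters inherit the parent's noise state
    noise <- field$noise[as.character(pm$parent)]
    names(noise) <- as.character(pm$child)
    snap <- res$snapshot
    snapshots[[t + 2]] <- snap
    intervals[[t + 1]] <- pm
  }
  series <- tissue_series(snapshots, intervals)
  attr(series, "giant_labels") <- giant
  attr(series, "config") <- config
  series
}
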