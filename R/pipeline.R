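# End-to-end orchestration: simulate -> track -> growth -> axis -> stats,
# writing every stage's tables as CSV (and optional PNG heat-map renders)
# into one output directory. Deterministic given the configuration seed.

#' Standard heat-map display ranges
#'
#' The display conventions used throughout: daughter counts 1-15,
#' per-interval proliferation 1-4, cell area 0-4000 um^2, 24 h growth
#' ratios 1-3, 72 h cumulative growth 1-10, PD/ML growth ratio 1-1.7.
#' Clipping to these ranges happens only when rendering; stored values are
#' never clipped.
#'
#' @return A tibble with columns `quantity`, `min`, `max`.
#' @export
render_spec <- function() {
  tibble::tribble(
    ~quantity,                ~min, ~max,
    "daughter_count",            1,   15,
    "interval_proliferation",    1,    4,
    "cell_area",                 0, 4000,
    "growth_ratio_24h",          1,    3,
    "growth_ratio_72h",          1,   10,
    "pd_ml_growth_ratio",        1,  1.7
  )
}

#' Bundled demonstration configuration
#'
#' A small simulation (8 x 5 starting cells, 5 steps) that exercises every
#' pipeline stage in seconds.
#'
#' @param seed RNG seed.
#' @return A [sim_config()].
#' @export
demo_config <- function(seed = 1) {
  sim_config(grid = c(8, 5), seed = seed)
}

#' Run the full analysis pipeline on a simulated tissue
#'
#' Simulates a tissue series from `config`, then runs lineage tracking
#' (cumulative daughter counts, non-divider count), per-interval and
#' cumulative growth maps, principal-direction growth tensors, the
#' proximal-distal axis field and PD/ML ratio map, shrunk-cell flags, and
#' the statistics layer (pairwise Wasserstein distances between the
#' per-interval growth distributions with their principal-coordinate
#' embedding, and the Kendall correlation between cumulative growth and
#' PD/ML ratio). Every stage writes CSV into `out_dir`; reruns with the
#' same seed are byte-identical. No stage mutates its inputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param render Also write PNG heat-map renders (needs a PNG device).
#' @return Invisibly, a list with the simulated `series`, the main result
#'   tables, and `paths` of everything written.
#' @export
run_pipeline <- function(config = demo_config(), out_dir, render = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  series <- stage("simulate", simulate_series(config))
  series_dir <- file.path(out_dir, "series")
  write_tissue_series(series, series_dir)
  paths$series <- series_dir

  rep <- stage("validate", validate_series(series))
  if (nrow(rep)) stop("pipeline stage 'validate' failed: inconsistent series")

  times <- series_times(series)
  t_first <- times[1]; t_last <- times[length(times)]

  # lineage tracking: cumulative daughter counts
  composed <- stage("track", compose_parent_maps(series$intervals))
  counts <- daughter_counts(composed)
  paths$daughter_counts <- file.path(out_dir, "daughter_counts.heat.csv")
  write_heatmap_csv(counts, paths$daughter_counts)

  # per-interval growth maps + shrunk flags + division outlines
  interval_growth <- list()
  for (i in seq_along(series$intervals)) {
    gm <- stage("growth", growth_map(series, times[i], times[i + 1]))
    interval_growth[[i]] <- gm
    f <- file.path(out_dir, sprintf("growth_T%03d_T%03d.heat.csv",
                                    round(times[i]), round(times[i + 1])))
    write_heatmap_csv(gm, f)
    paths$interval_growth <- c(paths$interval_growth, f)
  }
  shrunk <- detect_shrunk_cells(interval_growth[[1]])
  readr::write_csv(tibble::tibble(label = shrunk),
                   file.path(out_dir, "shrunk_T000.csv"))

  # cumulative growth + tensors over the 24-96 h span when available
  span <- if (length(times) >= 5) c(24, 96) else c(t_first, t_last)
  cum_growth <- stage("growth", growth_map(series, span[1], span[2]))
  paths$cumulative_growth <-
    file.path(out_dir, sprintf("growth_T%03d_T%03d.heat.csv", span[1], span[2]))
  write_heatmap_csv(cum_growth, paths$cumulative_growth)
  tensors <- stage("pdg", growth_tensors(series, span[1], span[2]))
  paths$tensors <- file.path(out_dir, "growth_tensors.csv")
  readr::write_csv(tensors, paths$tensors)

  # proximal-distal axis at the span's earlier time point
  snap0 <- snapshot_at(series, span[1])
  dfield <- stage("axis", cell_distance_field(snap0, distal_sources(snap0)))
  axis <- stage("axis", axis_from_distance(snap0, dfield))
  paths$axis <- file.path(out_dir, "axis.csv")
  readr::write_csv(axis[, c("label", "ax", "ay", "d")], paths$axis)
  pdmap <- stage("pdratio", pd_ratio_map(tensors, axis))
  paths$pd_ratio <- file.path(out_dir, "pd_ratio.heat.csv")
  write_heatmap_csv(pdmap, paths$pd_ratio)

  # statistics: Wasserstein -> PCoA over interval growth distributions;
  # Kendall between cumulative growth and PD/ML ratio
  samples <- stats::setNames(
    lapply(interval_growth, function(g) g$value),
    sprintf("T%03d", round(times[-1])))
  wmat <- stage("stats", wasserstein_matrix(samples))
  paths$wasserstein <- file.path(out_dir, "wasserstein.csv")
  readr::write_csv(tibble::as_tibble(wmat, rownames = "sample"),
                   paths$wasserstein)
  emb <- stage("stats", pcoa(wmat, k = 2))
  paths$pcoa <- file.path(out_dir, "pcoa_coords.csv")
  readr::write_csv(emb$points, paths$pcoa)

  ktab <- dplyr::inner_join(cum_growth, pdmap, by = "label",
                            suffix = c("_growth", "_pd"))
  ktau <- stage("stats", kendall_tau(ktab$value_growth, ktab$value_pd))
  paths$kendall <- file.path(out_dir, "kendall.csv")
  readr::write_csv(ktau, paths$kendall)

  # run log: versions, seed, parameters (no timestamps, for reproducibility)
  log <- c(
    paste0("sepaldyn ", as.character(utils::packageVersion("sepaldyn"))),
    paste0("R ", R.version$major, ".", R.version$minor),
    paste0("seed ", config$seed),
    paste0(names(unclass(config)), " = ",
           vapply(unclass(config), function(v) paste(v, collapse = "x"),
                  character(1)))
  )
  writeLines(log, file.path(out_dir, "run_log.txt"))

  if (render) {
    stage("render", render_heatmaps(series, counts, interval_growth,
                                    cum_growth, pdmap, tensors, out_dir,
                                    span))
  }

  invisible(list(series = series, daughter_counts = counts,
                 interval_growth = interval_growth,
                 cumulative_growth = cum_growth, tensors = tensors,
                 axis = axis, pd_ratio = pdmap, wasserstein = wmat,
                 pcoa = emb, kendall = ktau, shrunk = shrunk,
                 paths = paths))
}

#' @noRd
render_heatmaps <- function(series, counts, interval_growth, cum_growth,
                            pdmap, tensors, out_dir, span) {
  times <- series_times(series)
  last <- series$snapshots[[length(series$snapshots)]]
  save_png <- function(plot, name) {
    f <- file.path(out_dir, name)
    grDevices::png(f, width = 900, height = 900, res = 150)
    print(plot)
    grDevices::dev.off()
    f
  }
  save_png(autoplot(last, heat = counts), "daughter_counts.png")
  for (i in seq_along(interval_growth)) {
    out <- division_outlines(series, i)
    save_png(autoplot(series$snapshots[[i + 1]], heat = interval_growth[[i]],
                      outline = out),
             sprintf("growth_T%03d_T%03d.png", round(times[i]),
                     round(times[i + 1])))
  }
  snap0 <- snapshot_at(series, span[1])
  save_png(plot_growth_axes(snap0, tensors, heat = cum_growth),
           "cumulative_growth_pdg.png")
  save_png(autoplot(snap0, heat = pdmap), "pd_ratio.png")
  invisible(NULL)
}
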