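# Quantifying spatiotemporal averaging: the across-lineage spread of
# cumulative growth once the deterministic basipetal band is controlled
# for. Resampled growth noise averages out over successive intervals
# (spread shrinking like 1/sqrt(steps) per unit time), persistent noise
# does not — the distinction between wild-type-like and ftsh4-like growth.

#' Across-lineage SD of cumulative log growth at fixed band position
#'
#' Computes each starting lineage's cumulative areal growth ratio over a
#' span, stratifies lineages by their starting proximal-distal position
#' (bins one typical cell diameter tall, so every stratum sits at a fixed
#' position relative to the moving growth band), takes the SD of log
#' growth within each stratum, and pools strata as the root mean square.
#' Strata at the tissue margins are dropped (edge cells have truncated
#' neighbourhoods); strata with fewer than `min_cells` lineages are
#' ignored.
#'
#' @param series A [tissue_series()].
#' @param t0,t1 Span endpoints in hours (defaults: full series).
#' @param trim Number of strata dropped at each proximal/distal end
#'   (default 2).
#' @param min_cells Minimum lineages per stratum (default 4).
#' @return The pooled SD of log cumulative growth (dimensionless).
#' @export
growth_heterogeneity_sd <- function(series, t0 = NULL, t1 = NULL, trim = 2,
                                    min_cells = 4) {
  times <- series_times(series)
  t0 <- t0 %||% times[1]
  t1 <- t1 %||% times[length(times)]
  gm <- growth_map(series, t0, t1, project = "earlier")
  cen <- cell_centroids(snapshot_at(series, t0))
  tb <- dplyr::inner_join(gm, cen, by = "label")
  h <- sqrt(stats::median(cen$area))
  bin <- floor((tb$y - min(cen$y)) / h)
  keep <- bin >= trim & bin <= max(bin) - trim
  lg <- log(tb$value); yy <- tb$y
  # detrend linearly in y inside each stratum: the deterministic band has
  # a finite gradient across a stratum's height, which would otherwise
  # add a noise-independent floor to every stratum's SD
  vars <- tapply(seq_along(lg)[keep], bin[keep], function(ix) {
    if (length(ix) < min_cells) return(NA_real_)
    r <- stats::lm.fit(cbind(1, yy[ix]), lg[ix])$residuals
    sum(r^2) / (length(ix) - 2)
  })
  sqrt(mean(unlist(vars), na.rm = TRUE))
}

#' Decay of growth heterogeneity with time under resampled noise
#'
#' For each span `[0, 24 T]`, `T = 1..n_steps`, computes the pooled
#' across-lineage SD of cumulative log growth per unit time
#' ([growth_heterogeneity_sd()] divided by `T`) and fits the power-law
#' exponent of SD/T against T. Independent per-step noise gives an
#' exponent near -1/2 (spatiotemporal averaging); fully persistent noise
#' gives an exponent near 0.
#'
#' The power law concerns the stochastic growth component, so the cleanest
#' measurement uses a uniform-growth simulation (`band_peak = 0`): a
#' travelling growth band interacts with each lineage's accumulated
#' positional displacement, contaminating the fit with a deterministic
#' trend that within-stratum detrending cannot fully remove.
#'
#' @param series A [tissue_series()].
#' @return A list with `sd_per_step` (tibble `T`, `sd`) and `exponent`
#'   (fitted log-log slope).
#' @export
averaging_decay <- function(series) {
  times <- series_times(series)
  tt <- seq_along(times[-1])
  sds <- vapply(tt, function(T) {
    growth_heterogeneity_sd(series, times[1], times[T + 1]) / T
  }, numeric(1))
  fit <- stats::lm(log(sds) ~ log(tt))
  list(sd_per_step = tibble::tibble(T = tt, sd = sds),
       exponent = unname(stats::coef(fit)[2]))
}
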