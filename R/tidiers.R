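# broom-style tidiers for the package's fitted/summary objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn fit_deformation Tidy a growth tensor into a one-row tibble.
#' @param x A `growth_tensor`.
#' @param ... Unused.
#' @export
tidy.growth_tensor <- function(x, ...) {
  tibble::tibble(f11 = x$F[1, 1], f12 = x$F[1, 2],
                 f21 = x$F[2, 1], f22 = x$F[2, 2],
                 s1 = x$s1, s2 = x$s2, theta_max = x$theta_max,
                 anisotropy = x$s1 / x$s2, isotropic = x$isotropic,
                 n_points = x$n_points)
}

#' @describeIn fit_deformation One-row model summary.
#' @export
glance.growth_tensor <- function(x, ...) {
  tibble::tibble(area_ratio = det(x$F), anisotropy = x$s1 / x$s2,
                 n_points = x$n_points)
}

#' @describeIn anova_tukey Pairwise Tukey comparisons as a tibble.
#' @param x An `anova_tukey` object.
#' @param ... Unused.
#' @export
tidy.anova_tukey <- function(x, ...) x$tukey

#' @describeIn anova_tukey One-row fit summary (F, p, group count).
#' @export
glance.anova_tukey <- function(x, ...) {
  tibble::tibble(statistic = x$f, p.value = x$p,
                 n_groups = nrow(x$letters), alpha = x$alpha)
}

#' @describeIn pcoa Sample coordinates as a tibble.
#' @param x A `pcoa_fit`.
#' @param ... Unused.
#' @export
tidy.pcoa_fit <- function(x, ...) x$points

#' @describeIn pcoa Eigenvalue summary.
#' @export
glance.pcoa_fit <- function(x, ...) {
  ev <- x$eigenvalues
  tibble::tibble(k = x$k,
                 inertia_kept = sum(ev[seq_len(x$k)]) / sum(ev[ev > 0]),
                 n_negative_eigenvalues = sum(ev < 0),
                 min_eigenvalue = min(ev))
}

#' @describeIn shape_variability Per-contour deviations as a tibble.
#' @param x A `shape_variability` object.
#' @param ... Unused.
#' @export
tidy.shape_variability <- function(x, ...) x$deviations

#' @describeIn shape_variability One-row summary (S2, contour count).
#' @export
glance.shape_variability <- function(x, ...) {
  tibble::tibble(S2 = x$S2, n_contours = nrow(x$deviations))
}

#' @describeIn within_flower_area_sd Per-flower SDs as a tibble.
#' @param x A `flower_area_sd` object.
#' @param ... Unused.
#' @export
tidy.flower_area_sd <- function(x, ...) x$per_flower

#' @describeIn within_flower_area_sd Group summary (mean SD, SEM).
#' @export
glance.flower_area_sd <- function(x, ...) {
  tibble::tibble(mean_sd = x$mean_sd, sem = x$sem, n_flowers = x$n_flowers)
}
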