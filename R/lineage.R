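# Lineage algebra over parent maps: composition across intervals, daughter
# counts per ancestor, non-divider counts, shrunk-cell flagging and
# division outlines.

#' Compose consecutive parent maps into a multi-interval map
#'
#' Chains per-interval lineage maps (early -> late) into a single map
#' sending each final-time cell to its earliest ancestor, by following each
#' cell's parent back through every interval in order. Equivalent to the
#' multi-step lineage tracking used to build cumulative division maps from
#' per-interval parent CSVs.
#'
#' @param maps List of [parent_map()] objects, time-ordered, with
#'   `t_late` of map i equal to `t_early` of map i + 1.
#' @return A [parent_map()] spanning the full interval.
#' @export
compose_parent_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  for (i in seq_len(length(maps) - 1)) {
    if (!isTRUE(all.equal(attr(maps[[i]], "t_late"),
                          attr(maps[[i + 1]], "t_early")))) {
      stop("interval mismatch: map ", i, " ends at ",
           attr(maps[[i]], "t_late"), " h but map ", i + 1, " starts at ",
           attr(maps[[i + 1]], "t_early"), " h", call. = FALSE)
    }
  }
  last <- maps[[length(maps)]]
  anc <- last$parent
  for (i in rev(seq_len(length(maps) - 1))) {
    m <- maps[[i]]
    idx <- match(anc, m$child)
    if (anyNA(idx)) {
      bad <- unique(anc[is.na(idx)])
      stop("broken lineage: label(s) ", paste(bad, collapse = ", "),
           " missing from the children of interval ", i, call. = FALSE)
    }
    anc <- m$parent[idx]
  }
  parent_map(last$child, anc,
             attr(maps[[1]], "t_early"), attr(last, "t_late"))
}

#' Daughter cells per ancestor lineage
#'
#' Counts, for each ancestor in a (possibly composed) parent map, how many
#' final-time cells its lineage produced. A count of 1 means the cell never
#' divided. The default display range is 1 to 15 daughter cells, matching
#' the cumulative 120 h division heat maps; values are stored unclipped.
#'
#' @param composed A [parent_map()].
#' @param render_range Display range, default `c(1, 15)`.
#' @return A [heatmap_tbl()] keyed by ancestor label.
#' @export
daughter_counts <- function(composed, render_range = c(1, 15)) {
  cnt <- table(composed$parent)
  heatmap_tbl(as.integer(names(cnt)), as.integer(cnt),
              quantity = "daughter_count", render_range = render_range)
}

#' Number of non-dividing lineages
#'
#' @param counts Output of [daughter_counts()].
#' @return Integer count of ancestors with exactly one descendant.
#' @export
count_nondividing <- function(counts) {
  sum(counts$value == 1)
}

#' Flag cells whose tracked area shrank over an interval
#'
#' Cells with an areal growth ratio at or below the threshold are
#' candidates for edge segmentation artifacts (real epidermal cells do not
#' shrink); the threshold is inclusive and defaults to 0.999.
#'
#' @param ratios A [heatmap_tbl()] of per-cell growth ratios for one
#'   interval (see [growth_map()]).
#' @param threshold Inclusive upper bound for flagging; default 0.999.
#' @return Integer vector of flagged labels.
#' @export
detect_shrunk_cells <- function(ratios, threshold = 0.999) {
  sort(ratios$label[ratios$value <= threshold])
}

#' Later-time cells produced by a division in an interval
#'
#' Returns the labels of later-time-point cells whose parent has two or
#' more children over the given interval — the cells outlined as division
#' products on per-interval growth maps.
#'
#' @param series A [tissue_series()].
#' @param interval 1-based interval index.
#' @return Sorted integer vector of later-time labels.
#' @export
division_outlines <- function(series, interval) {
  stopifnot(interval >= 1, interval <= length(series$intervals))
  pm <- series$intervals[[interval]]
  multi <- names(which(table(pm$parent) >= 2))
  sort(pm$child[pm$parent %in% as.integer(multi)])
}
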