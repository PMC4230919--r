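#' Assign clone sequences to subclades by nearest reference
#'
#' Each clone is assigned to the reference subclade at minimal uncorrected
#' p-distance (pairwise deletion, as in [p_distance_pair()]). Ties are broken
#' by lexicographic group label and reported with margin 0 so callers can
#' detect them. A clone whose best distance exceeds `threshold` is labelled
#' `UNASSIGNED`. The default threshold 0.02 sits between the published
#' within-pair subclade distance scale (at most ~1.9%) and the cross-pair
#' scale (at least ~3%), so the two regimes are separable by distance alone.
#'
#' @param clones An [aligned_seqs] matrix of clones, or a single residue
#'   string/vector, aligned to the panel's reference length.
#' @param panel A [simulate_references()] panel, or any `subclade_panel`-like
#'   list with `labels` and a `references` character matrix.
#' @param threshold Maximum distance to the best reference for an assignment,
#'   in (0, 0.75\].
#' @return A tibble of class `assignment_table` with one row per clone:
#'   `clone_id`, `group` (panel label or `"UNASSIGNED"`), `best_group`,
#'   `distance` (to best reference), `margin` (second-best minus best,
#'   always >= 0).
#' @export
assign_to_subclades <- function(clones, panel, threshold = 0.02) {
  if (threshold <= 0 || threshold > 0.75) {
    abort("threshold must be in (0, 0.75]")
  }
  if (!is.matrix(clones)) {
    if (is.character(clones) && length(clones) == 1) {
      clones <- setNames(clones, "clone")
    }
    clones <- aligned_seqs(clones)
  }
  if (ncol(clones) != ncol(panel$references)) {
    abort(paste0("clones have ", ncol(clones), " columns but panel ",
                 "references have ", ncol(panel$references)))
  }
  labels <- sort(panel$labels)  # lexicographic tie-break via column order
  ccodes <- encode_acgt(clones)
  rcodes <- match(panel$references[labels, , drop = FALSE],
                  c("A", "C", "G", "T"))
  dim(rcodes) <- c(length(labels), ncol(panel$references))
  n <- nrow(clones)
  dist_to_ref <- matrix(NA_real_, n, length(labels),
                        dimnames = list(rownames(clones), labels))
  for (g in seq_along(labels)) {
    rg <- rcodes[g, ]
    for (i in seq_len(n)) {
      comp <- !is.na(ccodes[i, ]) & !is.na(rg)
      m <- sum(comp)
      if (m > 0) {
        dist_to_ref[i, g] <- sum(ccodes[i, comp] != rg[comp]) / m
      }
    }
  }
  no_sites <- rowSums(!is.na(dist_to_ref)) == 0
  if (any(no_sites)) {
    abort(paste0("zero comparable sites against every reference for clone '",
                 rownames(clones)[which(no_sites)[1]], "'"))
  }
  best_idx <- apply(dist_to_ref, 1, which.min)  # first min = lexicographic
  best <- dist_to_ref[cbind(seq_len(n), best_idx)]
  second <- vapply(seq_len(n), function(i) {
    v <- dist_to_ref[i, -best_idx[i]]
    if (length(v)) min(v, na.rm = TRUE) else Inf
  }, double(1))
  out <- tibble(
    clone_id = rownames(clones),
    group = ifelse(best <= threshold, labels[best_idx], "UNASSIGNED"),
    best_group = labels[best_idx],
    distance = best,
    margin = second - best
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("assignment_table", class(out))
  out
}

#' Per-host, per-site subclade composition of a survey
#'
#' Tabulates assigned clones by host, site and subclade, with each group's
#' fraction of its site total. `UNASSIGNED` clones are reported as their own
#' group, so counts sum to all clones and fractions per (host, site) sum
#' to 1.
#'
#' @param assignments An [assign_to_subclades()] table (or any data frame
#'   with `clone_id` and `group`).
#' @param context Mapping from clone id to host and site: a data frame with
#'   columns `clone_id`, `host`, `site_code` (a `clone_survey` truth table
#'   works directly). Every assigned clone must be mapped.
#' @return A tibble of class `composition_table`: `host`, `site_code`,
#'   `group`, `clone_count`, `fraction`.
#' @examples
#' panel <- simulate_references(L = 500, seed = 1)
#' survey <- simulate_survey(panel, survey_design_default(), seed = 1)
#' asg <- assign_to_subclades(survey$alignment, panel)
#' composition_table(asg, survey$truth)
#' @export
composition_table <- function(assignments, context) {
  context <- as_tibble(context)[, c("clone_id", "host", "site_code")]
  unmapped <- setdiff(assignments$clone_id, context$clone_id)
  if (length(unmapped)) {
    abort(paste0("clone id(s) missing from context: ",
                 paste(head(unmapped, 5), collapse = ", ")))
  }
  out <- as_tibble(assignments)[, c("clone_id", "group")] |>
    dplyr::left_join(context, by = "clone_id") |>
    dplyr::count(.data$host, .data$site_code, .data$group,
                 name = "clone_count") |>
    dplyr::group_by(.data$host, .data$site_code) |>
    dplyr::mutate(fraction = .data$clone_count / sum(.data$clone_count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$host, .data$site_code, .data$group)
  class(out) <- c("composition_table", class(out))
  out
}

#' Stacked-bar chart of survey composition
#'
#' @param object A [composition_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot composition_table
#' @export
autoplot.composition_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$site_code, .data$fraction,
                                       fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(. ~ host, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "site", y = "fraction of site clones",
                  fill = "subclade") +
    ggplot2::theme_minimal()
}
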