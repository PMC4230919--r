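# Integer codes 1..4 for A,C,G,T; NA for gaps and ambiguity codes.
# A site enters a pairwise comparison only when both residues are coded,
# i.e. pairwise deletion; ambiguity codes never count as match or mismatch.
encode_acgt <- function(aln) {
  codes <- match(unclass(aln), c("A", "C", "G", "T"))
  dim(codes) <- dim(aln)
  rownames(codes) <- rownames(aln)
  codes
}

#' Uncorrected p-distance between two aligned residue rows
#'
#' The uncorrected ("p") distance is the proportion of differing residues
#' among comparable sites. A site is comparable iff both residues are plain
#' `A`, `C`, `G` or `T`; gaps and IUPAC ambiguity codes are excluded per pair
#' (pairwise deletion). A pair with zero comparable sites is an error, never
#' a silent 0 or NaN.
#'
#' @param x,y Residue strings or character vectors of equal positive length.
#' @return A list with `distance` (proportion in \[0, 1\]) and
#'   `comparable_sites` (integer count).
#' @examples
#' p_distance_pair("ACGT", "ACGA")  # one mismatch in four
#' p_distance_pair("AC-T", "ACGT")  # gap column excluded
#' @export
p_distance_pair <- function(x, y) {
  if (is.character(x) && length(x) == 1) x <- strsplit(x, "")[[1]]
  if (is.character(y) && length(y) == 1) y <- strsplit(y, "")[[1]]
  if (length(x) != length(y)) abort("rows have unequal lengths")
  if (length(x) == 0) abort("rows have zero length")
  cx <- match(toupper(x), c("A", "C", "G", "T"))
  cy <- match(toupper(y), c("A", "C", "G", "T"))
  comp <- !is.na(cx) & !is.na(cy)
  m <- sum(comp)
  if (m == 0) abort("undefined p-distance: zero comparable sites")
  list(distance = sum(cx[comp] != cy[comp]) / m, comparable_sites = m)
}

#' Uncorrected p-distance matrix for an alignment
#'
#' All unordered pairs via the [p_distance_pair()] rule (pairwise deletion of
#' gaps and ambiguity codes). The result carries both the distance matrix and
#' the per-pair comparable-site counts.
#'
#' @param aln An [aligned_seqs] matrix with at least two sequences and
#'   positive length.
#' @return An object of class `p_dist`: list with `ids`, symmetric matrix `d`
#'   (zero diagonal), and matrix `m` of comparable-site counts.
#' @export
p_distance_matrix <- function(aln) {
  n <- nrow(aln)
  if (n < 2) abort("need at least two sequences")
  if (ncol(aln) == 0) abort("alignment has zero columns")
  ids <- rownames(aln)
  codes <- encode_acgt(aln)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(m) <- as.integer(rowSums(!is.na(codes)))
  for (i in seq_len(n - 1)) {
    xi <- codes[i, ]
    for (j in (i + 1):n) {
      yj <- codes[j, ]
      comp <- !is.na(xi) & !is.na(yj)
      mij <- sum(comp)
      if (mij == 0) {
        abort(paste0("undefined p-distance: zero comparable sites between '",
                     ids[i], "' and '", ids[j], "'"))
      }
      d[i, j] <- d[j, i] <- sum(xi[comp] != yj[comp]) / mij
      m[i, j] <- m[j, i] <- mij
    }
  }
  structure(list(ids = ids, d = d, m = m), class = "p_dist")
}

#' @export
print.p_dist <- function(x, ...) {
  cat("<p_dist> ", length(x$ids), " sequences; distances ",
      format(min(x$d[upper.tri(x$d)]), digits = 4), "-",
      format(max(x$d), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.p_dist <- function(x, ...) x$d

#' Tidy a p-distance matrix into a long tibble
#'
#' @param x A `p_dist` object.
#' @param ... Unused.
#' @return A tibble with one row per unordered pair: `id1`, `id2`,
#'   `distance`, `comparable_sites`.
#' @method tidy p_dist
#' @export
tidy.p_dist <- function(x, ...) {
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(
    id1 = x$ids[idx[, 1]],
    id2 = x$ids[idx[, 2]],
    distance = x$d[idx],
    comparable_sites = as.integer(x$m[idx])
  )
}

#' Heatmap of a p-distance matrix
#'
#' @param object A `p_dist` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot p_dist
#' @export
autoplot.p_dist <- function(object, ...) {
  df <- expand.grid(id1 = object$ids, id2 = object$ids,
                    stringsAsFactors = FALSE)
  df$distance <- as.vector(object$d)
  ggplot2::ggplot(df, ggplot2::aes(.data$id1, .data$id2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "p-distance") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Per-group ranges of pairwise p-distances
#'
#' Summarises a p-distance matrix into min/max percentage distances for every
#' unordered pair of groups and for each group with itself. Between-group
#' cells use only cross-group pairs; within-group cells exclude self-pairs,
#' and a singleton group's within cell is reported as `NA`, not 0. Percent
#' values are rounded half away from zero to two decimals.
#'
#' @param dm A `p_dist` object.
#' @param grouping Mapping from sequence id to group label: either a named
#'   character vector or a data frame with columns `id` and `group`. Every id
#'   in `dm` must be grouped.
#' @return A tibble of class `group_range_table` with columns `group1`,
#'   `group2`, `min_pct`, `max_pct`, `n_pairs`.
#' @export
subclade_range_table <- function(dm, grouping) {
  if (is.data.frame(grouping)) {
    grouping <- setNames(as.character(grouping$group), grouping$id)
  }
  missing <- setdiff(dm$ids, names(grouping))
  if (length(missing)) {
    abort(paste0("ungrouped sequence id(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  groups <- sort(unique(unname(grouping[dm$ids])))
  members <- lapply(groups, function(g) dm$ids[grouping[dm$ids] == g])
  names(members) <- groups
  rows <- list()
  for (a in seq_along(groups)) {
    for (b in a:length(groups)) {
      ia <- match(members[[a]], dm$ids)
      ib <- match(members[[b]], dm$ids)
      if (a == b) {
        sub <- dm$d[ia, ia, drop = FALSE]
        vals <- sub[upper.tri(sub)]
      } else {
        vals <- as.vector(dm$d[ia, ib, drop = FALSE])
      }
      rows[[length(rows) + 1]] <- tibble(
        group1 = groups[a], group2 = groups[b],
        min_pct = if (length(vals)) round_half_away(100 * min(vals), 2)
                  else NA_real_,
        max_pct = if (length(vals)) round_half_away(100 * max(vals), 2)
                  else NA_real_,
        n_pairs = length(vals)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("group_range_table", class(out))
  out
}

#' Write a distance matrix as TSV and PHYLIP
#'
#' @param dm A `p_dist` object.
#' @param path Output path for the square TSV (ids in header and first
#'   column).
#' @param phylip_path Optional output path for PHYLIP square format.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, phylip_path = NULL) {
  df <- as.data.frame(dm$d)
  df <- cbind(id = dm$ids, df)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  if (!is.null(phylip_path)) {
    lines <- c(sprintf("%5d", length(dm$ids)),
               vapply(seq_along(dm$ids), function(i) {
                 paste0(formatC(dm$ids[i], width = -10),
                        paste(sprintf("%.6f", dm$d[i, ]), collapse = " "))
               }, character(1)))
    writeLines(lines, phylip_path)
  }
  invisible(path)
}
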