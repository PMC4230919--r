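IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Construct an aligned sequence set
#'
#' An aligned sequence set is a character matrix with one row per sequence
#' (rownames are the unique sequence identifiers) and one column per alignment
#' column. Residues are uppercase IUPAC nucleotide codes or the gap `-`;
#' `U` is normalised to `T` on construction.
#'
#' @param x A character matrix of single residues with unique rownames, or a
#'   named character vector of equal-length residue strings.
#' @return A matrix of class `aligned_seqs`.
#' @export
aligned_seqs <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    ids <- names(x)
    if (is.null(ids)) abort("sequence strings must be named")
    widths <- nchar(x)
    if (length(unique(widths)) > 1) {
      bad <- ids[which(widths != widths[1])[1]]
      abort(paste0("alignment is ragged: sequence '", bad,
                   "' has length ", nchar(x[[bad]]),
                   ", expected ", widths[1]))
    }
    x <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(x) <- ids
  }
  if (!is.matrix(x) || !is.character(x)) abort("expected a character matrix")
  ids <- rownames(x)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    abort("aligned sequences must have non-empty rownames (ids)")
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  x[] <- toupper(x)
  x[x == "U"] <- "T"
  bad <- which(!(x %in% IUPAC_CHARS))
  if (length(bad)) {
    i <- (bad[1] - 1) %% nrow(x) + 1
    j <- (bad[1] - 1) %/% nrow(x) + 1
    abort(paste0("illegal residue '", x[bad[1]], "' in sequence '",
                 ids[i], "' at column ", j))
  }
  class(x) <- c("aligned_seqs", class(x))
  x
}

#' @export
`[.aligned_seqs` <- function(x, i, j, ..., drop = TRUE) {
  xm <- unclass(x)
  n_args <- nargs() - (!missing(drop))
  if (n_args <= 2) {                            # linear indexing x[i]
    return(if (missing(i)) xm else xm[i])
  }
  out <- if (missing(i) && missing(j)) xm[, , drop = drop]
  else if (missing(i)) xm[, j, drop = drop]
  else if (missing(j)) xm[i, , drop = drop]
  else xm[i, j, drop = drop]
  if (is.matrix(out)) class(out) <- c("aligned_seqs", class(out))
  out
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat("<aligned_seqs> ", nrow(x), " sequences x ", ncol(x), " columns\n",
      sep = "")
  show <- head(rownames(x), 5)
  for (id in show) {
    s <- paste(x[id, seq_len(min(ncol(x), 60))], collapse = "")
    cat("  ", id, ": ", s, if (ncol(x) > 60) "..." else "", "\n", sep = "")
  }
  if (nrow(x) > 5) cat("  ... and ", nrow(x) - 5, " more\n", sep = "")
  invisible(x)
}

#' Read an aligned multi-FASTA file
#'
#' Reads a multi-FASTA alignment, folds residues to uppercase, normalises
#' `U` to `T`, and rejects ragged inputs (sequences of unequal length) with
#' an error naming the offending record.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return An [aligned_seqs] matrix.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("no FASTA records in ", path))
  ids <- sub("\\s.*$", "", names(set))
  strs <- setNames(as.character(set), ids)
  widths <- nchar(strs)
  if (length(unique(widths)) > 1) {
    bad <- which(widths != widths[1])[1]
    abort(paste0("alignment is ragged: sequence '", ids[bad],
                 "' has length ", widths[bad], ", expected ", widths[1]))
  }
  aligned_seqs(strs)
}

#' Write an aligned sequence set as FASTA
#'
#' Standard multi-FASTA, wrapped at 80 columns. Reading the file back with
#' [read_aligned_fasta()] reproduces ids, order and residues exactly.
#'
#' @param aln An [aligned_seqs] matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(aln, path) {
  strs <- apply(unclass(aln), 1, paste, collapse = "")
  set <- Biostrings::BStringSet(strs)
  names(set) <- rownames(aln)
  Biostrings::writeXStringSet(set, path, width = 80)
  invisible(path)
}

#' Restrict an alignment to a set of kept columns
#'
#' Column masking removes ambiguously aligned alignment regions before
#' distance or tree computation. Indices are 1-based column positions into
#' the alignment; they must be strictly increasing and within range.
#'
#' @param aln An [aligned_seqs] matrix.
#' @param keep Integer vector of 1-based column indices to retain, strictly
#'   increasing. An empty vector yields zero-length rows (ids preserved);
#'   downstream distance operations reject such alignments.
#' @return The masked [aligned_seqs].
#' @seealso [read_mask()]
#' @export
apply_mask <- function(aln, keep) {
  keep <- as.integer(keep)
  if (anyNA(keep)) abort("mask indices must be integers")
  if (length(keep)) {
    if (any(diff(keep) <= 0)) abort("mask indices must be strictly increasing")
    bad <- keep[keep < 1 | keep > ncol(aln)]
    if (length(bad)) {
      abort(paste0("mask index out of range: ", bad[1],
                   " (alignment has ", ncol(aln), " columns)"))
    }
  }
  out <- unclass(aln)[, keep, drop = FALSE]
  class(out) <- c("aligned_seqs", class(out))
  out
}

#' Read a column mask file
#'
#' One 1-based inclusive range per line, `start<TAB>end`. Ranges may overlap;
#' the result is the sorted union of covered columns.
#'
#' @param path Path to the mask file.
#' @param n_cols Alignment width, used to validate ranges.
#' @return Sorted integer vector of kept 1-based column indices.
#' @export
read_mask <- function(path, n_cols) {
  if (!file.exists(path)) abort(paste0("mask file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  keep <- integer(0)
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[\t ]+")[[1]]
    if (length(parts) != 2) abort(paste0("malformed mask line: '", ln, "'"))
    a <- suppressWarnings(as.integer(parts[1]))
    b <- suppressWarnings(as.integer(parts[2]))
    if (is.na(a) || is.na(b) || a < 1 || b < a) {
      abort(paste0("malformed mask range: '", ln, "'"))
    }
    if (b > n_cols) {
      abort(paste0("mask range end ", b, " exceeds alignment width ", n_cols))
    }
    keep <- c(keep, a:b)
  }
  sort(unique(keep))
}
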