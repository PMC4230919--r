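# Independent site-by-site p-distance oracle: plain loop, no vectorisation,
# written against the definition (comparable iff both residues in ACGT).
p_dist_bruteforce <- function(x, y) {
  if (is.character(x) && length(x) == 1) x <- strsplit(x, "")[[1]]
  if (is.character(y) && length(y) == 1) y <- strsplit(y, "")[[1]]
  plain <- c("A", "C", "G", "T")
  mism <- 0L
  comp <- 0L
  for (s in seq_along(x)) {
    a <- toupper(x[s])
    b <- toupper(y[s])
    if (a %in% plain && b %in% plain) {
      comp <- comp + 1L
      if (a != b) mism <- mism + 1L
    }
  }
  list(distance = if (comp > 0) mism / comp else NA_real_,
       comparable_sites = comp)
}

# Random alignment with optional gaps and ambiguity codes injected.
random_alignment <- function(n, L, seed, gap_frac = 0, amb_frac = 0) {
  withr::with_seed(seed, {
    m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
    if (gap_frac > 0) {
      idx <- sample(length(m), round(gap_frac * length(m)))
      m[idx] <- "-"
    }
    if (amb_frac > 0) {
      idx <- sample(length(m), round(amb_frac * length(m)))
      m[idx] <- sample(c("N", "R", "Y", "W", "S"), length(idx), replace = TRUE)
    }
    rownames(m) <- paste0("s", seq_len(n))
    aligned_seqs(m)
  })
}

# Smallest n with detection probability >= P, by linear scan.
required_clones_bruteforce <- function(P, q) {
  n <- 1
  while (1 - (1 - q)^n < P) n <- n + 1
  n
}

# Canonical split-set of a tree, computed independently via phangorn.
splits_phangorn <- function(tree) {
  spl <- phangorn::as.splits(tree)
  tips <- attr(spl, "labels")
  n <- length(tips)
  keys <- vapply(spl, function(s) {
    side <- tips[s]
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    ref <- min(tips)
    if (ref %in% side) side <- setdiff(tips, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  sort(unique(keys[!is.na(keys)]))
}
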