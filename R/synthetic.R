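BASES <- c("A", "C", "G", "T")

#' Default between-subclade divergence matrix
#'
#' Target uncorrected p-distances between the four symbiont subclade
#' reference sequences, seeded from the midpoints of the published
#' between-subclade percentage ranges: the two close pairs (I-II and III-IV)
#' near 1.2% and 1.6%, all cross pairs near 3.3-3.7%.
#'
#' @return A symmetric 4x4 matrix (labels I-IV) of divergence proportions.
#' @export
default_divergence_matrix <- function() {
  labels <- c("I", "II", "III", "IV")
  d <- matrix(0, 4, 4, dimnames = list(labels, labels))
  d["I", "II"] <- 0.012
  d["I", "III"] <- 0.036
  d["I", "IV"] <- 0.037
  d["II", "III"] <- 0.033
  d["II", "IV"] <- 0.034
  d["III", "IV"] <- 0.016
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# tip indices below each node of an ape tree (tips below a tip = itself)
tips_below <- function(tree) {
  n <- ape::Ntip(tree)
  res <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) res[[i]] <- i
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(ed))) {
    res[[ed[r, 1]]] <- c(res[[ed[r, 1]]], res[[ed[r, 2]]])
  }
  res
}

#' Simulate subclade reference sequences at target divergences
#'
#' Draws a random ancestor sequence and derives one ungapped reference per
#' subclade by placing substitutions so that realized pairwise p-distances
#' approximate the requested divergence matrix. The matrix is first fitted to
#' an unrooted tree (neighbor joining); each edge is then assigned its own
#' disjoint set of columns, mutated in all references on one side, so realized
#' divergences equal the fitted path lengths up to rounding. If the requested
#' matrix is too far from additive — any realized divergence off by more than
#' 20% relative — a constructive error reports the realized values as a
#' feasible alternative.
#'
#' @param L Sequence length in columns, at least 100.
#' @param divergence_matrix Symmetric matrix of target pairwise divergences
#'   (proportions, zero diagonal, entries in \[0, 0.75\]) with labelled rows.
#' @param seed Integer seed; identical seeds give byte-identical panels.
#' @return An object of class `subclade_panel`: list with `labels`,
#'   `references` (character matrix, rows = subclades), `ancestor`,
#'   `divergence_requested`, `divergence_realized`, `L`.
#' @examples
#' panel <- simulate_references(L = 1000, seed = 1)
#' panel$divergence_realized
#' @export
simulate_references <- function(L = 1685,
                                divergence_matrix = default_divergence_matrix(),
                                seed = 1) {
  if (L < 100) abort("L must be at least 100")
  dmx <- as.matrix(divergence_matrix)
  k <- nrow(dmx)
  if (k < 2) abort("need at least two subclades")
  if (is.null(rownames(dmx))) rownames(dmx) <- colnames(dmx) <- as.roman(1:k)
  labels <- rownames(dmx)
  if (!isSymmetric(unname(dmx)) || any(diag(dmx) != 0) ||
      any(dmx < 0 | dmx > 0.75)) {
    abort(paste0("divergence_matrix must be symmetric with zero diagonal ",
                 "and entries in [0, 0.75]"))
  }

  with_seed_(seed, {
    ancestor <- sample(BASES, L, replace = TRUE)
    refs <- matrix(rep(ancestor, each = k), nrow = k,
                   dimnames = list(labels, NULL))

    if (any(dmx > 0)) {
      # fit an unrooted tree to the requested matrix; each edge gets its own
      # disjoint block of columns so path lengths realize exactly
      if (k == 2) {
        sides <- list(1L)
        lens <- dmx[1, 2]
      } else {
        tr <- ape::nj(dmx)
        tb <- tips_below(tr)
        sides <- lapply(tb[tr$edge[, 2]],
                        function(tips) match(tr$tip.label[tips], labels))
        lens <- pmax(tr$edge.length, 0)
      }
      k_e <- round(lens * L)
      if (sum(k_e) > L) {
        abort(paste0("requested divergences need ", sum(k_e),
                     " substituted columns but L = ", L,
                     "; increase L or lower the divergences"))
      }
      cols <- sample.int(L, sum(k_e))
      offset <- 0L
      for (e in seq_along(k_e)) {
        if (k_e[e] == 0) next
        here <- cols[(offset + 1):(offset + k_e[e])]
        offset <- offset + k_e[e]
        shift <- sample.int(3, k_e[e], replace = TRUE)
        newb <- BASES[((match(ancestor[here], BASES) - 1 + shift) %% 4) + 1]
        for (i in sides[[e]]) refs[i, here] <- newb
      }
    }

    realized <- matrix(0, k, k, dimnames = dimnames(dmx))
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        realized[i, j] <- realized[j, i] <- mean(refs[i, ] != refs[j, ])
      }
    }
    pos <- dmx > 0 & upper.tri(dmx)
    # allow site-count quantisation on top of the 20% relative band: each of
    # the <= 3 path edges rounds to whole columns (+- 0.5 site apiece)
    tol <- pmax(0.20 * dmx[pos], 1.5 / L)
    if (any(abs(realized[pos] - dmx[pos]) > tol) ||
        any(realized[dmx == 0 & upper.tri(dmx)] > 0)) {
      abort(paste0("requested divergence matrix is too far from additive; ",
                   "nearest attainable divergences: ",
                   paste(sprintf("%s-%s %.4f",
                                 labels[row(dmx)[pos]], labels[col(dmx)[pos]],
                                 realized[pos]), collapse = ", ")))
    }

    structure(
      list(labels = labels, references = refs, ancestor = ancestor,
           divergence_requested = dmx, divergence_realized = realized, L = L),
      class = "subclade_panel"
    )
  })
}

#' @export
print.subclade_panel <- function(x, ...) {
  cat("<subclade_panel> ", length(x$labels), " references (",
      paste(x$labels, collapse = ", "), "), L = ", x$L, "\n", sep = "")
  invisible(x)
}

#' Pairwise divergences of a subclade panel
#'
#' @param x A `subclade_panel`.
#' @param ... Unused.
#' @return Tibble with one row per reference pair: `group1`, `group2`,
#'   `requested`, `realized`.
#' @method tidy subclade_panel
#' @export
tidy.subclade_panel <- function(x, ...) {
  idx <- which(upper.tri(x$divergence_requested), arr.ind = TRUE)
  tibble(
    group1 = x$labels[idx[, 1]],
    group2 = x$labels[idx[, 2]],
    requested = x$divergence_requested[idx],
    realized = x$divergence_realized[idx]
  )
}

# substitute entries `idx` of char matrix `m` uniformly over the 3 other bases
mutate_uniform <- function(m, idx) {
  if (length(idx) == 0) return(m)
  cur <- match(m[idx], BASES)
  shift <- sample.int(3, length(idx), replace = TRUE)
  m[idx] <- BASES[((cur - 1 + shift) %% 4) + 1]
  m
}

#' Simulate one egg capsule's clone library
#'
#' Each of `n_clones` clones is independently a non-target contaminant with
#' probability `q` (equal incidence among samples, no amplification bias —
#' i.i.d. draws). Target clones pick a subclade by `subclade_mixture`, copy
#' its reference, and receive independent per-site substitutions at
#' `error_rate`, uniform over the three alternative bases. Non-target clones
#' are built by substituting a fixed fraction (default 20%) of sites of the
#' first reference, guaranteeing at least 10% divergence from every
#' reference; the published record gives no divergence for non-target taxa,
#' so the floor is a package convention.
#'
#' @param panel A [simulate_references()] panel.
#' @param host Host label recorded in the library.
#' @param n_clones Positive number of clones.
#' @param q Non-target incidence in \[0, 1\].
#' @param subclade_mixture Named probability vector over panel labels
#'   (default uniform); must sum to 1 within 1e-9.
#' @param error_rate Per-site substitution probability in \[0, 0.05\].
#' @param seed Integer seed.
#' @param capsule_id Identifier prefixed to clone ids.
#' @param non_target_divergence Fraction of sites substituted in non-target
#'   clones, in \[0.15, 0.75\].
#' @return Object of class `capsule_library`: list with `capsule_id`, `host`,
#'   `q`, `subclade_mixture`, `error_rate`, `clones` (an [aligned_seqs]
#'   matrix) and `truth` (tibble `clone_id`, `truth_label`; non-targets are
#'   labelled `"NON_TARGET"`).
#' @export
simulate_capsule_library <- function(panel, host, n_clones, q,
                                     subclade_mixture = NULL,
                                     error_rate = 0.005, seed = 1,
                                     capsule_id = "cap1",
                                     non_target_divergence = 0.2) {
  if (n_clones < 1) abort("n_clones must be at least 1")
  check_q(q)
  if (error_rate < 0 || error_rate > 0.05) {
    abort("error_rate must be in [0, 0.05]")
  }
  if (non_target_divergence < 0.15 || non_target_divergence > 0.75) {
    abort("non_target_divergence must be in [0.15, 0.75]")
  }
  if (is.null(subclade_mixture)) {
    subclade_mixture <- setNames(rep(1 / length(panel$labels),
                                     length(panel$labels)), panel$labels)
  }
  if (is.null(names(subclade_mixture)) ||
      !all(names(subclade_mixture) %in% panel$labels) ||
      any(subclade_mixture < 0) ||
      abs(sum(subclade_mixture) - 1) > 1e-9) {
    abort(paste0("subclade_mixture must be a probability vector named by ",
                 "panel labels, summing to 1"))
  }
  L <- panel$L
  with_seed_(seed, {
    is_nt <- runif(n_clones) < q
    groups <- character(n_clones)
    groups[is_nt] <- "NON_TARGET"
    if (any(!is_nt)) {
      groups[!is_nt] <- sample(names(subclade_mixture), sum(!is_nt),
                               replace = TRUE, prob = subclade_mixture)
    }
    clones <- matrix("", n_clones, L)
    for (i in which(!is_nt)) clones[i, ] <- panel$references[groups[i], ]
    n_sub <- round(non_target_divergence * L)
    for (i in which(is_nt)) {
      row <- panel$references[1, ]
      sites <- sample.int(L, n_sub)
      shift <- sample.int(3, n_sub, replace = TRUE)
      row[sites] <- BASES[((match(row[sites], BASES) - 1 + shift) %% 4) + 1]
      clones[i, ] <- row
    }
    if (error_rate > 0) {
      clones <- mutate_uniform(clones, which(runif(n_clones * L) < error_rate))
    }
    ids <- paste0(capsule_id, "_c", seq_len(n_clones))
    rownames(clones) <- ids
    structure(
      list(capsule_id = capsule_id, host = host, q = q,
           subclade_mixture = subclade_mixture, error_rate = error_rate,
           clones = aligned_seqs(clones),
           truth = tibble(clone_id = ids, truth_label = groups)),
      class = "capsule_library"
    )
  })
}

#' Paper-shaped default survey design
#'
#' A multi-site, multi-host design mirroring the published survey's clone
#' accounting: 85 A. maculatum, 27 A. gracile, 9 L. sylvatica and 5 L. aurora
#' clones across 8 sites. Host mixtures follow the reported subclade
#' structure: A. maculatum capsules draw mostly subclade I with some III,
#' A. gracile is subclade II, L. aurora subclade III, L. sylvatica subclade
#' IV. The default incidence `q = 0` reproduces the survey outcome of zero
#' non-target detections.
#'
#' @param q Non-target incidence applied to every site.
#' @return A design tibble for [simulate_survey()].
#' @export
survey_design_default <- function(q = 0) {
  tibble(
    host = c("A. maculatum", "A. maculatum", "A. maculatum",
             "A. gracile", "A. gracile",
             "L. sylvatica", "L. aurora", "L. aurora"),
    site_code = c("NS", "GS", "TN", "BF", "CA", "R", "WL", "SL"),
    n_capsules = c(11L, 4L, 2L, 1L, 1L, 1L, 1L, 1L),
    clones_per_capsule = c(5L, 5L, 5L, 13L, 14L, 9L, 1L, 4L),
    q = q,
    mixture = list(
      c(I = 0.9, III = 0.1), c(I = 0.9, III = 0.1), c(I = 0.9, III = 0.1),
      c(II = 1), c(II = 1), c(IV = 1), c(III = 1), c(III = 1)
    )
  )
}

#' Simulate a multi-site clone-library survey
#'
#' Builds one capsule library per (site, capsule) cell of the design, pools
#' all clones into a single gap-free alignment (references and clones share
#' one ungapped coordinate system, so pooling is trivially aligned), and
#' records a truth table mapping every clone to its capsule, host and true
#' subclade. A generated manifest carries one row per site with the site's
#' clone ids as accessions. Per-capsule random substreams are derived by
#' hashing the capsule id with the seed, so results do not depend on
#' iteration order.
#'
#' @param panel A [simulate_references()] panel.
#' @param design Tibble with columns `host`, `site_code` (unique),
#'   `n_capsules`, `clones_per_capsule`, `q` and optionally `mixture`
#'   (list-column of named probability vectors; default uniform). See
#'   [survey_design_default()].
#' @param error_rate Per-site substitution probability for clones.
#' @param seed Integer master seed.
#' @return Object of class `clone_survey`: list with `manifest`
#'   (a `sample_manifest`), `capsules`, `alignment` (pooled [aligned_seqs]),
#'   `truth` (tibble `clone_id`, `capsule_id`, `host`, `site_code`,
#'   `truth_label`), `panel` and `params`.
#' @examples
#' panel <- simulate_references(L = 500, seed = 1)
#' survey <- simulate_survey(panel, survey_design_default(), seed = 1)
#' glance(survey)
#' @export
simulate_survey <- function(panel, design, error_rate = 0.005, seed = 1) {
  if (nrow(design) == 0) abort("design is empty")
  dup <- design$site_code[duplicated(design$site_code)]
  if (length(dup)) {
    abort(paste0("duplicate site_code(s) in design: ",
                 paste(unique(dup), collapse = ", ")))
  }
  has_mixture <- "mixture" %in% names(design)
  capsules <- list()
  manifest_rows <- list()
  for (r in seq_len(nrow(design))) {
    site <- design$site_code[r]
    site_clone_ids <- character(0)
    for (j in seq_len(design$n_capsules[r])) {
      cid <- paste0(site, "-k", j)
      cap <- simulate_capsule_library(
        panel, host = design$host[r],
        n_clones = design$clones_per_capsule[r], q = design$q[r],
        subclade_mixture = if (has_mixture) design$mixture[[r]] else NULL,
        error_rate = error_rate, seed = substream_seed(seed, cid),
        capsule_id = cid
      )
      capsules[[cid]] <- cap
      site_clone_ids <- c(site_clone_ids, cap$truth$clone_id)
    }
    manifest_rows[[r]] <- tibble(
      location = paste("Simulated site", site), code = site,
      lon = -130 + r, lat = 35 + r / 2, date = "2012",
      sample_type = "ES", host = design$host[r],
      accessions = list(site_clone_ids)
    )
  }
  manifest <- new_manifest(dplyr::bind_rows(manifest_rows))
  alignment <- aligned_seqs(do.call(rbind, lapply(capsules, function(c)
    unclass(c$clones))))
  truth <- dplyr::bind_rows(lapply(capsules, function(cap) {
    dplyr::mutate(cap$truth, capsule_id = cap$capsule_id, host = cap$host,
                  site_code = sub("-k[0-9]+$", "", cap$capsule_id),
                  .after = "clone_id")
  }))
  structure(
    list(manifest = manifest, capsules = capsules, alignment = alignment,
         truth = truth, panel = panel,
         params = list(seed = seed, error_rate = error_rate,
                       design = dplyr::select(design, -dplyr::any_of("mixture")))),
    class = "clone_survey"
  )
}

#' @export
print.clone_survey <- function(x, ...) {
  cat("<clone_survey> ", nrow(x$truth), " clones, ", length(x$capsules),
      " capsules, ", nrow(x$manifest), " sites\n", sep = "")
  invisible(x)
}

#' @method tidy clone_survey
#' @export
tidy.clone_survey <- function(x, ...) x$truth

#' One-row summary of a simulated survey
#'
#' @param x A `clone_survey`.
#' @param ... Unused.
#' @return Tibble with clone, capsule, site and host counts and the realized
#'   non-target clone count.
#' @method glance clone_survey
#' @export
glance.clone_survey <- function(x, ...) {
  tibble(
    n_clones = nrow(x$truth),
    n_capsules = length(x$capsules),
    n_sites = nrow(x$manifest),
    n_hosts = length(unique(x$truth$host)),
    n_non_target = sum(x$truth$truth_label == "NON_TARGET"),
    alignment_columns = ncol(x$alignment)
  )
}

#' Write a simulated survey's artifacts
#'
#' Writes the pooled FASTA alignment, manifest TSV, truth-table TSV and a
#' JSON sidecar of simulation parameters (including the seed) to a directory.
#'
#' @param survey A `clone_survey`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_aligned_fasta(survey$alignment, file.path(dir, "survey.fasta"))
  write_manifest(survey$manifest, file.path(dir, "manifest.tsv"))
  readr::write_tsv(survey$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(seed = survey$params$seed, error_rate = survey$params$error_rate,
         L = survey$panel$L, design = survey$params$design),
    file.path(dir, "params.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
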