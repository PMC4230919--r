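#' Configuration for a survey pipeline run
#'
#' Collects every knob of the end-to-end analysis in one serialisable list.
#' A run is fully determined by its config: re-running the same config (with
#' its seed) reproduces every artifact byte for byte.
#'
#' Exactly one input mode applies:
#' * simulation mode — `design` given: a survey is simulated and analysed;
#' * file mode — `alignment_path` given: an existing alignment is analysed
#'   (classification is skipped unless a panel is simulated alongside);
#' * detection-only mode — only `per_host_n` given: just the incidence table
#'   is produced.
#'
#' @param out_dir Output directory for the artifact bundle.
#' @param design Optional simulation design tibble (see
#'   [survey_design_default()]).
#' @param alignment_path Optional path to an aligned FASTA to analyse.
#' @param manifest_path Optional manifest TSV accompanying `alignment_path`.
#' @param mask_path Optional column-mask file (see [read_mask()]).
#' @param per_host_n Optional named vector of per-host clone counts for
#'   detection-only mode; in the other modes counts are derived from the
#'   survey itself.
#' @param detection_P Cumulative detection probability threshold.
#' @param classify_threshold Nearest-reference assignment threshold.
#' @param bootstrap_reps Bootstrap replicates for the tree stage (0 disables
#'   the tree stage).
#' @param error_rate Simulation per-site substitution rate.
#' @param panel_L Simulated reference length in columns.
#' @param seed Integer seed driving all randomness in the run.
#' @param digits Decimals for rounded display values.
#' @return A list of class `run_config`.
#' @export
survey_config <- function(out_dir, design = NULL, alignment_path = NULL,
                          manifest_path = NULL, mask_path = NULL,
                          per_host_n = NULL, detection_P = 0.99,
                          classify_threshold = 0.02, bootstrap_reps = 100,
                          error_rate = 0.005, panel_L = 1685, seed = 1,
                          digits = 3) {
  if (is.null(design) && is.null(alignment_path) && is.null(per_host_n)) {
    abort("config needs a design, an alignment_path, or per_host_n")
  }
  structure(
    list(out_dir = out_dir, design = design, alignment_path = alignment_path,
         manifest_path = manifest_path, mask_path = mask_path,
         per_host_n = per_host_n, detection_P = detection_P,
         classify_threshold = classify_threshold,
         bootstrap_reps = bootstrap_reps, error_rate = error_rate,
         panel_L = panel_L, seed = seed, digits = digits),
    class = "run_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[stage ", stage, "] ", conditionMessage(e)))
  })
}

#' Run the full clone-library survey pipeline
#'
#' Orchestrates simulate -> distances -> classify -> detect -> tree into one
#' reproducible run. Artifacts are written under `config$out_dir` with fixed
#' names: `distances.tsv`, `ranges.tsv`, `composition.tsv`, `incidence.tsv`,
#' `tree.nwk`, `run.json` and `report.md` (plus the survey files in
#' simulation mode). Stage errors propagate with the stage name, and any
#' artifacts from the failed run are removed. Identical config and seed give
#' byte-identical outputs.
#'
#' @param config A [survey_config()].
#' @return The result bundle (named list of in-memory results and artifact
#'   paths), invisibly.
#' @export
run_survey_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  note <- function(path) {
    written <<- c(written, path)
    path
  }
  bundle <- list(config = config)

  ok <- FALSE
  on.exit({
    if (!ok) unlink(written)
  })

  survey <- NULL
  aln <- NULL
  grouping <- NULL

  if (!is.null(config$design)) {
    survey <- run_stage("simulate", {
      panel <- simulate_references(L = config$panel_L, seed = config$seed)
      simulate_survey(panel, config$design,
                      error_rate = config$error_rate, seed = config$seed)
    })
    run_stage("simulate", write_survey(survey, out))
    written <- c(written, file.path(out, c("survey.fasta", "manifest.tsv",
                                           "truth.tsv", "params.json")))
    aln <- survey$alignment
    bundle$survey <- survey
  } else if (!is.null(config$alignment_path)) {
    aln <- run_stage("ingest", read_aligned_fasta(config$alignment_path))
    if (!is.null(config$manifest_path)) {
      bundle$manifest <- run_stage("ingest",
                                   read_manifest(config$manifest_path))
    }
  }

  if (!is.null(aln) && !is.null(config$mask_path)) {
    aln <- run_stage("mask", {
      apply_mask(aln, read_mask(config$mask_path, ncol(aln)))
    })
  }

  if (!is.null(aln)) {
    dm <- run_stage("distances", p_distance_matrix(aln))
    run_stage("distances", write_distance_matrix(
      dm, note(file.path(out, "distances.tsv")),
      phylip_path = note(file.path(out, "distances.phy"))))
    bundle$distances <- dm

    if (!is.null(survey)) {
      asg <- run_stage("classify", assign_to_subclades(
        aln, survey$panel, threshold = config$classify_threshold))
      comp <- run_stage("classify", composition_table(asg, survey$truth))
      readr::write_tsv(as_tibble(asg), note(file.path(out, "assignments.tsv")),
                       progress = FALSE)
      readr::write_tsv(comp, note(file.path(out, "composition.tsv")),
                       progress = FALSE)
      bundle$assignments <- asg
      bundle$composition <- comp

      grouping <- setNames(asg$group, asg$clone_id)
      ranges <- run_stage("distances", subclade_range_table(dm, grouping))
      readr::write_tsv(ranges, note(file.path(out, "ranges.tsv")),
                       progress = FALSE)
      bundle$ranges <- ranges
    }
  }

  per_host_n <- config$per_host_n
  if (is.null(per_host_n) && !is.null(survey)) {
    counts <- dplyr::count(survey$truth, .data$host)
    per_host_n <- setNames(counts$n, counts$host)
  }
  if (!is.null(per_host_n)) {
    inc <- run_stage("detect", incidence_table(
      per_host_n, P = config$detection_P, digits = config$digits))
    readr::write_tsv(tidy(inc), note(file.path(out, "incidence.tsv")),
                     progress = FALSE)
    bundle$incidence <- inc
  }

  if (!is.null(aln) && config$bootstrap_reps > 0) {
    tree <- run_stage("phylo", bootstrap_supports(
      aln, reps = config$bootstrap_reps, seed = config$seed))
    run_stage("phylo", write_newick(tree, note(file.path(out, "tree.nwk"))))
    bundle$tree <- tree
  }

  run_json <- list(
    package = "clonesurvey",
    version = as.character(utils::packageVersion("clonesurvey")),
    seed = config$seed,
    config = config[setdiff(names(config), c("design", "out_dir"))],
    design = if (!is.null(config$design)) {
      dplyr::select(config$design, -dplyr::any_of("mixture"))
    },
    artifacts = basename(unique(written))
  )
  jsonlite::write_json(run_json, note(file.path(out, "run.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")

  write_report(bundle, note(file.path(out, "report.md")))
  ok <- TRUE
  bundle$paths <- unique(written)
  invisible(bundle)
}

#' Write a human-readable survey report
#'
#' One markdown summary of a pipeline bundle: the detection model's i.i.d.
#' assumption, the per-host maximum-incidence table, subclade composition,
#' and clone totals. Every number is the rounded form of a value present in
#' a machine-readable artifact.
#'
#' @param bundle A bundle from [run_survey_pipeline()] (or a compatible named
#'   list with at least one result).
#' @param path Output markdown path.
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path) {
  if (is.null(bundle$incidence) && is.null(bundle$composition) &&
      is.null(bundle$distances)) {
    abort("bundle is empty: nothing to report")
  }
  if (!is.null(bundle$survey) && !is.null(bundle$composition)) {
    if (sum(bundle$composition$clone_count) != nrow(bundle$survey$truth)) {
      abort("inconsistent bundle: composition totals != truth-table totals")
    }
  }
  digits <- if (!is.null(bundle$config)) bundle$config$digits else 3
  lines <- c("# Clone-library survey report", "")
  if (!is.null(bundle$survey)) {
    g <- glance(bundle$survey)
    lines <- c(lines, sprintf(
      "Simulated survey: %d clones in %d capsules across %d sites (%d hosts); %d non-target clone(s); seed %d.",
      g$n_clones, g$n_capsules, g$n_sites, g$n_hosts, g$n_non_target,
      bundle$config$seed), "")
  }
  if (!is.null(bundle$incidence)) {
    P <- attr(bundle$incidence, "P")
    lines <- c(lines,
      "## Maximum undetected incidence", "",
      sprintf("Cumulative detection probability threshold P = %s.",
              format(P)),
      paste0("Assumes equal incidence of non-target taxa among all samples ",
             "and no amplification bias during PCR (clones are independent ",
             "identically distributed draws)."),
      "",
      "| host | n | max incidence |",
      "|---|---|---|",
      sprintf("| %s | %d | %s |", bundle$incidence$host, bundle$incidence$n,
              formatC(bundle$incidence$q_max_rounded,
                      format = "f", digits = digits)),
      "")
  }
  if (!is.null(bundle$composition)) {
    lines <- c(lines,
      "## Subclade composition", "",
      "| host | site | group | clones | fraction |",
      "|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %d | %.3f |",
              bundle$composition$host, bundle$composition$site_code,
              bundle$composition$group, bundle$composition$clone_count,
              bundle$composition$fraction),
      "")
  }
  if (!is.null(bundle$ranges)) {
    lines <- c(lines,
      "## Pairwise p-distance ranges (%)", "",
      "| group 1 | group 2 | min | max |",
      "|---|---|---|---|",
      sprintf("| %s | %s | %s | %s |",
              bundle$ranges$group1, bundle$ranges$group2,
              ifelse(is.na(bundle$ranges$min_pct), "-",
                     sprintf("%.2f", bundle$ranges$min_pct)),
              ifelse(is.na(bundle$ranges$max_pct), "-",
                     sprintf("%.2f", bundle$ranges$max_pct))),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}
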