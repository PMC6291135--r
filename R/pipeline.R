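#' Build a validated pipeline configuration
#'
#' Collects every tunable parameter of the full analysis into one list.
#' Unknown keys are rejected so that config typos fail loudly. A config
#' can also be loaded from YAML with [read_pipeline_config()].
#'
#' @param beta_path,annotation_path,samplesheet_path Input TSV paths
#'   ([read_beta_dataset()]); omit all three to analyse a dataset passed
#'   directly to [run_pipeline()].
#' @param pairs List of length-2 character vectors of method labels;
#'   default all pairwise combinations of the methods found in the data.
#' @param stages Character vector of stages to run, a subset of
#'   `c("filter", "agreement", "pca", "differential", "dmr")`.
#' @param z Limit-of-agreement multiplier (default 1.96).
#' @param subsample_n,n_repeats Normality-screen subsample size and repeat
#'   count (defaults 5000 and 10).
#' @param max_gap,cutoff,n_boot Region-search parameters (defaults 1000 bp,
#'   0.01, 250).
#' @param loess_span,min_sites_smooth Smoothing parameters for the region
#'   search.
#' @param fit_subsample Optional point subsample for the variance-model
#'   fit.
#' @param seed Global seed; a fixed seed makes the whole run reproducible.
#' @param out_dir Output directory for the report and stage outputs, or
#'   `NULL` to return the report only.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(beta_path = NULL, annotation_path = NULL,
                            samplesheet_path = NULL, pairs = NULL,
                            stages = c("filter", "agreement", "pca",
                                       "differential", "dmr"),
                            z = 1.96, subsample_n = 5000, n_repeats = 10,
                            max_gap = 1000, cutoff = 0.01, n_boot = 250,
                            loess_span = 0.75, min_sites_smooth = 7,
                            fit_subsample = NULL, seed = 1L,
                            out_dir = NULL) {
  known_stages <- c("filter", "agreement", "pca", "differential", "dmr")
  bad <- setdiff(stages, known_stages)
  if (length(bad) > 0)
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(beta_path = beta_path, annotation_path = annotation_path,
                 samplesheet_path = samplesheet_path, pairs = pairs,
                 stages = stages, z = z, subsample_n = subsample_n,
                 n_repeats = n_repeats, max_gap = max_gap, cutoff = cutoff,
                 n_boot = n_boot, loess_span = loess_span,
                 min_sites_smooth = min_sites_smooth,
                 fit_subsample = fit_subsample, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments;
#'   unknown keys are rejected.
#' @param ... Overrides applied on top of the file's values (an override
#'   wins over the file).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full agreement-analysis pipeline
#'
#' Executes, in order: site filtering, per-pair Bland-Altman agreement
#' (points summary, variance-model fit, normality screen, difference
#' distribution), PC-covariate screening, and per-pair differential
#' testing (global and per-CpG paired t, optional region search). Returns
#' a single report list embedding every stage's output plus provenance
#' (config hash, package and R versions, seed); if `config$out_dir` is set
#' the report is also written as JSON, stage tables as TSV, and a MANIFEST
#' records per-stage completion so a failed run leaves its partial outputs
#' identifiable.
#'
#' Timestamps live only in `report$header$created`, so two runs with the
#' same config and seed are identical everywhere else.
#'
#' @param config A [pipeline_config()].
#' @param ds Optional [beta_dataset()]; required when the config carries no
#'   input paths.
#' @param filter A [filter_spec()] for the filter stage (default
#'   [filter_spec()] with no detection matrix).
#' @return The report, invisibly also written to disk when `out_dir` is
#'   set. See `inst/schema/report-schema.json` for its structure.
#' @export
run_pipeline <- function(config, ds = NULL, filter = filter_spec()) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list()
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  note_stage <- function(stage, status) {
    manifest[[stage]] <<- status
    if (!is.null(out_dir))
      jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                           auto_unbox = TRUE)
  }

  if (is.null(ds)) {
    if (is.null(config$beta_path))
      stop("no dataset given and no input paths in config")
    ds <- read_beta_dataset(config$beta_path, config$annotation_path,
                            config$samplesheet_path)
  }

  report <- list(
    header = list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    provenance = list(
      package_version = as.character(utils::packageVersion("methagree")),
      r_version = R.version.string,
      seed = config$seed,
      config = config_for_report(config),
      config_hash = rlang::hash(config_for_report(config))
    )
  )

  if ("filter" %in% config$stages) {
    fl <- filter_sites(ds, filter)
    ds <- fl$dataset
    report$filter <- list(counts = as.list(stats::setNames(
      fl$report$n_removed, fl$report$category)))
    note_stage("filter", "done")
  }

  methods <- dataset_methods(ds)
  pairs <- config$pairs %||% utils::combn(methods, 2, simplify = FALSE)
  report$dataset <- list(n_sites = nrow(ds$betas), n_samples = ncol(ds$betas),
                         n_subjects = length(dataset_subjects(ds)),
                         methods = methods)

  if ("agreement" %in% config$stages) {
    report$agreement <- lapply(pairs, function(pr) {
      pts <- pairwise_points(ds, pr[1], pr[2])
      fit <- fit_variance_model(pts, z = config$z,
                                subsample = config$fit_subsample,
                                seed = config$seed)
      scr <- if (nrow(pts) >= config$subsample_n)
        normality_screen(pts, config$subsample_n, config$n_repeats,
                         config$seed)
      else NULL
      dd <- difference_distribution(ds, pr[1], pr[2])
      if (!is.null(out_dir))
        readr::write_tsv(dd, file.path(out_dir, sprintf(
          "distribution_%s_vs_%s.tsv", pr[1], pr[2])), progress = FALSE)
      list(pair = pr, n_points = nrow(pts),
           fit = as.list(glance(fit)),
           normality_p = if (is.null(scr)) NULL else scr$p_value,
           distribution = list(bin_lo = dd$bin_lo, bin_hi = dd$bin_hi,
                               percent = dd$percent))
    })
    names(report$agreement) <- vapply(pairs, paste, character(1),
                                      collapse = "_vs_")
    note_stage("agreement", "done")
  }

  if ("pca" %in% config$stages) {
    pca <- run_pca(ds)
    screen <- pc_association_screen(pca)
    if (!is.null(out_dir)) {
      readr::write_tsv(pca$scores, file.path(out_dir, "pca_scores.tsv"),
                       progress = FALSE)
      readr::write_tsv(screen, file.path(out_dir, "pc_associations.tsv"),
                       progress = FALSE)
    }
    report$pca <- list(
      variance_explained = pca$variance_explained,
      n_components = pca$n_components,
      significant = as.list(screen[!is.na(screen$p_adjusted) &
                                     screen$p_adjusted < 0.05, ])
    )
    note_stage("pca", "done")
  }

  if ("differential" %in% config$stages) {
    report$differential <- lapply(pairs, function(pr) {
      gl <- global_paired_t(ds, pr[1], pr[2])
      per <- per_site_paired_t(ds, pr[1], pr[2])
      if (!is.null(out_dir))
        readr::write_tsv(per, file.path(out_dir, sprintf(
          "per_site_%s_vs_%s.tsv", pr[1], pr[2])), progress = FALSE)
      block <- list(pair = pr, global = as.list(gl),
                    n_sites_tested = sum(!is.na(per$p_raw)),
                    n_significant_fdr05 = sum(per$p_bh < 0.05, na.rm = TRUE))
      if ("dmr" %in% config$stages) {
        regions <- find_bumps(ds, pr[1], pr[2], cutoff = config$cutoff,
                              loess_span = config$loess_span,
                              min_sites_smooth = config$min_sites_smooth,
                              n_boot = config$n_boot,
                              max_gap = config$max_gap, seed = config$seed)
        if (!is.null(out_dir))
          readr::write_tsv(regions, file.path(out_dir, sprintf(
            "regions_%s_vs_%s.tsv", pr[1], pr[2])), progress = FALSE)
        block$regions <- list(n_candidates = nrow(regions),
                              n_significant_fwer05 =
                                sum(regions$fwer < 0.05))
      }
      block
    })
    names(report$differential) <- vapply(pairs, paste, character(1),
                                         collapse = "_vs_")
    note_stage("differential", "done")
    if ("dmr" %in% config$stages) note_stage("dmr", "done")
  }

  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

# config as plain named list for hashing/serialisation: drops the class,
# NULLs, and out_dir (where outputs land does not affect what is computed,
# and must not break the same-config determinism contract)
config_for_report <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  x[!vapply(x, is.null, logical(1))]
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks the report's structure against the JSON schema at
#' `inst/schema/report-schema.json`: required keys must be present and of
#' the declared type (a minimal structural check, not a full JSON-Schema
#' engine).
#'
#' @param report A report list from [run_pipeline()] or a path to a
#'   `report.json`.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(
    system.file("schema", "report-schema.json", package = "methagree"))
  check_node(report, schema, "report")
  invisible(TRUE)
}

check_node <- function(node, schema, where) {
  type <- schema$type
  if (identical(type, "object")) {
    if (!is.list(node)) stop(where, ": expected object")
    for (key in unlist(schema$required))
      if (is.null(node[[key]]))
        stop(where, ": missing required key '", key, "'")
    props <- schema$properties
    for (key in names(props))
      if (!is.null(node[[key]]))
        check_node(node[[key]], props[[key]], paste0(where, ".", key))
  } else if (identical(type, "number")) {
    if (!is.numeric(unlist(node))) stop(where, ": expected number")
  } else if (identical(type, "integer")) {
    v <- unlist(node)
    if (!is.numeric(v) || any(v != round(v))) stop(where, ": expected integer")
  } else if (identical(type, "string")) {
    if (!is.character(unlist(node))) stop(where, ": expected string")
  } else if (identical(type, "array")) {
    if (!is.null(schema$items))
      for (el in node) check_node(el, schema$items, paste0(where, "[]"))
  }
  invisible(TRUE)
}
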