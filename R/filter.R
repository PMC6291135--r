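#' Specify a site-filtering scheme
#'
#' Describes which sites to remove before analysis. Filters are applied in a
#' fixed order -- blacklist, detection p-value, non-CpG context, missing
#' values, chromosome -- and each removed site is counted once, under the
#' first rule that removes it.
#'
#' @param detection_p Optional sites-by-samples matrix of detection
#'   p-values (same shape and dimnames as the beta matrix). A site is
#'   removed when any sample's detection p exceeds `detection_threshold`.
#' @param detection_threshold Detection p-value cutoff, default 0.01.
#' @param blacklist_ids Character vector of site ids to drop (e.g.
#'   cross-reactive probes).
#' @param drop_non_cpg Drop sites annotated `context == "non_cpg"`? Default
#'   `TRUE`.
#' @param drop_missing Drop sites with any missing beta value? Default
#'   `TRUE`.
#' @param drop_chroms Chromosome names to drop; default the sex chromosomes
#'   `c("chrX", "chrY")`. Names are matched as given, optionally after
#'   normalising a "chr" prefix with `normalize_chr`.
#' @param normalize_chr If `TRUE`, compare chromosome names after stripping
#'   any leading "chr" from both sides. Default `FALSE`.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(detection_p = NULL, detection_threshold = 0.01,
                        blacklist_ids = character(), drop_non_cpg = TRUE,
                        drop_missing = TRUE, drop_chroms = c("chrX", "chrY"),
                        normalize_chr = FALSE) {
  if (!is.null(detection_p)) detection_p <- as.matrix(detection_p)
  stopifnot(is.numeric(detection_threshold), length(detection_threshold) == 1,
            detection_threshold > 0, detection_threshold < 1)
  structure(list(detection_p = detection_p,
                 detection_threshold = detection_threshold,
                 blacklist_ids = as.character(blacklist_ids),
                 drop_non_cpg = isTRUE(drop_non_cpg),
                 drop_missing = isTRUE(drop_missing),
                 drop_chroms = as.character(drop_chroms),
                 normalize_chr = isTRUE(normalize_chr)),
            class = "filter_spec")
}

#' Filter sites from a beta-value dataset
#'
#' Removes low-quality or unwanted sites according to a [filter_spec()].
#' Rules are applied in the order blacklist, detection, non-CpG, missing,
#' chromosome; each site is counted under the first rule that removes it, so
#' the per-category counts plus the retained count always add up to the
#' input site count.
#'
#' @param ds A [beta_dataset()].
#' @param spec A [filter_spec()].
#' @return A list with elements `dataset` (the filtered [beta_dataset()])
#'   and `report` (a tibble with columns `category` and `n_removed`,
#'   including a final `retained` row). An error is raised if no site
#'   survives.
#' @export
#' @examples
#' ds <- simulate_dataset(simulation_params(n_subjects = 2, n_sites = 20))
#' filtered <- filter_sites(ds, filter_spec(drop_chroms = character()))
#' filtered$report
filter_sites <- function(ds, spec = filter_spec()) {
  stopifnot(inherits(ds, "beta_dataset"), inherits(spec, "filter_spec"))
  n <- nrow(ds$betas)
  reason <- rep(NA_character_, n)

  mark <- function(reason, hit, label) {
    ifelse(is.na(reason) & hit, label, reason)
  }

  reason <- mark(reason, ds$sites$site_id %in% spec$blacklist_ids, "blacklist")

  if (!is.null(spec$detection_p)) {
    dp <- spec$detection_p
    if (!identical(dim(dp), dim(ds$betas)))
      stop("detection_p has dimensions ", paste(dim(dp), collapse = " x "),
           " but beta matrix is ", paste(dim(ds$betas), collapse = " x "))
    bad <- apply(dp > spec$detection_threshold, 1, any, na.rm = TRUE)
    reason <- mark(reason, bad, "detection")
  }

  if (spec$drop_non_cpg)
    reason <- mark(reason, ds$sites$context == "non_cpg", "non_cpg")

  if (spec$drop_missing)
    reason <- mark(reason, rowSums(is.na(ds$betas)) > 0, "missing")

  chroms <- ds$sites$chrom
  drop_chr <- spec$drop_chroms
  if (spec$normalize_chr) {
    chroms <- sub("^chr", "", chroms)
    drop_chr <- sub("^chr", "", drop_chr)
  }
  reason <- mark(reason, chroms %in% drop_chr, "chromosome")

  keep <- is.na(reason)
  if (!any(keep)) stop("no sites retained after filtering")

  categories <- c("blacklist", "detection", "non_cpg", "missing", "chromosome")
  counts <- vapply(categories, function(cat) sum(reason == cat, na.rm = TRUE),
                   integer(1))
  report <- tibble::tibble(
    category = c(categories, "retained"),
    n_removed = c(unname(counts), NA_integer_)
  )
  report$n_removed[report$category == "retained"] <- sum(keep)

  out <- beta_dataset(ds$betas[keep, , drop = FALSE],
                      ds$sites[keep, ], ds$samples)
  list(dataset = out, report = report)
}

#' Write a filter report as JSON
#'
#' @param report The `report` tibble returned by [filter_sites()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_filter_report <- function(report, path) {
  x <- as.list(stats::setNames(report$n_removed, report$category))
  jsonlite::write_json(x, path, auto_unbox = TRUE)
  invisible(path)
}
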