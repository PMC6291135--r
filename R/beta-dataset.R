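#' Construct a beta-value dataset
#'
#' A `beta_dataset` bundles a sites-by-samples matrix of methylation
#' beta-values (fractions in \[0, 1\]) with a site annotation table and a
#' sample sheet. It is the central object of the package: every analysis
#' function takes one.
#'
#' @param betas Numeric matrix, sites in rows, samples in columns. Row names
#'   are site ids and column names sample ids; if absent they are taken from
#'   `sites$site_id` and `samples$sample_id`. Values must lie in \[0, 1\];
#'   `NA` is allowed (filter before analysis).
#' @param sites Data frame with columns `site_id`, `chrom`, `pos` (1-based,
#'   array-manifest convention) and `context` (`"cpg"` or `"non_cpg"`), one
#'   row per matrix row.
#' @param samples Data frame with columns `sample_id`, `subject_id`,
#'   `method`, `chip_position`, `yield_ug`, `a260_280`, `a260_230`, one row
#'   per matrix column.
#'
#' @return An object of class `beta_dataset`: a list with elements `betas`
#'   (matrix), `sites` and `samples` (tibbles).
#' @export
#' @examples
#' b <- matrix(c(0.1, 0.9, 0.5, 0.2, 0.8, 0.6), nrow = 3,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' ds <- beta_dataset(b, example_sites(3), example_samples(c("s1", "s2")))
#' ds
beta_dataset <- function(betas, sites, samples) {
  betas <- as.matrix(betas)
  storage.mode(betas) <- "double"
  sites <- tibble::as_tibble(sites)
  samples <- tibble::as_tibble(samples)

  need_site <- c("site_id", "chrom", "pos", "context")
  need_samp <- c("sample_id", "subject_id", "method", "chip_position",
                 "yield_ug", "a260_280", "a260_230")
  miss <- setdiff(need_site, names(sites))
  if (length(miss) > 0)
    stop("site annotation is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need_samp, names(samples))
  if (length(miss) > 0)
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))

  if (nrow(betas) != nrow(sites))
    stop("beta matrix has ", nrow(betas), " rows but annotation has ",
         nrow(sites), " sites")
  if (ncol(betas) != nrow(samples))
    stop("beta matrix has ", ncol(betas), " columns but sample sheet has ",
         nrow(samples), " samples")
  if (anyDuplicated(sites$site_id))
    stop("duplicated site_id in annotation: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]), collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample sheet")
  if (anyDuplicated(paste(samples$subject_id, samples$method, sep = "\r")))
    stop("sample sheet has duplicated (subject_id, method) combinations")
  if (any(sites$pos < 1, na.rm = TRUE)) stop("site positions must be >= 1")
  if (!all(sites$context %in% c("cpg", "non_cpg")))
    stop("site context must be 'cpg' or 'non_cpg'")

  if (is.null(rownames(betas))) rownames(betas) <- sites$site_id
  if (is.null(colnames(betas))) colnames(betas) <- samples$sample_id
  if (!identical(rownames(betas), as.character(sites$site_id)))
    stop("beta matrix row names do not match annotation site_id order")
  if (!identical(colnames(betas), as.character(samples$sample_id)))
    stop("beta matrix column names do not match sample sheet sample_id order")

  check_beta_range(betas)

  structure(list(betas = betas, sites = sites, samples = samples),
            class = "beta_dataset")
}

check_beta_range <- function(betas) {
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop("beta values outside [0, 1]: first offender is site '",
         rownames(betas)[i], "', sample '", colnames(betas)[j], "' (value ",
         format(betas[i, j]), "); ", nrow(bad), " offending cell(s) in total")
  }
  invisible(TRUE)
}

#' @export
print.beta_dataset <- function(x, ...) {
  cat("<beta_dataset> ", nrow(x$betas), " sites x ", ncol(x$betas),
      " samples\n", sep = "")
  cat("  subjects: ", length(unique(x$samples$subject_id)),
      " | methods: ", paste(unique(x$samples$method), collapse = ", "), "\n",
      sep = "")
  nmiss <- sum(is.na(x$betas))
  cat("  missing beta values: ", nmiss, "\n", sep = "")
  invisible(x)
}

#' @export
dim.beta_dataset <- function(x) dim(x$betas)

#' Number of subjects and methods in a dataset
#' @param ds A [beta_dataset()].
#' @return Character vector of method labels (`methods()`), or subject ids.
#' @export
dataset_methods <- function(ds) unique(ds$samples$method)

#' @rdname dataset_methods
#' @export
dataset_subjects <- function(ds) unique(ds$samples$subject_id)

#' Read a beta-value dataset from TSV files
#'
#' Reads the three tab-separated files that define a dataset: the beta
#' matrix (first column `site_id`, remaining columns one per sample), the
#' site annotation (`site_id`, `chrom`, `pos`, `context`) and the sample
#' sheet (`sample_id`, `subject_id`, `method`, `chip_position`, `yield_ug`,
#' `a260_280`, `a260_230`). Missing beta values may be encoded as an empty
#' field or `NA`.
#'
#' @param beta_path,annotation_path,samplesheet_path Paths to the three TSV
#'   files.
#' @return A validated [beta_dataset()]. Sample columns of the matrix are
#'   matched to the sample sheet by `sample_id`; any mismatch is an error
#'   listing the offending ids.
#' @export
read_beta_dataset <- function(beta_path, annotation_path, samplesheet_path) {
  for (p in c(beta_path, annotation_path, samplesheet_path))
    if (!file.exists(p)) stop("file not found: ", p)

  # beta columns come in as character and go through base strtod: vroom's
  # fast double parser can be one ulp off, breaking round-trip identity
  beta_df <- readr::read_tsv(beta_path, show_col_types = FALSE,
                             na = c("", "NA"), progress = FALSE,
                             col_types = readr::cols(.default = "c"))
  if (names(beta_df)[1] != "site_id")
    stop("beta matrix must have 'site_id' as its first column, found '",
         names(beta_df)[1], "'")
  sites <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                           progress = FALSE)
  samples <- readr::read_tsv(samplesheet_path, show_col_types = FALSE,
                             progress = FALSE)

  sample_cols <- names(beta_df)[-1]
  for (cn in sample_cols) {
    v <- beta_df[[cn]]
    num <- suppressWarnings(as.double(v))
    bad <- is.na(num) & !is.na(v)
    if (any(bad))
      stop("non-numeric beta value in column '", cn, "', site '",
           beta_df$site_id[which(bad)[1]], "' (value '", v[which(bad)[1]], "')")
    beta_df[[cn]] <- num
  }

  unmatched_cols <- setdiff(sample_cols, samples$sample_id)
  if (length(unmatched_cols) > 0)
    stop("beta matrix column(s) absent from sample sheet: ",
         paste(unmatched_cols, collapse = ", "))
  unmatched_sheet <- setdiff(samples$sample_id, sample_cols)
  if (length(unmatched_sheet) > 0)
    stop("sample sheet sample(s) absent from beta matrix: ",
         paste(unmatched_sheet, collapse = ", "))

  miss_ann <- setdiff(beta_df$site_id, sites$site_id)
  if (length(miss_ann) > 0)
    stop("site(s) in beta matrix missing from annotation: ",
         paste(utils::head(miss_ann, 5), collapse = ", "),
         if (length(miss_ann) > 5) ", ...")
  extra_ann <- setdiff(sites$site_id, beta_df$site_id)
  if (length(extra_ann) > 0)
    stop("annotated site(s) missing from beta matrix: ",
         paste(utils::head(extra_ann, 5), collapse = ", "),
         if (length(extra_ann) > 5) ", ...")

  sites <- sites[match(beta_df$site_id, sites$site_id), ]
  betas <- as.matrix(beta_df[sample_cols])
  rownames(betas) <- beta_df$site_id
  # order sample-sheet rows to the matrix columns
  samples <- samples[match(sample_cols, samples$sample_id), ]
  beta_dataset(betas, sites, samples)
}

#' Write a beta-value dataset to TSV files
#'
#' Inverse of [read_beta_dataset()]. Values are written with full precision
#' (shortest round-trip representation) so that `read(write(ds))`
#' reproduces `ds` bit-exactly.
#'
#' @param ds A [beta_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"dataset"`.
#' @return Invisibly, a named character vector of the three paths written
#'   (`beta`, `annotation`, `samplesheet`).
#' @export
write_beta_dataset <- function(ds, dir, prefix = "dataset") {
  stopifnot(inherits(ds, "beta_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    beta = file.path(dir, paste0(prefix, "_beta.tsv")),
    annotation = file.path(dir, paste0(prefix, "_annotation.tsv")),
    samplesheet = file.path(dir, paste0(prefix, "_samples.tsv"))
  )
  beta_df <- tibble::as_tibble(ds$betas, rownames = "site_id")
  # %.17g guarantees bit-exact round-trip of doubles through the TSV
  beta_df <- dplyr::mutate(beta_df, dplyr::across(
    -"site_id", function(x) ifelse(is.na(x), NA, sprintf("%.17g", x))))
  readr::write_tsv(beta_df, paths["beta"], progress = FALSE, na = "NA")
  readr::write_tsv(ds$sites, paths["annotation"], progress = FALSE)
  readr::write_tsv(ds$samples, paths["samplesheet"], progress = FALSE)
  invisible(paths)
}

#' Minimal example annotation and sample sheet
#'
#' Convenience builders used in examples and tests: `example_sites()` places
#' `n` CpG sites on one chromosome at 500-bp spacing; `example_samples()`
#' fills a sample sheet with one subject per sample and neutral QC values.
#'
#' @param n Number of sites.
#' @param chrom Chromosome label.
#' @param spacing Base-pair spacing between consecutive sites.
#' @return A tibble in the annotation (resp. sample sheet) layout.
#' @export
example_sites <- function(n, chrom = "chr1", spacing = 500) {
  tibble::tibble(
    site_id = sprintf("cg%07d", seq_len(n)),
    chrom = chrom,
    pos = as.integer(seq(1, by = spacing, length.out = n)),
    context = "cpg"
  )
}

#' @rdname example_sites
#' @param sample_ids Character vector of sample ids.
#' @export
example_samples <- function(sample_ids) {
  n <- length(sample_ids)
  tibble::tibble(
    sample_id = sample_ids,
    subject_id = paste0("subj", seq_len(n)),
    method = paste0("method", seq_len(n)),
    chip_position = "R01C01",
    yield_ug = 10,
    a260_280 = 1.9,
    a260_230 = 2.0
  )
}

# Extract the sites x subjects beta matrix for one method, columns ordered
# by subject id. Errors if any subject lacks the method.
method_matrix <- function(ds, method, subjects = NULL) {
  if (is.null(subjects)) subjects <- sort(dataset_subjects(ds))
  rows <- ds$samples[ds$samples$method == method, ]
  if (nrow(rows) == 0) stop("method '", method, "' not present in dataset")
  missing_subj <- setdiff(subjects, rows$subject_id)
  if (length(missing_subj) > 0)
    stop("subject(s) missing method '", method, "': ",
         paste(missing_subj, collapse = ", "))
  ids <- rows$sample_id[match(subjects, rows$subject_id)]
  m <- ds$betas[, ids, drop = FALSE]
  colnames(m) <- subjects
  m
}
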