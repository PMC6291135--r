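#' Principal component analysis of a beta-value dataset
#'
#' Runs PCA with samples as observations and sites as variables (site-wise
#' centring by default, no scaling: beta-values already share a common
#' scale). Used to screen for strong signals related to technical factors
#' such as extraction method or chip position.
#'
#' @param ds A [beta_dataset()] without missing values.
#' @param center,scale. Passed to [stats::prcomp()]; defaults centre only.
#' @param n_components Number of components to keep; default all
#'   `min(n_samples - 1, n_sites)`.
#' @return An object of class `beta_pca`: `scores` (tibble, one row per
#'   sample), `variance_explained` (fractions, non-increasing, summing to
#'   <= 1), `n_components`, and the sample sheet.
#' @export
#' @examples
#' ds <- simulate_dataset(simulation_params(n_subjects = 4, n_sites = 200))
#' pca <- run_pca(ds)
#' glance(pca)
run_pca <- function(ds, center = TRUE, scale. = FALSE, n_components = NULL) {
  stopifnot(inherits(ds, "beta_dataset"))
  if (anyNA(ds$betas))
    stop("beta matrix contains missing values; run filter_sites() first")
  if (ncol(ds$betas) < 2) stop("PCA needs at least 2 samples")
  pr <- stats::prcomp(t(ds$betas), center = center, scale. = scale.)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  # centring makes at most n_samples - 1 components meaningful
  k_max <- min(ncol(ds$betas) - 1, nrow(ds$betas), length(ve))
  k <- min(n_components %||% k_max, length(ve))
  scores <- tibble::as_tibble(pr$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = ds$samples$sample_id), scores)
  structure(list(scores = scores, variance_explained = ve[seq_len(k)],
                 n_components = k, samples = ds$samples),
            class = "beta_pca")
}

#' @export
print.beta_pca <- function(x, ...) {
  cat("<beta_pca> ", nrow(x$scores), " samples, ", x$n_components,
      " components\n", sep = "")
  cat("  variance explained (first 5): ",
      paste(sprintf("%.1f%%",
                    100 * utils::head(x$variance_explained, 5)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy methods for PCA results
#'
#' @param x A `beta_pca`.
#' @param ... Unused.
#' @return `tidy()`: long tibble (`sample_id`, `component`, `score`);
#'   `glance()`: one row per component with `variance_explained` and its
#'   cumulative sum.
#' @method tidy beta_pca
#' @export
tidy.beta_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"sample_id", names_to = "component",
                      values_to = "score")
}

#' @rdname tidy.beta_pca
#' @method glance beta_pca
#' @export
glance.beta_pca <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_len(x$n_components)),
                 variance_explained = x$variance_explained,
                 cumulative = cumsum(x$variance_explained))
}

#' Kruskal-Wallis rank test
#'
#' Thin wrapper around [stats::kruskal.test()] returning a one-row tibble,
#' with explicit handling of the degenerate all-identical case (H = 0,
#' p = 1, with a warning).
#'
#' @param values Numeric vector.
#' @param groups Grouping factor (>= 2 non-empty groups).
#' @return Tibble with columns `statistic` (tie-corrected H), `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  if (length(unique(values)) == 1) {
    warning("all values identical; Kruskal-Wallis H = 0, p = 1")
    return(tibble::tibble(statistic = 0, df = nlevels(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = as.integer(kt$parameter), p = kt$p.value)
}

#' Spearman rank correlation test
#'
#' Thin wrapper around [stats::cor.test()] with `method = "spearman"`,
#' two-sided. A constant input makes the correlation undefined: `NA` is
#' returned with a warning rather than an error.
#'
#' @param values,covariate Equal-length numeric vectors (n >= 3).
#' @return Tibble with columns `rho` and `p`.
#' @export
spearman <- function(values, covariate) {
  stopifnot(length(values) == length(covariate), length(values) >= 3)
  if (stats::sd(values) == 0 || stats::sd(covariate) == 0) {
    warning("constant input; Spearman correlation undefined, recorded as NA")
    return(tibble::tibble(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(  # tie-induced "cannot compute exact p" is expected
    stats::cor.test(values, covariate, method = "spearman",
                    alternative = "two.sided"))
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value)
}

#' Screen principal components against technical covariates
#'
#' Tests each retained PC against each covariate: Kruskal-Wallis for
#' categorical covariates (method, chip position), two-sided Spearman
#' correlation for numeric ones (DNA yield, purity ratios). Multiple
#' testing is corrected per covariate across PCs by Bonferroni
#' (`p_adjusted = min(1, n_components * p_raw)`).
#'
#' @param pca A `beta_pca` from [run_pca()].
#' @param samples Sample sheet; defaults to the one stored in `pca`.
#' @param covariates Covariate column names to test; default
#'   `c("method", "chip_position", "yield_ug", "a260_280", "a260_230")`.
#' @return A tibble with one row per (component, covariate): columns
#'   `component`, `covariate`, `test`, `statistic`, `p_raw`, `p_adjusted`.
#' @export
pc_association_screen <- function(pca, samples = NULL,
                                  covariates = c("method", "chip_position",
                                                 "yield_ug", "a260_280",
                                                 "a260_230")) {
  stopifnot(inherits(pca, "beta_pca"))
  samples <- samples %||% pca$samples
  unknown <- setdiff(covariates, names(samples))
  if (length(unknown) > 0)
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
  stopifnot(identical(samples$sample_id, pca$scores$sample_id))

  comps <- paste0("PC", seq_len(pca$n_components))
  res <- purrr::map_dfr(covariates, function(cv) {
    v <- samples[[cv]]
    categorical <- is.character(v) || is.factor(v)
    purrr::map_dfr(comps, function(pc) {
      sc <- pca$scores[[pc]]
      if (categorical) {
        r <- kruskal_wallis(sc, v)
        tibble::tibble(component = pc, covariate = cv,
                       test = "kruskal_wallis", statistic = r$statistic,
                       p_raw = r$p)
      } else {
        r <- spearman(sc, as.numeric(v))
        tibble::tibble(component = pc, covariate = cv, test = "spearman",
                       statistic = r$rho, p_raw = r$p)
      }
    })
  })
  dplyr::mutate(dplyr::group_by(res, .data$covariate),
                p_adjusted = pmin(1, dplyr::n() * .data$p_raw)) %>%
    dplyr::ungroup()
}

#' Scatter plot of two principal components
#'
#' @param object A `beta_pca`.
#' @param components Which two PCs to plot, default `c(1, 2)`.
#' @param colour Sample-sheet column mapped to colour, default
#'   `"subject_id"`.
#' @param shape Sample-sheet column mapped to shape, default `"method"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot beta_pca
#' @export
autoplot.beta_pca <- function(object, components = c(1, 2),
                              colour = "subject_id", shape = "method", ...) {
  pcs <- paste0("PC", components)
  df <- dplyr::left_join(object$scores, object$samples, by = "sample_id")
  ve <- 100 * object$variance_explained[components]
  ggplot2::ggplot(df, ggplot2::aes(.data[[pcs[1]]], .data[[pcs[2]]],
                                   colour = .data[[colour]],
                                   shape = .data[[shape]])) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", pcs[1], ve[1]),
                  y = sprintf("%s (%.1f%%)", pcs[2], ve[2])) +
    ggplot2::theme_minimal()
}
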