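#' Bland-Altman points for a pair of methods
#'
#' For every subject-site combination, computes the average of the two
#' methods' beta-values (`x`) and their signed difference
#' (`d = method1 - method2`). With a complete paired design this yields
#' `n_subjects * n_sites` points -- e.g. 4,401,100 for 10 subjects over
#' 440,110 sites.
#'
#' @param ds A [beta_dataset()].
#' @param method1,method2 Method labels present for every subject.
#' @return A tibble of class `ba_points` with columns `subject_id`,
#'   `site_id`, `x`, `d`, and attributes `methods` and `n_points`.
#' @export
#' @examples
#' ds <- simulate_dataset(simulation_params(n_subjects = 3, n_sites = 100))
#' pts <- pairwise_points(ds, "M", "A")
#' head(pts)
pairwise_points <- function(ds, method1, method2) {
  stopifnot(inherits(ds, "beta_dataset"))
  subjects <- sort(dataset_subjects(ds))
  b1 <- method_matrix(ds, method1, subjects)
  b2 <- method_matrix(ds, method2, subjects)
  if (anyNA(b1) || anyNA(b2))
    stop("beta matrix contains missing values; run filter_sites() first")
  pts <- tibble::tibble(
    subject_id = rep(subjects, each = nrow(b1)),
    site_id = rep(rownames(b1), times = length(subjects)),
    x = as.vector((b1 + b2) / 2),
    d = as.vector(b1 - b2)
  )
  attr(pts, "methods") <- c(method1, method2)
  attr(pts, "n_points") <- nrow(pts)
  class(pts) <- c("ba_points", class(pts))
  pts
}

# Negative log-likelihood of d_i ~ N(0, sigma(x_i)^2),
# sigma(x) = exp(a + b*u), u = (x - 0.5)^2, and its gradient.
ba_nll <- function(par, u, d2) {
  s2inv <- exp(-2 * (par[1] + par[2] * u))
  sum(par[1] + par[2] * u) + sum(d2 * s2inv) / 2
}
ba_nll_grad <- function(par, u, d2) {
  w <- d2 * exp(-2 * (par[1] + par[2] * u))
  c(length(u) - sum(w), sum(u) - sum(u * w))
}

#' Fit the heteroscedastic variance model to Bland-Altman points
#'
#' Fits `d_i ~ N(0, sigma(x_i)^2)` with
#' `sigma(x) = exp(a + b*(x - 0.5)^2)` by minimising the Gaussian negative
#' log-likelihood `sum(log sigma(x_i) + d_i^2 / (2 sigma(x_i)^2))`. The
#' model has no bias (mean-difference) term; the empirical mean difference
#' is reported alongside, since classical Bland-Altman analysis centres its
#' limits on it.
#'
#' With `fix_b = 0` (or when all `x` are identical, making `b`
#' unidentifiable) the closed-form maximum-likelihood solution
#' `exp(2a) = mean(d^2)` is used directly.
#'
#' @param pts A [pairwise_points()] tibble, or any data frame with columns
#'   `x` and `d`.
#' @param z Limit-of-agreement multiplier, default 1.96.
#' @param subsample Optional integer: fit on a seeded uniform random subset
#'   of this many points (the full data is used by default; a two-parameter
#'   fit on millions of points is fast).
#' @param seed Seed for the subsample draw.
#' @param fix_b If non-`NULL`, hold `b` fixed at this value and solve for
#'   `a` in closed form (`fix_b = 0` gives the classical constant-variance
#'   Bland-Altman fit).
#' @return An object of class `variance_model_fit` with elements `a`, `b`,
#'   `z`, `converged`, `n_used`, `final_objective`, `mean_diff`, `methods`.
#'   Non-convergence yields `converged = FALSE` with a warning, never a
#'   silent failure.
#' @export
fit_variance_model <- function(pts, z = 1.96, subsample = NULL, seed = 1L,
                               fix_b = NULL) {
  stopifnot(is.data.frame(pts), all(c("x", "d") %in% names(pts)), z > 0)
  x <- pts$x; d <- pts$d
  if (length(d) < 10) stop("need at least 10 points to fit the variance model")
  if (all(d == 0)) stop("all differences are zero; variance model undefined")
  n_used <- length(d)
  if (!is.null(subsample) && subsample < length(d)) {
    set.seed(seed)
    idx <- sample.int(length(d), subsample)
    x <- x[idx]; d <- d[idx]
    n_used <- subsample
  }
  mean_diff <- mean(d)
  u <- (x - 0.5)^2
  d2 <- d^2

  degenerate_x <- stats::var(u) == 0
  if (degenerate_x && is.null(fix_b)) {
    warning("all x identical: b is unidentifiable, fixing b = 0")
    fix_b <- 0
  }

  if (!is.null(fix_b)) {
    # profile MLE for a at fixed b: exp(2a) = mean(d^2 * exp(-2 b u))
    a_hat <- 0.5 * log(mean(d2 * exp(-2 * fix_b * u)))
    fit <- list(a = a_hat, b = fix_b, converged = TRUE,
                objective = ba_nll(c(a_hat, fix_b), u, d2))
  } else {
    start <- c(0.5 * log(mean(d2)), 0)
    opt <- stats::optim(start, ba_nll, gr = ba_nll_grad, u = u, d2 = d2,
                        method = "BFGS",
                        control = list(reltol = 1e-12, maxit = 500))
    converged <- opt$convergence == 0
    if (!converged)
      warning("variance-model optimisation did not converge (code ",
              opt$convergence, ")")
    fit <- list(a = opt$par[1], b = opt$par[2], converged = converged,
                objective = opt$value)
  }

  structure(list(a = fit$a, b = fit$b, z = z, converged = fit$converged,
                 n_used = n_used, final_objective = fit$objective,
                 mean_diff = mean_diff,
                 methods = attr(pts, "methods") %||% c(NA, NA)),
            class = "variance_model_fit")
}

#' @export
print.variance_model_fit <- function(x, ...) {
  cat("<variance_model_fit> sigma(x) = exp(a + b*(x - 0.5)^2)\n")
  cat(sprintf("  a = %.4f, b = %.4f  (n = %d, %s)\n", x$a, x$b, x$n_used,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  limits of agreement: +/- %.2f * sigma(x); empirical mean difference %.2e\n",
              x$z, x$mean_diff))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted variance model
#'
#' @param x A `variance_model_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter with columns `term`, `estimate`.
#'   `glance()`: a one-row tibble with the fit summary.
#' @method tidy variance_model_fit
#' @export
tidy.variance_model_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @rdname tidy.variance_model_fit
#' @method glance variance_model_fit
#' @export
glance.variance_model_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, z = x$z, converged = x$converged,
                 n_used = x$n_used, objective = x$final_objective,
                 mean_diff = x$mean_diff)
}

#' Limits of agreement from a fitted variance model
#'
#' The limits at mean methylation `x` are `+/- z * sigma(x)` with
#' `sigma(x) = exp(a + b*(x - 0.5)^2)`; roughly 95% of between-method
#' differences are expected to fall inside them when `z = 1.96`.
#'
#' @param fit A `variance_model_fit`.
#' @param x_grid Numeric vector of mean methylation values in \[0, 1\].
#' @return A tibble with columns `x`, `lower`, `upper`.
#' @export
limits_of_agreement <- function(fit, x_grid = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(fit, "variance_model_fit"),
            all(x_grid >= 0 & x_grid <= 1))
  s <- sigma_fun(x_grid, fit$a, fit$b)
  tibble::tibble(x = x_grid, lower = -fit$z * s, upper = fit$z * s)
}

#' Repeated Shapiro-Wilk screen for normality of the differences
#'
#' Classical Bland-Altman limits assume normally distributed differences.
#' This screen draws `n_repeats` random subsamples of size `subsample_n`
#' (without replacement) from the differences and runs a Shapiro-Wilk test
#' on each; consistently tiny p-values indicate the constant-variance
#' normal model is inadequate and the heteroscedastic fit should be used.
#'
#' @param pts A [pairwise_points()] tibble (or data frame with column `d`).
#' @param subsample_n Subsample size per repeat, default 5000.
#' @param n_repeats Number of repeats, default 10.
#' @param seed Seed for the subsample draws.
#' @return A tibble of class `normality_screen` with columns `repeat_id`
#'   and `p_value` (NA with a warning if a subsample is constant).
#' @export
normality_screen <- function(pts, subsample_n = 5000, n_repeats = 10,
                             seed = 1L) {
  d <- if (is.data.frame(pts)) pts$d else pts
  if (length(d) < subsample_n)
    stop("need at least subsample_n = ", subsample_n, " points, have ",
         length(d))
  set.seed(seed)
  p <- vapply(seq_len(n_repeats), function(i) {
    di <- sample(d, subsample_n)
    if (length(unique(di)) == 1) {
      warning("constant subsample in repeat ", i,
              "; Shapiro-Wilk p undefined, recorded as NA")
      return(NA_real_)
    }
    stats::shapiro.test(di)$p.value
  }, numeric(1))
  out <- tibble::tibble(repeat_id = seq_len(n_repeats), p_value = p)
  attr(out, "subsample_n") <- subsample_n
  attr(out, "seed") <- seed
  class(out) <- c("normality_screen", class(out))
  out
}

#' Binned distribution of per-site absolute mean differences
#'
#' Per site, takes the mean over subjects of the signed difference
#' `method1 - method2`, then its absolute value, and bins it into
#' \[0, 0.01), \[0.01, 0.02), ..., \[0.09, 0.10), \[0.10, Inf). Reports the
#' percentage of sites per bin -- the standard summary table for
#' between-method agreement of array methylation data.
#'
#' @param ds A [beta_dataset()].
#' @param method1,method2 Method labels.
#' @return A tibble of class `difference_distribution` with columns
#'   `bin_lo`, `bin_hi`, `percent`, and attribute `n_sites`. Percentages sum
#'   to 100 exactly (before any rounding for display).
#' @export
difference_distribution <- function(ds, method1, method2) {
  subjects <- sort(dataset_subjects(ds))
  b1 <- method_matrix(ds, method1, subjects)
  b2 <- method_matrix(ds, method2, subjects)
  md <- abs(rowMeans(b1 - b2))
  edges <- c(seq(0, 0.10, by = 0.01), Inf)
  # half-open bins [lo, hi)
  idx <- findInterval(md, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  out <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    percent = 100 * counts / length(md)
  )
  attr(out, "n_sites") <- length(md)
  attr(out, "methods") <- c(method1, method2)
  class(out) <- c("difference_distribution", class(out))
  out
}

#' Two-dimensional density grid of a Bland-Altman plot
#'
#' Bins the (x, d) points into an `n_bins_x` by `n_bins_d` grid of counts,
#' suitable for shaded plotting of millions of points. `x` is binned over
#' \[0, 1\] and `d` over \[-1, 1\]; counts always sum to the number of
#' points.
#'
#' @param pts A [pairwise_points()] tibble.
#' @param n_bins_x,n_bins_d Number of bins on each axis (>= 2).
#' @return A tibble with columns `x_lo`, `x_hi`, `d_lo`, `d_hi`, `count`,
#'   one row per non-empty cell, plus attribute `n_points`.
#' @export
ba_density_grid <- function(pts, n_bins_x = 200, n_bins_d = 200) {
  stopifnot(n_bins_x >= 2, n_bins_d >= 2)
  xb <- seq(0, 1, length.out = n_bins_x + 1)
  db <- seq(-1, 1, length.out = n_bins_d + 1)
  xi <- pmin(findInterval(pts$x, xb, rightmost.closed = TRUE), n_bins_x)
  di <- pmin(findInterval(pts$d, db, rightmost.closed = TRUE), n_bins_d)
  tab <- table(factor(xi, levels = seq_len(n_bins_x)),
               factor(di, levels = seq_len(n_bins_d)))
  cells <- which(tab > 0, arr.ind = TRUE)
  out <- tibble::tibble(
    x_lo = xb[cells[, 1]], x_hi = xb[cells[, 1] + 1],
    d_lo = db[cells[, 2]], d_hi = db[cells[, 2] + 1],
    count = as.integer(tab[cells])
  )
  attr(out, "n_points") <- nrow(pts)
  attr(out, "n_bins") <- c(x = n_bins_x, d = n_bins_d)
  out
}

#' Plot a Bland-Altman density with limits of agreement
#'
#' @param object A [pairwise_points()] tibble.
#' @param fit Optional `variance_model_fit` whose limits are drawn in red.
#' @param n_bins Grid resolution per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ba_points
#' @export
autoplot.ba_points <- function(object, fit = NULL, n_bins = 200, ...) {
  grid <- ba_density_grid(object, n_bins, n_bins)
  meths <- attr(object, "methods")
  p <- ggplot2::ggplot(grid) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$x_lo, xmax = .data$x_hi,
                                    ymin = .data$d_lo, ymax = .data$d_hi,
                                    fill = .data$count)) +
    ggplot2::scale_fill_gradient(low = "grey85", high = "black",
                                 trans = "log10") +
    ggplot2::coord_cartesian(ylim = c(-0.3, 0.3)) +
    ggplot2::labs(x = "Average methylation of the two methods",
                  y = if (!anyNA(meths))
                    paste0("Difference (", meths[1], " - ", meths[2], ")")
                  else "Difference",
                  fill = "Points") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    loa <- limits_of_agreement(fit, seq(0, 1, by = 0.005))
    p <- p +
      ggplot2::geom_line(data = loa, ggplot2::aes(.data$x, .data$lower),
                         colour = "red") +
      ggplot2::geom_line(data = loa, ggplot2::aes(.data$x, .data$upper),
                         colour = "red")
  }
  p
}

#' @rdname autoplot.ba_points
#' @param pts A [pairwise_points()] tibble.
#' @export
plot_bland_altman <- function(pts, fit = NULL, n_bins = 200) {
  autoplot.ba_points(pts, fit = fit, n_bins = n_bins)
}

#' Plot a binned difference distribution
#'
#' @param object A [difference_distribution()] tibble.
#' @param ... Unused.
#' @return A ggplot object (bar chart of percent per bin, log10 y scale).
#' @method autoplot difference_distribution
#' @export
autoplot.difference_distribution <- function(object, ...) {
  lab <- ifelse(is.finite(object$bin_hi),
                sprintf("%.2f-%.2f", object$bin_lo, object$bin_hi),
                sprintf(">%.2f", object$bin_lo))
  df <- tibble::tibble(bin = factor(lab, levels = lab),
                       percent = object$percent)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Absolute mean methylation difference",
                  y = "Percent of sites") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
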