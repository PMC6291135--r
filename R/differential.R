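#' Global paired t-test between two methods
#'
#' Per subject, averages the beta-values over all sites separately for each
#' method, then runs a paired t-test on the resulting per-subject global
#' means (two-sided, df = n_subjects - 1).
#'
#' @param ds A [beta_dataset()].
#' @param method1,method2 Method labels.
#' @return A one-row tibble with columns `site_id` (`"global"`),
#'   `mean_diff`, `t`, `df`, `p_raw`. If the subject differences have zero
#'   variance the t statistic is undefined: with zero mean it is reported
#'   as `t = 0, p = 1`, otherwise as `NA`, in both cases with a warning.
#' @export
global_paired_t <- function(ds, method1, method2) {
  subjects <- sort(dataset_subjects(ds))
  if (length(subjects) < 2) stop("need at least 2 subjects")
  g1 <- colMeans(method_matrix(ds, method1, subjects))
  g2 <- colMeans(method_matrix(ds, method2, subjects))
  diffs <- g1 - g2
  n <- length(diffs)
  if (stats::sd(diffs) == 0) {
    warning("zero variance of subject differences; t statistic undefined")
    if (mean(diffs) == 0)
      return(tibble::tibble(site_id = "global", mean_diff = 0, t = 0,
                            df = n - 1L, p_raw = 1))
    return(tibble::tibble(site_id = "global", mean_diff = mean(diffs),
                          t = NA_real_, df = n - 1L, p_raw = NA_real_))
  }
  tt <- stats::t.test(diffs)
  tibble::tibble(site_id = "global", mean_diff = mean(diffs),
                 t = unname(tt$statistic), df = n - 1L, p_raw = tt$p.value)
}

#' Per-CpG paired t-tests between two methods
#'
#' One two-sided paired t-test per site on the n_subjects differences
#' `method1 - method2`, with Benjamini-Hochberg FDR adjustment across all
#' sites. Sites whose differences have zero variance get `p_raw = NA`, are
#' excluded from the BH family, and their count is reported in a warning.
#'
#' @param ds A [beta_dataset()].
#' @param method1,method2 Method labels.
#' @return A tibble with one row per site: `site_id`, `mean_diff`, `t`,
#'   `df`, `p_raw`, `p_bh`.
#' @export
per_site_paired_t <- function(ds, method1, method2) {
  subjects <- sort(dataset_subjects(ds))
  n <- length(subjects)
  if (n < 2) stop("need at least 2 subjects")
  d <- method_matrix(ds, method1, subjects) -
    method_matrix(ds, method2, subjects)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  t_stat <- ifelse(s > 0, m / (s / sqrt(n)), NA_real_)
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  n_degenerate <- sum(s == 0)
  if (n_degenerate > 0)
    warning(n_degenerate,
            " site(s) with zero-variance differences excluded from BH")
  tibble::tibble(site_id = rownames(d), mean_diff = unname(m),
                 t = unname(t_stat), df = n - 1L, p_raw = unname(p),
                 p_bh = bh_adjust(unname(p)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wrapper around [stats::p.adjust()] that tolerates missing values:
#' `NA` entries are excluded from the family and returned as `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\], `NA` allowed.
#' @return Adjusted p-values: monotone in the input ranks, capped at 1,
#'   elementwise >= the raw values.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Group CpG sites into positional clusters
#'
#' Sorts sites by chromosome and position, then starts a new cluster at
#' every chromosome change or whenever the gap to the previous site exceeds
#' `max_gap` base pairs (a gap of exactly `max_gap` stays in the same
#' cluster). Sites on different chromosomes never share a cluster;
#' duplicate positions stay together.
#'
#' @param sites Site annotation tibble (`site_id`, `chrom`, `pos`).
#' @param max_gap Maximum within-cluster gap in bp, default 1000.
#' @return A tibble `site_id`, `cluster` (integer ids), in the input row
#'   order.
#' @export
#' @examples
#' sites <- tibble::tibble(site_id = c("a", "b", "c"), chrom = "chr1",
#'                         pos = c(100L, 900L, 2500L), context = "cpg")
#' make_clusters(sites)  # {a, b} then {c}: the 1600-bp gap splits
make_clusters <- function(sites, max_gap = 1000) {
  stopifnot(max_gap >= 1)
  ord <- order(sites$chrom, sites$pos)
  chrom <- sites$chrom[ord]
  pos <- sites$pos[ord]
  new_cluster <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                     diff(pos) > max_gap)
  cl_sorted <- cumsum(new_cluster)
  cl <- integer(length(ord))
  cl[ord] <- cl_sorted
  tibble::tibble(site_id = sites$site_id, cluster = cl)
}

# Per-cluster smoothing of site effects: loess over position for clusters
# with >= min_sites sites, raw effects otherwise (loess needs support).
# The span is chosen per cluster so the smoothing window covers about
# bp_span base pairs (at least min_sites sites), capped at max_span: a
# constant fraction would smooth narrow bumps away in large clusters.
smooth_effects <- function(effect, pos, cluster, max_span, min_sites,
                           bp_span = 1000) {
  sm <- effect
  for (cl in split(seq_along(effect), cluster)) {
    n <- length(cl)
    if (n >= min_sites) {
      width <- diff(range(pos[cl])) + 1
      span <- min(max_span, max(bp_span / width, min_sites / n))
      fit <- tryCatch(
        stats::loess(effect[cl] ~ pos[cl], span = span, degree = 2,
                     family = "gaussian",
                     control = stats::loess.control(surface = "direct")),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning("loess failed in a cluster of ", n,
                " sites; using raw effects")
      } else {
        sm[cl] <- stats::fitted(fit)
      }
    }
  }
  sm
}

# Maximal same-sign runs of |smoothed effect| >= cutoff within clusters.
# Returns a data.frame of candidate regions with their areas.
find_candidate_runs <- function(sm, cluster, cutoff) {
  above <- abs(sm) >= cutoff & sm != 0
  sgn <- sign(sm)
  # run boundaries: change in cluster, in above-status, or in sign while above
  n <- length(sm)
  if (n == 0) return(NULL)
  brk <- c(TRUE, cluster[-1] != cluster[-n] | above[-1] != above[-n] |
             (above[-1] & sgn[-1] != sgn[-n]))
  run_id <- cumsum(brk)
  keep <- above
  if (!any(keep)) return(NULL)
  idx <- seq_len(n)[keep]
  spl <- split(idx, run_id[keep])
  data.frame(
    first = vapply(spl, min, integer(1)),
    last = vapply(spl, max, integer(1)),
    area = vapply(spl, function(i) sum(abs(sm[i])), numeric(1)),
    direction = vapply(spl, function(i) if (sm[i[1]] > 0) "hyper" else "hypo",
                       character(1))
  )
}

#' Search for differentially methylated regions between paired methods
#'
#' A bump-hunting region search for the paired two-method design. Per site
#' the effect is the mean over subjects of the difference
#' `method1 - method2`; effects are smoothed by loess within positional
#' clusters (clusters with fewer than `min_sites_smooth` sites use raw
#' effects); candidate regions are maximal same-sign runs of sites whose
#' absolute smoothed effect reaches `cutoff`, scored by their area (the sum
#' of absolute smoothed effects). Family-wise error rates come from a
#' sign-flip bootstrap: under the paired null the sign of each subject's
#' whole difference vector is exchangeable, so each bootstrap flips every
#' subject's vector independently with probability 1/2, repeats the search,
#' and records the maximum null area; `fwer` is the fraction of bootstraps
#' whose maximum reaches the observed area.
#'
#' @param ds A [beta_dataset()].
#' @param method1,method2 Method labels.
#' @param clusters Optional precomputed [make_clusters()] tibble; computed
#'   from the dataset's annotation (with `max_gap`) if omitted.
#' @param cutoff Effect-size threshold on the smoothed mean difference,
#'   default 0.01.
#' @param loess_span Maximum loess span over within-cluster positions,
#'   default 0.75. Within each cluster the span actually used targets a
#'   smoothing window of about `bp_span` base pairs (never fewer than
#'   `min_sites_smooth` sites), so large clusters are not over-smoothed.
#' @param bp_span Target smoothing-window width in base pairs, default
#'   1000.
#' @param min_sites_smooth Minimum cluster size for loess smoothing,
#'   default 7.
#' @param n_boot Number of sign-flip bootstraps, default 250.
#' @param max_gap Passed to [make_clusters()] when `clusters` is `NULL`.
#' @param seed Seed for the bootstrap.
#' @return A tibble of class `bump_regions`, one row per candidate region:
#'   `cluster`, `chrom`, `start`, `end` (1-based inclusive positions),
#'   `n_sites`, `direction` (`"hyper"`/`"hypo"` for the sign of
#'   `method1 - method2`), `area`, `fwer`; sorted by `fwer` then
#'   decreasing area. Empty (zero rows) when no run reaches the cutoff.
#' @export
find_bumps <- function(ds, method1, method2, clusters = NULL, cutoff = 0.01,
                       loess_span = 0.75, bp_span = 1000,
                       min_sites_smooth = 7, n_boot = 250, max_gap = 1000,
                       seed = 1L) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  subjects <- sort(dataset_subjects(ds))
  d <- method_matrix(ds, method1, subjects) -
    method_matrix(ds, method2, subjects)
  n_subj <- ncol(d)
  if (is.null(clusters)) clusters <- make_clusters(ds$sites, max_gap)
  stopifnot(identical(clusters$site_id, ds$sites$site_id))

  # work in (chrom, pos) order so runs are positional
  ord <- order(ds$sites$chrom, ds$sites$pos)
  d <- d[ord, , drop = FALSE]
  pos <- ds$sites$pos[ord]
  chrom <- ds$sites$chrom[ord]
  cl <- clusters$cluster[ord]

  search <- function(effect) {
    sm <- smooth_effects(effect, pos, cl, loess_span, min_sites_smooth,
                         bp_span)
    find_candidate_runs(sm, cl, cutoff)
  }

  obs <- search(rowMeans(d))
  empty <- tibble::tibble(cluster = integer(), chrom = character(),
                          start = integer(), end = integer(),
                          n_sites = integer(), direction = character(),
                          area = numeric(), fwer = numeric())
  class(empty) <- c("bump_regions", class(empty))
  if (is.null(obs)) return(empty)

  set.seed(seed)
  max_null <- vapply(seq_len(n_boot), function(b) {
    signs <- sample(c(-1, 1), n_subj, replace = TRUE)
    cand <- search(as.vector(d %*% signs) / n_subj)
    if (is.null(cand)) 0 else max(cand$area)
  }, numeric(1))

  out <- tibble::tibble(
    cluster = cl[obs$first],
    chrom = chrom[obs$first],
    start = as.integer(pos[obs$first]),
    end = as.integer(pos[obs$last]),
    n_sites = as.integer(obs$last - obs$first + 1L),
    direction = obs$direction,
    area = obs$area,
    fwer = vapply(obs$area, function(a) mean(max_null >= a), numeric(1))
  )
  out <- dplyr::arrange(out, .data$fwer, dplyr::desc(.data$area))
  attr(out, "n_boot") <- n_boot
  attr(out, "cutoff") <- cutoff
  class(out) <- c("bump_regions", class(out))
  out
}

#' Directional summary of per-CpG test results across three method pairs
#'
#' Tabulates, for groups of sites defined by t-test p-value cutoffs, (i)
#' the sign of the mean methylation difference within each pairwise
#' comparison, and (ii) the between-method ranking of each method: method k
#' is "lowest" ("highest") at a site when both comparisons involving k show
#' k with the smaller (larger) mean and both satisfy the group's p-value
#' rule. Groups are `p < cutoff` for each cutoff plus a null-like group
#' `p > p_floor`.
#'
#' @param results Named list of three [per_site_paired_t()] tibbles, one
#'   per method pair, with names of the form `"M_vs_A"` (i.e.
#'   `<method1>_vs_<method2>` with `mean_diff = method1 - method2`). All
#'   three must share the same site universe.
#' @param methods The three method labels.
#' @param p_cutoffs Upper p-value cutoffs, default `c(0.002, 0.01)`.
#' @param p_floor Lower cutoff for the null-like group, default 0.75.
#' @return A tibble with columns `group`, `kind` (`"sign"` or `"ranking"`),
#'   `comparison`, `category`, `n_sites`, `percent`; percentages sum to 100
#'   within each (group, kind, comparison).
#' @export
directional_summary <- function(results, methods, p_cutoffs = c(0.002, 0.01),
                                p_floor = 0.75) {
  stopifnot(length(methods) == 3)
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  expect_names <- vapply(pairs, function(p) paste(p, collapse = "_vs_"),
                         character(1))
  missing <- setdiff(expect_names, names(results))
  if (length(missing) > 0)
    stop("missing comparison result(s): ", paste(missing, collapse = ", "))
  results <- results[expect_names]
  universe <- results[[1]]$site_id
  for (r in results)
    if (!identical(sort(r$site_id), sort(universe)))
      stop("comparison results do not share the same site universe")
  results <- lapply(results, function(r) r[match(universe, r$site_id), ])

  groups <- c(stats::setNames(lapply(p_cutoffs, function(ct) {
    function(p) !is.na(p) & p < ct
  }), sprintf("p < %g", p_cutoffs)),
  stats::setNames(list(function(p) !is.na(p) & p > p_floor),
                  sprintf("p > %g", p_floor)))

  sign_rows <- purrr::map_dfr(names(groups), function(g) {
    rule <- groups[[g]]
    purrr::map_dfr(seq_along(pairs), function(i) {
      r <- results[[i]]
      sel <- rule(r$p_raw)
      n <- sum(sel)
      m1 <- pairs[[i]][1]; m2 <- pairs[[i]][2]
      up <- sum(sel & r$mean_diff > 0)
      dn <- sum(sel & r$mean_diff < 0)
      tibble::tibble(
        group = g, kind = "sign", comparison = expect_names[i],
        category = c(paste0(m1, ">", m2), paste0(m1, "<", m2)),
        n_sites = c(up, dn),
        percent = if (n > 0) 100 * c(up, dn) / n else c(NA_real_, NA_real_)
      )
    })
  })

  # signed diff of method k versus the other within each pair
  signed_for <- function(k, pair_i) {
    r <- results[[pair_i]]
    if (pairs[[pair_i]][1] == k) r$mean_diff else -r$mean_diff
  }
  rank_rows <- purrr::map_dfr(names(groups), function(g) {
    rule <- groups[[g]]
    cats <- purrr::map_dfr(methods, function(k) {
      involving <- which(vapply(pairs, function(p) k %in% p, logical(1)))
      ok <- rule(results[[involving[1]]]$p_raw) &
        rule(results[[involving[2]]]$p_raw)
      s1 <- signed_for(k, involving[1])
      s2 <- signed_for(k, involving[2])
      tibble::tibble(
        category = c(paste(k, "lowest"), paste(k, "highest")),
        n_sites = c(sum(ok & s1 < 0 & s2 < 0), sum(ok & s1 > 0 & s2 > 0))
      )
    })
    n <- sum(cats$n_sites)
    tibble::tibble(group = g, kind = "ranking", comparison = "all",
                   category = cats$category, n_sites = cats$n_sites,
                   percent = if (n > 0) 100 * cats$n_sites / n
                   else rep(NA_real_, nrow(cats)))
  })

  dplyr::bind_rows(sign_rows, rank_rows)
}

#' Paired Wilcoxon tests on per-sample summary statistics
#'
#' Generic utility for comparing any per-sample statistic (e.g. externally
#' predicted epigenetic age or estimated cell-type proportions) between
#' method pairs: per statistic and method pair, a two-sided paired Wilcoxon
#' signed-rank test, Bonferroni-corrected across all tests performed.
#'
#' @param df Data frame with columns `subject_id`, `method`, and one or
#'   more numeric statistic columns.
#' @param statistics Statistic column names; default all numeric columns
#'   other than the identifiers.
#' @param methods Method labels to compare pairwise; default all present.
#' @return A tibble with one row per (statistic, method pair): `statistic`,
#'   `method1`, `method2`, `v` (Wilcoxon statistic), `p_raw`,
#'   `p_bonferroni`.
#' @export
paired_wilcoxon <- function(df, statistics = NULL, methods = NULL) {
  stopifnot(all(c("subject_id", "method") %in% names(df)))
  methods <- methods %||% unique(df$method)
  statistics <- statistics %||%
    setdiff(names(df)[vapply(df, is.numeric, logical(1))],
            c("subject_id", "method"))
  if (length(statistics) == 0) stop("no statistic columns found")
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  res <- purrr::map_dfr(statistics, function(st) {
    purrr::map_dfr(pairs, function(pr) {
      a <- df[df$method == pr[1], ]
      b <- df[df$method == pr[2], ]
      subj <- intersect(a$subject_id, b$subject_id)
      va <- a[[st]][match(subj, a$subject_id)]
      vb <- b[[st]][match(subj, b$subject_id)]
      wt <- suppressWarnings(  # ties/zeroes make the exact p approximate
        stats::wilcox.test(va, vb, paired = TRUE))
      tibble::tibble(statistic = st, method1 = pr[1], method2 = pr[2],
                     v = unname(wt$statistic), p_raw = wt$p.value)
    })
  })
  res$p_bonferroni <- pmin(1, nrow(res) * res$p_raw)
  res
}
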