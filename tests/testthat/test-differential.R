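make_pair_from_diffs <- function(diffs_by_subject, n_sites = 3) {
  # builds a two-method dataset whose per-subject global differences are
  # exactly `diffs_by_subject`
  n <- length(diffs_by_subject)
  b2 <- matrix(0.5, n_sites, n)
  b1 <- sweep(b2, 2, diffs_by_subject, `+`)
  toy_dataset(list(M = b1, A = b2))
}

test_that("global paired t matches the closed form", {
  # diffs {0.01, 0.02, 0.03}: t = mean/(sd/sqrt(3)) = 0.02/(0.01/sqrt(3))
  res <- global_paired_t(make_pair_from_diffs(c(0.01, 0.02, 0.03)), "M", "A")
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$df, 2L)
  expect_equal(res$mean_diff, 0.02)
  # symmetric diffs give t = 0
  res0 <- global_paired_t(make_pair_from_diffs(c(0.1, -0.1, 0.1, -0.1)),
                          "M", "A")
  expect_equal(res0$t, 0, tolerance = 1e-12)
  # identical matrices: degenerate, reported as no difference
  b <- matrix(runif(12, 0.3, 0.7), 4, 3)
  expect_warning(resid <- global_paired_t(toy_dataset(list(M = b, A = b)),
                                          "M", "A"),
                 "zero variance")
  expect_equal(resid$mean_diff, 0)
  expect_equal(resid$p_raw, 1)
})

test_that("per-site paired t agrees with stats::t.test site by site", {
  p <- simulation_params(n_subjects = 6, n_sites = 30, methods = c("M", "A"),
                         seed = 51)
  ds <- simulate_dataset(p)
  res <- per_site_paired_t(ds, "M", "A")
  b1 <- methagree:::method_matrix(ds, "M")
  b2 <- methagree:::method_matrix(ds, "A")
  for (i in c(1, 7, 30)) {
    tt <- t.test(b1[i, ], b2[i, ], paired = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p_raw[i], tt$p.value, tolerance = 1e-12)
  }
  # antisymmetry in the method order
  res_rev <- per_site_paired_t(ds, "A", "M")
  expect_equal(res_rev$t, -res$t)
  expect_equal(res_rev$p_raw, res$p_raw)
})

test_that("per-site t holds its nominal type-I error on null data", {
  p <- simulation_params(n_subjects = 10, n_sites = 10000,
                         methods = c("M", "A"), seed = 61)
  res <- per_site_paired_t(simulate_dataset(p), "M", "A")
  expect_lt(abs(mean(res$p_raw < 0.05, na.rm = TRUE) - 0.05), 0.01)
  # and no site survives FDR correction on null data
  expect_equal(sum(res$p_bh < 0.05, na.rm = TRUE), 0)
})

test_that("injected per-site effects rank far above null sites", {
  reg <- tibble::tibble(chrom = "chr1", start = 1L, end = 50000L,
                        method = "M", delta = 0.05)
  p <- simulation_params(n_subjects = 10, n_sites = 2000,
                         methods = c("M", "A"), injected_regions = reg,
                         seed = 62)
  ds <- simulate_dataset(p)
  mask <- attr(ds, "region_mask")
  expect_equal(sum(mask), 100)
  res <- per_site_paired_t(ds, "M", "A")
  expect_lt(median(res$p_raw[mask]), 0.01 * median(res$p_raw[!mask]))
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(9)
  for (i in 1:100) {
    p <- runif(sample(1:1000, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute_force(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  # NA entries are excluded from the family and preserved
  p_na <- c(0.01, NA, 0.04)
  adj_na <- bh_adjust(p_na)
  expect_true(is.na(adj_na[2]))
  expect_equal(adj_na[c(1, 3)], bh_brute_force(c(0.01, 0.04)))
})

test_that("positional clustering splits on chromosome and gap > max_gap", {
  sites <- tibble::tibble(site_id = letters[1:3], chrom = "chr1",
                          pos = c(100L, 900L, 2500L), context = "cpg")
  cl <- make_clusters(sites, max_gap = 1000)
  expect_equal(cl$cluster, c(1L, 1L, 2L))
  # gap exactly max_gap stays together
  sites2 <- tibble::tibble(site_id = letters[1:2], chrom = "chr1",
                           pos = c(100L, 1100L), context = "cpg")
  expect_equal(make_clusters(sites2, 1000)$cluster, c(1L, 1L))
  # different chromosomes never share a cluster, even at equal positions
  sites3 <- tibble::tibble(site_id = letters[1:2], chrom = c("chr1", "chr2"),
                           pos = c(100L, 100L), context = "cpg")
  expect_equal(length(unique(make_clusters(sites3, 1000)$cluster)), 2L)
  # duplicate positions stay in one cluster; unsorted input is handled
  sites4 <- tibble::tibble(site_id = letters[1:4], chrom = "chr1",
                           pos = c(900L, 100L, 900L, 5000L), context = "cpg")
  cl4 <- make_clusters(sites4, 1000)
  expect_equal(cl4$cluster, c(1L, 1L, 1L, 2L))
})

test_that("find_bumps recovers an injected region and respects the cutoff", {
  reg <- tibble::tibble(chrom = "chr1", start = 50001L, end = 60000L,
                        method = "A", delta = 0.05)
  hits <- 0
  for (seed in 1:5) {
    p <- simulation_params(n_subjects = 10, n_sites = 2000,
                           methods = c("M", "A"), injected_regions = reg,
                           seed = seed)
    ds <- simulate_dataset(p)
    regions <- find_bumps(ds, "M", "A", n_boot = 50, seed = seed + 100)
    sig <- regions[regions$fwer < 0.05, ]
    if (nrow(sig) > 0 && any(sig$start <= 60000 & sig$end >= 50001 &
                               sig$direction == "hypo"))
      hits <- hits + 1
  }
  expect_gte(hits, 4)  # recovered in most seeded runs
  # all effects below the cutoff: empty region list
  b <- matrix(0.5, 50, 4)
  ds0 <- toy_dataset(list(M = b + 0.001, A = b))
  expect_equal(nrow(find_bumps(ds0, "M", "A", n_boot = 5)), 0L)
})

test_that("find_bumps is deterministic and order-invariant", {
  p <- simulation_params(n_subjects = 8, n_sites = 1000,
                         methods = c("M", "A"), noise_a = -2.2, seed = 77)
  ds <- simulate_dataset(p)
  r1 <- find_bumps(ds, "M", "A", n_boot = 20, seed = 5)
  r2 <- find_bumps(ds, "M", "A", n_boot = 20, seed = 5)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  perm <- sample(nrow(ds$betas))
  ds_perm <- beta_dataset(ds$betas[perm, ], ds$sites[perm, ], ds$samples)
  r3 <- find_bumps(ds_perm, "M", "A", n_boot = 20, seed = 5)
  expect_equal(as.data.frame(r1), as.data.frame(r3))
})

test_that("the sign-flip null preserves each subject's absolute differences", {
  # the bootstrap flips whole per-subject difference vectors: for any flip
  # pattern, the multiset of |d| per subject is unchanged
  set.seed(15)
  d <- matrix(rnorm(50), 10, 5)
  signs <- sample(c(-1, 1), 5, replace = TRUE)
  flipped <- sweep(d, 2, signs, `*`)
  for (j in 1:5)
    expect_equal(sort(abs(flipped[, j])), sort(abs(d[, j])))
  # and the per-site mean under flipping equals d %*% signs / n, the
  # statistic find_bumps bootstraps
  expect_equal(rowMeans(flipped), as.vector(d %*% signs) / 5)
})

test_that("directional summary tabulates signs and rankings", {
  # construct three-pair results over 4 sites with known structure
  mk <- function(mean_diff, p_raw) {
    tibble::tibble(site_id = paste0("s", seq_along(mean_diff)),
                   mean_diff = mean_diff, t = 1, df = 9,
                   p_raw = p_raw, p_bh = p_raw)
  }
  results <- list(
    M_vs_A = mk(c(0.02, -0.01, 0.03, 0.01), c(0.001, 0.001, 0.9, 0.5)),
    M_vs_O = mk(c(0.01, -0.02, -0.01, 0.01), c(0.001, 0.001, 0.9, 0.5)),
    A_vs_O = mk(c(-0.01, -0.01, 0.02, 0.01), c(0.5, 0.001, 0.9, 0.5))
  )
  ds <- directional_summary(results, methods = c("M", "A", "O"))
  sign_ma <- ds[ds$kind == "sign" & ds$comparison == "M_vs_A" &
                  ds$group == "p < 0.002", ]
  expect_equal(sign_ma$n_sites[sign_ma$category == "M>A"], 1L)
  expect_equal(sign_ma$n_sites[sign_ma$category == "M<A"], 1L)
  expect_equal(sum(sign_ma$percent), 100)
  # site 2 has M below both A and O with p < 0.002 in both M-comparisons
  rank_row <- ds[ds$kind == "ranking" & ds$group == "p < 0.002" &
                   ds$category == "M lowest", ]
  expect_equal(rank_row$n_sites, 1L)
  # ranking percentages sum to 100 within the group
  rk <- ds[ds$kind == "ranking" & ds$group == "p < 0.002", ]
  expect_equal(sum(rk$percent, na.rm = TRUE), 100)
  # missing comparison is fatal
  expect_error(directional_summary(results[1:2], c("M", "A", "O")),
               "missing comparison")
})

test_that("null data splits signs about evenly among low-p sites", {
  p <- simulation_params(n_subjects = 10, n_sites = 5000, seed = 81)
  ds <- simulate_dataset(p)
  pairs <- list(c("M", "A"), c("M", "O"), c("A", "O"))
  results <- setNames(
    lapply(pairs, function(pr) per_site_paired_t(ds, pr[1], pr[2])),
    vapply(pairs, paste, "", collapse = "_vs_"))
  dsum <- directional_summary(results, methods = c("M", "A", "O"),
                              p_cutoffs = 0.05)
  sgn <- dsum[dsum$kind == "sign" & dsum$group == "p < 0.05", ]
  expect_true(all(abs(sgn$percent - 50) < 15))
})

test_that("paired Wilcoxon utility compares per-sample statistics", {
  set.seed(5)
  df <- tibble::tibble(
    subject_id = rep(paste0("s", 1:10), 2),
    method = rep(c("M", "A"), each = 10),
    age = c(rnorm(10, 40), rnorm(10, 40)),
    cd4 = c(rnorm(10, 0.2, 0.01), rnorm(10, 0.3, 0.01))
  )
  res <- paired_wilcoxon(df)
  expect_equal(nrow(res), 2)  # two statistics, one method pair
  expect_equal(res$p_bonferroni, pmin(1, 2 * res$p_raw))
  cd4 <- res[res$statistic == "cd4", ]
  expect_lt(cd4$p_raw, 0.01)  # the shifted statistic is detected
  age <- res[res$statistic == "age", ]
  expect_gt(age$p_raw, 0.05)
})
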