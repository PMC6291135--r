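make_pair_dataset <- function(b1, b2, methods = c("M", "A")) {
  toy_dataset(setNames(list(b1, b2), methods))
}

test_that("pairwise_points computes averages and differences per subject-site", {
  b1 <- matrix(0.2, 2, 3)
  b2 <- matrix(0.4, 2, 3)
  ds <- make_pair_dataset(b1, b2)
  pts <- pairwise_points(ds, "M", "A")
  expect_equal(nrow(pts), 6)  # n_subjects * n_sites
  expect_equal(pts$x, rep(0.3, 6))
  expect_equal(pts$d, rep(-0.2, 6))
  # identical matrices give all-zero differences
  pts0 <- pairwise_points(make_pair_dataset(b1, b1), "M", "A")
  expect_true(all(pts0$d == 0))
  # a missing subject-method combination is fatal and names the subject
  ds2 <- make_pair_dataset(b1, b2)
  ds2$samples <- ds2$samples[-1, ]
  ds2$betas <- ds2$betas[, -1]
  expect_error(pairwise_points(ds2, "M", "A"), "subj1")
})

test_that("two x-groups with equal spread force b to zero and a to log sd", {
  # d = +/-0.1 at x = 0.5 and at x = 0.3: per-group MLE sigma^2 = mean(d^2)
  # = 0.01 in both groups, so the variance function must be flat
  pts <- tibble::tibble(
    x = rep(c(0.5, 0.3), each = 6),
    d = rep(c(0.1, -0.1), times = 6)
  )
  fit <- fit_variance_model(pts)
  expect_true(fit$converged)
  expect_equal(fit$a, log(0.1), tolerance = 1e-4)
  expect_equal(fit$b, 0, tolerance = 1e-3)
})

test_that("with b fixed at 0 the closed form exp(2a) = mean(d^2) holds", {
  set.seed(31)
  pts <- tibble::tibble(x = runif(500), d = rnorm(500, sd = 0.05))
  fit <- fit_variance_model(pts, fix_b = 0)
  expect_equal(exp(2 * fit$a), mean(pts$d^2), tolerance = 1e-8)
})

test_that("optimizer agrees with an independent grid-search oracle", {
  set.seed(77)
  for (i in 1:3) {
    n <- 400
    x <- runif(n)
    d <- rnorm(n, sd = exp(-2.5 - 3 * (x - 0.5)^2))
    fit <- fit_variance_model(tibble::tibble(x = x, d = d))
    a_grid <- seq(fit$a - 0.5, fit$a + 0.5, length.out = 200)
    b_grid <- seq(fit$b - 2, fit$b + 2, length.out = 200)
    nll <- outer(a_grid, b_grid, Vectorize(function(a, b) nll_oracle(a, b, x, d)))
    best <- which(nll == min(nll), arr.ind = TRUE)[1, ]
    res_a <- diff(a_grid)[1]
    res_b <- diff(b_grid)[1]
    expect_lt(abs(a_grid[best[1]] - fit$a), 2 * res_a)
    expect_lt(abs(b_grid[best[2]] - fit$b), 2 * res_b)
    # and the optimizer's objective is no worse than the grid's best
    expect_lte(fit$final_objective, min(nll) + 1e-6)
  }
})

test_that("degenerate designs are handled explicitly", {
  pts_same_x <- tibble::tibble(x = rep(0.5, 20), d = rnorm(20, sd = 0.1))
  expect_warning(fit <- fit_variance_model(pts_same_x), "unidentifiable")
  expect_equal(fit$b, 0)
  expect_equal(exp(2 * fit$a), mean(pts_same_x$d^2), tolerance = 1e-8)
  expect_error(fit_variance_model(tibble::tibble(x = runif(20), d = 0)),
               "all differences are zero")
  expect_error(fit_variance_model(tibble::tibble(x = 0.5, d = 0.1)),
               "at least 10")
})

test_that("subsampled fits are seeded and recorded", {
  set.seed(1)
  pts <- tibble::tibble(x = runif(5000), d = rnorm(5000, sd = 0.05))
  f1 <- fit_variance_model(pts, subsample = 1000, seed = 42)
  f2 <- fit_variance_model(pts, subsample = 1000, seed = 42)
  expect_equal(f1$a, f2$a)
  expect_equal(f1$n_used, 1000)
})

test_that("limits of agreement follow the variance function", {
  fit <- structure(list(a = log(0.1), b = 0, z = 1.96, converged = TRUE,
                        n_used = 100, final_objective = 0, mean_diff = 0,
                        methods = c("M", "A")),
                   class = "variance_model_fit")
  loa <- limits_of_agreement(fit, c(0, 0.5, 1))
  expect_equal(loa$upper, rep(1.96 * 0.1, 3))
  expect_equal(loa$lower, -loa$upper)
  # with b < 0 the band is widest at x = 0.5
  fit$b <- -4
  loa2 <- limits_of_agreement(fit, seq(0, 1, 0.05))
  expect_equal(loa2$x[which.max(loa2$upper)], 0.5)
})

test_that("95% of model-simulated differences fall within the limits", {
  set.seed(12)
  n <- 100000
  # simulate from a fitted model and check coverage of +/- 1.96 sigma(x)
  x0 <- runif(20000)
  fit <- fit_variance_model(tibble::tibble(
    x = x0, d = rnorm(20000, sd = exp(-3 - 4 * (x0 - 0.5)^2))))
  x <- runif(n)
  d <- rnorm(n, sd = sigma_fun(x, fit$a, fit$b))
  inside <- abs(d) <= 1.96 * sigma_fun(x, fit$a, fit$b)
  expect_lt(abs(mean(inside) - 0.95), 0.01)
})

test_that("normality screen is level under H0 and powerful under the model", {
  set.seed(3)
  null_pts <- tibble::tibble(d = rnorm(60000, sd = 0.05))
  scr <- normality_screen(null_pts, seed = 21)
  expect_equal(nrow(scr), 10)
  expect_gt(median(scr$p_value), 0.05)
  # heteroscedastic mixture across a bimodal x: strongly non-normal
  p <- simulation_params(n_subjects = 5, n_sites = 20000,
                         methods = c("M", "A"), seed = 14)
  pts <- pairwise_points(simulate_dataset(p), "M", "A")
  scr2 <- normality_screen(pts, seed = 22)
  expect_true(all(scr2$p_value < 0.01))
  # determinism
  scr3 <- normality_screen(pts, seed = 22)
  expect_identical(scr2$p_value, scr3$p_value)
})

test_that("difference distribution bins half-open and sums to 100", {
  # per-site |mean difference| = 0.005, 0.015, 0.005, 0.105
  b1 <- matrix(0.5, 4, 2)
  b2 <- b1 - c(0.005, 0.015, 0.005, 0.105)
  dd <- difference_distribution(make_pair_dataset(b1, b2), "M", "A")
  expect_equal(dd$percent, c(50, 25, rep(0, 8), 25))
  expect_equal(sum(dd$percent), 100, tolerance = 1e-9)
  # identical matrices: everything in the first bin
  dd0 <- difference_distribution(make_pair_dataset(b1, b1), "M", "A")
  expect_equal(dd0$percent[1], 100)
  # a difference of exactly 0.01 falls in the second bin (half-open bins)
  b3 <- b1 - 0.01
  dd2 <- difference_distribution(make_pair_dataset(b1, b3), "M", "A")
  expect_equal(dd2$percent[2], 100)
})

test_that("swapping the methods negates d but fixes bins and fit", {
  p <- simulation_params(n_subjects = 4, n_sites = 2000,
                         methods = c("M", "A"), seed = 19)
  ds <- simulate_dataset(p)
  p12 <- pairwise_points(ds, "M", "A")
  p21 <- pairwise_points(ds, "A", "M")
  expect_equal(p21$d, -p12$d)
  expect_equal(p21$x, p12$x)
  f12 <- fit_variance_model(p12)
  f21 <- fit_variance_model(p21)
  expect_equal(f12$a, f21$a, tolerance = 1e-6)
  expect_equal(f12$b, f21$b, tolerance = 1e-5)
  expect_equal(difference_distribution(ds, "M", "A")$percent,
               difference_distribution(ds, "A", "M")$percent)
})

test_that("density grid conserves counts and marginalises correctly", {
  pts <- tibble::tibble(x = c(0.11, 0.11, 0.11, 0.11), d = rep(0.05, 4))
  g <- ba_density_grid(pts, 10, 10)
  expect_equal(nrow(g), 1)
  expect_equal(g$count, 4L)
  set.seed(8)
  pts2 <- tibble::tibble(x = runif(5000), d = runif(5000, -0.2, 0.2))
  g2 <- ba_density_grid(pts2, 20, 15)
  expect_equal(sum(g2$count), 5000)
  # marginal over d reproduces the 1-D histogram of x on the same breaks
  marg <- tapply(g2$count, g2$x_lo, sum)
  h <- hist(pts2$x, breaks = seq(0, 1, length.out = 21), plot = FALSE)
  expect_equal(as.integer(marg), h$counts[h$counts > 0])
})

test_that("tidy/glance/autoplot interfaces work on fitted objects", {
  set.seed(2)
  pts <- tibble::tibble(x = runif(200), d = rnorm(200, sd = 0.05))
  fit <- fit_variance_model(pts)
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_used, 200)
  p <- simulation_params(n_subjects = 3, n_sites = 300,
                         methods = c("M", "A"), seed = 2)
  ds <- simulate_dataset(p)
  bap <- pairwise_points(ds, "M", "A")
  plt <- autoplot(bap, fit = fit_variance_model(bap))
  expect_s3_class(plt, "ggplot")
  plt2 <- autoplot(difference_distribution(ds, "M", "A"))
  expect_s3_class(plt2, "ggplot")
})
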