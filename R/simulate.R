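#' Parameters for the paired-methylation simulator
#'
#' Defines the generative model for a multi-method paired beta dataset. Per
#' site, a true methylation level is drawn from a three-component mixture of
#' beta distributions (lowly, intermediately and highly methylated CpGs, the
#' bimodal shape typical of whole-blood array data). Per subject, biological
#' variation is added on the logit scale with standard deviation
#' `subject_sd`. Per measurement, technical noise is added so that the
#' difference between two methods at true level x has standard deviation
#' `sigma(x) = exp(noise_a + noise_b * (x - 0.5)^2)` -- largest at
#' intermediate methylation when `noise_b < 0`.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param n_sites Number of CpG sites.
#' @param methods Character vector of method labels (default
#'   `c("M", "A", "O")`, three extraction methods).
#' @param mixture_weights Length-3 weights of the (low, mid, high)
#'   components; must sum to 1.
#' @param mixture_shapes 3x2 matrix of beta-distribution shape pairs, one
#'   row per component.
#' @param subject_sd Between-subject standard deviation on the logit scale.
#' @param noise_a,noise_b Constants of the variance function
#'   `sigma(x) = exp(noise_a + noise_b*(x-0.5)^2)` governing the SD of a
#'   between-method difference. Each single measurement receives noise with
#'   SD `sigma(x)/sqrt(2)` so that the difference of two methods has SD
#'   `sigma(x)`.
#' @param method_bias Named numeric vector of global per-method offsets on
#'   the beta scale; default all zero.
#' @param injected_regions Data frame with columns `chrom`, `start`, `end`,
#'   `method`, `delta`: sites falling in \[start, end\] on `chrom` get
#'   `delta` added for the affected `method` (an injected method-effect
#'   region). Default none.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_subjects = 10,
                              n_sites = 10000,
                              methods = c("M", "A", "O"),
                              mixture_weights = c(0.40, 0.15, 0.45),
                              mixture_shapes = rbind(low = c(2, 20),
                                                     mid = c(5, 5),
                                                     high = c(20, 2)),
                              subject_sd = 0.5,
                              noise_a = -3.0,
                              noise_b = -4.0,
                              method_bias = NULL,
                              injected_regions = NULL,
                              seed = 1L) {
  stopifnot(n_sites >= 1, n_subjects >= 1, length(methods) >= 1)
  mixture_weights <- as.numeric(mixture_weights)
  if (anyNA(mixture_weights)) stop("mixture weights contain NA")
  if (abs(sum(mixture_weights) - 1) > 1e-8)
    stop("mixture weights must sum to 1")
  mixture_shapes <- as.matrix(mixture_shapes)
  stopifnot(nrow(mixture_shapes) == 3, ncol(mixture_shapes) == 2,
            all(mixture_shapes > 0), subject_sd >= 0, is.finite(noise_a),
            is.finite(noise_b))
  if (is.null(method_bias))
    method_bias <- stats::setNames(rep(0, length(methods)), methods)
  if (!all(names(method_bias) %in% methods))
    stop("method_bias names must be a subset of methods")
  bias <- stats::setNames(rep(0, length(methods)), methods)
  bias[names(method_bias)] <- method_bias
  if (is.null(injected_regions)) {
    injected_regions <- tibble::tibble(chrom = character(), start = integer(),
                                       end = integer(), method = character(),
                                       delta = numeric())
  } else {
    injected_regions <- tibble::as_tibble(injected_regions)
    stopifnot(all(c("chrom", "start", "end", "method", "delta") %in%
                    names(injected_regions)))
    bad <- setdiff(injected_regions$method, methods)
    if (length(bad) > 0)
      stop("injected region method(s) not among simulated methods: ",
           paste(bad, collapse = ", "))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sites = as.integer(n_sites), methods = methods,
                 mixture_weights = mixture_weights,
                 mixture_shapes = mixture_shapes, subject_sd = subject_sd,
                 noise_a = noise_a, noise_b = noise_b, method_bias = bias,
                 injected_regions = injected_regions,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' The difference-scale variance function
#'
#' `sigma(x) = exp(a + b * (x - 0.5)^2)`: the standard deviation of a
#' between-method beta-value difference at mean methylation `x`.
#'
#' @param x Mean methylation values in \[0, 1\].
#' @param a,b Constants.
#' @return Numeric vector of standard deviations (always positive).
#' @export
sigma_fun <- function(x, a, b) exp(a + b * (x - 0.5)^2)

#' Simulate true methylation levels
#'
#' Draws the subject-level ground truth: per site a mixture component and a
#' site-level mean, then per subject a value around that mean with
#' `subject_sd` on the logit scale. With `subject_sd = 0` all subjects are
#' identical at every site.
#'
#' @param p A [simulation_params()].
#' @return A `simulated_truth` list: `true_methylation` (sites x subjects
#'   matrix in \[0, 1\]), `sites` (default annotation: one chromosome,
#'   500-bp spacing, unless overridden later), `region_mask` (logical, site
#'   in any injected region), `subjects` (ids).
#' @export
simulate_truth <- function(p) {
  stopifnot(inherits(p, "simulation_params"))
  set.seed(p$seed)
  comp <- sample.int(3, p$n_sites, replace = TRUE, prob = p$mixture_weights)
  site_mean <- stats::rbeta(p$n_sites, p$mixture_shapes[comp, 1],
                            p$mixture_shapes[comp, 2])
  eps <- 1e-6
  site_mean <- pmin(pmax(site_mean, eps), 1 - eps)
  lg <- stats::qlogis(site_mean)
  truth <- matrix(lg, nrow = p$n_sites, ncol = p$n_subjects)
  if (p$subject_sd > 0)
    truth <- truth + matrix(stats::rnorm(length(truth), sd = p$subject_sd),
                            nrow = p$n_sites)
  truth <- stats::plogis(truth)
  subjects <- sprintf("subj%02d", seq_len(p$n_subjects))
  dimnames(truth) <- list(sprintf("cg%07d", seq_len(p$n_sites)), subjects)
  sites <- example_sites(p$n_sites)
  structure(list(true_methylation = truth, sites = sites,
                 region_mask = region_mask(sites, p$injected_regions),
                 subjects = subjects),
            class = "simulated_truth")
}

region_mask <- function(sites, regions) {
  mask <- rep(FALSE, nrow(sites))
  if (nrow(regions) > 0) {
    for (k in seq_len(nrow(regions))) {
      mask <- mask | (sites$chrom == regions$chrom[k] &
                        sites$pos >= regions$start[k] &
                        sites$pos <= regions$end[k])
    }
  }
  mask
}

#' Simulate a measured multi-method beta dataset
#'
#' Adds method bias, injected region effects and heteroscedastic technical
#' noise to a simulated truth, then clamps to \[0, 1\]. Each measurement
#' gets independent noise with SD `sigma(true)/sqrt(2)`, so the difference
#' between two methods has SD `sigma(true)` -- the model the agreement
#' analysis fits. Clamping slightly deflates variance near the boundaries;
#' with `noise_b < 0` boundary noise is tiny, so the bias is small (see the
#' methods vignette).
#'
#' @param p A [simulation_params()].
#' @param truth A `simulated_truth` from [simulate_truth()]; generated
#'   internally if omitted.
#' @param positions Optional site annotation tibble overriding the default
#'   one-chromosome, 500-bp-spaced layout.
#' @return A [beta_dataset()] with one sample per subject-method pair, with
#'   the region mask attached as attribute `"region_mask"` and the truth as
#'   attribute `"truth"`.
#' @export
#' @examples
#' ds <- simulate_dataset(simulation_params(n_subjects = 3, n_sites = 50))
#' ds
simulate_dataset <- function(p, truth = NULL, positions = NULL) {
  stopifnot(inherits(p, "simulation_params"))
  if (is.null(truth)) truth <- simulate_truth(p)
  stopifnot(inherits(truth, "simulated_truth"))
  tm <- truth$true_methylation
  if (!identical(dim(tm), c(p$n_sites, p$n_subjects)))
    stop("truth dimensions do not match simulation parameters")
  sites <- if (is.null(positions)) truth$sites else tibble::as_tibble(positions)
  mask <- region_mask(sites, p$injected_regions)

  set.seed(p$seed + 1L)
  noise_sd <- sigma_fun(tm, p$noise_a, p$noise_b) / sqrt(2)
  mats <- vector("list", length(p$methods))
  names(mats) <- p$methods
  for (m in p$methods) {
    x <- tm + p$method_bias[[m]]
    reg <- p$injected_regions[p$injected_regions$method == m, ]
    for (k in seq_len(nrow(reg))) {
      mk <- region_mask(sites, reg[k, ])
      x[mk, ] <- x[mk, ] + reg$delta[k]
    }
    eps <- matrix(stats::rnorm(length(tm)), nrow = nrow(tm)) * noise_sd
    mats[[m]] <- pmin(pmax(x + eps, 0), 1)
  }

  betas <- do.call(cbind, lapply(p$methods, function(m) {
    mm <- mats[[m]]
    colnames(mm) <- paste(m, truth$subjects, sep = "_")
    mm
  }))
  rownames(betas) <- sites$site_id

  samples <- simulate_samplesheet(p, truth$subjects)
  ds <- beta_dataset(betas, sites, samples)
  attr(ds, "region_mask") <- mask
  attr(ds, "truth") <- truth
  ds
}

# Sample sheet with chip positions (subjects of one chip share it, as when
# all methods of a subject are run on the same BeadChip) and QC metadata
# drawn from method-typical distributions.
simulate_samplesheet <- function(p, subjects) {
  grid <- expand.grid(subject_id = subjects, method = p$methods,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  # 12 positions per BeadChip (R01C01..R06C02); a subject's methods sit in
  # consecutive positions of the same chip
  pos_labels <- paste0("R", sprintf("%02d", rep(1:6, each = 2)),
                       "C", sprintf("%02d", rep(1:2, times = 6)))
  subj_idx <- match(grid$subject_id, subjects)
  meth_idx <- match(grid$method, p$methods)
  slot <- (subj_idx - 1) * length(p$methods) + meth_idx - 1
  chip_position <- pos_labels[(slot %% 12) + 1]

  qc <- list(  # loosely modelled on typical yields/purities per method class
    yield = stats::setNames(rep(12, length(p$methods)), p$methods),
    a230 = stats::setNames(rep(2.0, length(p$methods)), p$methods)
  )
  defaults <- c(16, 7, 17)[seq_along(p$methods)]
  qc$yield[seq_along(defaults)] <- defaults
  a230_def <- c(2.0, 1.4, 2.3)[seq_along(p$methods)]
  qc$a230[seq_along(a230_def)] <- a230_def

  tibble::tibble(
    sample_id = paste(grid$method, grid$subject_id, sep = "_"),
    subject_id = grid$subject_id,
    method = grid$method,
    chip_position = chip_position,
    yield_ug = pmax(stats::rnorm(n, qc$yield[grid$method], 3), 0.5),
    a260_280 = stats::rnorm(n, 1.93, 0.03),
    a260_230 = pmax(stats::rnorm(n, qc$a230[grid$method], 0.15), 0.5)
  )
}

#' Write a simulated dataset and its ground truth to disk
#'
#' Writes the beta matrix, annotation and sample sheet via
#' [write_beta_dataset()], plus the true methylation matrix as TSV and the
#' simulation parameters as JSON.
#'
#' @param ds A dataset from [simulate_dataset()] (must carry its `"truth"`
#'   attribute).
#' @param p The [simulation_params()] used.
#' @param dir Output directory.
#' @return Invisibly, the named vector of paths written.
#' @export
write_simulation <- function(ds, p, dir) {
  paths <- write_beta_dataset(ds, dir, prefix = "sim")
  truth <- attr(ds, "truth")
  if (!is.null(truth)) {
    tp <- file.path(dir, "sim_truth.tsv")
    readr::write_tsv(tibble::as_tibble(truth$true_methylation,
                                       rownames = "site_id"),
                     tp, progress = FALSE)
    paths <- c(paths, truth = tp)
  }
  pp <- file.path(dir, "sim_params.json")
  pl <- unclass(p)
  pl$mixture_shapes <- as.data.frame(pl$mixture_shapes)
  jsonlite::write_json(pl, pp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, params = pp))
}
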