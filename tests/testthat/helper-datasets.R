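# Fixture builders shared across test files. Everything is generated in
# code; no data files are read from disk.

# A tiny hand-constructed dataset: `betas` is a named list of per-method
# site x subject matrices (all with identical dimnames).
toy_dataset <- function(betas, sites = NULL) {
  n_sites <- nrow(betas[[1]])
  subjects <- colnames(betas[[1]])
  if (is.null(subjects)) {
    subjects <- paste0("subj", seq_len(ncol(betas[[1]])))
    betas <- lapply(betas, function(m) {
      colnames(m) <- subjects
      m
    })
  }
  if (is.null(sites)) sites <- methagree::example_sites(n_sites)
  mat <- do.call(cbind, lapply(names(betas), function(m) {
    mm <- betas[[m]]
    rownames(mm) <- sites$site_id
    colnames(mm) <- paste(m, subjects, sep = "_")
    mm
  }))
  samples <- tibble::tibble(
    sample_id = colnames(mat),
    subject_id = rep(subjects, times = length(betas)),
    method = rep(names(betas), each = length(subjects)),
    chip_position = "R01C01",
    yield_ug = 10, a260_280 = 1.9, a260_230 = 2.0
  )
  methagree::beta_dataset(mat, sites, samples)
}

# Independent brute-force BH step-up, straight from the definition:
# p_(i) * m / i, cumulative minimum from the largest rank down, capped at 1.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Gaussian NLL of the heteroscedastic variance model, written independently
# of the package internals, for grid-search oracles.
nll_oracle <- function(a, b, x, d) {
  s <- exp(a + b * (x - 0.5)^2)
  sum(log(s) + d^2 / (2 * s^2))
}
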