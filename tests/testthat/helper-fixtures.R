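# small in-code fixtures shared across test files

toy_infections <- function() {
  tibble::tibble(
    phage_id = paste0("p", 1:5),
    s1 = c(1L, 1L, 0L, 0L, 1L),
    s2 = c(0L, 1L, 1L, 0L, 0L),
    s3 = c(1L, 0L, 1L, 0L, 1L)
  )
}

identity_infections <- function(n = 4) {
  m <- diag(n)
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- paste0("s", seq_len(n))
  dplyr::bind_cols(tibble::tibble(phage_id = paste0("p", seq_len(n))), out)
}

random_partition <- function(ids, k) {
  tibble::tibble(item = ids,
                 label = as.character(sample(seq_len(k), length(ids), replace = TRUE)))
}

random_dist <- function(n) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("i", seq_len(n)), paste0("i", seq_len(n)))
  m
}

# mixed binary/quantitative phenotype table with some missing cells
random_phenotypes <- function(n, n_bin = 3, n_quant = 2, p_na = 0.1) {
  stopifnot(n_bin >= 1, n_quant >= 1)
  bin <- matrix(rbinom(n * n_bin, 1, 0.5), n, n_bin)
  quant <- matrix(rnorm(n * n_quant, sd = 3), n, n_quant)
  X <- cbind(bin, quant)
  # keep the first feature fully observed so every pair shares one
  na_mask <- matrix(runif(length(X)) < p_na, n, ncol(X))
  na_mask[, 1] <- FALSE
  X[na_mask] <- NA
  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- c(paste0("b", seq_len(n_bin)), paste0("q", seq_len(n_quant)))
  dplyr::bind_cols(tibble::tibble(phage_id = paste0("p", seq_len(n))), out)
}
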