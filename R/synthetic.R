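#' Configuration for the synthetic phage-panel generator
#'
#' Bundles and validates the parameters of [simulate_phage_panel()]. The
#' defaults mirror the study conditions the package's worked examples use:
#' 13 phages in 6 receptor types, a reference titer of 1e7 PFU-equivalents,
#' 3 spot-test replicates, blocked pairs mostly reading ND, and a mixed
#' phenotype table with 16 binary host-range columns (the size of the
#' optimized host panel) plus 4 quantitative physiology features.
#'
#' @param n_phages Number of phages.
#' @param n_types Number of planted receptor types (`<= n_phages`).
#' @param genes_per_type Genes required per type (1-3).
#' @param n_single_mutant_strains Number of single-gene knockout strains;
#'   default `NULL` = one per gene (full coverage, needed for exact
#'   zero-noise profile recovery).
#' @param n_double_mutant_strains Number of double-gene knockout strains.
#' @param reference_titer Wild-type titer (PFU-equivalent).
#' @param noise_sd Measurement noise sd of permissive log-EoP values.
#' @param p_spurious_drop Probability a permissive phage-strain pair shows a
#'   spurious >10-fold drop.
#' @param p_nd_given_blocked Probability a blocked pair reads ND rather than
#'   a large finite drop.
#' @param n_replicates Spot-test replicates per phage-strain pair.
#' @param n_binary_hosts Binary host-range columns in the phenotype table.
#' @param n_quant_features Quantitative physiology columns.
#' @param delta Between-type separation of quantitative feature means.
#' @param sigma Within-type sd of quantitative features.
#' @param epsilon Bit-flip rate of the binary host-range patterns.
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @return A validated `synthetic_config` list.
#' @export
sim_config <- function(n_phages = 13, n_types = 6, genes_per_type = 2,
                       n_single_mutant_strains = NULL,
                       n_double_mutant_strains = 2,
                       reference_titer = 1e7, noise_sd = 0.3,
                       p_spurious_drop = 0.02, p_nd_given_blocked = 0.7,
                       n_replicates = 3, n_binary_hosts = 16,
                       n_quant_features = 4, delta = 2, sigma = 0.5,
                       epsilon = 0.05, seed = 1L) {
  cfg <- list(
    n_phages = as.integer(n_phages), n_types = as.integer(n_types),
    genes_per_type = as.integer(genes_per_type),
    n_single_mutant_strains = if (is.null(n_single_mutant_strains)) NULL
                              else as.integer(n_single_mutant_strains),
    n_double_mutant_strains = as.integer(n_double_mutant_strains),
    reference_titer = reference_titer, noise_sd = noise_sd,
    p_spurious_drop = p_spurious_drop,
    p_nd_given_blocked = p_nd_given_blocked,
    n_replicates = as.integer(n_replicates),
    n_binary_hosts = as.integer(n_binary_hosts),
    n_quant_features = as.integer(n_quant_features),
    delta = delta, sigma = sigma, epsilon = epsilon, seed = as.integer(seed)
  )
  if (cfg$n_types > cfg$n_phages) {
    stop("`n_types` must not exceed `n_phages`", call. = FALSE)
  }
  if (cfg$n_types < 1 || cfg$n_phages < 1) stop("counts must be positive", call. = FALSE)
  if (!cfg$genes_per_type %in% 1:3) stop("`genes_per_type` must be 1, 2 or 3", call. = FALSE)
  for (p in c("p_spurious_drop", "p_nd_given_blocked", "epsilon")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(sprintf("`%s` must be in [0, 1]", p), call. = FALSE)
  }
  if (cfg$delta < 0 || cfg$sigma < 0 || cfg$noise_sd < 0) {
    stop("`delta`, `sigma` and `noise_sd` must be nonnegative", call. = FALSE)
  }
  if (cfg$reference_titer <= 0) stop("`reference_titer` must be positive", call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

# per-type gene-requirement sets: type 1 and type 2 are nested (type 2 adds
# one gene), deliberately exercising the one-bit near-identical-type case;
# remaining types get disjoint gene blocks
planted_gene_sets <- function(n_types, genes_per_type) {
  n_genes <- genes_per_type + (if (n_types >= 2) 1L else 0L) +
    max(0L, n_types - 2L) * genes_per_type
  genes <- sprintf("g%02d", seq_len(max(n_genes, 1L)))
  sets <- vector("list", n_types)
  sets[[1L]] <- genes[seq_len(genes_per_type)]
  if (n_types >= 2) sets[[2L]] <- genes[seq_len(genes_per_type + 1L)]
  if (n_types >= 3) {
    start <- genes_per_type + 2L
    for (t in 3:n_types) {
      sets[[t]] <- genes[start:(start + genes_per_type - 1L)]
      start <- start + genes_per_type
    }
  }
  names(sets) <- paste0("type", seq_len(n_types))
  list(genes = genes[seq_len(n_genes)], sets = sets)
}

# truncated-normal draw on (lower, upper] via inverse CDF; sd = 0 -> mean
rtruncnorm01 <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Simulate a full phage-panel dataset with planted receptor types
#'
#' Generates every input the analysis chain consumes, with known ground
#' truth: phages are assigned to receptor types round-robin; each type has a
#' distinct gene-requirement vector; knockout strains (singles covering
#' every gene, plus random doubles) yield spot-test titers where blocked
#' pairs read ND or a large finite drop and permissive pairs carry
#' measurement noise truncated above the 10-fold-reduction boundary (so at
#' `p_spurious_drop = 0` no permissive pair is ever called reduced); and a
#' mixed phenotype table whose cluster structure mirrors the planted types
#' with tunable noise. At zero noise the whole pipeline recovers the planted
#' profile, typing and partition exactly.
#'
#' @param config A `synthetic_config` from [sim_config()].
#' @return A `synthetic_bundle` list with elements `truth` (planted
#'   partition tibble `item`, `label`), `profile` (planted long
#'   receptor-profile tibble), `titers`, `mutant_genes`, `phenotypes`,
#'   `infections`, `reference_strain`, and `config`.
#' @examples
#' b <- simulate_phage_panel(sim_config(n_phages = 8, n_types = 4, seed = 42))
#' names(b)
#' @export
simulate_phage_panel <- function(config = sim_config()) {
  if (!inherits(config, "synthetic_config")) {
    stop("`config` must come from sim_config()", call. = FALSE)
  }
  with_local_seed(config$seed, simulate_phage_panel_impl(config))
}

simulate_phage_panel_impl <- function(cfg) {
  phages <- sprintf("P%02d", seq_len(cfg$n_phages))
  type_of <- ((seq_len(cfg$n_phages) - 1L) %% cfg$n_types) + 1L  # round-robin
  gs <- planted_gene_sets(cfg$n_types, cfg$genes_per_type)
  genes <- gs$genes

  # knockout strains: singles cycle over the gene list, then random doubles
  n_single <- cfg$n_single_mutant_strains %||% length(genes)
  single_genes <- genes[((seq_len(n_single) - 1L) %% length(genes)) + 1L]
  strains <- sprintf("KO%02d", seq_len(n_single + cfg$n_double_mutant_strains))
  strain_sets <- as.list(single_genes)
  if (cfg$n_double_mutant_strains > 0) {
    for (i in seq_len(cfg$n_double_mutant_strains)) {
      strain_sets[[n_single + i]] <- sample(genes, 2L)
    }
  }
  names(strain_sets) <- strains
  mutant_genes <- tibble::tibble(
    strain_id = rep(strains, lengths(strain_sets)),
    gene_id = unlist(strain_sets, use.names = FALSE)
  )

  # planted receptor profile (long form, no ambiguity in the ground truth)
  required <- vapply(seq_len(cfg$n_phages), function(i) {
    genes %in% gs$sets[[type_of[i]]]
  }, logical(length(genes)))
  profile <- tibble::tibble(
    phage_id = rep(phages, each = length(genes)),
    gene_id = rep(genes, cfg$n_phages),
    required = as.integer(as.vector(required)),
    ambiguous = FALSE
  )
  class(profile) <- c("receptor_profile", class(profile))

  # spot-test titers: reference strain + knockouts, n_replicates each
  ref_strain <- "WT"
  grid <- tidyr::expand_grid(
    phage_id = phages, strain_id = strains,
    replicate = seq_len(cfg$n_replicates)
  )
  blocked <- purrr::map2_lgl(grid$phage_id, grid$strain_id, function(p, s) {
    any(strain_sets[[s]] %in% gs$sets[[type_of[match(p, phages)]]])
  })
  n_obs <- nrow(grid)
  log_eop <- numeric(n_obs)
  is_nd <- logical(n_obs)
  # blocked pairs: ND with p_nd_given_blocked, else a large finite drop
  nb <- sum(blocked)
  if (nb > 0) {
    is_nd[blocked] <- runif(nb) < cfg$p_nd_given_blocked
    log_eop[blocked] <- runif(nb, -6, -1.5)
  }
  # permissive pairs: noise truncated to (-1, 0], spurious drops injected
  np <- sum(!blocked)
  if (np > 0) {
    log_eop[!blocked] <- rtruncnorm01(np, 0, cfg$noise_sd, -1, 0)
    spur <- !blocked
    spur[spur] <- runif(np) < cfg$p_spurious_drop
    log_eop[spur] <- runif(sum(spur), -6, -1.5)
  }
  titer <- cfg$reference_titer * 10^log_eop
  titer[is_nd] <- NA_real_
  titers <- dplyr::bind_rows(
    tibble::tibble(phage_id = rep(phages, each = cfg$n_replicates),
                   strain_id = ref_strain,
                   replicate = rep(seq_len(cfg$n_replicates), cfg$n_phages),
                   titer = cfg$reference_titer),
    dplyr::mutate(grid, titer = titer)
  )

  # mixed phenotype table: binary host-range bits (type-specific patterns,
  # distinct by construction via a binary encoding prefix) + quantitative
  # physiology features with separated type means
  n_code <- max(1L, ceiling(log2(max(cfg$n_types, 2L))))
  if (cfg$n_binary_hosts < n_code) {
    stop(sprintf("`n_binary_hosts` must be at least %d to keep type patterns distinct", n_code),
         call. = FALSE)
  }
  base_bits <- t(vapply(seq_len(cfg$n_types), function(t) {
    code <- as.integer(intToBits(t - 1L))[seq_len(n_code)]
    extra <- if (cfg$n_binary_hosts > n_code) {
      rbinom(cfg$n_binary_hosts - n_code, 1L, 0.5)
    } else integer(0)
    c(code, extra)
  }, integer(cfg$n_binary_hosts)))
  bits <- base_bits[type_of, , drop = FALSE]
  flips <- matrix(runif(length(bits)) < cfg$epsilon, nrow(bits))
  bits[flips] <- 1L - bits[flips]
  colnames(bits) <- sprintf("host%02d", seq_len(cfg$n_binary_hosts))

  quant <- NULL
  if (cfg$n_quant_features > 0) {
    mu <- matrix(cfg$delta * rnorm(cfg$n_types * cfg$n_quant_features),
                 cfg$n_types, cfg$n_quant_features)
    quant <- mu[type_of, , drop = FALSE] +
      cfg$sigma * matrix(rnorm(cfg$n_phages * cfg$n_quant_features),
                         cfg$n_phages, cfg$n_quant_features)
    colnames(quant) <- sprintf("phys%02d", seq_len(cfg$n_quant_features))
  }
  phenotypes <- dplyr::bind_cols(
    tibble::tibble(phage_id = phages),
    tibble::as_tibble(bits),
    if (!is.null(quant)) tibble::as_tibble(quant)
  )

  infections <- dplyr::bind_cols(tibble::tibble(phage_id = phages),
                                 tibble::as_tibble(bits))

  structure(
    list(
      truth = tibble::tibble(item = phages,
                             label = type_letters(cfg$n_types)[type_of]),
      profile = profile,
      titers = titers,
      mutant_genes = mutant_genes,
      phenotypes = phenotypes,
      infections = infections,
      reference_strain = ref_strain,
      config = cfg
    ),
    class = "synthetic_bundle"
  )
}

#' Write a synthetic bundle's standard input files
#'
#' Materializes the bundle as the plain-text files the readers of this
#' package consume: `titers.tsv`, `mutants.tsv`, `phenotypes.tsv`,
#' `infections.tsv` and `truth.json`.
#'
#' @param bundle A `synthetic_bundle` from [simulate_phage_panel()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!inherits(bundle, "synthetic_bundle")) {
    stop("`bundle` must come from simulate_phage_panel()", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  titers <- bundle$titers
  titers$titer <- ifelse(is.na(titers$titer), "ND", format(titers$titer, scientific = FALSE))
  readr::write_tsv(titers, file.path(dir, "titers.tsv"))
  readr::write_tsv(bundle$mutant_genes, file.path(dir, "mutants.tsv"))
  readr::write_tsv(bundle$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_infection_matrix(bundle$infections, file.path(dir, "infections.tsv"))
  write_partition(bundle$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
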