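# Independent oracles used across the suite. These deliberately use a
# different computational route than the package implementation.

# upper tail P(X >= count) by direct pmf summation from count upward
# (avoids the cancellation of 1 - sum(lower pmf) for far-tail counts)
brute_nb_tail <- function(count, mu, phi) {
  if (count <= 0) return(1)
  upper <- max(count, ceiling(mu + 20 * sqrt(mu + phi * mu^2))) + 2000
  dens <- if (phi <= 0) stats::dpois(count:upper, mu)
          else stats::dnbinom(count:upper, mu = mu, size = 1 / phi)
  sum(dens)
}

# exact two-sided rank-sum p by enumeration of all group assignments
brute_ranksum_p <- function(x, y) {
  m <- length(x)
  v <- c(x, y)
  r <- rank(v)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(v), m)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# exact two-sided signed-rank p by enumeration of all 2^n sign vectors
brute_signedrank_p <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# do two peptides share an identical substring of length k? sliding
# window + fixed-string search (no k-mer index)
brute_share_kmer <- function(a, b, k) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  for (i in 1:(nchar(a) - k + 1)) {
    if (grepl(substr(a, i, i + k - 1), b, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

random_peptide <- function(len = 56) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# random Erdos-Renyi graph as an igraph with letter ids
random_named_graph <- function(n, p_edge) {
  g <- igraph::sample_gnp(n, p_edge)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# assemble an allerscan_hits object directly from matrices (unit tests
# of downstream stages)
make_hits <- function(hit, values = NULL) {
  if (is.null(values)) values <- ifelse(hit, 10, 1)
  structure(list(clone_ids = rownames(hit), sample_ids = colnames(hit),
                 hit = hit, values = values,
                 thresholds = c(min_count = 100, max_p = 0.001, min_fc = 5)),
            class = "allerscan_hits")
}

# small simulated cohort shared by several test files
small_cohort <- function(seed = 11) {
  cfg <- sim_config(
    n_proteins = 24, protein_length_range = c(80, 250), n_organisms = 4,
    n_mocks = 4, depth = 3e5, dispersion = 0.1,
    groups = list(
      list(name = "allergic", n_samples = 8,
           ige = list(organism = "wheat", n_peptides = 10,
                      fc_meanlog = log(20), fc_sdlog = 0.5),
           igg = list(organism = "wheat", n_peptides = 10,
                      fc_meanlog = log(20), fc_sdlog = 0.5),
           epitope_rate = c(ige = 0.3, igg = 0.05)),
      list(name = "non_allergic", n_samples = 8,
           ige = list(organism = "any", n_peptides = 1,
                      fc_meanlog = log(8), fc_sdlog = 0.5),
           igg = list(organism = "wheat", n_peptides = 1,
                      fc_meanlog = log(10), fc_sdlog = 0.5),
           epitope_rate = c(ige = 0, igg = 0.7))),
    n_replicate_pairs = 2,
    oit = list(group = "allergic", n_subjects = 6, ige_loss_fraction = 0.5,
               igg_gain_fraction = 0.5, purothionin_like_gain = TRUE,
               gain_rate = 0.9),
    seed = seed)
  simulate_cohort(cfg)
}
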