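#' Fit the mock-IP null model
#'
#' Estimates, from the mock (no-serum) immunoprecipitations, each clone's
#' expected share of reads and its negative binomial dispersion. Expected
#' proportions are additively regularised pooled mock counts. Per-clone
#' dispersions are method-of-moments estimates on depth-normalised mock
#' counts, shrunk toward a trended (mean-binned) dispersion.
#'
#' @param counts Wide count tibble (`clone_id` + sample columns).
#' @param mock_ids Character vector naming the mock sample columns.
#' @param alpha Additive regulariser on pooled counts (default 0.5);
#'   `alpha = 0` can leave clones with estimated proportion 0, which are
#'   then tested against a minimum-proportion floor and flagged.
#' @param shrinkage_strength Weight in `[0, 1]` pulling each clone's raw
#'   dispersion toward the trend (default 0.5).
#' @param fallback_dispersion Dispersion used for every clone when only
#'   one mock is available (no variance information); default 0.2.
#' @return An `allerscan_mock_model`: list with `clones` tibble
#'   (`clone_id`, `p_hat`, `mean_norm`, `phi_raw`, `phi_trend`, `phi`),
#'   `n_mocks`, `alpha`, `shrinkage_strength`, `global_phi`, `floor_p`.
#' @export
fit_mock_model <- function(counts, mock_ids, alpha = 0.5,
                           shrinkage_strength = 0.5,
                           fallback_dispersion = 0.2) {
  counts <- tibble::as_tibble(counts)
  if (length(mock_ids) == 0) stop("no mock samples given", call. = FALSE)
  missing <- setdiff(mock_ids, names(counts))
  if (length(missing)) {
    stop("mock samples absent from counts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stopifnot(shrinkage_strength >= 0, shrinkage_strength <= 1, alpha >= 0)
  M <- as.matrix(counts[mock_ids])
  rownames(M) <- counts$clone_id
  pooled <- rowSums(M) + alpha
  p_hat <- pooled / sum(pooled)
  if (alpha == 0 && any(p_hat == 0)) {
    warning(sum(p_hat == 0), " clone(s) unseen in mocks have p_hat = 0; ",
            "they will be tested against the minimum-proportion floor",
            call. = FALSE)
  }
  depths <- colSums(M)
  D <- mean(depths)
  if (length(mock_ids) < 2) {
    warning("only one mock sample: per-clone dispersion cannot be ",
            "estimated; using fallback_dispersion = ", fallback_dispersion,
            " for all clones", call. = FALSE)
    m <- as.numeric(M[, 1] * (D / depths[1]))
    clones <- tibble::tibble(
      clone_id = counts$clone_id, p_hat = as.numeric(p_hat),
      mean_norm = m, phi_raw = NA_real_, phi_trend = fallback_dispersion,
      phi = fallback_dispersion)
    global_phi <- fallback_dispersion
  } else {
    Y <- sweep(M, 2, D / depths, "*")
    m <- rowMeans(Y)
    v <- apply(Y, 1, stats::var)
    phi_raw <- ifelse(m > 0, (v - m) / m^2, NA_real_)
    phi_pos <- pmax(phi_raw, 0)
    # trend: mean positive dispersion within log-mean bins
    ok <- which(m > 0)
    nbin <- max(1L, min(10L, floor(length(ok) / 20)))
    bins <- if (nbin < 2 || length(ok) < 2) rep(1L, length(ok))
            else cut(rank(m[ok], ties.method = "first"), nbin, labels = FALSE)
    trend_by_bin <- tapply(phi_pos[ok], bins, mean, na.rm = TRUE)
    phi_trend <- rep(mean(phi_pos, na.rm = TRUE), length(m))
    phi_trend[ok] <- trend_by_bin[bins]
    phi <- ifelse(is.na(phi_raw), phi_trend,
                  (1 - shrinkage_strength) * phi_pos +
                    shrinkage_strength * phi_trend)
    clones <- tibble::tibble(
      clone_id = counts$clone_id, p_hat = as.numeric(p_hat),
      mean_norm = as.numeric(m), phi_raw = as.numeric(phi_raw),
      phi_trend = as.numeric(phi_trend), phi = as.numeric(phi))
    global_phi <- stats::weighted.mean(phi_pos, w = m, na.rm = TRUE)
  }
  pos <- clones$p_hat[clones$p_hat > 0]
  structure(list(clones = clones, n_mocks = length(mock_ids),
                 alpha = alpha, shrinkage_strength = shrinkage_strength,
                 global_phi = global_phi,
                 floor_p = if (length(pos)) min(pos) else NA_real_),
            class = "allerscan_mock_model")
}

#' Upper-tail probability of the negative binomial null
#'
#' `P(X >= count)` for `X ~ NB(mu, phi)` with variance `mu + phi mu^2`;
#' `phi = 0` is the Poisson limit. Vectorised over all arguments.
#'
#' @param count Observed count(s).
#' @param mu Expected count(s).
#' @param phi Dispersion(s).
#' @return Tail probabilities in `(0, 1]`.
#' @export
nb_tail <- function(count, mu, phi = 0) {
  n <- max(length(count), length(mu), length(phi))
  count <- rep_len(count, n); mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  p <- ifelse(phi <= 0,
              stats::ppois(count - 1, mu, lower.tail = FALSE),
              stats::pnbinom(count - 1, mu = mu, size = 1 / pmax(phi, 1e-12),
                             lower.tail = FALSE))
  p[count <= 0] <- 1
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Test one sample's counts against the mock model
#'
#' For each clone the expected count is the sample depth times the mock
#' proportion; the p-value is the one-sided (enrichment) NB tail
#' probability and the fold change is pseudocount-stabilised observed over
#' expected. Clones with zero mock proportion are tested against the
#' minimum positive proportion and flagged.
#'
#' @param sample_counts Integer vector aligned to the mock model's clones.
#' @param mock_model An `allerscan_mock_model`.
#' @param pseudocount Added to numerator and denominator of the fold
#'   change (default 1).
#' @return A tibble: `clone_id`, `count`, `expected`, `fold_change`,
#'   `p_value`, `fdr` (Benjamini-Hochberg, informational only),
#'   `floored` (logical).
#' @export
test_sample <- function(sample_counts, mock_model, pseudocount = 1) {
  cl <- mock_model$clones
  stopifnot(length(sample_counts) == nrow(cl))
  depth <- sum(sample_counts)
  if (depth <= 0) stop("sample depth must be positive", call. = FALSE)
  floored <- cl$p_hat == 0 & sample_counts > 0
  p_use <- ifelse(cl$p_hat == 0, mock_model$floor_p, cl$p_hat)
  mu <- depth * p_use
  pv <- nb_tail(sample_counts, mu, cl$phi)
  tibble::tibble(
    clone_id = cl$clone_id,
    count = as.integer(sample_counts),
    expected = depth * cl$p_hat,
    fold_change = (sample_counts + pseudocount) / (depth * p_use + pseudocount),
    p_value = pv,
    fdr = stats::p.adjust(pv, "BH"),
    floored = floored
  )
}

#' Test every sample of a count table against the mock model
#'
#' @param counts Wide count tibble (`clone_id` + sample columns).
#' @param mock_model An `allerscan_mock_model`.
#' @param sample_ids Columns to test; defaults to every non-`clone_id`
#'   column (mocks included only if listed).
#' @inheritParams test_sample
#' @return An `allerscan_enrichment` object holding clone/sample ids and
#'   count, expected, fold-change and p-value matrices. Use
#'   [generics::tidy()] for a long tibble.
#' @export
test_enrichment <- function(counts, mock_model,
                            sample_ids = NULL, pseudocount = 1) {
  counts <- tibble::as_tibble(counts)
  if (is.null(sample_ids)) sample_ids <- setdiff(names(counts), "clone_id")
  stopifnot(identical(counts$clone_id, mock_model$clones$clone_id))
  res <- lapply(sample_ids, function(s)
    test_sample(counts[[s]], mock_model, pseudocount))
  pack <- function(col) {
    m <- do.call(cbind, lapply(res, `[[`, col))
    dimnames(m) <- list(counts$clone_id, sample_ids)
    m
  }
  structure(list(
    clone_ids = counts$clone_id,
    sample_ids = sample_ids,
    counts = pack("count"),
    expected = pack("expected"),
    fold_change = pack("fold_change"),
    p_value = pack("p_value")
  ), class = "allerscan_enrichment")
}

#' Call enriched peptides ("hits")
#'
#' A clone-sample pair is a hit when its read count, enrichment p-value
#' and fold change simultaneously pass the thresholds (defaults: count >=
#' 100, p <= 0.001, fold change >= 5). The hits matrix carries the fold
#' change for hits and exactly 1 for non-hits.
#'
#' @param enrichment An `allerscan_enrichment`.
#' @param min_count Minimum read count (default 100).
#' @param max_p Maximum p-value (default 0.001; "p of at least 0.001"
#'   read in the significance direction, i.e. p <= 0.001).
#' @param min_fc Minimum fold change (default 5).
#' @return An `allerscan_hits` object: logical `hit` matrix, numeric
#'   `values` matrix (fold change or 1), thresholds used.
#' @export
call_hits <- function(enrichment, min_count = 100, max_p = 0.001,
                      min_fc = 5) {
  stopifnot(inherits(enrichment, "allerscan_enrichment"),
            min_count > 0, max_p > 0, min_fc > 0)
  hit <- enrichment$counts >= min_count &
    enrichment$p_value <= max_p &
    enrichment$fold_change >= min_fc
  values <- ifelse(hit, enrichment$fold_change, 1)
  structure(list(
    clone_ids = enrichment$clone_ids,
    sample_ids = enrichment$sample_ids,
    hit = hit,
    values = values,
    thresholds = c(min_count = min_count, max_p = max_p, min_fc = min_fc)
  ), class = "allerscan_hits")
}

#' @export
print.allerscan_mock_model <- function(x, ...) {
  cat("Mock-IP null model:", nrow(x$clones), "clones,", x$n_mocks,
      "mocks; global dispersion", signif(x$global_phi, 3), "\n")
  invisible(x)
}

#' @export
print.allerscan_enrichment <- function(x, ...) {
  cat("Enrichment results:", length(x$clone_ids), "clones x",
      length(x$sample_ids), "samples\n")
  invisible(x)
}

#' @export
print.allerscan_hits <- function(x, ...) {
  cat("Hit matrix:", length(x$clone_ids), "clones x",
      length(x$sample_ids), "samples;", sum(x$hit), "hits\n")
  invisible(x)
}
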