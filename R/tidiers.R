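#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mock-IP null model
#'
#' @param x An `allerscan_mock_model`.
#' @param ... Unused.
#' @return The per-clone tibble (`clone_id`, `p_hat`, `mean_norm`,
#'   `phi_raw`, `phi_trend`, `phi`).
#' @method tidy allerscan_mock_model
#' @export
tidy.allerscan_mock_model <- function(x, ...) x$clones

#' One-row summary of a mock-IP null model
#' @inheritParams tidy.allerscan_mock_model
#' @return Tibble with `n_clones`, `n_mocks`, `global_phi`, `alpha`,
#'   `shrinkage_strength`.
#' @method glance allerscan_mock_model
#' @export
glance.allerscan_mock_model <- function(x, ...) {
  tibble::tibble(n_clones = nrow(x$clones), n_mocks = x$n_mocks,
                 global_phi = x$global_phi, alpha = x$alpha,
                 shrinkage_strength = x$shrinkage_strength)
}

#' Tidy enrichment results into a long tibble
#'
#' @param x An `allerscan_enrichment`.
#' @param ... Unused.
#' @return Long tibble: `clone_id`, `sample_id`, `count`, `expected`,
#'   `fold_change`, `p_value`, `fdr` (BH within sample).
#' @method tidy allerscan_enrichment
#' @export
tidy.allerscan_enrichment <- function(x, ...) {
  long <- tibble::tibble(
    clone_id = rep(x$clone_ids, times = length(x$sample_ids)),
    sample_id = rep(x$sample_ids, each = length(x$clone_ids)),
    count = as.vector(x$counts),
    expected = as.vector(x$expected),
    fold_change = as.vector(x$fold_change),
    p_value = as.vector(x$p_value)
  )
  long |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(fdr = stats::p.adjust(.data$p_value, "BH")) |>
    dplyr::ungroup()
}

#' One-row summary of enrichment results
#' @inheritParams tidy.allerscan_enrichment
#' @return Tibble with `n_clones`, `n_samples`, `min_p`,
#'   `median_fold_change`.
#' @method glance allerscan_enrichment
#' @export
glance.allerscan_enrichment <- function(x, ...) {
  tibble::tibble(n_clones = length(x$clone_ids),
                 n_samples = length(x$sample_ids),
                 min_p = min(x$p_value),
                 median_fold_change = stats::median(x$fold_change))
}

#' Tidy a hit matrix into a long tibble
#'
#' @param x An `allerscan_hits`.
#' @param hits_only Keep only hit rows (default `TRUE`).
#' @param ... Unused.
#' @return Long tibble: `clone_id`, `sample_id`, `hit`, `value` (fold
#'   change for hits, 1 otherwise).
#' @method tidy allerscan_hits
#' @export
tidy.allerscan_hits <- function(x, hits_only = TRUE, ...) {
  long <- tibble::tibble(
    clone_id = rep(x$clone_ids, times = length(x$sample_ids)),
    sample_id = rep(x$sample_ids, each = length(x$clone_ids)),
    hit = as.vector(x$hit),
    value = as.vector(x$values)
  )
  if (hits_only) long <- dplyr::filter(long, .data$hit)
  long
}

#' One-row summary of a hit matrix
#' @param x An `allerscan_hits`.
#' @param ... Unused.
#' @return Tibble with `n_clones`, `n_samples`, `n_hits`,
#'   `hits_per_sample`, plus the thresholds used.
#' @method glance allerscan_hits
#' @export
glance.allerscan_hits <- function(x, ...) {
  tibble::tibble(n_clones = length(x$clone_ids),
                 n_samples = length(x$sample_ids),
                 n_hits = sum(x$hit),
                 hits_per_sample = sum(x$hit) / length(x$sample_ids),
                 min_count = x$thresholds[["min_count"]],
                 max_p = x$thresholds[["max_p"]],
                 min_fc = x$thresholds[["min_fc"]])
}
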