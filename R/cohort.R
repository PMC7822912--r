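#' Keep peptides recognised by at least `min_samples` samples
#'
#' @param hits An `allerscan_hits` object.
#' @param min_samples Minimum number of samples in which a peptide must be
#'   a hit (default 3).
#' @return Character vector of retained clone ids.
#' @export
prevalence_filter <- function(hits, min_samples = 3) {
  stopifnot(inherits(hits, "allerscan_hits"), min_samples >= 1)
  hits$clone_ids[rowSums(hits$hit) >= min_samples]
}

#' Drop organisms contributing fewer than `min_peptides` recognised peptides
#'
#' Applied after [prevalence_filter()]: peptides whose source organism has
#' fewer than `min_peptides` peptides in the recognised set are removed.
#'
#' @param clone_ids Character vector of recognised peptide ids.
#' @param annotation Clone annotation (`clone_id`, `organism`).
#' @param min_peptides Minimum recognised peptides per organism
#'   (default 5).
#' @return Filtered character vector of clone ids.
#' @export
organism_filter <- function(clone_ids, annotation, min_peptides = 5) {
  stopifnot(min_peptides >= 1)
  if (length(clone_ids) == 0) return(character(0))
  ann <- annotation[match(clone_ids, annotation$clone_id), ]
  if (anyNA(ann$clone_id)) {
    stop("clones without annotation: ",
         paste(utils::head(clone_ids[is.na(ann$clone_id)], 5),
               collapse = ", "), call. = FALSE)
  }
  keep_org <- names(which(table(ann$organism) >= min_peptides))
  clone_ids[ann$organism %in% keep_org]
}

#' Hierarchically cluster samples by their reactivity profiles
#'
#' Binary mode clusters hit/non-hit indicator profiles with the binary
#' (Jaccard-complement) distance; euclidean mode clusters the supplied
#' values with Euclidean distance. Both use Ward.D2 agglomeration, which
#' is deterministic for a fixed input ordering.
#'
#' @param hits An `allerscan_hits` object, or a samples-by-features
#'   numeric matrix.
#' @param distance `"binary"` or `"euclidean"`.
#' @param k Optional number of flat clusters to cut.
#' @param clone_ids Optional peptide subset to cluster on (for
#'   `allerscan_hits` input).
#' @return List with `hclust` (the dendrogram) and `clusters` (named
#'   integer vector, present when `k` is given).
#' @export
cluster_samples <- function(hits, distance = c("binary", "euclidean"),
                            k = NULL, clone_ids = NULL) {
  distance <- match.arg(distance)
  if (inherits(hits, "allerscan_hits")) {
    rows <- if (is.null(clone_ids)) hits$clone_ids
            else intersect(hits$clone_ids, clone_ids)
    m <- if (distance == "binary") t(hits$hit[rows, , drop = FALSE] * 1)
         else t(log10(hits$values[rows, , drop = FALSE]))
  } else {
    m <- as.matrix(hits)
  }
  if (nrow(m) < 2) stop("need at least 2 samples to cluster", call. = FALSE)
  if (!is.null(k) && k > nrow(m)) {
    stop("k exceeds the number of samples", call. = FALSE)
  }
  d <- stats::dist(m, method = distance)
  hc <- stats::hclust(d, method = "ward.D2")
  out <- list(hclust = hc)
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  out
}

#' Compare a metric between groups (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum tests between every pair of groups, with
#' no multiple-testing correction by default (a Benjamini-Hochberg column
#' can be added). Exact p-values are used whenever sample sizes permit
#' and there are no ties; otherwise the normal approximation with tie
#' correction.
#'
#' @param data Data frame with one row per sample.
#' @param value Column holding the metric (tidy-eval).
#' @param group Column holding the group label (tidy-eval).
#' @param adjust Add a BH-adjusted p-value column (default `FALSE`).
#' @return A tibble with one row per group pair: `group1`, `group2`,
#'   `n1`, `n2`, `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(data, value, group, adjust = FALSE) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  lev <- unique(g)
  if (length(lev) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs >= 2 values", call. = FALSE)
  pairs <- utils::combn(lev, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- v[g == pairs[1, j]]
    b <- v[g == pairs[2, j]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    tibble::tibble(group1 = pairs[1, j], group2 = pairs[2, j],
                   n1 = length(a), n2 = length(b),
                   statistic = unname(wt$statistic),
                   p_value = wt$p.value,
                   method = "wilcoxon_rank_sum")
  })
  if (adjust) res$p_adj <- stats::p.adjust(res$p_value, "BH")
  res
}

#' Paired before/after comparison (Wilcoxon signed-rank)
#'
#' Two-sided Wilcoxon signed-rank test on matched pairs. Zero differences
#' are dropped (Wilcoxon's original treatment); if every difference is
#' zero the test is degenerate and `p_value = 1` is returned with
#' `degenerate = TRUE`.
#'
#' @param before,after Matched numeric vectors.
#' @return One-row tibble: `n_pairs`, `n_nonzero`, `statistic`,
#'   `p_value`, `method`, `degenerate`.
#' @export
paired_change <- function(before, after) {
  stopifnot(length(before) == length(after))
  keep <- !is.na(before) & !is.na(after)
  before <- before[keep]; after <- after[keep]
  d <- after - before
  if (all(d == 0)) {
    return(tibble::tibble(n_pairs = length(d), n_nonzero = 0L,
                          statistic = NA_real_, p_value = 1,
                          method = "wilcoxon_signed_rank",
                          degenerate = TRUE))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(after, before, paired = TRUE,
                       alternative = "two.sided"))
  tibble::tibble(n_pairs = length(d), n_nonzero = sum(d != 0),
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = "wilcoxon_signed_rank", degenerate = FALSE)
}

#' IgE/IgG isotype concordance of reactive peptides
#'
#' Classifies every reactive peptide-sample pair (the union of IgE and
#' IgG hits over matched samples) as reactive in both isotypes, IgE only,
#' or IgG only.
#'
#' @param hits_ige,hits_igg Logical hit matrices (or `allerscan_hits`)
#'   with identical dimensions, columns matched by subject.
#' @return One-row tibble: `both`, `ige_only`, `igg_only` (fractions
#'   summing to 1) and `n_reactive`. All-`NA` with a warning when there
#'   are no reactive entries.
#' @export
isotype_concordance <- function(hits_ige, hits_igg) {
  h1 <- if (inherits(hits_ige, "allerscan_hits")) hits_ige$hit else hits_ige
  h2 <- if (inherits(hits_igg, "allerscan_hits")) hits_igg$hit else hits_igg
  stopifnot(identical(dim(h1), dim(h2)))
  union <- h1 | h2
  n <- sum(union)
  if (n == 0) {
    warning("no reactive entries; concordance undefined", call. = FALSE)
    return(tibble::tibble(both = NA_real_, ige_only = NA_real_,
                          igg_only = NA_real_, n_reactive = 0L))
  }
  tibble::tibble(both = sum(h1 & h2) / n,
                 ige_only = sum(h1 & !h2) / n,
                 igg_only = sum(!h1 & h2) / n,
                 n_reactive = n)
}

#' Summarise reactivity to a named epitope
#'
#' An epitope is a small set of member peptides (e.g. the three isoform
#' tiles of one discriminating allergen epitope). Each sample's epitope
#' reactivity is the maximum hit fold change over the members; a sample
#' is epitope-reactive if any member is a hit. Prevalence is the fraction
#' of reactive samples per metadata group.
#'
#' @param hits An `allerscan_hits` object.
#' @param epitope_ids Member peptide ids.
#' @param meta Optional sample metadata (must contain `sample_id`; a
#'   `group` column drives the prevalence summary).
#' @return List with `samples` (per-sample tibble: `sample_id`, `value`,
#'   `reactive`) and, when `meta` has a `group` column, `prevalence`
#'   (per-group tibble).
#' @export
epitope_summary <- function(hits, epitope_ids, meta = NULL) {
  stopifnot(inherits(hits, "allerscan_hits"), length(epitope_ids) > 0)
  unknown <- setdiff(epitope_ids, hits$clone_ids)
  if (length(unknown)) {
    stop("unknown epitope peptides: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vals <- hits$values[epitope_ids, , drop = FALSE]
  hit <- hits$hit[epitope_ids, , drop = FALSE]
  samples <- tibble::tibble(
    sample_id = hits$sample_ids,
    value = unname(apply(vals, 2, max)),
    reactive = unname(apply(hit, 2, any))
  )
  out <- list(samples = samples)
  if (!is.null(meta)) {
    samples <- dplyr::left_join(samples, meta, by = "sample_id")
    out$samples <- samples
    if ("group" %in% names(meta)) {
      grp_cols <- intersect(c("group", "isotype"), names(samples))
      out$prevalence <- samples |>
        dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
        dplyr::summarise(n = dplyr::n(),
                         prevalence = mean(.data$reactive),
                         .groups = "drop")
    }
  }
  out
}

#' Paired longitudinal count table for one subject
#'
#' Prepares the clone-level data behind pre/post pairwise scatter plots:
#' log-scale counts at both timepoints with an organism flag, plus the
#' fraction of target-organism clones above and below the diagonal
#' (restricted to `hit_ids` when given).
#'
#' @param counts_t0,counts_t1 Aligned count vectors for the two
#'   timepoints.
#' @param annotation Clone annotation (`clone_id`, `organism`) aligned to
#'   the vectors.
#' @param organism Target organism flagged in the output (default
#'   `"wheat"`).
#' @param hit_ids Optional peptide ids over which the off-diagonal
#'   summary is computed (e.g. the subject's hits); defaults to all
#'   target-organism clones.
#' @return List with `table` (tibble: `clone_id`, `log_t0`, `log_t1`,
#'   `is_target`) and `summary` (fractions above/below the diagonal).
#' @export
longitudinal_pairplot_data <- function(counts_t0, counts_t1, annotation,
                                       organism = "wheat", hit_ids = NULL) {
  stopifnot(length(counts_t0) == length(counts_t1),
            length(counts_t0) == nrow(annotation))
  if (sum(counts_t0) == 0 || sum(counts_t1) == 0) {
    stop("zero sequencing depth at a timepoint", call. = FALSE)
  }
  tab <- tibble::tibble(
    clone_id = annotation$clone_id,
    log_t0 = log10(counts_t0 + 1),
    log_t1 = log10(counts_t1 + 1),
    is_target = annotation$organism %in% organism
  )
  focus <- if (is.null(hit_ids)) tab$clone_id[tab$is_target]
           else intersect(hit_ids, tab$clone_id[tab$is_target])
  f <- tab[tab$clone_id %in% focus, ]
  summary <- tibble::tibble(
    n_target = nrow(f),
    frac_above = if (nrow(f)) mean(f$log_t1 > f$log_t0) else NA_real_,
    frac_below = if (nrow(f)) mean(f$log_t1 < f$log_t0) else NA_real_
  )
  list(table = tab, summary = summary)
}

#' Classify oral-immunotherapy response by food-challenge dose gain
#'
#' A participant responds to treatment when the tolerated cumulative
#' challenge dose increases by more than `threshold_mg` between baseline
#' and post-treatment. Missing doses give `NA` (not evaluable) rather
#' than an error.
#'
#' @param baseline_dose_mg,post_dose_mg Tolerated doses in mg
#'   (vectorised).
#' @param threshold_mg Required dose gain, exclusive (default 1000).
#' @return Logical vector (`TRUE` responder, `FALSE` non-responder, `NA`
#'   not evaluable).
#' @export
classify_woit_response <- function(baseline_dose_mg, post_dose_mg,
                                   threshold_mg = 1000) {
  stopifnot(threshold_mg >= 0)
  if (any(baseline_dose_mg < 0, na.rm = TRUE) ||
      any(post_dose_mg < 0, na.rm = TRUE)) {
    stop("doses must be >= 0", call. = FALSE)
  }
  (post_dose_mg - baseline_dose_mg) > threshold_mg
}
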