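#' Count reads by exact match against library insert prefixes
#'
#' A read is assigned to a clone if and only if its first `match_len`
#' bases (after an optional fixed-length adapter trim) exactly equal that
#' clone's insert prefix; anything else is unmapped. Prefix uniqueness at
#' `match_len` is verified up front, so assignment is unambiguous.
#'
#' @param fastq Path to a FASTQ file (plain or gzip).
#' @param inserts Named character vector of clone insert DNA (names are
#'   clone ids).
#' @param match_len Number of bases matched; default 50.
#' @param trim Bases trimmed from the read start before matching;
#'   default 0.
#' @return A list with `counts` (named integer vector per clone),
#'   `n_mapped`, `n_unmapped`, `n_total`.
#' @export
map_reads <- function(fastq, inserts, match_len = 50L, trim = 0L) {
  stopifnot(length(inserts) > 0, match_len >= 1)
  prefixes <- substr(unname(inserts), 1L, match_len)
  if (any(nchar(prefixes) < match_len)) {
    stop("some inserts are shorter than match_len = ", match_len,
         call. = FALSE)
  }
  dup <- duplicated(prefixes) | duplicated(prefixes, fromLast = TRUE)
  if (any(dup)) {
    stop("insert prefixes collide at match_len = ", match_len, ": ",
         paste(utils::head(names(inserts)[dup], 10), collapse = ", "),
         call. = FALSE)
  }
  reads <- tryCatch(
    as.character(Biostrings::readDNAStringSet(fastq, format = "fastq")),
    error = function(e) character(0))
  counts <- stats::setNames(integer(length(inserts)), names(inserts))
  if (length(reads) == 0) {
    warning("no reads in ", fastq, call. = FALSE)
    return(list(counts = counts, n_mapped = 0L, n_unmapped = 0L,
                n_total = 0L))
  }
  keys <- substr(reads, trim + 1L, trim + match_len)
  idx <- match(keys, prefixes)
  tab <- table(factor(idx[!is.na(idx)], levels = seq_along(inserts)))
  counts[] <- as.integer(tab)
  list(counts = counts,
       n_mapped = sum(!is.na(idx)),
       n_unmapped = sum(is.na(idx)),
       n_total = length(reads))
}

#' Library representation quality metrics
#'
#' @param library_counts Integer count vector over clones (e.g. from
#'   sequencing the packaged library).
#' @return A one-row tibble: `fraction_detected` (share of clones with
#'   count > 0), `fraction_within_one_log` (share of detected clones whose
#'   count lies within a symmetric one-log10 window `[m/sqrt(10),
#'   m*sqrt(10)]` around the median detected count `m`), and
#'   `fold_coverage` (total reads / number of clones).
#' @export
library_qc <- function(library_counts) {
  stopifnot(length(library_counts) > 0, all(library_counts >= 0))
  detected <- library_counts[library_counts > 0]
  if (length(detected) == 0) {
    return(tibble::tibble(fraction_detected = 0,
                          fraction_within_one_log = NA_real_,
                          fold_coverage = 0))
  }
  m <- stats::median(detected)
  tibble::tibble(
    fraction_detected = length(detected) / length(library_counts),
    fraction_within_one_log =
      mean(detected >= m / sqrt(10) & detected <= m * sqrt(10)),
    fold_coverage = sum(library_counts) / length(library_counts)
  )
}

#' Replicate concordance on the log scale
#'
#' Squared Pearson correlation of `log10(count + 1)` between two aligned
#' count vectors, the standard reproducibility metric for technical
#' replicate immunoprecipitations.
#'
#' @param counts_a,counts_b Aligned count vectors.
#' @return R-squared, or `NA` (with a warning) if either vector has zero
#'   variance on the log scale.
#' @export
replicate_r2 <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b))
  a <- log10(counts_a + 1)
  b <- log10(counts_b + 1)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance; R^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' Per-organism read share of each sample
#'
#' @param counts Wide count tibble (`clone_id` + one column per sample).
#' @param annotation Clone annotation with `clone_id` and `organism`.
#' @return Long tibble (`sample_id`, `organism`, `share`); shares sum to 1
#'   within each sample.
#' @export
organism_representation <- function(counts, annotation) {
  counts <- tibble::as_tibble(counts)
  missing <- setdiff(counts$clone_id, annotation$clone_id)
  if (length(missing)) {
    stop("clones without annotation: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  counts |>
    tidyr::pivot_longer(-"clone_id", names_to = "sample_id",
                        values_to = "count") |>
    dplyr::left_join(dplyr::select(annotation, "clone_id", "organism"),
                     by = "clone_id") |>
    dplyr::group_by(.data$sample_id, .data$organism) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop_last") |>
    dplyr::mutate(share = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "organism", "share")
}
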