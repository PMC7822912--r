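#' Read a clone-by-sample count table
#'
#' First column must be `clone_id`; every other column is one sample and
#' must contain non-negative integers. Parsing is strict: any
#' non-integer cell fails with its row and column named.
#'
#' @param path Counts TSV path.
#' @return Wide count tibble.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(x)[1] != "clone_id") {
    stop("first column of ", path, " must be 'clone_id'", call. = FALSE)
  }
  for (col in setdiff(names(x), "clone_id")) {
    v <- x[[col]]
    bad <- which(is.na(v) | !is.numeric(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      stop("non-integer count in ", path, " at row ", bad[1],
           ", sample '", col, "'", call. = FALSE)
    }
    x[[col]] <- as.integer(v)
  }
  x
}

#' Write a clone-by-sample count table
#' @param counts Wide count tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path Metadata TSV with at least `sample_id`; typical columns
#'   are `subject_id`, `group`, `isotype`, `timepoint`, `is_mock`,
#'   `replicate_of`.
#' @return Metadata tibble.
#' @export
read_metadata <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(m)) {
    stop("metadata must contain a sample_id column", call. = FALSE)
  }
  if ("is_mock" %in% names(m)) m$is_mock <- as.logical(m$is_mock)
  m
}

#' Check that counts and metadata describe the same samples
#' @param counts Wide count tibble.
#' @param meta Metadata tibble.
#' @return Invisibly `TRUE`; errors naming offending samples otherwise.
#' @export
validate_counts_meta <- function(counts, meta) {
  cs <- setdiff(names(counts), "clone_id")
  extra <- setdiff(cs, meta$sample_id)
  missing <- setdiff(meta$sample_id, cs)
  if (length(extra) || length(missing)) {
    stop("counts/metadata sample mismatch; in counts only: ",
         paste(utils::head(extra, 5), collapse = ", "),
         "; in metadata only: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Export a homology graph as edge-list TSV and GraphML
#' @param graph igraph object from [build_homology_graph()].
#' @param out_prefix Path prefix; writes `<prefix>.edges.tsv` and
#'   `<prefix>.graphml`.
#' @return The two paths, invisibly.
#' @export
write_homology_graph <- function(graph, out_prefix) {
  el <- igraph::as_edgelist(graph)
  tsv <- paste0(out_prefix, ".edges.tsv")
  gml <- paste0(out_prefix, ".graphml")
  readr::write_tsv(tibble::tibble(from = el[, 1], to = el[, 2]), tsv)
  igraph::write_graph(graph, gml, format = "graphml")
  invisible(c(tsv, gml))
}

#' Run the full analysis pipeline on a count table
#'
#' counts -> mock model -> enrichment -> hits -> prevalence/organism
#' filters -> homology graph -> per-sample breadth -> group comparison,
#' writing every stage's output plus a manifest (parameters, package
#' version, MD5 of each written file) under `out_dir`. Re-running with
#' identical inputs reproduces the outputs byte for byte.
#'
#' @param counts Wide count tibble.
#' @param meta Sample metadata with `sample_id` and logical `is_mock`;
#'   `group`/`isotype` drive the comparison stage.
#' @param annotation Clone annotation (`clone_id`, `organism`, `aa_seq`).
#' @param out_dir Output directory.
#' @param min_count,max_p,min_fc Hit thresholds (defaults 100, 0.001, 5).
#' @param min_samples,min_peptides Prevalence and organism filter
#'   thresholds (defaults 3 and 5).
#' @param homology_k Shared k-mer length for the homology graph
#'   (default 7).
#' @param organism Organism restriction for the breadth stage (default
#'   `"wheat"`; `NULL` for all).
#' @return List with every stage's objects, invisibly; files under
#'   `out_dir`.
#' @export
run_pipeline <- function(counts, meta, annotation, out_dir,
                         min_count = 100, max_p = 0.001, min_fc = 5,
                         min_samples = 3, min_peptides = 5,
                         homology_k = 7L, organism = "wheat") {
  stopifnot(min_count > 0, max_p > 0, min_fc > 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  validate_counts_meta(counts, meta)
  mock_ids <- meta$sample_id[meta$is_mock]
  sample_ids <- meta$sample_id[!meta$is_mock]
  message("fitting mock model on ", length(mock_ids), " mocks")
  mock <- fit_mock_model(counts, mock_ids)
  message("testing ", length(sample_ids), " samples; thresholds: count>=",
          min_count, ", p<=", max_p, ", fc>=", min_fc)
  enr <- test_enrichment(counts, mock, sample_ids)
  hits <- call_hits(enr, min_count, max_p, min_fc)
  recognised <- prevalence_filter(hits, min_samples)
  recognised <- organism_filter(recognised, annotation, min_peptides)
  message(length(recognised), " peptides pass prevalence (>=", min_samples,
          " samples) and organism (>=", min_peptides, " peptides) filters")
  hit_any <- hits$clone_ids[rowSums(hits$hit) > 0]
  graph_ids <- union(recognised, hit_any)
  pep <- annotation[annotation$clone_id %in% graph_ids,
                    c("clone_id", "aa_seq")]
  graph <- build_homology_graph(pep, k = homology_k)
  btab <- sample_breadth(hits, graph, annotation, organism, meta)
  comparison <- NULL
  grp <- btab[!is.na(btab$group) & btab$group != "mock" &
                is.na(btab$replicate_of) &
                (is.na(btab$timepoint) | btab$timepoint == "t0"), ]
  if ("isotype" %in% names(grp)) {
    comparison <- grp |>
      dplyr::group_by(.data$isotype) |>
      dplyr::group_modify(function(d, key) {
        if (length(unique(d$group)) >= 2 && all(table(d$group) >= 2))
          compare_groups(d, .data$breadth, .data$group)
        else tibble::tibble()
      }) |>
      dplyr::ungroup()
  }
  # write stage outputs
  files <- c(
    p_values = "p_values.tsv", fold_change = "fold_change.tsv",
    hits = "hits.tsv", recognised = "recognised_peptides.tsv",
    breadth = "breadth.tsv")
  mat_tbl <- function(m) tibble::as_tibble(cbind(
    tibble::tibble(clone_id = rownames(m)), tibble::as_tibble(m)))
  readr::write_tsv(mat_tbl(enr$p_value), file.path(out_dir, files["p_values"]))
  readr::write_tsv(mat_tbl(enr$fold_change),
                   file.path(out_dir, files["fold_change"]))
  readr::write_tsv(mat_tbl(hits$values), file.path(out_dir, files["hits"]))
  readr::write_tsv(tibble::tibble(clone_id = recognised),
                   file.path(out_dir, files["recognised"]))
  readr::write_tsv(btab, file.path(out_dir, files["breadth"]))
  if (!is.null(comparison) && nrow(comparison)) {
    files <- c(files, comparison = "group_comparison.tsv")
    readr::write_tsv(comparison, file.path(out_dir, "group_comparison.tsv"))
  }
  write_homology_graph(graph, file.path(out_dir, "homology"))
  files <- c(files, edges = "homology.edges.tsv", graphml = "homology.graphml")
  paths <- file.path(out_dir, files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("allerscan")),
    parameters = list(min_count = min_count, max_p = max_p, min_fc = min_fc,
                      min_samples = min_samples, min_peptides = min_peptides,
                      homology_k = as.integer(homology_k),
                      organism = organism),
    n_clones = nrow(counts), n_mocks = length(mock_ids),
    n_samples = length(sample_ids),
    outputs = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                      basename(paths)))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(mock_model = mock, enrichment = enr, hits = hits,
                 recognised = recognised, graph = graph, breadth = btab,
                 comparison = comparison, manifest = manifest))
}
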