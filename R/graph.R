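#' Build the peptide sequence-homology graph
#'
#' Peptides are nodes; two peptides are linked when they share at least
#' one identical substring of length `k` (default 7, a minimal linear
#' epitope). Edges are found through a k-mer index rather than all-pairs
#' alignment, so construction is near-linear in total sequence length.
#'
#' @param peptides Tibble with `clone_id` and `aa_seq` columns.
#' @param k Shared-substring length defining homology (default 7).
#' @return An undirected simple [igraph::igraph] whose vertex names are
#'   clone ids, with graph attribute `k`.
#' @export
build_homology_graph <- function(peptides, k = 7L) {
  peptides <- tibble::as_tibble(peptides)
  stopifnot(k >= 1, all(nchar(peptides$aa_seq) > 0))
  if (anyDuplicated(peptides$clone_id)) {
    stop("duplicate peptide ids", call. = FALSE)
  }
  n <- nrow(peptides)
  kmer_sets <- lapply(peptides$aa_seq, function(s) {
    L <- nchar(s)
    if (L < k) character(0)
    else unique(substring(s, 1:(L - k + 1), k:L))
  })
  idx <- rep(seq_len(n), lengths(kmer_sets))
  buckets <- split(idx, unlist(kmer_sets))
  edges <- unique(do.call(rbind, lapply(buckets, function(b) {
    if (length(b) < 2) return(NULL)
    t(utils::combn(sort(b), 2))
  })))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- peptides$clone_id
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, t(edges))
  }
  g <- igraph::simplify(g)
  g$k <- as.integer(k)
  g
}

#' Repertoire breadth: greedy maximal independent vertex set
#'
#' The breadth of a sample's response is the size of a maximal
#' independent vertex set of its reactive peptides in the homology graph:
#' a count of reactivities that share no sequence homology with one
#' another. The set is built greedily — repeatedly take the
#' lowest-degree remaining reactive peptide (ties broken
#' lexicographically by id), then delete it and its neighbours — which is
#' deterministic and guarantees maximality (every excluded reactive
#' peptide is adjacent to a member).
#'
#' @param graph Homology graph from [build_homology_graph()].
#' @param reactive_ids Character vector of reactive peptide ids (must be
#'   vertices of `graph`).
#' @return List with `breadth` (integer) and `members` (character vector
#'   of the independent set).
#' @export
breadth <- function(graph, reactive_ids) {
  reactive_ids <- unique(as.character(reactive_ids))
  unknown <- setdiff(reactive_ids, igraph::V(graph)$name)
  if (length(unknown)) {
    stop("reactive ids not in graph: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (length(reactive_ids) == 0) {
    return(list(breadth = 0L, members = character(0)))
  }
  sub <- igraph::induced_subgraph(graph, reactive_ids)
  adj <- lapply(igraph::adjacent_vertices(sub, igraph::V(sub)),
                function(v) igraph::V(sub)$name[as.integer(v)])
  names(adj) <- igraph::V(sub)$name
  alive <- sort(names(adj))
  members <- character(0)
  while (length(alive)) {
    # alive is kept sorted, so which.min takes the lexicographically
    # smallest id among minimum-degree nodes
    d <- vapply(alive, function(v) sum(adj[[v]] %in% alive), integer(1))
    pick <- alive[which.min(d)]
    members <- c(members, pick)
    alive <- setdiff(alive, c(pick, adj[[pick]]))
  }
  list(breadth = length(members), members = sort(members))
}

#' Per-sample repertoire breadth table
#'
#' Applies [breadth()] to every sample of a hit matrix, optionally
#' restricting the reactive set to peptides of one organism.
#'
#' @param hits An `allerscan_hits` object.
#' @param graph Homology graph covering the hit peptides.
#' @param annotation Clone annotation (`clone_id`, `organism`); required
#'   when `organism` is given.
#' @param organism Optional organism filter (e.g. `"wheat"`).
#' @param meta Optional sample metadata joined onto the result.
#' @return Tibble (`sample_id`, `n_reactive`, `breadth`, plus metadata).
#' @export
sample_breadth <- function(hits, graph, annotation = NULL, organism = NULL,
                           meta = NULL) {
  stopifnot(inherits(hits, "allerscan_hits"))
  keep <- hits$clone_ids
  if (!is.null(organism)) {
    if (is.null(annotation)) stop("annotation required for organism filter",
                                  call. = FALSE)
    keep <- annotation$clone_id[annotation$organism %in% organism]
  }
  res <- purrr::map_dfr(hits$sample_ids, function(s) {
    reactive <- intersect(hits$clone_ids[hits$hit[, s]], keep)
    b <- breadth(graph, reactive)
    tibble::tibble(sample_id = s, n_reactive = length(reactive),
                   breadth = b$breadth)
  })
  if (!is.null(meta)) res <- dplyr::left_join(res, meta, by = "sample_id")
  res
}

#' Epitope clusters: connected components of the reactive subgraph
#'
#' @inheritParams breadth
#' @return List with `components` (list of character vectors, sorted by
#'   size descending then by first member id; components of size >= 2)
#'   and `singletons` (peptides with no homology link in the reactive
#'   set).
#' @export
epitope_clusters <- function(graph, reactive_ids) {
  reactive_ids <- unique(as.character(reactive_ids))
  if (length(reactive_ids) == 0) {
    return(list(components = list(), singletons = character(0)))
  }
  sub <- igraph::induced_subgraph(graph, reactive_ids)
  comp <- igraph::components(sub)
  groups <- split(igraph::V(sub)$name, comp$membership)
  groups <- lapply(groups, sort)
  sizes <- lengths(groups)
  ord <- order(-sizes, vapply(groups, `[`, character(1), 1))
  groups <- groups[ord]
  sizes <- sizes[ord]
  list(components = unname(groups[sizes >= 2]),
       singletons = sort(unlist(groups[sizes == 1], use.names = FALSE)))
}

#' Consensus motif of an epitope cluster
#'
#' Anchors the cluster's peptides on their most frequent shared k-mer and
#' tabulates per-column residue frequencies over the anchored window plus
#' flanks — a position-frequency matrix suitable for sequence-logo
#' rendering.
#'
#' @param peptides Tibble (`clone_id`, `aa_seq`) of one cluster.
#' @param anchor_k Anchor k-mer length (default 7).
#' @param flank Columns added on each side of the anchor (default 5).
#' @return A matrix (residues x positions) whose columns sum to 1, with
#'   attributes `anchor` (the k-mer) and `n_anchored`. If no k-mer is
#'   shared by all members, the largest anchorable subset is used and a
#'   warning is raised.
#' @export
consensus_motif <- function(peptides, anchor_k = 7L, flank = 5L) {
  peptides <- tibble::as_tibble(peptides)
  stopifnot(nrow(peptides) >= 1)
  kmers <- lapply(peptides$aa_seq, function(s) {
    L <- nchar(s)
    if (L < anchor_k) character(0)
    else unique(substring(s, 1:(L - anchor_k + 1), anchor_k:L))
  })
  tab <- table(unlist(kmers))
  if (length(tab) == 0) stop("peptides shorter than anchor_k", call. = FALSE)
  best <- max(tab)
  anchor <- sort(names(tab)[tab == best])[1]
  if (best < nrow(peptides)) {
    warning("no k-mer shared by all ", nrow(peptides),
            " peptides; anchoring the ", best, " that share '", anchor, "'",
            call. = FALSE)
  }
  anchored <- peptides[vapply(kmers, function(k) anchor %in% k, logical(1)), ]
  offsets <- regexpr(anchor, anchored$aa_seq, fixed = TRUE)
  width <- anchor_k + 2L * flank
  cols <- lapply(seq_len(width), function(j) {
    pos <- as.integer(offsets) - flank + j - 1L
    ch <- substr(anchored$aa_seq, pos, pos)
    ch[pos < 1] <- ""
    ch[ch != ""]
  })
  residues <- sort(unique(unlist(cols)))
  pfm <- vapply(cols, function(ch) {
    out <- stats::setNames(numeric(length(residues)), residues)
    if (length(ch)) {
      t <- table(ch) / length(ch)
      out[names(t)] <- as.numeric(t)
    }
    out
  }, numeric(length(residues)))
  rownames(pfm) <- residues
  colnames(pfm) <- seq_len(width) - flank - 1L
  structure(pfm, anchor = anchor, n_anchored = nrow(anchored))
}
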