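#' Read an allergen protein FASTA
#'
#' Headers following the `ID|organism|group` convention are split into the
#' three annotation fields; headers without pipes fall back to using the
#' first whitespace-delimited token as `protein_id` with missing organism
#' and group. Wrapped lines and CRLF line endings are handled by the
#' underlying Biostrings parser.
#'
#' @param path Path to a protein FASTA file.
#' @return A tibble with columns `protein_id`, `organism`, `group`,
#'   `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("no sequences in ", path, call. = FALSE)
  headers <- names(aa)
  parts <- strsplit(headers, "|", fixed = TRUE)
  tibble::tibble(
    protein_id = vapply(parts, function(p) {
      strsplit(trimws(p[[1]]), "\\s+")[[1]][1]
    }, character(1)),
    organism = vapply(parts, function(p) {
      if (length(p) >= 2) trimws(p[[2]]) else NA_character_
    }, character(1)),
    group = vapply(parts, function(p) {
      if (length(p) >= 3) trimws(p[[3]]) else NA_character_
    }, character(1)),
    sequence = unname(toupper(as.character(aa)))
  )
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Run the full library design step
#'
#' Tiles a protein table, builds oligos, and writes the standard design
#' outputs: oligo FASTA, insert FASTA, a tab-separated clone annotation
#' table and a YAML design report with per-protein and per-organism tile
#' counts. Outputs are byte-identical for identical inputs.
#'
#' @param proteins Protein tibble (see [read_protein_fasta()]).
#' @param out_dir Output directory (created if needed).
#' @inheritParams tile_proteins
#' @inheritParams build_oligos
#' @return The annotated oligo tibble, invisibly; files are written under
#'   `out_dir`.
#' @export
design_library <- function(proteins, out_dir, tile_len = 56L, step = 28L,
                           adapter5 = "AGGAATTCCGCTGCGT",
                           adapter3 = "GCCTCGAGAAGCTTCA",
                           codon_table = ecoli_codon_table(),
                           forbidden_motifs = default_forbidden_motifs()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tiles <- tile_proteins(proteins, tile_len = tile_len, step = step)
  oligos <- build_oligos(tiles, adapter5, adapter3, codon_table,
                         forbidden_motifs)
  write_fasta(stats::setNames(oligos$full_oligo_nt, oligos$tile_id),
              file.path(out_dir, "oligos.fasta"), "DNA")
  write_fasta(stats::setNames(oligos$insert_nt, oligos$tile_id),
              file.path(out_dir, "inserts.fasta"), "DNA")
  ann <- dplyr::select(oligos, "tile_id", "protein_id",
                       dplyr::any_of(c("organism", "group")),
                       "start", "end", "aa_seq", "insert_nt")
  readr::write_tsv(ann, file.path(out_dir, "annotation.tsv"))
  report <- list(
    n_proteins = length(unique(tiles$protein_id)),
    n_tiles = nrow(tiles),
    tile_len = as.integer(tile_len),
    step = as.integer(step),
    tiles_per_protein = as.list(table(tiles$protein_id)),
    tiles_per_organism = if ("organism" %in% names(tiles) &&
                             !all(is.na(tiles$organism)))
      as.list(table(tiles$organism)) else NULL
  )
  yaml::write_yaml(report, file.path(out_dir, "design_report.yaml"))
  invisible(oligos)
}
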