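#' Tile a protein sequence into overlapping peptides
#'
#' Slices an amino-acid sequence into fixed-length windows advancing by
#' `step` residues. The final window is anchored to the C-terminus (its
#' start is `L - tile_len`), so the last pair of tiles may overlap by more
#' than `tile_len - step`. Proteins shorter than `tile_len` yield a single
#' tile covering the whole sequence.
#'
#' Coordinates are 0-based half-open: a tile covers `[start, end)`.
#'
#' @param sequence Amino-acid string (standard 20 letters plus `X`).
#' @param protein_id Identifier used to construct tile ids
#'   (`proteinID_start_end`).
#' @param tile_len Tile length in residues; default 56.
#' @param step Offset between consecutive tile starts; default 28, giving
#'   28-residue overlaps between neighbours.
#' @return A tibble with columns `tile_id`, `protein_id`, `start`, `end`,
#'   `aa_seq`, one row per tile, sorted by `start`.
#' @examples
#' tile_protein(strrep("A", 100), "P1")
#' @export
tile_protein <- function(sequence, protein_id = "protein", tile_len = 56L,
                         step = 28L) {
  stopifnot(tile_len > step, step > 0)
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  if (is.na(L) || L == 0) {
    stop("empty protein sequence for '", protein_id, "'", call. = FALSE)
  }
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", sequence)) {
    stop("sequence for '", protein_id,
         "' contains letters outside the amino-acid alphabet", call. = FALSE)
  }
  if (L < tile_len) {
    starts <- 0L
    ends <- L
  } else {
    starts <- seq.int(0L, by = step, length.out = 1L + (L - tile_len) %/% step)
    # anchor the final tile so the C-terminus is always covered
    if (starts[length(starts)] + tile_len < L) {
      starts <- c(starts, L - tile_len)
    } else {
      starts[length(starts)] <- L - tile_len
    }
    starts <- sort(unique(starts))
    ends <- starts + tile_len
  }
  tibble::tibble(
    tile_id = paste(protein_id, starts, ends, sep = "_"),
    protein_id = protein_id,
    start = as.integer(starts),
    end = as.integer(ends),
    aa_seq = substring(sequence, starts + 1L, ends)
  )
}

#' Tile every protein of a library design table
#'
#' Data-frame-first wrapper around [tile_protein()]: applies the tiling to
#' each row of a protein table and carries organism annotations through to
#' the tile (clone) level.
#'
#' @param proteins A data frame with columns `protein_id`, `sequence`, and
#'   optionally `organism` and `group` (as produced by
#'   [read_protein_fasta()]).
#' @inheritParams tile_protein
#' @return A tibble of tiles with provenance columns (`tile_id`,
#'   `protein_id`, `organism`, `group`, `start`, `end`, `aa_seq`).
#' @export
tile_proteins <- function(proteins, tile_len = 56L, step = 28L) {
  proteins <- tibble::as_tibble(proteins)
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$protein_id)) {
    stop("protein_id values must be unique within a design run", call. = FALSE)
  }
  if (!"organism" %in% names(proteins)) proteins$organism <- NA_character_
  if (!"group" %in% names(proteins)) proteins$group <- NA_character_
  tiles <- purrr::pmap(
    list(proteins$sequence, proteins$protein_id),
    function(seq, id) tile_protein(seq, id, tile_len = tile_len, step = step)
  )
  dplyr::bind_rows(tiles) |>
    dplyr::left_join(
      dplyr::select(proteins, "protein_id", "organism", "group"),
      by = "protein_id"
    ) |>
    dplyr::relocate("organism", "group", .after = "protein_id")
}
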