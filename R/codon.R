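#' Ranked E. coli codon table
#'
#' Codons for each amino acid ordered by usage frequency in highly
#' expressed Escherichia coli genes; rank 1 is the preferred codon used by
#' [reverse_translate()], later ranks are fallbacks when a preferred codon
#' would create a forbidden restriction motif.
#'
#' @return Named list mapping one-letter amino-acid codes to character
#'   vectors of codons in decreasing order of preference.
#' @export
ecoli_codon_table <- function() {
  list(
    A = c("GCG", "GCC", "GCA", "GCT"),
    R = c("CGT", "CGC", "CGG", "CGA", "AGA", "AGG"),
    N = c("AAC", "AAT"),
    D = c("GAT", "GAC"),
    C = c("TGC", "TGT"),
    Q = c("CAG", "CAA"),
    E = c("GAA", "GAG"),
    G = c("GGC", "GGT", "GGG", "GGA"),
    H = c("CAT", "CAC"),
    I = c("ATT", "ATC", "ATA"),
    L = c("CTG", "TTA", "TTG", "CTC", "CTT", "CTA"),
    K = c("AAA", "AAG"),
    M = "ATG",
    F = c("TTT", "TTC"),
    P = c("CCG", "CCA", "CCT", "CCC"),
    S = c("AGC", "TCT", "TCC", "AGT", "TCG", "TCA"),
    T = c("ACC", "ACG", "ACT", "ACA"),
    W = "TGG",
    Y = c("TAT", "TAC"),
    V = c("GTG", "GTT", "GTC", "GTA")
  )
}

#' Default forbidden motifs: the cloning enzyme recognition sites
#' (EcoRI, HindIII) that must not occur inside an insert.
#' @export
default_forbidden_motifs <- function() c("GAATTC", "AAGCTT")

#' Reverse-translate a peptide into codon-optimised DNA
#'
#' Deterministic reverse translation: each residue gets its rank-1 codon;
#' if a forbidden motif appears in the resulting DNA, the codon at the
#' leftmost position overlapping the motif is bumped to its next-ranked
#' alternative, scanning from the 5' end until the sequence is clean.
#'
#' @param aa_seq Amino-acid string.
#' @param codon_table Ranked codon list, default [ecoli_codon_table()].
#' @param forbidden_motifs Character vector of DNA motifs that must not
#'   occur as substrings of the output; default
#'   [default_forbidden_motifs()].
#' @return A DNA string of length `3 * nchar(aa_seq)` whose in-frame
#'   translation reproduces `aa_seq`.
#' @examples
#' reverse_translate("MKV")
#' @export
reverse_translate <- function(aa_seq, codon_table = ecoli_codon_table(),
                              forbidden_motifs = default_forbidden_motifs()) {
  aa_seq <- toupper(as.character(aa_seq))
  if (is.na(aa_seq) || nchar(aa_seq) == 0) {
    stop("empty peptide sequence", call. = FALSE)
  }
  residues <- strsplit(aa_seq, "", fixed = TRUE)[[1]]
  missing <- setdiff(unique(residues), names(codon_table))
  if (length(missing)) {
    stop("no codons defined for residue(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ranks <- rep(1L, length(residues))
  n_ranks <- vapply(codon_table[residues], length, integer(1))
  build <- function() paste(
    vapply(seq_along(residues),
           function(i) codon_table[[residues[i]]][ranks[i]], character(1)),
    collapse = ""
  )
  nt <- build()
  max_iter <- 20L * length(residues)
  for (iter in seq_len(max_iter)) {
    hit_pos <- Inf
    hit_len <- 0L
    for (m in forbidden_motifs) {
      p <- regexpr(m, nt, fixed = TRUE)
      if (p > 0 && p < hit_pos) {
        hit_pos <- as.integer(p)
        hit_len <- nchar(m)
      }
    }
    if (!is.finite(hit_pos)) return(nt)
    # codon indices (1-based) overlapping the motif span
    involved <- unique(((hit_pos - 1L):(hit_pos + hit_len - 2L)) %/% 3L + 1L)
    involved <- involved[involved >= 1L & involved <= length(residues)]
    bumpable <- involved[ranks[involved] < n_ranks[involved]]
    if (!length(bumpable)) {
      stop("cannot remove forbidden motif at position ", hit_pos,
           " in reverse translation of '", aa_seq, "'", call. = FALSE)
    }
    i <- bumpable[1L]
    ranks[i] <- ranks[i] + 1L
    # residues downstream of the bump restart at their preferred codon
    later <- involved[involved > i]
    ranks[later] <- 1L
    nt <- build()
  }
  stop("motif elimination did not converge for '", aa_seq, "'", call. = FALSE)
}

#' Translate DNA in frame 0 to amino acids
#'
#' @param nt_seq DNA string with length a multiple of 3.
#' @return Amino-acid string.
#' @export
translate_dna <- function(nt_seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(nt_seq),
                                     no.init.codon = TRUE))
}

#' Build synthesis-ready oligonucleotides for a tile table
#'
#' Reverse-translates every tile and flanks the insert with cloning
#' adapters, producing the full-length oligo and an annotation table in
#' one pass. With 56-residue tiles and 16-nt adapters the full oligo is
#' the classic 200-mer (16 + 168 + 16).
#'
#' @param tiles Tile tibble from [tile_proteins()] (columns `tile_id`,
#'   `protein_id`, `start`, `end`, `aa_seq`, optionally `organism`).
#' @param adapter5,adapter3 DNA adapter strings ligated 5' and 3' of the
#'   insert.
#' @inheritParams reverse_translate
#' @return The input tibble with added columns `insert_nt` and
#'   `full_oligo_nt`.
#' @export
build_oligos <- function(tiles,
                         adapter5 = "AGGAATTCCGCTGCGT",
                         adapter3 = "GCCTCGAGAAGCTTCA",
                         codon_table = ecoli_codon_table(),
                         forbidden_motifs = default_forbidden_motifs()) {
  tiles <- tibble::as_tibble(tiles)
  if (nrow(tiles) == 0) {
    return(dplyr::mutate(tiles, insert_nt = character(0),
                         full_oligo_nt = character(0)))
  }
  stopifnot(all(c("tile_id", "aa_seq") %in% names(tiles)))
  if (!grepl("^[ACGT]*$", adapter5) || !grepl("^[ACGT]*$", adapter3)) {
    stop("adapters must be plain DNA strings", call. = FALSE)
  }
  inserts <- vapply(seq_len(nrow(tiles)), function(i) {
    tryCatch(
      reverse_translate(tiles$aa_seq[i], codon_table, forbidden_motifs),
      error = function(e) stop("tile '", tiles$tile_id[i], "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }, character(1))
  dplyr::mutate(tiles,
                insert_nt = inserts,
                full_oligo_nt = paste0(adapter5, inserts, adapter3))
}
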