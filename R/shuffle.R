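# k-mer-preserving shuffling and seed-collision screening.
#
# Mock-sequence generation relies on shuffles that preserve the exact k-mer
# counts of the input: k = 1 is a uniform random permutation of the letters;
# k = 2 is the Altschul-Erickson random-Euler-path shuffle, which preserves
# every dinucleotide count (and therefore mononucleotide counts) as well as
# the first and last letters. Both draw from R's RNG, so results are
# reproducible under set.seed().

#' Shuffle a sequence preserving k-mer counts
#'
#' @param seq RNA string.
#' @param k 1 (mononucleotide permutation) or 2 (Altschul-Erickson
#'   dinucleotide-preserving Euler-path shuffle).
#' @return A shuffled string with identical k-mer counts.
#' @export
shuffle_kmer <- function(seq, k = 1L) {
  assert_rna(seq, allow_n = TRUE)
  if (!k %in% c(1L, 2L)) stop("k must be 1 or 2", call. = FALSE)
  if (nchar(seq) < k) stop("sequence shorter than k", call. = FALSE)
  if (k == 1L) {
    paste(sample(chars(seq)), collapse = "")
  } else {
    dinuc_shuffle_cpp(seq)
  }
}

#' Index of seed windows of a miRNA catalog
#'
#' Collects the 6-mers at positions 2-7 and 3-8 of every catalog miRNA, for
#' screening shuffled (mock) miRNAs against real seed sequences.
#'
#' @param catalog Data frame with a `sequence` column (a miRNA catalog).
#' @return A `seed_window_index`: list with character sets `w2_7`, `w3_8`.
#' @export
seed_window_index <- function(catalog) {
  seqs <- catalog$sequence
  if (length(seqs) > 0 && any(nchar(seqs) < 8))
    stop("catalog contains sequences shorter than 8 nt", call. = FALSE)
  structure(list(w2_7 = unique(substr(seqs, 2, 7)),
                 w3_8 = unique(substr(seqs, 3, 8))),
            class = "seed_window_index")
}

#' Does a candidate miRNA collide with real seed windows?
#'
#' True when the candidate's positions 2-7 match any catalog window 2-7, or
#' its positions 3-8 match any catalog window 3-8 (1-based inclusive).
#'
#' @param candidate RNA string of length >= 8.
#' @param index A `seed_window_index`.
#' @return Logical scalar.
#' @export
seed_collides <- function(candidate, index) {
  if (nchar(candidate) < 8)
    stop("candidate shorter than 8 nt", call. = FALSE)
  substr(candidate, 2, 7) %in% index$w2_7 ||
    substr(candidate, 3, 8) %in% index$w3_8
}
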