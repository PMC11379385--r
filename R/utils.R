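# shared helpers: sequence checks, reverse complement, seeded evaluation


assert_rna <- function(seq, allow_n = TRUE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty string", call. = FALSE)
  pat <- if (allow_n) "^[ACGUTN]+$" else "^[ACGUT]+$"
  if (!grepl(pat, seq))
    stop(what, " contains characters outside {A,C,G,U", if (allow_n) ",N", "}",
         call. = FALSE)
  invisible(seq)
}

#' Reverse complement of an RNA string
#'
#' @param seq RNA string over A/C/G/U (N maps to N).
#' @return The reverse complement, 5' to 3'.
#' @export
rna_revcomp <- function(seq) {
  assert_rna(seq)
  chartr("ACGUN", "UGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# random sequence over the RNA alphabet with given base probabilities
random_rna <- function(len, probs = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  paste(sample(RNA_BASES, len, replace = TRUE, prob = probs), collapse = "")
}

chars <- function(seq) strsplit(seq, "")[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
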