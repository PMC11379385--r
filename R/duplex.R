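# Duplex computation and the seed/density validity scheme.
#
# A duplex is the antiparallel base-pairing pattern between a miRNA and a
# target sequence: miRNA positions (1-based from the 5' end) strictly
# increase while their target partners strictly decrease, every pair is
# Watson-Crick (A:U, G:C) or wobble (G:U), and the minimum free energy (MFE)
# is non-positive whenever at least one pair exists. Duplexes are classified
# by seed type -- canonical (exact, contiguous Watson-Crick pairing across
# miRNA window 2-7 or 3-8), non-canonical (G:U allowed plus at most one
# bulged or mismatched nucleotide in a window), or other -- and by
# base-pairing density (low < 11 bp, medium 11-16 bp, high > 16 bp).
# Canonical and non-canonical duplexes are collectively "valid"; every
# dataset emitted by the generation methods is restricted to valid records.

#' Built-in hybridization duplex engine
#'
#' A deterministic gap-affine antiparallel alignment engine with a
#' stacking-bonus energy model (see `duplex_energy_params()`), implemented in
#' C++. `N` is unpairable. This is the package default engine: it supports
#' fast batch scanning, which the generation methods rely on.
#'
#' @return A `duplex_engine` object with elements `name`, `align(mirna,
#'   target)` and `scan(mirnas, targets, max_tail)`.
#' @export
duplex_engine_dp <- function() {
  structure(list(
    name = "hybrid-dp",
    align = function(mirna, target) {
      d <- duplex_align_cpp(mirna, target)
      if (is.null(d) || length(d) == 0) NULL else d
    },
    scan = function(mirnas, targets, max_tail = -1L) {
      duplex_scan_cpp(as.character(mirnas), as.character(targets),
                      as.integer(max_tail))
    }
  ), class = "duplex_engine")
}

#' RNAduplex (ViennaRNA) adapter engine
#'
#' Wraps the `RNAduplex` command-line tool when it is installed. Input pairs
#' are streamed through one process invocation; the reported interstrand
#' structure is converted to the package's pair-map representation.
#'
#' @param path Path to the RNAduplex executable.
#' @return A `duplex_engine`, or an error if the executable is missing.
#' @export
duplex_engine_rnaduplex <- function(path = "RNAduplex") {
  if (Sys.which(path) == "")
    stop("RNAduplex executable not found on PATH", call. = FALSE)
  align_many <- function(mirnas, targets) {
    inp <- paste0(mirnas, "\n", targets, collapse = "\n")
    out <- system2(path, c("--noLP"), input = inp, stdout = TRUE, stderr = FALSE)
    out <- out[grepl("&", out, fixed = TRUE)]
    if (length(out) != length(mirnas))
      stop("RNAduplex returned ", length(out), " results for ",
           length(mirnas), " inputs", call. = FALSE)
    lapply(seq_along(out), function(i) {
      parse_rnaduplex_line(out[i])
    })
  }
  structure(list(
    name = "rnaduplex",
    align = function(mirna, target) align_many(mirna, target)[[1]],
    scan = function(mirnas, targets, max_tail = -1L) {
      scan_generic(mirnas, targets, align_many(mirnas, targets), max_tail)
    }
  ), class = "duplex_engine")
}

# "(((&)))  2,4 : 3,5 (-5.40)" -> pair map in duplex coordinates
parse_rnaduplex_line <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  struct <- toks[1]
  halves <- strsplit(struct, "&", fixed = TRUE)[[1]]
  if (length(halves) != 2) return(NULL)
  sp1 <- as.integer(strsplit(toks[2], ",")[[1]])
  sp2 <- as.integer(strsplit(toks[4], ",")[[1]])
  mfe <- as.numeric(sub("^\\(", "", sub("\\)$", "", toks[length(toks)])))
  l <- chars(halves[1]); r <- chars(halves[2])
  mi <- sp1[1] + which(l == "(") - 1L
  tj <- sp2[1] + which(r == ")") - 1L
  if (length(mi) == 0 || length(mi) != length(tj)) return(NULL)
  # left brackets pair with right brackets in LIFO order across the '&'
  list(mirna_pos = mi, target_pos = rev(tj), mfe = mfe)
}

# annotated scan for engines without a native batch path
scan_generic <- function(mirnas, targets, aligned, max_tail = -1L) {
  n <- length(aligned)
  out <- data.frame(found = logical(n), valid = logical(n),
                    seed_code = integer(n), n_pairs = integer(n),
                    tail = integer(n), mfe = NA_real_,
                    site_start = NA_integer_, site_end = NA_integer_,
                    pairs = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    d <- aligned[[i]]
    if (is.null(d) || length(d) == 0) {
      out$tail[i] <- nchar(mirnas[i])
      next
    }
    st <- seed_window_stats_cpp(mirnas[i], targets[i],
                                d$mirna_pos, d$target_pos)
    out$found[i] <- TRUE
    out$seed_code[i] <- st$seed_code
    out$n_pairs[i] <- length(d$mirna_pos)
    out$tail[i] <- nchar(mirnas[i]) - max(d$mirna_pos)
    out$mfe[i] <- d$mfe
    out$site_start[i] <- min(d$target_pos) - 1L
    out$site_end[i] <- max(d$target_pos)
    ok <- st$seed_code %in% c(1L, 2L)
    if (ok && max_tail >= 0 && out$tail[i] > max_tail) ok <- FALSE
    out$valid[i] <- ok
    if (ok) out$pairs[i] <- paste(d$mirna_pos, d$target_pos,
                                  sep = ":", collapse = ";")
  }
  out
}

#' Energy parameters of the built-in duplex engine
#'
#' @return Named list: pair energies (`pair_gc`, `pair_au`, `pair_gu`),
#'   stacking bonus (`stack`) and affine loop penalties (`gap_open`,
#'   `gap_ext`), in the engine's kcal/mol-like units.
#' @export
duplex_energy_params <- function() duplex_energy_params_cpp()

#' Compute the minimum-free-energy duplex of a miRNA and a target
#'
#' @param mirna_seq,target_seq RNA strings over A/C/G/U/N (T tolerated).
#' @param engine A `duplex_engine`; default the built-in DP engine.
#' @return A `mti_duplex` object (list with `pairs` data frame of
#'   `mirna_pos`/`target_pos`, `mfe`, `site_span` 0-based half-open on the
#'   target, `seed_type`, `density_class`), or `NULL` when no legal pair
#'   exists.
#' @export
compute_duplex <- function(mirna_seq, target_seq, engine = duplex_engine_dp()) {
  assert_rna(mirna_seq, what = "mirna_seq")
  assert_rna(target_seq, what = "target_seq")
  d <- engine$align(mirna_seq, target_seq)
  if (is.null(d) || length(d) == 0) return(NULL)
  dup <- structure(list(
    pairs = data.frame(mirna_pos = d$mirna_pos, target_pos = d$target_pos),
    mfe = d$mfe,
    site_span = c(min(d$target_pos) - 1L, max(d$target_pos)),
    seed_type = NA_character_, density_class = NA_character_
  ), class = "mti_duplex")
  dup$seed_type <- if (nchar(mirna_seq) >= 9)
    classify_seed(dup, mirna_seq, target_seq) else "other"
  dup$density_class <- classify_density(dup)
  dup
}

#' Classify the seed type of a duplex
#'
#' Canonical: one of the miRNA windows 2-7 or 3-8 is fully Watson-Crick
#' paired to consecutive target positions. Non-canonical: not canonical, but
#' one window's pairs are Watson-Crick or G:U with at most one bulged or
#' mismatched nucleotide. Otherwise: other.
#'
#' @param duplex A `mti_duplex`.
#' @param mirna_seq,target_seq The sequences the duplex was computed on.
#' @return One of `"canonical"`, `"non_canonical"`, `"other"`.
#' @export
classify_seed <- function(duplex, mirna_seq, target_seq) {
  if (nchar(mirna_seq) < 9)
    stop("miRNA shorter than 9 nt: seed windows 2-7 and 3-8 undefined",
         call. = FALSE)
  st <- seed_window_stats_cpp(mirna_seq, target_seq,
                              duplex$pairs$mirna_pos, duplex$pairs$target_pos)
  c("other", "non_canonical", "canonical")[st$seed_code + 1L]
}

#' Classify base-pairing density of a duplex
#'
#' @param duplex A `mti_duplex`.
#' @return `"low"` (< 11 paired miRNA positions), `"medium"` (11-16) or
#'   `"high"` (> 16). G:U pairs count towards density.
#' @export
classify_density <- function(duplex) {
  n <- nrow(duplex$pairs)
  if (n < 11) "low" else if (n <= 16) "medium" else "high"
}

density_class_from_count <- function(n) {
  ifelse(n < 11, "low", ifelse(n <= 16, "medium", "high"))
}

seed_type_from_code <- function(code) {
  c("other", "non_canonical", "canonical")[code + 1L]
}

#' Is a duplex a valid interaction?
#'
#' Valid means the seed type is canonical or non-canonical; `NULL` (no
#' duplex) is invalid.
#'
#' @param duplex A `mti_duplex` or `NULL`.
#' @return Logical scalar.
#' @export
is_valid_interaction <- function(duplex) {
  if (is.null(duplex)) return(FALSE)
  duplex$seed_type %in% c("canonical", "non_canonical")
}

#' Length of the unpaired miRNA 3' tail
#'
#' @param duplex A `mti_duplex`.
#' @param mirna_len miRNA length in nt.
#' @return `mirna_len` minus the largest paired miRNA position; by convention
#'   `mirna_len` for an empty pair list.
#' @export
unpaired_tail_length <- function(duplex, mirna_len) {
  if (is.null(duplex) || nrow(duplex$pairs) == 0) return(mirna_len)
  mirna_len - max(duplex$pairs$mirna_pos)
}

# serialize / parse the pair map ("1:70;2:69;...")
pairs_to_string <- function(pairs) {
  paste(pairs$mirna_pos, pairs$target_pos, sep = ":", collapse = ";")
}

parse_pairs_string <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(mirna_pos = integer(0), target_pos = integer(0)))
  m <- matrix(as.integer(unlist(strsplit(strsplit(s, ";", fixed = TRUE)[[1]],
                                         ":", fixed = TRUE))),
              ncol = 2, byrow = TRUE)
  data.frame(mirna_pos = m[, 1], target_pos = m[, 2])
}
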