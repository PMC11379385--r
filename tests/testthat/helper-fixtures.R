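# shared fixtures: a small memoized synthetic world and hand-built duplexes

small_world <- local({
  w <- NULL
  function() {
    if (is.null(w))
      w <<- gen_world(list(n_mirnas = 60, n_utrs = 150, n_interactions = 250,
                           clip_extra_mrnas = 30, tarbase_rows = 400),
                      seed = 42)
    w
  }
})

small_positives <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- process_positives(small_world()$positives)
    p
  }
})

# duplex object from explicit pair vectors (bypasses the engine)
fake_duplex <- function(mirna_pos, target_pos, mfe = -10) {
  span <- if (length(target_pos) == 0) c(NA_integer_, NA_integer_) else
    c(min(target_pos) - 1L, max(target_pos))
  structure(list(pairs = data.frame(mirna_pos = mirna_pos,
                                    target_pos = target_pos),
                 mfe = mfe,
                 site_span = span,
                 seed_type = NA_character_, density_class = NA_character_),
            class = "mti_duplex")
}

# brute-force enumeration of nested secondary structures (pair sets) with
# minimum hairpin loop 3; used as the accessibility oracle on tiny inputs
enumerate_structures <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  pairable <- function(i, j) {
    a <- v[i]; b <- v[j]
    (j - i > 3) && (paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG"))
  }
  rec <- function(i, j) {
    if (j <= i) return(list(list()))
    out <- lapply(rec(i, j - 1), identity)  # j unpaired
    for (k in i:(j - 1)) {
      if (pairable(k, j)) {
        left <- rec(i, k - 1)
        inner <- rec(k + 1, j - 1)
        for (L in left) for (I in inner)
          out[[length(out) + 1]] <- c(L, I, list(c(k, j)))
      }
    }
    out
  }
  rec(1, nchar(seq))
}

# exact region-unpaired probability under the counting model (weight 2/pair)
oracle_unpaired_prob <- function(seq, a, b, w_pair = 2) {
  structs <- enumerate_structures(seq)
  wts <- vapply(structs, function(s) w_pair^length(s), numeric(1))
  unp <- vapply(structs, function(s) {
    if (length(s) == 0) return(TRUE)
    paired <- unlist(s)
    !any(paired >= a & paired <= b)
  }, logical(1))
  sum(wts[unp]) / sum(wts)
}

# all contiguous helices of a (miRNA, target) pair under the engine's
# energy model; used as the MFE upper-bound oracle
oracle_best_helix <- function(mirna, target) {
  par <- duplex_energy_params()
  pe <- function(a, b) {
    k <- paste0(min(a, b), max(a, b))
    switch(k, CG = par$pair_gc, AU = par$pair_au, GU = par$pair_gu, NA_real_)
  }
  x <- strsplit(mirna, "")[[1]]; y <- strsplit(target, "")[[1]]
  best <- 0
  for (i in seq_along(x)) for (j in seq_along(y)) {
    e <- 0; L <- 0
    while (i + L <= length(x) && j - L >= 1) {
      p <- pe(x[i + L], y[j - L])
      if (is.na(p)) break
      e <- e + p + if (L > 0) par$stack else 0
      L <- L + 1
      best <- min(best, e)
    }
  }
  best
}
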