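# Independent brute-force oracles used to cross-check the production
# implementations.  These deliberately share no code with the package:
# character-by-character scans, recursive permutation generation, and
# plain-loop statistics.

# -- counting ---------------------------------------------------------------

# Occurrences of motif in sequence by explicit character comparison.
oracle_count <- function(motif, sequence) {
  mk <- strsplit(motif, "")[[1]]
  sk <- strsplit(sequence, "")[[1]]
  if (length(sk) < length(mk)) return(0L)
  hits <- 0L
  for (i in 1:(length(sk) - length(mk) + 1L)) {
    if (all(sk[i:(i + length(mk) - 1L)] == mk)) hits <- hits + 1L
  }
  hits
}

oracle_presence_frequency <- function(motif, sequences) {
  counts <- vapply(sequences, oracle_count, integer(1), motif = motif)
  c(presence = sum(counts > 0L), frequency = sum(counts))
}

# -- kappa ------------------------------------------------------------------

# All unique permutations of a label vector, recursively.
oracle_perms <- function(labels) {
  if (length(labels) <= 1L) return(list(labels))
  out <- list()
  for (u in unique(labels)) {
    rest <- labels[-match(u, labels)]
    for (p in oracle_perms(rest)) out[[length(out) + 1L]] <- c(u, p)
  }
  out
}

oracle_sigma <- function(lab) {
  fp <- mean(lab == "+"); fm <- mean(lab == "-")
  if (fp + fm == 0) 0 else (fp - fm)^2 / (fp + fm)
}

oracle_delta <- function(lab, g) {
  sg <- oracle_sigma(lab)
  devs <- numeric(0)
  for (i in 1:(length(lab) - g + 1L))
    devs <- c(devs, (oracle_sigma(lab[i:(i + g - 1L)]) - sg)^2)
  mean(devs)
}

# kappa by full enumeration of the charge-label multiset.
oracle_kappa <- function(sequence, blob_sizes = c(5L, 6L)) {
  ch <- strsplit(sequence, "")[[1]]
  lab <- ifelse(ch %in% c("K", "R"), "+", ifelse(ch %in% c("D", "E"), "-", "0"))
  if (!any(lab != "0")) return(NA_real_)
  usable <- blob_sizes[blob_sizes <= length(lab)]
  if (!length(usable)) return(NA_real_)
  perms <- unique(oracle_perms(lab))
  ratios <- c()
  for (g in usable) {
    d <- oracle_delta(lab, g)
    dmax <- max(vapply(perms, oracle_delta, numeric(1), g = g))
    if (dmax > 0) ratios <- c(ratios, d / dmax)
  }
  if (!length(ratios)) return(NA_real_)
  mean(ratios)
}

# -- superstrings -----------------------------------------------------------

# Every way to append y to x with any valid suffix-prefix overlap
# (not just the maximal one), plus containment.
oracle_merges <- function(x, y) {
  outs <- character(0)
  if (grepl(y, x, fixed = TRUE)) outs <- c(outs, x)
  for (o in 0:min(nchar(x), nchar(y))) {
    if (o == 0 || substr(x, nchar(x) - o + 1L, nchar(x)) == substr(y, 1L, o))
      outs <- c(outs, paste0(x, substr(y, o + 1L, nchar(y))))
  }
  unique(outs)
}

# Minimal superstring length over all orderings and all overlap choices.
oracle_min_superstring <- function(motifs) {
  best <- Inf
  idx <- seq_along(motifs)
  for (a in idx) for (b in idx[-a]) {
    c3 <- setdiff(idx, c(a, b))
    for (s1 in oracle_merges(motifs[a], motifs[b]))
      for (s2 in oracle_merges(s1, motifs[c3])) {
        if (all(vapply(motifs, grepl, logical(1), x = s2, fixed = TRUE)))
          best <- min(best, nchar(s2))
      }
  }
  best
}

# -- shared fixtures --------------------------------------------------------

random_peptide <- function(n, alphabet = c("G", "S", "E", "K", "A", "P")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

motifs129_path <- function() {
  system.file("extdata", "motifs129_synthetic.tsv", package = "phasemotif")
}
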