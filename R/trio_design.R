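# Trio co-occurrence scoring and minimalistic peptide design.  Trios of
# selected motifs are scored by how often and how symmetrically they
# coexist within DPRs (final score FS on a 0-100 scale); top trios are
# merged into minimal superstrings under 20 residues and filtered by the
# disorder sequence parameters.

#' Motif-by-region presence matrix
#'
#' Logical matrix (motifs x regions), TRUE where the motif occurs at
#' least once in the region.  Built from one k-mer pass per motif length,
#' so it scales to hundreds of regions and motifs.
#'
#' @param motifs Character vector of motifs.
#' @param region_seqs Character vector of DPR sequences.
#' @return Logical matrix with motif rownames.
#' @export
motif_region_matrix <- function(motifs, region_seqs) {
  motifs <- unique(motifs)
  M <- matrix(FALSE, length(motifs), length(region_seqs),
              dimnames = list(motifs, NULL))
  for (k in sort(unique(nchar(motifs)))) {
    mk <- motifs[nchar(motifs) == k]
    tab <- kmer_count_table(region_seqs, seq_along(region_seqs), k, k)
    tab <- tab[tab$motif %in% mk]
    if (nrow(tab)) M[cbind(match(tab$motif, motifs), tab$seq_id)] <- TRUE
  }
  M
}

#' Number of regions containing both motifs
#'
#' Symmetric in its motif arguments; a motif paired with itself returns
#' its own presence.
#'
#' @param motif_a,motif_b Motif strings.
#' @param region_seqs DPR sequences.
#' @export
pair_cooccurrence <- function(motif_a, motif_b, region_seqs) {
  in_a <- vapply(region_seqs, function(s) count_motif_occurrences(motif_a, s) > 0,
                 logical(1), USE.NAMES = FALSE)
  in_b <- vapply(region_seqs, function(s) count_motif_occurrences(motif_b, s) > 0,
                 logical(1), USE.NAMES = FALSE)
  sum(in_a & in_b)
}

trio_score_fields <- function(a, b, c, n_ab, n_ac, n_bc, n_abc, pres) {
  pairs <- c(n_ab, n_ac, n_bc)
  coverage <- if (min(pres) == 0) 0 else n_abc / min(pres)
  symmetry <- if (max(pairs) == 0) 0 else min(pairs) / max(pairs)
  data.frame(motif_a = a, motif_b = b, motif_c = c,
             n_ab = n_ab, n_ac = n_ac, n_bc = n_bc, n_abc = n_abc,
             vs_sum = sum(pairs), coverage = coverage, symmetry = symmetry,
             fs = 100 * (0.5 * coverage + 0.5 * symmetry),
             stringsAsFactors = FALSE)
}

#' Score one motif trio by co-occurrence across DPRs
#'
#' Pairwise counts n_ab, n_ac, n_bc (regions containing both members),
#' the triple count n_abc, coverage = n_abc divided by the smallest
#' single-motif presence, symmetry = min/max of the pairwise counts, and
#' FS = 100 (0.5 coverage + 0.5 symmetry).  FS is 100 exactly when all
#' three motifs occur in every region each of them touches, in equal
#' pairwise proportions, and 0 when no region contains any pair.
#' Invariant under permutation of the three motifs (stored in
#' lexicographic order).
#'
#' @param motif_a,motif_b,motif_c Three distinct motifs.
#' @param region_seqs DPR sequences.
#' @return One-row data frame (see [score_all_trios()] for the columns).
#' @export
score_trio <- function(motif_a, motif_b, motif_c, region_seqs) {
  trio <- c(motif_a, motif_b, motif_c)
  if (anyDuplicated(trio)) stop("trio motifs must be distinct", call. = FALSE)
  trio <- sort(trio)
  M <- motif_region_matrix(trio, region_seqs)
  P <- M + 0
  pres <- rowSums(P)
  C2 <- tcrossprod(P)
  n_abc <- sum(M[1, ] & M[2, ] & M[3, ])
  trio_score_fields(trio[1], trio[2], trio[3],
                    C2[1, 2], C2[1, 3], C2[2, 3], n_abc, pres)
}

#' Score every trio of a motif set
#'
#' Enumerates all C(m, 3) trios using the presence matrix: pairwise
#' counts come from one cross-product, triple counts from one masked
#' cross-product per leading motif, so 129 motifs x ~700 regions stays
#' desk-scale.  Output is ranked FS descending with the canonical
#' (lexicographic) trio order breaking ties.
#'
#' @param motifs Character vector of at least three distinct motifs.
#' @param region_seqs DPR sequences.
#' @return Data frame, one row per trio: `motif_a/b/c` (lexicographic),
#'   pairwise counts, `n_abc`, `vs_sum`, `coverage`, `symmetry`, `fs`.
#' @export
score_all_trios <- function(motifs, region_seqs) {
  motifs <- sort(unique(motifs))
  m <- length(motifs)
  if (m < 3L) stop("need at least 3 motifs", call. = FALSE)
  P <- motif_region_matrix(motifs, region_seqs) + 0
  pres <- rowSums(P)
  C2 <- tcrossprod(P)
  blocks <- vector("list", m - 2L)
  for (a in seq_len(m - 2L)) {
    rest <- (a + 1L):m
    Ma <- P[rest, , drop = FALSE] * rep(P[a, ], each = length(rest))
    T3 <- tcrossprod(Ma)
    ut <- which(upper.tri(T3), arr.ind = TRUE)
    b <- rest[ut[, 1L]]
    cc <- rest[ut[, 2L]]
    blocks[[a]] <- data.table::data.table(
      ia = a, ib = b, ic = cc,
      n_ab = C2[cbind(a, b)], n_ac = C2[cbind(a, cc)], n_bc = C2[cbind(b, cc)],
      n_abc = T3[ut])
  }
  res <- data.table::rbindlist(blocks)
  pair_min <- pmin(res$n_ab, res$n_ac, res$n_bc)
  pair_max <- pmax(res$n_ab, res$n_ac, res$n_bc)
  pres_min <- pmin(pres[res$ia], pres[res$ib], pres[res$ic])
  coverage <- ifelse(pres_min == 0, 0, res$n_abc / pres_min)
  symmetry <- ifelse(pair_max == 0, 0, pair_min / pair_max)
  out <- data.frame(motif_a = motifs[res$ia], motif_b = motifs[res$ib],
                    motif_c = motifs[res$ic],
                    n_ab = res$n_ab, n_ac = res$n_ac, n_bc = res$n_bc,
                    n_abc = res$n_abc, vs_sum = res$n_ab + res$n_ac + res$n_bc,
                    coverage = coverage, symmetry = symmetry,
                    fs = 100 * (0.5 * coverage + 0.5 * symmetry),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fs, out$motif_a, out$motif_b, out$motif_c), ]
  rownames(out) <- NULL
  out
}

#' Merge two strings with their maximal suffix-prefix overlap
#'
#' Returns `x` unchanged when `y` is already contained in it.
#'
#' @param x,y Strings.
#' @export
merge_overlap <- function(x, y) {
  if (grepl(y, x, fixed = TRUE)) return(x)
  for (o in seq(min(nchar(x), nchar(y)) - 1L, 0L)) {
    if (o == 0L ||
        substr(x, nchar(x) - o + 1L, nchar(x)) == substr(y, 1L, o))
      return(paste0(x, substr(y, o + 1L, nchar(y))))
  }
  paste0(x, y)
}

#' Build merged peptide candidates from a motif trio
#'
#' Motifs that are substrings of another trio member are dropped first
#' (redundancy elimination); every ordering of the survivors is merged
#' left-to-right with maximal suffix-prefix overlap; duplicate sequences
#' are deduplicated and candidates of 20 residues or more discarded.
#' Because the surviving motifs are substring-free, the shortest
#' candidate over all orderings is the true minimal superstring of the
#' trio.
#'
#' @param trio Character vector of 3 motifs (3-6 residues each).
#' @return Data frame `sequence`, `ordering` (motifs joined with `+` in
#'   merge order), `length`, `is_minimal`, sorted by length then
#'   sequence.
#' @export
build_peptides <- function(trio) {
  stopifnot(length(trio) == 3L)
  keep <- vapply(seq_along(trio), function(i) {
    others <- trio[-i]
    !any(others != trio[i] & grepl(trio[i], others, fixed = TRUE))
  }, logical(1))
  motifs <- unique(trio[keep])
  perms <- all_permutations(length(motifs))
  rows <- lapply(seq_len(nrow(perms)), function(r) {
    ord <- motifs[perms[r, ]]
    merged <- Reduce(merge_overlap, ord)
    data.frame(sequence = merged, ordering = paste(ord, collapse = "+"),
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, rows)
  cand <- cand[!duplicated(cand$sequence), , drop = FALSE]
  cand$length <- nchar(cand$sequence)
  cand <- cand[cand$length < 20L, , drop = FALSE]
  cand <- cand[order(cand$length, cand$sequence), , drop = FALSE]
  cand$is_minimal <- cand$length == min(cand$length)
  rownames(cand) <- NULL
  cand
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}

#' Default designed-peptide filter ranges
#'
#' Closed intervals for the five sequence parameters used to annotate
#' designed peptides.  These defaults are this package's own editable
#' configuration (broadly shaped on published human-IDR distributions),
#' not values printed in any reference: FCR \[0, 0.7\], NCPR
#' \[-0.35, 0.35\], kappa \[0, 0.5\], mean hydropathy \[0, 4.8\] on the
#' 0-9 scale, disorder fraction \[0.55, 1\].
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
default_filter_ranges <- function() {
  list(fcr = c(0, 0.7),
       ncpr = c(-0.35, 0.35),
       kappa = c(0, 0.5),
       mean_hydropathy = c(0, 4.8),
       disorder_fraction = c(0.55, 1))
}

#' Annotate designed-peptide candidates with parameters and filter verdicts
#'
#' Computes the five sequence parameters for each candidate and marks
#' `passes_filter` TRUE iff every parameter lies inside its closed
#' interval; failing parameter names are listed.  Nothing is removed.
#'
#' @param candidates Data frame with a `sequence` column
#'   ([build_peptides()]).
#' @param ranges Parameter ranges ([default_filter_ranges()]).
#' @param kappa_na Policy for kappa not-applicable: `"pass"` (default)
#'   or `"fail"`.
#' @return `candidates` plus parameter columns, `passes_filter`,
#'   `filter_failures` (comma-joined names, "" when none).
#' @export
filter_candidates <- function(candidates, ranges = default_filter_ranges(),
                              kappa_na = c("pass", "fail")) {
  kappa_na <- match.arg(kappa_na)
  bad <- vapply(ranges, function(r) r[1] > r[2], logical(1))
  if (any(bad))
    stop("malformed range (lo > hi): ", paste(names(ranges)[bad], collapse = ", "),
         call. = FALSE)
  params <- compute_all(candidates$sequence)
  out <- cbind(candidates, params[setdiff(names(params), "sequence")])
  failures <- vapply(seq_len(nrow(out)), function(i) {
    fails <- character()
    for (p in names(ranges)) {
      v <- out[[p]][i]
      if (is.na(v)) {
        if (p == "kappa" && kappa_na == "pass") next
        fails <- c(fails, p)
      } else if (v < ranges[[p]][1] || v > ranges[[p]][2]) {
        fails <- c(fails, p)
      }
    }
    paste(fails, collapse = ",")
  }, character(1))
  out$passes_filter <- failures == ""
  out$filter_failures <- failures
  out
}

#' Rank designed peptides
#'
#' Passing candidates first, then FS descending, length ascending,
#' sequence lexicographic -- fully deterministic.
#'
#' @param peptides Data frame with `passes_filter`, `fs`, `length`,
#'   `sequence` columns.
#' @export
rank_designs <- function(peptides) {
  ord <- order(!peptides$passes_filter, -peptides$fs, peptides$length,
               peptides$sequence)
  out <- peptides[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Design peptides from top-scoring trios
#'
#' For each of the top `top_k` trios of `trio_scores`, builds merged
#' candidates, attaches the trio's FS, computes parameters and filter
#' verdicts, and ranks the pooled designs.
#'
#' @param trio_scores Output of [score_all_trios()].
#' @param top_k Number of leading trios to design from.
#' @inheritParams filter_candidates
#' @return Ranked data frame of designed peptides with `trio`, `fs`,
#'   parameters and verdicts.
#' @export
design_peptides <- function(trio_scores, top_k = 10L,
                            ranges = default_filter_ranges(),
                            kappa_na = c("pass", "fail")) {
  kappa_na <- match.arg(kappa_na)
  top <- utils::head(trio_scores, top_k)
  rows <- lapply(seq_len(nrow(top)), function(i) {
    trio <- unlist(top[i, c("motif_a", "motif_b", "motif_c")], use.names = FALSE)
    cand <- build_peptides(trio)
    if (!nrow(cand)) return(NULL)
    cand$trio <- paste(trio, collapse = "+")
    cand$fs <- top$fs[i]
    cand
  })
  pooled <- do.call(rbind, rows)
  if (is.null(pooled)) stop("no candidates under 20 residues", call. = FALSE)
  rank_designs(filter_candidates(pooled, ranges, kappa_na))
}
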