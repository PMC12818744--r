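# Motif discovery: enumerate every 3-6-residue substring of the positive
# DPRs, count presence (distinct regions with >= 1 occurrence) and
# frequency (total occurrences, overlapping matches counted) in positives
# and in the negative universe, convert to normalized fold scores and the
# combined score CF = 0.5 PF + 0.5 FF, select CF >= threshold, and
# characterize the selected set.

#' Count occurrences of a motif in one sequence (overlaps counted)
#'
#' Step-1 sliding window, so "QQQQ" occurs twice in "QQQQQ".
#'
#' @param motif Motif string.
#' @param sequence Sequence string.
#' @return Integer count.
#' @export
count_motif_occurrences <- function(motif, sequence) {
  k <- nchar(motif)
  n <- nchar(sequence)
  if (k < 1L) stop("motif must be non-empty", call. = FALSE)
  if (n < k) return(0L)
  starts <- seq_len(n - k + 1L)
  sum(substring(sequence, starts, starts + k - 1L) == motif)
}

#' Presence and frequency of a motif over a sequence set
#'
#' Presence = number of sequences containing the motif at least once;
#' frequency = total occurrences with overlapping matches counted.
#'
#' @param motif Motif string.
#' @param sequences Character vector of sequences (DPR subsequences or
#'   whole negative proteins).
#' @return Named integer vector `c(presence=, frequency=)`.
#' @export
count_presence_frequency <- function(motif, sequences) {
  counts <- vapply(sequences, count_motif_occurrences, integer(1),
                   motif = motif, USE.NAMES = FALSE)
  c(presence = sum(counts > 0L), frequency = sum(counts))
}

# data.table of (seq_id, motif, count) for all k-mers of the given sizes
# in all sequences; windows containing the sanitization sentinel are
# dropped.  This is the counting engine behind the universe-level tables.
kmer_count_table <- function(sequences, ids, k_min, k_max) {
  stopifnot(length(sequences) == length(ids))
  pieces <- list()
  for (k in k_min:k_max) {
    n <- nchar(sequences)
    keep <- which(n >= k)
    if (!length(keep)) next
    wins <- lapply(keep, function(i) {
      starts <- seq_len(n[i] - k + 1L)
      substring(sequences[i], starts, starts + k - 1L)
    })
    dt <- data.table::data.table(
      seq_id = rep(ids[keep], lengths(wins)),
      motif = unlist(wins, use.names = FALSE))
    dt <- dt[!grepl(AA_SENTINEL, dt$motif, fixed = TRUE)]
    pieces[[length(pieces) + 1L]] <- dt[, list(count = .N),
                                        by = c("seq_id", "motif")]
  }
  if (!length(pieces))
    return(data.table::data.table(seq_id = character(), motif = character(),
                                  count = integer()))
  data.table::rbindlist(pieces)
}

#' Enumerate candidate motifs from positive DPR sequences
#'
#' Exactly the distinct k-mers (k in `[k_min, k_max]`) occurring in at
#' least one DPR; sentinel-containing windows excluded.  Motifs seen only
#' in the negative universe are by construction never candidates.
#'
#' @param dpr_sequences Character vector of DPR subsequences.
#' @param k_min,k_max Motif length bounds (default 3 and 6).
#' @return Sorted character vector of candidate motifs.
#' @export
enumerate_candidates <- function(dpr_sequences, k_min = 3L, k_max = 6L) {
  if (k_min < 1L || k_max < k_min)
    stop("require 1 <= k_min <= k_max", call. = FALSE)
  tab <- kmer_count_table(dpr_sequences, seq_along(dpr_sequences), k_min, k_max)
  sort(unique(tab$motif))
}

# Universe-level presence/frequency for every candidate motif, computed
# via one k-mer aggregation pass rather than per-motif scans.
universe_counts <- function(candidates, sequences, k_min, k_max) {
  tab <- kmer_count_table(sequences, seq_along(sequences), k_min, k_max)
  agg <- tab[, list(presence = .N, frequency = sum(count)), by = "motif"]
  idx <- match(candidates, agg$motif)
  data.frame(motif = candidates,
             presence = ifelse(is.na(idx), 0L, agg$presence[idx]),
             frequency = ifelse(is.na(idx), 0L, agg$frequency[idx]),
             stringsAsFactors = FALSE)
}

#' Fold scores and combined score CF for candidate motifs
#'
#' Raw folds are positive/negative count ratios with the denominator
#' floored at 1 occurrence (motifs absent from the negatives keep a
#' finite, order-preserving fold; such rows are flagged).  PF and FF are
#' min-max normalizations of the raw folds over the candidate set being
#' scored, and CF = 0.5 PF + 0.5 FF.
#'
#' @param candidates Character vector of motifs.
#' @param pos_counts,neg_counts Data frames with columns `motif`,
#'   `presence`, `frequency` covering the candidates (see
#'   [count_presence_frequency()]); rows are matched by motif.
#' @return Data frame of motif statistics: counts in both universes, raw
#'   folds, `PF`, `FF`, `CF`, and `neg_floor` flags.
#' @export
compute_fold_scores <- function(candidates, pos_counts, neg_counts) {
  if (!length(candidates))
    return(data.frame(motif = character(), length = integer(),
                      presence_pos = integer(), frequency_pos = integer(),
                      presence_neg = integer(), frequency_neg = integer(),
                      pf_raw = numeric(), ff_raw = numeric(),
                      PF = numeric(), FF = numeric(), CF = numeric(),
                      neg_floor = logical(), stringsAsFactors = FALSE))
  ip <- match(candidates, pos_counts$motif)
  im <- match(candidates, neg_counts$motif)
  get0 <- function(v, i) ifelse(is.na(i), 0L, v[i])
  pp <- get0(pos_counts$presence, ip); fp <- get0(pos_counts$frequency, ip)
  pn <- get0(neg_counts$presence, im); fn <- get0(neg_counts$frequency, im)
  pf_raw <- pp / pmax(pn, 1L)
  ff_raw <- fp / pmax(fn, 1L)
  minmax <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) {
      message("degenerate fold range (all values equal); normalized to 0")
      return(rep(0, length(x)))
    }
    (x - rng[1]) / (rng[2] - rng[1])
  }
  PF <- minmax(pf_raw)
  FF <- minmax(ff_raw)
  data.frame(motif = candidates, length = nchar(candidates),
             presence_pos = pp, frequency_pos = fp,
             presence_neg = pn, frequency_neg = fn,
             pf_raw = pf_raw, ff_raw = ff_raw,
             PF = PF, FF = FF, CF = 0.5 * PF + 0.5 * FF,
             neg_floor = pn == 0L | fn == 0L,
             stringsAsFactors = FALSE)
}

#' Select motifs at or above a combined-score threshold
#'
#' Inclusive threshold (CF >= cf_threshold); output ordered CF
#' descending with lexicographic tie-break.
#'
#' @param stats Motif statistics ([compute_fold_scores()]).
#' @param cf_threshold Threshold in \[0,1\] (default 0.2).
#' @export
select_enriched <- function(stats, cf_threshold = 0.2) {
  if (cf_threshold < 0 || cf_threshold > 1)
    stop("cf_threshold must lie in [0,1]", call. = FALSE)
  kept <- stats[stats$CF >= cf_threshold, , drop = FALSE]
  kept <- kept[order(-kept$CF, kept$motif), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Fraction of motifs embedded within other motifs of the set
#'
#' A motif is embedded iff it is a proper substring of some other motif
#' in the set (e.g. QQQQ in QQQQQ, GRGG in GGRGG).  Embedded motifs are
#' reported, never removed.
#'
#' @param motifs Character vector of distinct motifs.
#' @return List with `fraction` (embedded share of the set) and
#'   `embeddings` (data frame `motif`, `host`, one row per containment).
#' @export
embedded_fraction <- function(motifs) {
  motifs <- unique(motifs)
  emb <- list()
  for (m in motifs) {
    hosts <- motifs[motifs != m & grepl(m, motifs, fixed = TRUE)]
    if (length(hosts))
      emb[[length(emb) + 1L]] <- data.frame(motif = m, host = hosts,
                                            stringsAsFactors = FALSE)
  }
  embeddings <- if (length(emb)) do.call(rbind, emb)
                else data.frame(motif = character(), host = character(),
                                stringsAsFactors = FALSE)
  list(fraction = length(unique(embeddings$motif)) / length(motifs),
       embeddings = embeddings)
}

#' Length distribution and amino-acid membership of a motif set
#'
#' Membership counts each motif once per residue type it contains,
#' regardless of copy number.
#'
#' @param motifs Non-empty character vector of motifs.
#' @return List with `length_distribution` (data frame `length`, `count`,
#'   `percent`) and `aa_membership` (data frame `residue`, `count`,
#'   `percent` over all 20 residues).
#' @export
motif_set_summary <- function(motifs) {
  motifs <- unique(motifs)
  if (!length(motifs)) stop("empty motif set", call. = FALSE)
  lens <- table(nchar(motifs))
  length_distribution <- data.frame(
    length = as.integer(names(lens)),
    count = as.integer(lens),
    percent = 100 * as.integer(lens) / length(motifs))
  member <- vapply(AA_ALPHABET, function(a)
    sum(grepl(a, motifs, fixed = TRUE)), integer(1))
  aa_membership <- data.frame(
    residue = AA_ALPHABET, count = unname(member),
    percent = 100 * unname(member) / length(motifs),
    stringsAsFactors = FALSE)
  list(length_distribution = length_distribution,
       aa_membership = aa_membership)
}

#' Per-region motif occurrence counts
#'
#' One row per (motif, region) pair with at least one occurrence; the
#' maximum single-region count per motif and the sum (= frequency) are
#' both derivable from the output.
#'
#' @param motifs Character vector of motifs.
#' @param regions Region table with `region_id` and `subsequence`
#'   columns, or a named character vector of region sequences.
#' @return Data frame `motif`, `region_id`, `count` (count >= 1).
#' @export
per_region_counts <- function(motifs, regions) {
  if (is.character(regions)) {
    seqs <- unname(regions)
    ids <- names(regions)
    if (is.null(ids)) ids <- as.character(seq_along(seqs))
  } else {
    seqs <- regions$subsequence
    ids <- regions$region_id
  }
  rows <- lapply(motifs, function(m) {
    counts <- vapply(seqs, count_motif_occurrences, integer(1), motif = m,
                     USE.NAMES = FALSE)
    keep <- counts > 0L
    if (!any(keep)) return(NULL)
    data.frame(motif = m, region_id = ids[keep], count = counts[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(motif = character(), region_id = character(),
                      count = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Full discovery pipeline over one positive DPR set
#'
#' Enumerates candidates in the DPRs, counts both universes, computes
#' fold scores, and (optionally) adds NODPR validation counts for the
#' selected motifs.
#'
#' @param dpr_sequences Positive DPR subsequences.
#' @param negative_sequences Whole negative-protein sequences (the
#'   negative universe).
#' @param k_min,k_max Motif length bounds.
#' @param cf_threshold Selection threshold on CF.
#' @param nodpr_sequences Optional NODPR subsequences; when given, the
#'   selected motifs gain `presence_nodpr`/`frequency_nodpr` columns.
#' @return List with `stats` (all candidates) and `selected` (CF >=
#'   threshold, ordered).
#' @export
discover_motifs <- function(dpr_sequences, negative_sequences,
                            k_min = 3L, k_max = 6L, cf_threshold = 0.2,
                            nodpr_sequences = NULL) {
  candidates <- enumerate_candidates(dpr_sequences, k_min, k_max)
  pos <- universe_counts(candidates, dpr_sequences, k_min, k_max)
  neg <- universe_counts(candidates, negative_sequences, k_min, k_max)
  stats <- compute_fold_scores(candidates, pos, neg)
  selected <- select_enriched(stats, cf_threshold)
  if (!is.null(nodpr_sequences) && nrow(selected)) {
    nod <- universe_counts(selected$motif, nodpr_sequences, k_min, k_max)
    selected$presence_nodpr <- nod$presence
    selected$frequency_nodpr <- nod$frequency
  }
  list(stats = stats, selected = selected)
}

#' Per-family motif discovery
#'
#' Reruns the discovery pipeline on each family's DPRs against the
#' unchanged negative universe; normalization is computed within each
#' family's own candidate set.
#'
#' @param records Protein records with `family` labels.
#' @param regions Region table with subsequences (DPRs are used).
#' @param negative_sequences Negative universe.
#' @inheritParams discover_motifs
#' @return Named list (family -> [discover_motifs()] result); families
#'   without DPRs are omitted with a warning.
#' @export
discover_per_family <- function(records, regions, negative_sequences,
                                k_min = 3L, k_max = 6L, cf_threshold = 0.2) {
  fams <- unique(records$family[!is.na(records$family)])
  out <- list()
  for (fam in fams) {
    ids <- records$id[!is.na(records$family) & records$family == fam]
    dprs <- regions$subsequence[regions$kind == "DPR" &
                                regions$protein_id %in% ids]
    if (!length(dprs)) {
      warning("family '", fam, "' has no DPRs; omitted")
      next
    }
    out[[fam]] <- discover_motifs(dprs, negative_sequences, k_min, k_max,
                                  cf_threshold)
  }
  out
}

#' Motifs unique to each family
#'
#' Set difference of each family's selected motifs against the union of
#' all other families' selections.
#'
#' @param per_family Result of [discover_per_family()].
#' @return Named list of character vectors.
#' @export
family_unique_motifs <- function(per_family) {
  sel <- lapply(per_family, function(x) x$selected$motif)
  lapply(stats::setNames(names(sel), names(sel)), function(fam)
    setdiff(sel[[fam]], unlist(sel[names(sel) != fam], use.names = FALSE)))
}
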