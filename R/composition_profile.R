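# Amino-acid frequency and residue-character profiling of full sequences,
# droplet-promoting regions (DPRs) and non-droplet-promoting regions
# (NODPRs), pooled and per protein family.

#' Default residue-character classes
#'
#' A partition of the 20-letter alphabet used for the class-level profile.
#' Histidine sits in the positively charged class by default; the
#' partition is an argument everywhere so alternatives (e.g. His among
#' aromatics) are one call away.
#'
#' @return Named list of character vectors partitioning [AA_ALPHABET].
#' @export
default_residue_classes <- function() {
  list(positive = c("K", "R", "H"),
       negative = c("D", "E"),
       aromatic = c("F", "W", "Y"),
       polar_uncharged = c("S", "T", "N", "Q", "C"),
       hydrophobic_aliphatic = c("A", "V", "L", "I", "M"),
       special = c("G", "P"))
}

#' Pooled amino-acid composition profile
#'
#' Exact residue tallies pooled across the given sequences; sentinel
#' residues (non-canonical) are excluded from counts and totals.
#'
#' @param seqs Character vector of sequences.
#' @param group_label Label carried on the profile (e.g. `"DPR/RNA-binding"`).
#' @param classes Residue-character partition ([default_residue_classes()]).
#' @return Object of class `composition_profile`: list with `group_label`,
#'   `counts` (named integer over the alphabet), `percentages`,
#'   `class_percentages`, `n_residues`.  With an empty pool the
#'   percentages are NA and `n_residues` is 0.
#' @export
profile_sequences <- function(seqs, group_label = "all",
                              classes = default_residue_classes()) {
  stopifnot(setequal(unlist(classes), AA_ALPHABET))
  ch <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  ch <- ch[ch %in% AA_ALPHABET]
  counts <- table(factor(ch, levels = AA_ALPHABET))
  counts <- stats::setNames(as.integer(counts), AA_ALPHABET)
  n <- sum(counts)
  pct <- if (n > 0) 100 * counts / n else stats::setNames(rep(NA_real_, 20), AA_ALPHABET)
  class_pct <- vapply(classes, function(res) sum(pct[res]), numeric(1))
  structure(list(group_label = group_label, counts = counts,
                 percentages = pct, class_percentages = class_pct,
                 n_residues = n),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("Composition profile:", x$group_label,
      sprintf("(%d residues)\n", x$n_residues))
  if (x$n_residues > 0) {
    top <- rank_top_residues(x, 5L)
    cat("  top residues:",
        paste(sprintf("%s (%.1f%%)", top$residue, top$percent), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Composition profiles per protein family
#'
#' @param records Protein records with `family` labels.
#' @param regions Region table with `subsequence` filled; required for
#'   `kind` `"DPR"`/`"NODPR"`, ignored for `"full"`.
#' @param kind Pool full sequences or one region kind.
#' @inheritParams profile_sequences
#' @return Named list of `composition_profile`s, one per family with at
#'   least one sequence of the requested kind (empty families are dropped
#'   with a warning).
#' @export
profile_by_family <- function(records, regions = NULL,
                              kind = c("full", "DPR", "NODPR"),
                              classes = default_residue_classes()) {
  kind <- match.arg(kind)
  fams <- unique(records$family[!is.na(records$family)])
  out <- list()
  for (fam in fams) {
    ids <- records$id[!is.na(records$family) & records$family == fam]
    seqs <- if (kind == "full") {
      records$sequence[records$id %in% ids]
    } else {
      if (is.null(regions) || is.null(regions$subsequence))
        stop("regions with subsequences required for kind = ", kind,
             call. = FALSE)
      regions$subsequence[regions$kind == kind & regions$protein_id %in% ids]
    }
    if (!length(seqs)) {
      warning("family '", fam, "' has no ", kind, " sequences; omitted")
      next
    }
    out[[fam]] <- profile_sequences(seqs, paste(kind, fam, sep = "/"), classes)
  }
  out
}

#' Top-k residues of a profile
#'
#' Descending by percentage, ties broken alphabetically; length is
#' clamped to the alphabet size.
#'
#' @param profile A `composition_profile`.
#' @param k Number of residues requested (> 0).
#' @return Data frame with columns `residue`, `percent`.
#' @export
rank_top_residues <- function(profile, k) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (profile$n_residues == 0) stop("profile is empty", call. = FALSE)
  ord <- order(-profile$percentages, names(profile$percentages))
  k <- min(k, length(ord))
  data.frame(residue = names(profile$percentages)[ord][seq_len(k)],
             percent = unname(profile$percentages[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' Write composition profiles as TSV
#'
#' One row per (group, residue); a companion file with suffix
#' `.classes.tsv` holds the residue-character class percentages.
#'
#' @param profiles A `composition_profile` or list thereof.
#' @param path Output TSV.
#' @export
write_composition_table <- function(profiles, path) {
  if (inherits(profiles, "composition_profile")) profiles <- list(profiles)
  res <- do.call(rbind, lapply(profiles, function(p)
    data.frame(group_label = p$group_label, residue = names(p$counts),
               count = unname(p$counts), percent = unname(p$percentages),
               stringsAsFactors = FALSE)))
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cls <- do.call(rbind, lapply(profiles, function(p)
    data.frame(group_label = p$group_label,
               class = names(p$class_percentages),
               percent = unname(p$class_percentages),
               stringsAsFactors = FALSE)))
  utils::write.table(cls, sub("\\.tsv$", ".classes.tsv", path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
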