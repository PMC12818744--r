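# Reading and writing the package's on-disk dialects: FASTA with key=value
# metadata tokens in the header, tab-separated region tables, and the motif
# statistics table.  Internal region coordinates are 1-based inclusive (the
# R / IRanges convention); readers translate from either common dialect.

#' Read protein records from FASTA
#'
#' Headers carry the accession as the first whitespace-delimited token;
#' any further `key=value` tokens are parsed into metadata.  Recognised
#' keys: `family` (one of RNA-binding, DNA-binding, chromatin-binding,
#' regulation, hydrolase, structure, none), `set` (positive/negative) and
#' `pdp` (droplet-promoting probability in \[0,1\], from an upstream
#' predictor such as FuzDrop -- never computed here).
#'
#' @param path FASTA file.
#' @param sanitize Replace non-canonical letters with the sentinel.
#' @return A data.frame with columns `id`, `sequence`, `family`,
#'   `source_set`, `pdp` (NA where a token was absent), one row per entry,
#'   file order preserved.
#' @export
read_fasta <- function(path, sanitize = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(empty_protein_records())
  }
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  seqs <- as.character(aa)
  meta <- parse_header_tokens(headers)
  if (sanitize) seqs <- sanitize_sequence(seqs)
  if (any(!nzchar(seqs)))
    stop("FASTA entry with empty sequence: ",
         paste(meta$id[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  data.frame(id = meta$id, sequence = unname(seqs), family = meta$family,
             source_set = meta$source_set, pdp = meta$pdp,
             stringsAsFactors = FALSE)
}

empty_protein_records <- function() {
  data.frame(id = character(), sequence = character(), family = character(),
             source_set = character(), pdp = numeric(),
             stringsAsFactors = FALSE)
}

parse_header_tokens <- function(headers) {
  toks <- strsplit(headers, "\\s+")
  id <- vapply(toks, `[[`, "", 1L)
  get_key <- function(tk, key) {
    hit <- grep(paste0("^", key, "="), tk, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[[1L]]) else NA_character_
  }
  family <- vapply(toks, get_key, "", key = "family")
  source_set <- vapply(toks, get_key, "", key = "set")
  pdp <- suppressWarnings(as.numeric(vapply(toks, get_key, "", key = "pdp")))
  known <- is.na(family) | family %in% FAMILY_LEVELS
  if (!all(known))
    stop("unknown family label(s): ",
         paste(unique(family[!known]), collapse = ", "), call. = FALSE)
  if (any(!is.na(pdp) & (pdp < 0 | pdp > 1)))
    stop("pdp outside [0,1] in FASTA header", call. = FALSE)
  list(id = id, family = family, source_set = source_set, pdp = pdp)
}

#' Write protein records to FASTA
#'
#' Inverse of [read_fasta()]: metadata rides in the header as `key=value`
#' tokens so a single file round-trips all fields.
#'
#' @param records Data frame as returned by [read_fasta()].
#' @param path Output file.
#' @export
write_fasta <- function(records, path) {
  headers <- records$id
  add <- function(h, key, val) {
    keep <- !is.na(val)
    h[keep] <- paste0(h[keep], " ", key, "=", val[keep])
    h
  }
  if (!is.null(records$family)) headers <- add(headers, "family", records$family)
  if (!is.null(records$source_set)) headers <- add(headers, "set", records$source_set)
  if (!is.null(records$pdp)) headers <- add(headers, "pdp", records$pdp)
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, path, width = 80L)
  invisible(path)
}

#' Read a region annotation table
#'
#' The TSV must carry columns `protein_id`, `start`, `end`, `kind`
#' (`DPR` or `NODPR`); `#`-prefixed lines are comments.  `convention`
#' declares the file's coordinate dialect; internally the package stores
#' 1-based inclusive coordinates.
#'
#' @param path TSV file.
#' @param convention `"one_inclusive"` (start and end both 1-based,
#'   inclusive) or `"zero_half_open"` (0-based start, exclusive end).
#' @return Data frame with columns `protein_id`, `start`, `end`, `kind`,
#'   `region_id` (`protein_id:start-end` in internal coordinates).
#' @export
read_regions <- function(path, convention = c("one_inclusive", "zero_half_open")) {
  convention <- match.arg(convention)
  if (!file.exists(path)) stop("region file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end", "kind")
  if (!all(need %in% names(tab)))
    stop("region table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (convention == "zero_half_open") {
    tab$start <- tab$start + 1L        # end is exclusive == 1-based inclusive
  }
  bad_kind <- !tab$kind %in% c("DPR", "NODPR")
  if (any(bad_kind))
    stop("unknown region kind: ", paste(unique(tab$kind[bad_kind]), collapse = ", "),
         call. = FALSE)
  if (any(tab$end < tab$start | tab$start < 1L))
    stop("invalid region interval (end < start or start < 1) after ",
         "coordinate conversion", call. = FALSE)
  tab$region_id <- paste0(tab$protein_id, ":", tab$start, "-", tab$end)
  tab[c("protein_id", "start", "end", "kind", "region_id")]
}

#' Write a region annotation table
#'
#' @param regions Data frame with `protein_id`, `start`, `end`, `kind`
#'   (internal 1-based inclusive coordinates).
#' @param path Output TSV.
#' @param convention Coordinate dialect to emit.
#' @export
write_regions <- function(regions, path,
                          convention = c("one_inclusive", "zero_half_open")) {
  convention <- match.arg(convention)
  out <- regions[c("protein_id", "start", "end", "kind")]
  if (convention == "zero_half_open") out$start <- out$start - 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract region subsequences from their parent proteins
#'
#' @param records Protein records ([read_fasta()]).
#' @param regions Region table ([read_regions()]).
#' @return `regions` with a `subsequence` column filled; DPR and NODPR
#'   sets remain separable via `kind`.
#' @export
extract_region_sequences <- function(records, regions) {
  idx <- match(regions$protein_id, records$id)
  if (anyNA(idx))
    stop("regions reference unknown protein(s): ",
         paste(unique(regions$protein_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  len <- nchar(records$sequence)[idx]
  oob <- regions$end > len
  if (any(oob))
    stop("region(s) out of bounds: ",
         paste(regions$region_id[oob], collapse = ", "), call. = FALSE)
  regions$subsequence <- substr(records$sequence[idx], regions$start, regions$end)
  regions
}

#' Select negative-set proteins by droplet-promoting probability
#'
#' Keeps exactly the records with `pdp` strictly below `threshold` (the
#' study's negative set used pDP < 20%); input order preserved.
#'
#' @param records Protein records.
#' @param threshold Probability in (0, 1].
#' @param missing What to do with records lacking a pdp value:
#'   `"skip"` (drop with a warning, default) or `"error"`.
#' @export
filter_by_pdp <- function(records, threshold = 0.2,
                          missing = c("skip", "error")) {
  missing <- match.arg(missing)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  no_pdp <- is.na(records$pdp)
  if (any(no_pdp)) {
    if (missing == "error")
      stop(sum(no_pdp), " record(s) lack a pdp value", call. = FALSE)
    warning(sum(no_pdp), " record(s) lack a pdp value; skipped")
  }
  records[!no_pdp & records$pdp < threshold, , drop = FALSE]
}

MOTIF_TABLE_COLS <- c("motif", "length", "presence_pos", "frequency_pos",
                      "presence_neg", "frequency_neg",
                      "presence_nodpr", "frequency_nodpr",
                      "pf_raw", "ff_raw", "PF", "FF", "CF")

#' Write a motif statistics table
#'
#' Deterministic ordering: CF descending, motif lexicographic on ties.
#' Columns absent from `stats` (e.g. NODPR counts when no NODPR set was
#' supplied) are written as NA.
#'
#' @param stats Motif statistics ([compute_fold_scores()]).
#' @param path Output TSV.
#' @export
write_motif_table <- function(stats, path) {
  for (col in MOTIF_TABLE_COLS)
    if (is.null(stats[[col]])) stats[[col]] <- rep(NA, nrow(stats))
  stats <- stats[order(-stats$CF, stats$motif), MOTIF_TABLE_COLS]
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif table
#'
#' Accepts either the full statistics table written by
#' [write_motif_table()] or a minimal list with at least a `motif` column
#' (one motif per row, `#` comments allowed).
#'
#' @param path TSV file.
#' @export
read_motif_table <- function(path) {
  if (!file.exists(path)) stop("motif table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"motif" %in% names(tab))
    stop("motif table must have a 'motif' column", call. = FALSE)
  tab$motif <- toupper(tab$motif)
  tab
}
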