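# Seedable synthetic protein databases: composition-biased positives with
# non-overlapping DPR/NODPR intervals, Leu-rich hydrophobic negatives, and
# motifs planted at controlled presence so every downstream stage is
# testable without external downloads.

#' Default per-residue composition tables
#'
#' Probability tables over the 20 canonical residues, each summing to 1.
#' `"dpr"` is Gly/Ser/Pro/Ala-rich (Gly 11.5%, Ser 11.7%, Pro 10.6%, Ala
#' 7.6%, Glu 6.4% -- the enrichment profile reported for droplet-promoting
#' regions); `"negative"` is Leu-rich (Leu 11.1%) in the way hydrophobic
#' non-phase-separating proteins are; `"nodpr"` is intermediate with a
#' hydrophobic lean.
#'
#' @param type Which table.
#' @return Named numeric vector over [AA_ALPHABET], summing to 1.
#' @export
default_composition <- function(type = c("dpr", "nodpr", "negative")) {
  type <- match.arg(type)
  tab <- switch(type,
    dpr = c(A = 0.076, C = 0.010, D = 0.045, E = 0.064, F = 0.025,
            G = 0.115, H = 0.020, I = 0.025, K = 0.050, L = 0.040,
            M = 0.015, N = 0.045, P = 0.106, Q = 0.060, R = 0.055,
            S = 0.117, T = 0.050, V = 0.035, W = 0.007, Y = 0.040),
    nodpr = c(A = 0.070, C = 0.020, D = 0.050, E = 0.060, F = 0.040,
              G = 0.060, H = 0.022, I = 0.055, K = 0.055, L = 0.090,
              M = 0.022, N = 0.040, P = 0.045, Q = 0.040, R = 0.048,
              S = 0.068, T = 0.053, V = 0.070, W = 0.012, Y = 0.030),
    negative = c(A = 0.066, C = 0.023, D = 0.047, E = 0.063, F = 0.040,
                 G = 0.052, H = 0.023, I = 0.055, K = 0.052, L = 0.111,
                 M = 0.023, N = 0.038, P = 0.050, Q = 0.040, R = 0.050,
                 S = 0.068, T = 0.052, V = 0.069, W = 0.013, Y = 0.033))
  tab / sum(tab)
}

#' Specification for one planted motif
#'
#' @param motif Motif string (3-6 canonical letters).
#' @param presence_fraction Fraction of target regions/proteins receiving
#'   at least one copy (rounded to a whole number of targets).
#' @param copies Integer copies per chosen region: a single value or a
#'   `c(lo, hi)` range sampled uniformly.
#' @param target `"positive_dpr"` (plant inside positive DPRs) or
#'   `"negative"` (plant anywhere in negative proteins).
#' @export
plant_spec <- function(motif, presence_fraction, copies = 1L,
                       target = c("positive_dpr", "negative")) {
  target <- match.arg(target)
  motif <- toupper(motif)
  if (nchar(motif) < 3L || nchar(motif) > 6L ||
      grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), motif))
    stop("motif must be 3-6 canonical residues", call. = FALSE)
  if (presence_fraction < 0 || presence_fraction > 1)
    stop("presence_fraction must lie in [0,1]", call. = FALSE)
  structure(list(motif = motif, presence_fraction = presence_fraction,
                 copies = as.integer(copies), target = target),
            class = "plant_spec")
}

check_composition <- function(tab, what) {
  if (!setequal(names(tab), AA_ALPHABET) || any(tab < 0) || any(tab > 1) ||
      abs(sum(tab) - 1) > 1e-9)
    stop(what, " must be a 20-entry probability table summing to 1",
         call. = FALSE)
  tab[AA_ALPHABET]
}

#' Configuration for the synthetic database generator
#'
#' Defaults mirror the curated study databases: 178 positives / 208
#' negatives, protein lengths 400-800 residues, DPR segments of mean
#' length 72.1 and NODPR segments of mean 90.2, 1-6 DPRs per positive.
#'
#' @param n_positive,n_negative Protein counts.
#' @param protein_length_range `c(lo, hi)` residues.
#' @param dpr_length_mean,nodpr_length_mean Mean region lengths.
#' @param dprs_per_protein_range `c(lo, hi)` DPR count per positive.
#' @param composition_dpr,composition_nodpr,composition_negative
#'   Residue probability tables ([default_composition()]).
#' @param planted_motifs List of [plant_spec()]s.
#' @param seed Integer seed; the generator consumes one private RNG
#'   stream in a fixed documented order, so equal configs give
#'   byte-identical databases.
#' @return Validated `generator_config` list.
#' @export
generator_config <- function(n_positive = 178L, n_negative = 208L,
                             protein_length_range = c(400L, 800L),
                             dpr_length_mean = 72.1,
                             nodpr_length_mean = 90.2,
                             dprs_per_protein_range = c(1L, 6L),
                             composition_dpr = default_composition("dpr"),
                             composition_nodpr = default_composition("nodpr"),
                             composition_negative = default_composition("negative"),
                             planted_motifs = list(),
                             seed = 1L) {
  stopifnot(n_positive >= 0, n_negative >= 0,
            length(protein_length_range) == 2,
            protein_length_range[1] > 0,
            protein_length_range[1] <= protein_length_range[2],
            dpr_length_mean > 10, nodpr_length_mean > 10,
            dprs_per_protein_range[1] >= 0,
            dprs_per_protein_range[1] <= dprs_per_protein_range[2])
  if (length(planted_motifs) && !all(vapply(planted_motifs, inherits,
                                            logical(1), "plant_spec")))
    stop("planted_motifs must be a list of plant_spec objects", call. = FALSE)
  structure(list(
    n_positive = as.integer(n_positive), n_negative = as.integer(n_negative),
    protein_length_range = as.integer(protein_length_range),
    dpr_length_mean = dpr_length_mean, nodpr_length_mean = nodpr_length_mean,
    dprs_per_protein_range = as.integer(dprs_per_protein_range),
    composition_dpr = check_composition(composition_dpr, "composition_dpr"),
    composition_nodpr = check_composition(composition_nodpr, "composition_nodpr"),
    composition_negative = check_composition(composition_negative,
                                             "composition_negative"),
    planted_motifs = planted_motifs, seed = as.integer(seed)),
    class = "generator_config")
}

# sample() without the scalar-first-argument trap.
resample <- function(x, size = 1L, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# Evaluate fn under a private RNG stream without disturbing the caller's.
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Draw an i.i.d. sequence from a composition table
#'
#' @param table Residue probability table.
#' @param length Number of residues (0 gives an empty string).
#' @return Sequence string.
#' @export
sample_composition <- function(table, length) {
  table <- check_composition(table, "table")
  if (length == 0L) return("")
  paste(sample(names(table), length, replace = TRUE, prob = table),
        collapse = "")
}

# Region lengths: geometric tail shifted to a minimum of 10 residues
# (heavy right tail, mimicking real IDR length distributions), truncated
# to at most half the protein.
draw_region_length <- function(mean_len, max_len) {
  len <- 10L + stats::rgeom(1L, 1 / (mean_len - 9))
  as.integer(max(10L, min(len, max_len)))
}

#' Generate a synthetic positive/negative protein database
#'
#' Positives interleave DPR and NODPR segments (drawn from their
#' respective composition tables) with composition_nodpr background;
#' negatives are whole-sequence draws from `composition_negative`.
#' Planted motifs overwrite a random window fully inside a target region
#' (never straddling a boundary), preserving all lengths.  Deterministic
#' given the config seed.
#'
#' @param config A [generator_config()].
#' @return List with `records` (protein data frame; positives carry
#'   family labels and pdp >= 0.5, negatives pdp < 0.2) and `regions`
#'   (DPR/NODPR table with subsequences filled).
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, function() generate_database_impl(config))
}

generate_database_impl <- function(config) {
  lr <- config$protein_length_range
  fam_prob <- c(79, 42, 21, 27, 17, 10) / 196
  records <- list()
  regions <- list()

  for (i in seq_len(config$n_positive)) {
    id <- sprintf("POS%04d", i)
    L <- resample(lr[1]:lr[2])
    n_dpr <- resample(config$dprs_per_protein_range[1]:config$dprs_per_protein_range[2])
    n_nodpr <- max(0L, n_dpr + resample(-1L:1L))
    segs <- data.frame(kind = character(), len = integer())
    if (n_dpr + n_nodpr > 0) {
      v <- c(rep("DPR", n_dpr), rep("NODPR", n_nodpr))
      kinds <- resample(v, length(v))
      lens <- vapply(kinds, function(k)
        draw_region_length(if (k == "DPR") config$dpr_length_mean
                           else config$nodpr_length_mean, floor(L / 2)),
        integer(1), USE.NAMES = FALSE)
      # drop trailing segments until they (plus 1-residue gaps) fit
      while (length(lens) && sum(lens) + length(lens) + 1L > L) {
        kinds <- kinds[-length(kinds)]
        lens <- lens[-length(lens)]
      }
      segs <- data.frame(kind = kinds, len = lens, stringsAsFactors = FALSE)
    }
    k <- nrow(segs)
    slack <- L - sum(segs$len)
    gaps <- if (k > 0) as.integer(stats::rmultinom(1L, slack - (k + 1L),
                                                   rep(1 / (k + 1L), k + 1L))) + 1L
            else L
    # assemble: gap_1, seg_1, gap_2, ..., seg_k, gap_{k+1}
    pos <- 1L
    chunks <- character(0)
    for (j in seq_len(k)) {
      chunks <- c(chunks, sample_composition(config$composition_nodpr, gaps[j]))
      pos <- pos + gaps[j]
      tab <- if (segs$kind[j] == "DPR") config$composition_dpr
             else config$composition_nodpr
      chunks <- c(chunks, sample_composition(tab, segs$len[j]))
      regions[[length(regions) + 1L]] <- data.frame(
        protein_id = id, start = pos, end = pos + segs$len[j] - 1L,
        kind = segs$kind[j], stringsAsFactors = FALSE)
      pos <- pos + segs$len[j]
    }
    chunks <- c(chunks, sample_composition(config$composition_nodpr,
                                           L - pos + 1L))
    records[[length(records) + 1L]] <- data.frame(
      id = id, sequence = paste(chunks, collapse = ""),
      family = sample(FAMILY_LEVELS[1:6], 1L, prob = fam_prob),
      source_set = "positive", pdp = round(stats::runif(1L, 0.5, 1), 3),
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(config$n_negative)) {
    L <- resample(lr[1]:lr[2])
    records[[length(records) + 1L]] <- data.frame(
      id = sprintf("NEG%04d", i),
      sequence = sample_composition(config$composition_negative, L),
      family = "none", source_set = "negative",
      pdp = round(stats::runif(1L, 0, 0.199), 3), stringsAsFactors = FALSE)
  }

  records <- do.call(rbind, records)
  regions <- if (length(regions)) do.call(rbind, regions)
             else data.frame(protein_id = character(), start = integer(),
                             end = integer(), kind = character(),
                             stringsAsFactors = FALSE)
  regions$region_id <- paste0(regions$protein_id, ":", regions$start, "-",
                              regions$end)

  for (spec in config$planted_motifs) {
    planted <- plant_motif(records, regions, spec)
    records <- planted$records
  }
  regions <- extract_region_sequences(records, regions)
  list(records = records, regions = regions)
}

overwrite_window <- function(sequence, start, motif) {
  paste0(substr(sequence, 1L, start - 1L), motif,
         substr(sequence, start + nchar(motif), nchar(sequence)))
}

plant_motif <- function(records, regions, spec) {
  k <- nchar(spec$motif)
  if (spec$target == "positive_dpr") {
    dprs <- regions[regions$kind == "DPR", , drop = FALSE]
    ok <- dprs$end - dprs$start + 1L >= k
    if (!any(ok)) stop("no DPR long enough for planted motif ", spec$motif,
                       call. = FALSE)
    dprs <- dprs[ok, , drop = FALSE]
    n_plant <- round(spec$presence_fraction * nrow(dprs))
    chosen <- resample(seq_len(nrow(dprs)), n_plant)
    for (r in chosen) {
      copies <- if (length(spec$copies) == 2L)
        resample(spec$copies[1]:spec$copies[2]) else spec$copies
      irec <- match(dprs$protein_id[r], records$id)
      for (cp in seq_len(copies)) {
        start <- resample(dprs$start[r]:(dprs$end[r] - k + 1L))
        records$sequence[irec] <- overwrite_window(records$sequence[irec],
                                                   start, spec$motif)
      }
    }
  } else {
    negs <- which(records$source_set == "negative")
    n_plant <- round(spec$presence_fraction * length(negs))
    chosen <- resample(negs, n_plant)
    for (irec in chosen) {
      copies <- if (length(spec$copies) == 2L)
        resample(spec$copies[1]:spec$copies[2]) else spec$copies
      n <- nchar(records$sequence[irec])
      for (cp in seq_len(copies)) {
        start <- resample(seq_len(n - k + 1L))
        records$sequence[irec] <- overwrite_window(records$sequence[irec],
                                                   start, spec$motif)
      }
    }
  }
  list(records = records)
}

#' Write a generated database to disk
#'
#' Emits the same FASTA + region-TSV dialect the readers consume.
#'
#' @param db Result of [generate_database()].
#' @param dir Output directory (created if needed).
#' @return Invisible named vector of the two file paths.
#' @export
write_database <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "proteins.fasta")
  rtsv <- file.path(dir, "regions.tsv")
  write_fasta(db$records, fasta)
  write_regions(db$regions, rtsv)
  invisible(c(fasta = fasta, regions = rtsv))
}
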