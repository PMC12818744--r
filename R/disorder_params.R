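# Sequence parameters used throughout for region characterization and
# designed-peptide filtering: FCR, NCPR, kappa (blob-based charge
# patterning), Kyte-Doolittle mean hydropathy on the shifted 0-9 scale,
# and the fraction of disorder-promoting residues.  All are computed
# in-package; kappa's normalizing maximum is exact (exhaustive multiset
# enumeration) for short sequences and a constructed extremal bound for
# long ones.

# Kyte-Doolittle hydropathy values.
KD_SCALE <- c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
              G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
              M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
              S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

#' Disorder-promoting residues
#'
#' Default set: Ala, Arg, Gly, Gln, Ser, Pro, Glu, Lys.
#' @export
DISORDER_RESIDUES <- c("A", "R", "G", "Q", "S", "P", "E", "K")

#' Per-residue charge pattern of a sequence
#'
#' K and R are positive, D and E negative, everything else (including
#' histidine, by default -- the common neutral-pH convention) neutral.
#'
#' @param sequence Single sanitized sequence.
#' @param his_positive Treat His as positively charged.
#' @return List with `labels` (character vector over `+`, `-`, `0`),
#'   `f_plus` and `f_minus` (exact fractions).
#' @export
charge_pattern <- function(sequence, his_positive = FALSE) {
  assert_nonempty_sequence(sequence)
  ch <- seq_chars(sequence)
  pos <- c("K", "R", if (his_positive) "H")
  labels <- ifelse(ch %in% pos, "+", ifelse(ch %in% c("D", "E"), "-", "0"))
  list(labels = labels,
       f_plus = mean(labels == "+"),
       f_minus = mean(labels == "-"))
}

#' Fraction of charged residues and net charge per residue
#'
#' FCR = f+ + f-; NCPR = f+ - f-.  Always |NCPR| <= FCR.
#'
#' @inheritParams charge_pattern
#' @return Named numeric vector `c(fcr=, ncpr=)`.
#' @export
compute_fcr_ncpr <- function(sequence, his_positive = FALSE) {
  cp <- charge_pattern(sequence, his_positive)
  c(fcr = cp$f_plus + cp$f_minus, ncpr = cp$f_plus - cp$f_minus)
}

# charges: integer vector in {-1, 0, +1}.  sigma of a stretch is
# (f+ - f-)^2 / (f+ + f-), zero when the stretch carries no charge.
sigma_of <- function(charges) {
  n <- length(charges)
  p <- sum(charges > 0) / n
  m <- sum(charges < 0) / n
  if (p + m == 0) 0 else (p - m)^2 / (p + m)
}

# delta for one blob size over one arrangement (integer charge vector):
# mean over fully contained sliding windows of (sigma_window - sigma_seq)^2.
delta_g <- function(charges, g, sigma_seq) {
  n <- length(charges)
  if (g > n) return(NA_real_)
  cp <- c(0, cumsum(charges > 0))
  cm <- c(0, cumsum(charges < 0))
  i <- seq_len(n - g + 1L)
  p <- (cp[i + g] - cp[i]) / g
  m <- (cm[i + g] - cm[i]) / g
  tot <- p + m
  sig <- ifelse(tot == 0, 0, (p - m)^2 / tot)
  mean((sig - sigma_seq)^2)
}

# Matrix version: delta of many arrangements at once (rows of A in
# {-1,0,1}); used by the exhaustive delta_max enumeration.
delta_g_matrix <- function(A, g, sigma_seq) {
  n <- ncol(A)
  nwin <- n - g + 1L
  W <- matrix(0, n, nwin)
  for (j in seq_len(nwin)) W[j:(j + g - 1L), j] <- 1
  P <- ((A > 0) + 0) %*% W / g
  M <- ((A < 0) + 0) %*% W / g
  tot <- P + M
  sig <- matrix(0, nrow(A), nwin)
  nz <- tot > 0
  sig[nz] <- (P[nz] - M[nz])^2 / tot[nz]
  rowMeans((sig - sigma_seq)^2)
}

n_arrangements <- function(np, nm, nz) {
  exp(lgamma(np + nm + nz + 1) - lgamma(np + 1) - lgamma(nm + 1) -
        lgamma(nz + 1))
}

# All distinct arrangements of np +1s, nm -1s and nz 0s, as a matrix with
# one arrangement per row.  Caller guarantees the count is tractable.
enumerate_arrangements <- function(np, nm, nz) {
  n <- np + nm + nz
  pos_sets <- if (np > 0) utils::combn(n, np, simplify = FALSE) else list(integer())
  rows <- vector("list", round(n_arrangements(np, nm, nz)))
  k <- 0L
  for (ps in pos_sets) {
    rest <- setdiff(seq_len(n), ps)
    neg_sets <- if (nm > 0) utils::combn(length(rest), nm, simplify = FALSE)
                else list(integer())
    for (ns in neg_sets) {
      v <- integer(n)
      v[ps] <- 1L
      v[rest[ns]] <- -1L
      k <- k + 1L
      rows[[k]] <- v
    }
  }
  do.call(rbind, rows)
}

# Constructed extremal arrangements used when enumeration is intractable:
# segregated blocks (and reflection), charges split to opposite ends,
# all charges centered.  The observed arrangement is always included so
# kappa never exceeds 1.
extremal_arrangements <- function(np, nm, nz, observed) {
  arr <- list(
    c(rep(1L, np), rep(-1L, nm), rep(0L, nz)),
    c(rep(0L, nz), rep(1L, np), rep(-1L, nm)),
    c(rep(1L, np), rep(0L, nz), rep(-1L, nm)),
    c(rep(0L, floor(nz / 2)), rep(1L, np), rep(-1L, nm), rep(0L, ceiling(nz / 2))),
    observed)
  do.call(rbind, arr)
}

#' Blob-based charge-patterning parameter kappa
#'
#' For each blob size g, sigma of every fully contained window is compared
#' with the whole-sequence sigma; the mean squared deviation (delta) is
#' normalized by the maximum delta attainable by any rearrangement of the
#' same charge multiset, and kappa is the mean of these ratios over the
#' usable blob sizes.  Values near 0 mean well-mixed charge, near 1 mean
#' maximally segregated charge.
#'
#' The normalizing maximum is exact -- exhaustive enumeration of distinct
#' charge arrangements -- whenever their count is at most
#' `max_enumeration` (covers every designed peptide, length < 20 with few
#' charges); otherwise it is the maximum over a documented family of
#' extremal block arrangements plus the observed sequence, and the result
#' carries `attr(, "kappa_method") == "extremal"`.
#'
#' @inheritParams charge_pattern
#' @param blob_sizes Integer blob sizes (default 5 and 6); sizes larger
#'   than the sequence are skipped.
#' @param max_enumeration Arrangement-count cap for exact enumeration.
#' @return kappa in \[0,1\], or `NA` (not applicable) when the sequence
#'   carries no charge, is shorter than every blob size, or the charge
#'   multiset admits no patterning variation (delta_max = 0).
#' @export
compute_kappa <- function(sequence, blob_sizes = c(5L, 6L),
                          his_positive = FALSE, max_enumeration = 1e5) {
  assert_nonempty_sequence(sequence)
  if (any(blob_sizes < 2L)) stop("blob sizes must be >= 2", call. = FALSE)
  cp <- charge_pattern(sequence, his_positive)
  charges <- ifelse(cp$labels == "+", 1L, ifelse(cp$labels == "-", -1L, 0L))
  n <- length(charges)
  if (cp$f_plus + cp$f_minus == 0) return(NA_real_)
  usable <- blob_sizes[blob_sizes <= n]
  if (!length(usable)) return(NA_real_)

  np <- sum(charges > 0); nm <- sum(charges < 0); nz <- sum(charges == 0)
  sigma_seq <- sigma_of(charges)
  exact <- n_arrangements(np, nm, nz) <= max_enumeration
  A <- if (exact) enumerate_arrangements(np, nm, nz)
       else extremal_arrangements(np, nm, nz, charges)

  ratios <- vapply(usable, function(g) {
    d <- delta_g(charges, g, sigma_seq)
    dmax <- max(delta_g_matrix(A, g, sigma_seq))
    if (dmax == 0) NA_real_ else d / dmax
  }, numeric(1))
  if (all(is.na(ratios))) return(NA_real_)
  kappa <- mean(ratios, na.rm = TRUE)
  attr(kappa, "kappa_method") <- if (exact) "enumeration" else "extremal"
  kappa
}

#' Mean Kyte-Doolittle hydropathy
#'
#' Mean over residues of (KD + 4.5), i.e. the 0-9 shifted scale used for
#' disordered-region work; `scaled = FALSE` returns the raw KD mean.
#'
#' @inheritParams charge_pattern
#' @param scaled Shift to the 0-9 scale (default).
#' @export
compute_hydropathy <- function(sequence, scaled = TRUE) {
  assert_nonempty_sequence(sequence)
  ch <- seq_chars(sequence)
  kd <- KD_SCALE[ch]
  if (anyNA(kd))
    stop("sequence contains residues without a hydropathy value ",
         "(sanitize first?)", call. = FALSE)
  mean(kd) + if (scaled) 4.5 else 0
}

#' Fraction of disorder-promoting residues
#'
#' @inheritParams charge_pattern
#' @param residues Residue set counted as disorder-promoting
#'   (default [DISORDER_RESIDUES]).
#' @export
compute_disorder_fraction <- function(sequence, residues = DISORDER_RESIDUES) {
  assert_nonempty_sequence(sequence)
  mean(seq_chars(sequence) %in% residues)
}

#' All five sequence parameters in one record
#'
#' @param sequences Character vector of sanitized sequences.
#' @inheritParams compute_kappa
#' @return Data frame with one row per sequence: `sequence`, `fcr`,
#'   `ncpr`, `kappa` (NA when not applicable), `mean_hydropathy`,
#'   `disorder_fraction`.
#' @export
compute_all <- function(sequences, blob_sizes = c(5L, 6L),
                        his_positive = FALSE) {
  rows <- lapply(sequences, function(s) {
    fn <- compute_fcr_ncpr(s, his_positive)
    data.frame(sequence = s,
               fcr = unname(fn["fcr"]),
               ncpr = unname(fn["ncpr"]),
               kappa = as.numeric(compute_kappa(s, blob_sizes, his_positive)),
               mean_hydropathy = compute_hydropathy(s),
               disorder_fraction = compute_disorder_fraction(s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
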