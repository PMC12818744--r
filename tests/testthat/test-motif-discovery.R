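test_that("candidate enumeration yields exactly the observed k-mers", {
  expect_setequal(enumerate_candidates("GGGG", 3L, 4L), c("GGG", "GGGG"))
  expect_equal(enumerate_candidates("GSR", 3L, 3L), "GSR")
  expect_equal(length(enumerate_candidates("GS", 3L, 6L)), 0L)  # too short
  expect_error(enumerate_candidates("GGGG", 0L, 3L), "k_min")
  expect_error(enumerate_candidates("GGGG", 4L, 3L), "k_min")
  # sentinel windows are excluded
  expect_setequal(enumerate_candidates("GGXGG", 3L, 3L), character(0))
  expect_setequal(enumerate_candidates("GGGXSSS", 3L, 3L), c("GGG", "SSS"))
})

test_that("overlapping occurrences count toward frequency", {
  expect_equal(count_presence_frequency("QQQQ", "QQQQQ"),
               c(presence = 1L, frequency = 2L))
  expect_equal(count_presence_frequency("GG", c("GGG", "AGA", "GG")),
               c(presence = 2L, frequency = 3L))
  three_of_five <- c("AGGGA", "GGG", "TTGGGTT", "CCC", "AAA")
  expect_equal(count_presence_frequency("GGG", three_of_five),
               c(presence = 3L, frequency = 3L))
})

test_that("presence/frequency match the brute-force oracle on random fixtures", {
  set.seed(23)
  regions <- replicate(50, random_peptide(sample(20:60, 1)))
  motifs <- unique(replicate(40, random_peptide(sample(3:6, 1))))
  for (m in motifs) {
    expect_equal(count_presence_frequency(m, regions),
                 oracle_presence_frequency(m, regions), label = m)
  }
})

test_that("fold scores floor the negative denominator and min-max normalize", {
  pos <- data.frame(motif = c("AAA", "BBB", "CCC"), presence = c(10L, 1L, 7L),
                    frequency = c(20L, 2L, 7L))
  neg <- data.frame(motif = c("AAA", "BBB"), presence = c(1L, 1L),
                    frequency = c(2L, 2L))
  st <- compute_fold_scores(c("AAA", "BBB", "CCC"), pos, neg)
  expect_equal(st$pf_raw, c(10, 1, 7))     # CCC: 7 / max(0,1) = 7
  expect_true(st$neg_floor[st$motif == "CCC"])
  expect_equal(st$PF, c(1, 0, (7 - 1) / 9))
  expect_equal(st$CF, 0.5 * st$PF + 0.5 * st$FF)
  expect_true(all(st$PF >= 0 & st$PF <= 1))
  # stated arithmetic: PF 0.4, FF 0.8 -> CF 0.6
  expect_equal(0.5 * 0.4 + 0.5 * 0.8, 0.6)
})

test_that("degenerate all-equal folds normalize to zero", {
  pos <- data.frame(motif = c("AAA", "CCC"), presence = c(3L, 3L),
                    frequency = c(3L, 3L))
  neg <- data.frame(motif = c("AAA", "CCC"), presence = c(1L, 1L),
                    frequency = c(1L, 1L))
  expect_message(st <- compute_fold_scores(c("AAA", "CCC"), pos, neg),
                 "degenerate")
  expect_equal(st$CF, c(0, 0))
})

test_that("CF never decreases when presence in positives grows", {
  set.seed(51)
  cand <- unique(replicate(30, random_peptide(4)))
  pos <- data.frame(motif = cand,
                    presence = sample(1:30, length(cand), replace = TRUE),
                    frequency = sample(30:90, length(cand), replace = TRUE))
  neg <- data.frame(motif = cand,
                    presence = sample(0:10, length(cand), replace = TRUE),
                    frequency = sample(0:20, length(cand), replace = TRUE))
  base <- compute_fold_scores(cand, pos, neg)
  bumped_pos <- pos
  bumped_pos$presence[1] <- bumped_pos$presence[1] + 10L
  bumped <- compute_fold_scores(cand, bumped_pos, neg)
  expect_gte(bumped$CF[1], base$CF[1])
})

test_that("selection threshold is inclusive and ordering deterministic", {
  st <- data.frame(motif = c("AAA", "BBB", "CCC"), CF = c(0.19, 0.20, 0.25))
  sel <- select_enriched(st, 0.2)
  expect_equal(sel$motif, c("CCC", "BBB"))
  expect_equal(nrow(select_enriched(st, 0)), 3L)
  expect_error(select_enriched(st, 1.01), "cf_threshold")
  tie <- data.frame(motif = c("ZZZ", "AAA"), CF = c(0.5, 0.5))
  expect_equal(select_enriched(tie, 0.2)$motif, c("AAA", "ZZZ"))
})

test_that("embedded motifs are detected with their hosts", {
  e <- embedded_fraction(c("QQQQ", "QQQQQ"))
  expect_equal(e$fraction, 0.5)
  expect_equal(e$embeddings$motif, "QQQQ")
  expect_equal(e$embeddings$host, "QQQQQ")
  e2 <- embedded_fraction(c("GRGG", "GGRGG"))
  expect_equal(e2$embeddings$motif, "GRGG")
  expect_equal(embedded_fraction(c("AAA", "CCC"))$fraction, 0)
})

test_that("motif set summaries report lengths and residue membership", {
  s <- motif_set_summary(c("GGG", "GGGG"))
  expect_equal(s$length_distribution$percent, c(50, 50))
  expect_equal(s$aa_membership$percent[s$aa_membership$residue == "G"], 100)
  s2 <- motif_set_summary("GSR")
  expect_setequal(
    s2$aa_membership$residue[s2$aa_membership$percent == 100],
    c("G", "S", "R"))
  expect_equal(sum(s2$aa_membership$percent == 0), 17L)
  expect_error(motif_set_summary(character(0)), "empty")
})

test_that("per-region counts conserve frequency and expose maxima", {
  regions <- c(r1 = "YSPTYSPTYSPT", r2 = "GGGG", r3 = "YSPTAA")
  prc <- per_region_counts(c("YSPT", "GGG"), regions)
  expect_equal(prc$count[prc$motif == "YSPT" & prc$region_id == "r1"], 3L)
  expect_true(all(prc$count >= 1L))
  for (m in c("YSPT", "GGG")) {
    expect_equal(sum(prc$count[prc$motif == m]),
                 unname(count_presence_frequency(m, regions)["frequency"]))
  }
  expect_equal(max(prc$count[prc$motif == "YSPT"]), 3L)
})

test_that("discovery recovers planted motifs and omits negative-only motifs", {
  dprs <- c("AAGGWDGGAA", "CCGGWDGGCC", "TTGGWDGGTT", "AAAACCCC")
  negs <- c("LLLLVVVVLLLL", "VVVVMMMMVVVV")
  res <- discover_motifs(dprs, negs, 3L, 4L, cf_threshold = 0.2)
  expect_true("GGWD" %in% res$selected$motif)
  # motifs only in negatives never appear
  expect_false(any(grepl("LLL", res$stats$motif)))
  expect_true(all(res$stats$frequency_pos >= res$stats$presence_pos))
})

test_that("per-family discovery keeps families separate", {
  set.seed(61)
  spacer <- function() random_peptide(30, c("A", "T", "N"))
  fam_a <- replicate(3, paste0(spacer(), "GGWDG", spacer()))  # A's plant
  fam_b <- replicate(3, paste0(spacer(), "QPWPQ", spacer()))  # B's plant
  recs <- data.frame(id = c(paste0("A", 1:3), paste0("B", 1:3)),
                     sequence = c(fam_a, fam_b),
                     family = rep(c("RNA-binding", "hydrolase"), each = 3),
                     stringsAsFactors = FALSE)
  regions <- data.frame(protein_id = recs$id, start = 1L,
                        end = nchar(recs$sequence), kind = "DPR",
                        region_id = paste0("r", recs$id))
  regions <- extract_region_sequences(recs, regions)
  negs <- replicate(4, random_peptide(60, c("L", "V", "M")))
  out <- discover_per_family(recs, regions, negs, 3L, 5L, 0.2)
  expect_true("GGWDG" %in% out[["RNA-binding"]]$selected$motif)
  expect_false("GGWDG" %in% out[["hydrolase"]]$selected$motif)
  expect_true("QPWPQ" %in% out[["hydrolase"]]$selected$motif)
  uniq <- family_unique_motifs(out)
  expect_true("GGWDG" %in% uniq[["RNA-binding"]])
  # single family reduces to global discovery
  solo <- discover_per_family(recs[1:3, ], regions[1:3, ], negs, 3L, 5L, 0.2)
  glob <- discover_motifs(regions$subsequence[1:3], negs, 3L, 5L, 0.2)
  expect_equal(solo[[1]]$selected, glob$selected)
})
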