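# Regions built by planting motifs between neutral spacers.
spacered <- function(...) paste0("AAA", paste(c(...), collapse = "TTT"), "AAA")

test_that("pair co-occurrence is a support intersection", {
  regions <- c(spacered("GGWD"), spacered("GGWD", "QPWP"),
               spacered("GGWD", "QPWP"), spacered("QPWP"))
  expect_equal(pair_cooccurrence("GGWD", "QPWP", regions), 2L)
  expect_equal(pair_cooccurrence("QPWP", "GGWD", regions), 2L)
  expect_equal(pair_cooccurrence("GGWD", "CCC", regions), 0L)
  expect_equal(pair_cooccurrence("GGWD", "GGWD", regions), 3L)
})

test_that("a trio present in every region scores FS = 100 exactly", {
  regions <- replicate(10, spacered("GGWD", "QPWP", "SSYS"))
  sc <- score_trio("GGWD", "QPWP", "SSYS", regions)
  expect_equal(sc$coverage, 1)
  expect_equal(sc$symmetry, 1)
  expect_equal(sc$fs, 100)
})

test_that("disjoint supports score FS = 0", {
  regions <- c(spacered("GGWD"), spacered("QPWP"), spacered("SSYS"))
  sc <- score_trio("GGWD", "QPWP", "SSYS", regions)
  expect_equal(sc$fs, 0)
})

test_that("constructed half-coverage fixture scores FS = 75", {
  # all three in 4 regions; each motif alone in 4 more (equal pairwise
  # counts of 4, presence 8 each) -> coverage 0.5, symmetry 1
  regions <- c(replicate(4, spacered("GGWD", "QPWP", "SSYS")),
               replicate(4, spacered("GGWD")),
               replicate(4, spacered("QPWP")),
               replicate(4, spacered("SSYS")))
  sc <- score_trio("GGWD", "QPWP", "SSYS", regions)
  expect_equal(sc$n_ab, 4)
  expect_equal(sc$n_abc, 4)
  expect_equal(sc$coverage, 0.5)
  expect_equal(sc$symmetry, 1)
  expect_equal(sc$fs, 75)
})

test_that("score_trio is invariant under argument order and rejects duplicates", {
  regions <- c(spacered("GGWD", "QPWP", "SSYS"), spacered("GGWD", "QPWP"),
               spacered("SSYS"))
  ref <- score_trio("GGWD", "QPWP", "SSYS", regions)
  perms <- list(c(1, 3, 2), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1), c(3, 1, 2))
  trio <- c("GGWD", "QPWP", "SSYS")
  for (p in perms)
    expect_equal(score_trio(trio[p[1]], trio[p[2]], trio[p[3]], regions), ref)
  expect_error(score_trio("GGWD", "GGWD", "SSYS", regions), "distinct")
})

test_that("n_abc is bounded by every pairwise count and fs by [0,100]", {
  set.seed(71)
  regions <- replicate(30, random_peptide(40))
  motifs <- unique(replicate(6, random_peptide(3)))[1:4]
  sc <- score_all_trios(motifs, regions)
  expect_true(all(sc$n_abc <= pmin(sc$n_ab, sc$n_ac, sc$n_bc)))
  expect_true(all(sc$fs >= 0 & sc$fs <= 100))
})

test_that("adding a region containing all three never decreases fs", {
  set.seed(72)
  regions <- replicate(15, random_peptide(30))
  base <- score_trio("GGS", "SEK", "KAP", regions)
  grown <- score_trio("GGS", "SEK", "KAP", c(regions, "GGSEKAPGGSEKAP"))
  expect_gte(grown$fs, base$fs)
})

test_that("score_all_trios enumerates C(m,3) trios and agrees with score_trio", {
  regions <- c(spacered("GGWD", "QPWP", "SSYS"), spacered("GGWD", "NNEN"),
               spacered("QPWP", "SSYS", "NNEN"), spacered("HFHG"))
  motifs <- c("GGWD", "QPWP", "SSYS", "NNEN", "HFHG")
  sc <- score_all_trios(motifs, regions)
  expect_equal(nrow(sc), choose(5, 3))
  expect_equal(nrow(score_all_trios(motifs[1:3], regions)), 1L)
  expect_error(score_all_trios(motifs[1:2], regions), "at least 3")
  # every row matches the single-trio scorer
  for (i in seq_len(nrow(sc))) {
    one <- score_trio(sc$motif_a[i], sc$motif_b[i], sc$motif_c[i], regions)
    expect_equal(sc[i, names(one)], one, ignore_attr = TRUE)
  }
  # ranking: fs descending
  expect_true(all(diff(sc$fs) <= 0))
})

test_that("a planted perfectly co-occurring trio ranks first with fs 100", {
  set.seed(73)
  trio <- c("GGWDG", "QPWPQ", "SSYSS")
  regions <- c(replicate(8, spacered(trio[1], trio[2], trio[3])),
               replicate(10, random_peptide(40, c("A", "T", "N", "E"))))
  decoys <- unique(replicate(10, random_peptide(4, c("A", "T", "N", "E"))))
  sc <- score_all_trios(c(trio, decoys), regions)
  expect_equal(sort(unlist(sc[1, c("motif_a", "motif_b", "motif_c")],
                           use.names = FALSE)), sort(trio))
  expect_equal(sc$fs[1], 100)
})

test_that("maximal suffix-prefix merging behaves as specified", {
  expect_equal(merge_overlap("GRGG", "RGGF"), "GRGGF")
  expect_equal(merge_overlap("AAA", "TTT"), "AAATTT")
  expect_equal(merge_overlap("GGGG", "GG"), "GGGG")      # containment
  expect_equal(merge_overlap("ABCD", "CDEF"), "ABCDEF")
})

test_that("build_peptides finds the minimal superstring of a trio", {
  cand <- build_peptides(c("FGGG", "RGGF", "GGDRGG"))
  best <- cand[cand$is_minimal, ]
  expect_equal(best$sequence, "FGGGDRGGF")
  expect_equal(best$length, 9L)
  for (m in c("FGGG", "RGGF", "GGDRGG"))
    expect_true(all(grepl(m, cand$sequence, fixed = TRUE)))
  expect_true(all(cand$length < 20L))
})

test_that("substring-redundant motifs are absorbed before merging", {
  cand <- build_peptides(c("QQQ", "QQQQ", "GGG"))
  expect_true(all(grepl("QQQQ", cand$sequence, fixed = TRUE)))
  expect_equal(min(cand$length), 7L)  # QQQQGGG / GGGQQQQ
  expect_equal(nrow(cand), 2L)        # only two orderings of two motifs
})

test_that("minimal candidate length equals the exhaustive oracle on random trios", {
  set.seed(77)
  for (i in 1:20) {
    trio <- unique(replicate(3, random_peptide(sample(3:6, 1))))
    if (length(trio) < 3) next
    cand <- build_peptides(trio)
    expect_equal(min(cand$length), oracle_min_superstring(trio),
                 label = paste(trio, collapse = "+"))
  }
})

test_that("candidate filtering annotates without deleting", {
  cand <- build_peptides(c("GGSG", "SGGE", "KGGS"))
  out <- filter_candidates(cand)
  expect_equal(nrow(out), nrow(cand))
  expect_true(all(c("fcr", "ncpr", "kappa", "mean_hydropathy",
                    "disorder_fraction", "passes_filter", "filter_failures")
                  %in% names(out)))
  # an all-Leu peptide fails hydropathy and disorder fraction by name
  leu <- data.frame(sequence = "LLLLLLLLLLLL", stringsAsFactors = FALSE)
  fl <- filter_candidates(leu)
  expect_false(fl$passes_filter)
  expect_match(fl$filter_failures, "mean_hydropathy")
  expect_match(fl$filter_failures, "disorder_fraction")
  # kappa NA policy
  gly <- data.frame(sequence = "GGGGGGGGGGGG", stringsAsFactors = FALSE)
  expect_true(filter_candidates(gly, kappa_na = "pass")$passes_filter)
  expect_false(filter_candidates(gly, kappa_na = "fail")$passes_filter)
  expect_match(filter_candidates(gly, kappa_na = "fail")$filter_failures,
               "kappa")
  bad <- default_filter_ranges(); bad$fcr <- c(0.5, 0.1)
  expect_error(filter_candidates(cand, ranges = bad), "malformed")
})

test_that("design ranking puts passing candidates first, then fs, length, lex", {
  peps <- data.frame(
    sequence = c("BBBB", "AAAA", "CCC", "DDDD"),
    fs = c(74, 61.26, 61.26, 90),
    length = c(4L, 4L, 3L, 4L),
    passes_filter = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  ranked <- rank_designs(peps)
  expect_equal(ranked$sequence, c("BBBB", "CCC", "AAAA", "DDDD"))
  expect_equal(ranked$fs[1], 74)   # highest-fs passing design leads
})

test_that("design_peptides pools top trios into a ranked annotated table", {
  regions <- replicate(6, spacered("GGSG", "SGGE", "KGGS"))
  trios <- score_all_trios(c("GGSG", "SGGE", "KGGS", "AAEA"), regions)
  designs <- design_peptides(trios, top_k = 2L)
  expect_true(all(designs$length < 20L))
  expect_true(all(c("trio", "fs", "passes_filter") %in% names(designs)))
  expect_true(is.unsorted(rev(designs$fs)) == FALSE ||
              any(!designs$passes_filter))
})
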