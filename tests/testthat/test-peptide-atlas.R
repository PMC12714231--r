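test_that("peptides are located by substring search, overlaps included", {
  pre <- precursor("x", "MGSSFLSPSQR")
  hit <- locatePeptide("GSSFL", pre)
  expect_equal(hit$start, 2)
  expect_equal(hit$end, 6)
  expect_true(is.na(hit$variant))
  # overlapping occurrences are all reported, left to right
  hits <- locatePeptide("AA", precursor("y", "AAA"))
  expect_equal(hits$start, c(1, 2))
  expect_equal(hits$end, c(2, 3))
  expect_equal(nrow(locatePeptide("WWW", pre)), 0)
  # exhaustive oracle on a random sequence
  set.seed(71)
  seq <- paste(sample(c("A", "G", "S"), 40, TRUE), collapse = "")
  pep <- substring(seq, 17, 19)
  oracle <- which(vapply(1:38, function(i)
    substring(seq, i, i + 2) == pep, TRUE))
  expect_equal(locatePeptide(pep, precursor("z", seq))$start, oracle)
})

test_that("single-variant substitution extends peptide location", {
  pre <- precursor("x", "MGSR", variants = data.frame(pos = 3, ref = "S",
                                                      alt = "T"))
  hit <- locatePeptide("GTR", pre)
  expect_equal(hit$start, 2)
  expect_equal(hit$end, 4)
  expect_equal(hit$variant, "3:S>T")
  # reference hits are not re-reported through the variant
  expect_true(is.na(locatePeptide("MG", pre)$variant))
  # located span extracts back to the peptide under the variant image
  sub <- pre@sequence
  substring(sub, 3, 3) <- "T"
  expect_equal(substring(sub, hit$start, hit$end), "GTR")
  # a variant whose ref disagrees with the sequence is rejected
  expect_error(precursor("bad", "MGSR",
                         variants = data.frame(pos = 2, ref = "A",
                                               alt = "T")),
               "does not match")
})

test_that("peptide masses match the elemental-composition oracle", {
  expect_equal(peptideMass("G"), elementalMass("G"), tolerance = 1e-6)
  # glycine is C2H5NO2 as the free amino acid
  expect_equal(peptideMass("G"), 75.03203, tolerance = 1e-4)
  # exactly one water regardless of length
  expect_equal(peptideMass("GG"), 2 * (peptideMass("G") - 18.0105647) +
                 18.0105647, tolerance = 1e-9)
  expect_equal(peptideMass("GSSK", "4|amidation"),
               elementalMass("GSSK", "amidation"), tolerance = 1e-6)
})

test_that("mass additivity: concat loses one water", {
  set.seed(72)
  aas <- names(residueMasses())
  for (rep in 1:10) {
    p <- paste(sample(aas, 6, TRUE), collapse = "")
    q <- paste(sample(aas, 9, TRUE), collapse = "")
    expect_equal(peptideMass(paste0(p, q)),
                 peptideMass(p) + peptideMass(q) - 18.0105647,
                 tolerance = 1e-7)
  }
})

test_that("modification handling validates names and positions", {
  expect_error(peptideMass("GXG"), "unknown residue")
  expect_error(peptideMass("GAG", "2|phospho"), "unknown modification")
  # explicit numeric deltas are accepted for names outside the bundled set
  m <- data.frame(position = 2, name = "phospho", delta = 79.96633)
  expect_equal(peptideMass("GAG", m), peptideMass("GAG") + 79.96633)
  expect_error(peptideMass("GAG", "9|oxidation"), "outside")
  # pyroglutamate is restricted to Q/E at position 1
  expect_equal(peptideMass("QAG", "1|pyroglutamate-from-Q"),
               elementalMass("QAG", "pyroglutamate-from-Q"),
               tolerance = 1e-6)
  expect_error(peptideMass("AQG", "2|pyroglutamate-from-Q"), "position 1")
  expect_error(peptideMass("EAG", "1|pyroglutamate-from-Q"), "requires Q")
})

test_that("ppm matching is symmetric-ish, monotone and bounded", {
  expect_true(ppmMatch(1000, 1000))
  expect_false(ppmMatch(1000.011, 1000))      # 11 ppm
  expect_true(ppmMatch(1000.009, 1000))
  expect_error(ppmMatch(-1, 1000), "positive")
  set.seed(73)
  for (rep in 1:50) {
    a <- runif(1, 100, 5000)
    b <- a * (1 + runif(1, -2e-5, 2e-5))
    expect_equal(ppmMatch(a, b), ppmMatch(b, a))
    # monotone in tolerance
    tol <- sort(runif(3, 0, 30))
    m <- vapply(tol, function(t) ppmMatch(a, b, t), TRUE)
    expect_true(all(diff(m) >= 0))
  }
})

test_that("dibasic sites are every adjacent K/R pair, overlaps allowed", {
  expect_equal(findDibasicSites("AKRG")$start, 2)
  expect_equal(findDibasicSites("KKK")$start, c(1, 2))
  expect_equal(findDibasicSites("KKK")$pair, c("KK", "KK"))
  expect_equal(nrow(findDibasicSites("AGSTA")), 0)
  set.seed(74)
  for (rep in 1:20) {
    seq <- paste(sample(c("A", "K", "R", "G"), 30, TRUE), collapse = "")
    expect_equal(findDibasicSites(seq)$start, pairScanDibasic(seq))
  }
})

test_that("atlas coverage, junctions and region overlaps are correct", {
  pre <- precursor("p", paste(rep("A", 10), collapse = ""),
                   regions = data.frame(name = "func", start = 4, end = 7))
  hits <- data.frame(start = c(1, 6), end = c(5, 10))
  atl <- buildAtlas(pre, hits)
  expect_equal(atlasCoverage(atl), rep(1L, 10))
  expect_equal(atlasJunctions(atl), 5L)
  expect_setequal(atl@regionOverlaps$hit, c(1, 2))
  # empty case
  empty <- buildAtlas(pre, data.frame(start = integer(0), end = integer(0)))
  expect_equal(atlasCoverage(empty), rep(0L, 10))
  expect_equal(length(atlasJunctions(empty)), 0)
  expect_error(buildAtlas(pre, data.frame(start = 5, end = 12)),
               "outside")
})

test_that("coverage equals the interval-stabbing oracle on simulated sets", {
  pre <- precursor("sim", "MAGSFLKRSTPADEVKRSLHGAGNTEILKKVDWQAGNT")
  for (seed in 1:5) {
    hits <- simulatePeptides(pre, 30, seed = seed)
    atl <- buildAtlas(pre, hits)
    expect_equal(atlasCoverage(atl),
                 stabCoverage(hits$start, hits$end, length(pre)))
    # coverage mass = total peptide length
    expect_equal(sum(atlasCoverage(atl)), sum(hits$end - hits$start + 1))
    expect_equal(atl@dibasicSites$start, pairScanDibasic(pre@sequence))
  }
})

test_that("atlas round trips through FASTA/TSV and disk output", {
  dir <- tempfile()
  dir.create(dir)
  fa <- file.path(dir, "pre.fa")
  writeLines(c(">ghrl test precursor", "MGSSFLSPSQKPQGKRRSLLDM"), fa)
  sc <- file.path(dir, "ann.tsv")
  write.table(data.frame(precursor_id = c("ghrl", "ghrl"),
                         type = c("variant", "region"),
                         pos = c(5, NA), ref = c("F", NA), alt = c("L", NA),
                         name = c(NA, "signal"), start = c(NA, 1),
                         end = c(NA, 7)),
              sc, sep = "\t", row.names = FALSE, quote = FALSE)
  pres <- readPrecursors(fa, sc)
  expect_equal(names(pres), "ghrl")
  expect_equal(pres$ghrl@variants$alt, "L")
  expect_equal(pres$ghrl@regions$name, "signal")
  hits <- simulatePeptides(pres$ghrl, 10, seed = 3)
  tsv <- file.path(dir, "hits.tsv")
  write.table(hits, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- readPeptideHits(tsv, pres)
  expect_equal(back$start, hits$start)
  atl <- buildAtlas(pres$ghrl, back)
  out <- writeAtlas(atl, file.path(dir, "atlas"))
  tracks <- read.delim(file.path(out, "ghrl_tracks.tsv"))
  expect_equal(tracks$coverage, atlasCoverage(atl))
  js <- jsonlite::read_json(file.path(out, "ghrl_summary.json"))
  expect_equal(js$n_hits, nrow(back))
})
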