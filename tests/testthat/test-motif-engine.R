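# Motif libraries, annotation, wildcard generalization, deduplication and
# proportional quantification.

dsT <- "Neu5Ac(a2-3)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc"

test_that("the packaged motif library is loaded and validated", {
  lib <- loadKnownMotifs()
  expect_gte(nrow(lib), 25L)
  expect_false(anyDuplicated(lib$name) > 0)
  expect_true(all(c("Sda", "diSialylT", "Oglycan_core1", "SialylTn",
                    "CoreFucose", "BisectingGlcNAc", "LacdiNAc",
                    "SulfatedLacNAc") %in% lib$name))
  expect_identical(lib$pattern[lib$name == "diSialylT"], dsT)
  expect_identical(lib$constraint[lib$name == "diSialylT"], "reducing-end")
  # Sda counts its defining GalNAc(b1-4)Gal / Neu5Ac(a2-3) arrangement
  sda <- lib[lib$name == "Sda", ]
  expect_identical(
    countMotif("GalNAc(b1-4)[Neu5Ac(a2-3)]Gal(b1-4)GlcNAc",
               motifDefinition("Sda", sda$pattern, sda$constraint)), 1L)
})

test_that("user library additions are appended and duplicates rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tpattern\tconstraint\texcluded_context",
               "MyMotif\tGal(b1-3)GalNAc\tflexible"), f)
  lib <- loadKnownMotifs(f)
  expect_true("MyMotif" %in% lib$name)
  writeLines(c("name\tpattern\tconstraint",
               "Sda\tGal(b1-3)GalNAc\tflexible"), f)
  expect_error(loadKnownMotifs(f), "duplicate")
  writeLines(c("name\tpattern\tconstraint", "broken\t\tflexible"), f)
  expect_error(loadKnownMotifs(f), "line 2")
})

test_that("terminal annotation yields leaves plus informative wildcards", {
  ann <- annotateDataset(dsT, featureSets = "terminal")
  cn <- colnames(motifCounts(ann))
  expect_setequal(cn, c("Neu5Ac(a2-3)", "Neu5Ac(a2-6)", "Neu5Ac(a2-?)"))
  expect_identical(unname(motifCounts(ann)[1, "Neu5Ac(a2-?)"]), 2)
  expect_identical(unname(motifCounts(ann)[1, "Neu5Ac(a2-3)"]), 1)
})

test_that("generalized motifs are kept only when informative", {
  # two glycans separating a2-3 from a2-6: the wildcard adds information
  two <- c("Neu5Ac(a2-3)Gal(b1-3)GalNAc", "Neu5Ac(a2-6)Gal(b1-3)GalNAc")
  ann <- annotateDataset(two, featureSets = "terminal")
  expect_true("Neu5Ac(a2-?)" %in% colnames(motifCounts(ann)))
  expect_equal(unname(motifCounts(ann)[, "Neu5Ac(a2-?)"]), c(1, 1))
  # a single specialization: the wildcard duplicates it and is dropped
  one <- c("Neu5Ac(a2-3)Gal(b1-3)GalNAc", "Gal(b1-3)GalNAc")
  ann1 <- annotateDataset(one, featureSets = "terminal")
  expect_false("Neu5Ac(a2-?)" %in% colnames(motifCounts(ann1)))
  expect_true("Neu5Ac(a2-3)" %in% colnames(motifCounts(ann1)))
})

test_that("exhaustive annotation covers mono- and disaccharides", {
  ann <- annotateDataset("Gal(b1-3)GalNAc", featureSets = "exhaustive")
  cn <- colnames(motifCounts(ann))
  expect_true(all(c("Gal", "GalNAc", "Gal(b1-3)GalNAc") %in% cn))
  dd <- deduplicateFeatures(t(motifCounts(ann)),
                            klass = motifInfo(ann)$klass)
  expect_identical(nrow(dd), 1L)
  expect_identical(rownames(dd), "Gal(b1-3)GalNAc")  # disaccharide wins
})

test_that("substituent positions generalize for exhaustive motifs", {
  two <- c("Gal(b1-4)GlcNAc6S(b1-6)GalNAc", "Gal(b1-4)GlcNAc3S(b1-6)GalNAc")
  ann <- annotateDataset(two, featureSets = "exhaustive")
  cn <- colnames(motifCounts(ann))
  expect_true("GlcNAcOS" %in% cn)
  expect_equal(unname(motifCounts(ann)[, "GlcNAcOS"]), c(1, 1))
})

test_that("annotation agrees with brute-force counting across feature sets", {
  glycans <- oracle_fixture_glycans(12)
  ann <- annotateDataset(glycans,
                         featureSets = c("known", "terminal", "exhaustive"))
  tab <- motifInfo(ann)
  cnt <- motifCounts(ann)
  for (j in seq_len(nrow(tab))) {
    mo <- motifDefinition(tab$name[j], tab$pattern[j], tab$constraint[j],
                          tab$excluded_context[j], tab$klass[j])
    bf <- vapply(glycans, function(s) bf_count_motif(s, mo), numeric(1))
    expect_equal(unname(cnt[, j]), unname(bf), label = tab$name[j])
  }
})

test_that("annotation is deterministic given the glycan order", {
  glycans <- oracle_fixture_glycans(10)
  a1 <- annotateDataset(glycans)
  a2 <- annotateDataset(glycans)
  expect_identical(motifCounts(a1), motifCounts(a2))
  expect_identical(motifInfo(a1), motifInfo(a2))
})

test_that("deduplication keeps the documented representative", {
  v <- c(1, 5, 3)
  x <- rbind("Neu5Ac" = v, "Neu5Ac(a2-3)" = v, "Neu5Ac(a2-3)Gal" = v)
  out <- deduplicateFeatures(x, klass = c("monosaccharide", "terminal",
                                          "disaccharide"))
  expect_identical(rownames(out), "Neu5Ac(a2-3)Gal")
  x2 <- rbind("SialylTn" = v, "Neu5Ac(a2-6)GalNAc" = v)
  out2 <- deduplicateFeatures(x2, klass = c("named", "disaccharide"))
  expect_identical(rownames(out2), "SialylTn")
  x3 <- rbind(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  expect_identical(deduplicateFeatures(x3), x3)
})

test_that("quantifyMotifs computes renormalized weighted sums", {
  # two glycans, one sample, hand arithmetic: counts m1 = (2, 0),
  # m2 = (1, 1); abundances (60, 40) -> weighted (120, 100) -> (54.55, 45.45)
  ab <- matrix(c(60, 40), 2, 1, dimnames = list(
    c("Neu5Ac(a2-3)[Neu5Ac(a2-3)]GalNAc", "Gal(b1-3)GalNAc"), "s1"))
  lib <- data.frame(
    name = c("m1", "m2"),
    pattern = c("Neu5Ac(a2-3)", "GalNAc"),
    constraint = c("terminal", "reducing-end"),
    excluded_context = NA_character_, klass = "named",
    stringsAsFactors = FALSE)
  q <- quantifyMotifs(ab, featureSets = "known", motifLibrary = lib)
  expect_equal(q["m1", 1], 120 / 220 * 100, tolerance = 1e-12)
  expect_equal(q["m2", 1], 100 / 220 * 100, tolerance = 1e-12)
})

test_that("quantifyMotifs conserves the compositional scale", {
  set.seed(11)
  glycans <- oracle_fixture_glycans(25)
  ab <- matrix(rgamma(length(glycans) * 6, 2), length(glycans), 6,
               dimnames = list(glycans, paste0("s", 1:6)))
  ab <- sweep(ab, 2, colSums(ab), "/") * 100
  q <- quantifyMotifs(ab)
  expect_equal(unname(colSums(q)), rep(100, 6), tolerance = 1e-9)
  expect_identical(anyDuplicated(apply(q, 1, paste, collapse = ",")), 0L)
  # a motif carried once by every glycan tracks total abundance
  lib <- data.frame(name = "root", pattern = "GalNAc",
                    constraint = "reducing-end",
                    excluded_context = NA_character_, klass = "named",
                    stringsAsFactors = FALSE)
  og <- glycans[vapply(glycans, function(s) {
    countMotif(s, "GalNAc", constraint = "reducing-end") == 1L
  }, logical(1))]
  q2 <- quantifyMotifs(ab[og, , drop = FALSE], featureSets = "known",
                       motifLibrary = lib)
  expect_equal(unname(q2["root", ]), rep(100, 6), tolerance = 1e-9)
})

test_that("doubling a motif count doubles its pre-normalization weight", {
  ab <- matrix(c(30, 70), 2, 1, dimnames = list(
    c("Neu5Ac(a2-3)Gal(b1-3)GalNAc", "Gal(b1-3)GalNAc"), "s1"))
  lib1 <- data.frame(name = "m", pattern = "Gal",
                     constraint = "flexible",
                     excluded_context = NA_character_, klass = "named",
                     stringsAsFactors = FALSE)
  ann <- annotateDataset(rownames(ab), featureSets = "known",
                         motifLibrary = lib1)
  w1 <- t(motifCounts(ann)) %*% ab
  w2 <- t(2 * motifCounts(ann)) %*% ab
  expect_equal(unname(w2), unname(2 * w1))
})
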