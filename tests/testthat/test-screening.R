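# The whole-genome screen: planted-truth recovery, voting, maximal
# thresholds, the quality index, report writing and determinism.

screenFixture <- function(seed = 42L, ...) {
  planted <- lapply(c(3L, 11L, 22L, 30L, 37L), function(i)
    list(gene = i, species = c(sprintf("upper_glires_%02d", 1:3),
                               sprintf("upper_primates_%02d", 1:7))))
  generateFixture(fixtureSpec(
    upperCounts = c(glires = 3L, primates = 7L),
    lowerCounts = c(glires = 11L, primates = 10L),
    nContigs = 2L, genesPerContig = 20L,
    plantedLosses = planted, seed = seed, ...))
}

classicPredicate <- paste(
  "absent_in(UPPER_GLIRES, 1) and absent_in(UPPER_PRIMATES, 2)",
  "and present_in(LOWER_GLIRES, 2) and present_in(LOWER_PRIMATES, 2)",
  "and present_in(REFERENCE, 1)")

test_that("a noise-free screen recovers exactly the planted losses", {
  fix <- screenFixture()
  res <- screenGenes(fix$genomes, fix$refSpecies, fix$source,
                     classicPredicate, fixtureSets(fix), presenceParams())
  hits <- screenHits(res)
  expect_identical(hits$gene_id, sort(unique(fix$truth$gene_id)))
  # genes planted as lost in every upper species and retained in every
  # lower species sit at the extreme thresholds
  expect_true(all(hits$m_max == 3L))
  expect_true(all(hits$n_max == 7L))
  expect_true(all(hits$p_max == 11L))
  expect_true(all(hits$q_max == 10L))
  expect_true(all(hits$s_index == 31L))
})

test_that("voting: 2-of-3 keeps genes that one degraded source misses, consensus drops them", {
  fix <- screenFixture()
  s1 <- fix$source
  s2 <- degradeToSecondSource(s1, 0.3, seed = 7L)
  s3 <- degradeToSecondSource(s1, 0.3, seed = 8L)
  sets <- fixtureSets(fix)
  hitsAt <- function(v) screenHits(screenGenes(
    fix$genomes, fix$refSpecies, list(s1, s2, s3), classicPredicate,
    sets, presenceParams(), minVotes = v))$gene_id
  h1 <- hitsAt(1L); h2 <- hitsAt(2L); h3 <- hitsAt(3L)
  expect_true(all(h3 %in% h2))
  expect_true(all(h2 %in% h1))
  # degenerate voting: (d = 1, v = 1) equals the single-source screen
  single <- screenHits(screenGenes(fix$genomes, fix$refSpecies, s1,
                                   classicPredicate, sets,
                                   presenceParams()))$gene_id
  expect_identical(
    screenHits(screenGenes(fix$genomes, fix$refSpecies, list(s1),
                           classicPredicate, sets, presenceParams(),
                           minVotes = votingPolicy(1L, 1L)))$gene_id,
    single)
})

test_that("per-gene verdict voting matches explicit per-source verdicts", {
  fix <- screenFixture()
  s1 <- fix$source
  s2 <- degradeToSecondSource(s1, 0.5, seed = 3L)
  s3 <- degradeToSecondSource(s1, 0.5, seed = 4L)
  sets <- fixtureSets(fix)
  verdictOf <- function(src) screenHits(screenGenes(
    fix$genomes, fix$refSpecies, src, classicPredicate, sets,
    presenceParams()))$gene_id
  votes <- table(unlist(lapply(list(s1, s2, s3), verdictOf)))
  for (v in 1:3) {
    got <- screenHits(screenGenes(fix$genomes, fix$refSpecies,
                                  list(s1, s2, s3), classicPredicate,
                                  sets, presenceParams(),
                                  minVotes = v))$gene_id
    expect_identical(got, sort(names(votes)[votes >= v]))
  }
})

test_that("raising any threshold never adds a hit (grid monotonicity)", {
  fix <- screenFixture(seed = 9L)
  sets <- fixtureSets(fix)
  hitsAt <- function(m, n, p, q) {
    pred <- sprintf(paste("absent_in(UPPER_GLIRES, %d) and",
                          "absent_in(UPPER_PRIMATES, %d) and",
                          "present_in(LOWER_GLIRES, %d) and",
                          "present_in(LOWER_PRIMATES, %d)"), m, n, p, q)
    screenHits(screenGenes(fix$genomes, fix$refSpecies, fix$source,
                           pred, sets, presenceParams()))$gene_id
  }
  base <- hitsAt(1, 2, 2, 2)
  for (step in list(c(2, 2, 2, 2), c(1, 3, 2, 2), c(1, 2, 5, 2),
                    c(1, 2, 2, 5), c(3, 7, 11, 10))) {
    harder <- do.call(hitsAt, as.list(step))
    expect_true(all(harder %in% base))
  }
  # a hit at (m,n,p,q) is a hit iff each component is within its maximum
  res <- screenGenes(fix$genomes, fix$refSpecies, fix$source,
                     classicPredicate, sets, presenceParams())
  hits <- screenHits(res)
  for (i in seq_len(nrow(hits))) {
    expect_true(hits$gene_id[i] %in% hitsAt(hits$m_max[i], hits$n_max[i],
                                            hits$p_max[i], hits$q_max[i]))
    if (hits$m_max[i] < 3L)   # k may not exceed the set size
      expect_false(hits$gene_id[i] %in% hitsAt(hits$m_max[i] + 1L,
                                               hits$n_max[i],
                                               hits$p_max[i],
                                               hits$q_max[i]))
  }
})

test_that("maximal thresholds equal explicit per-set status counts", {
  set.seed(23)
  sets <- list(
    UPPER_GLIRES = speciesSet("UPPER_GLIRES", sprintf("ug%d", 1:3), 1L),
    UPPER_PRIMATES = speciesSet("UPPER_PRIMATES", sprintf("up%d", 1:7),
                                2L),
    LOWER_GLIRES = speciesSet("LOWER_GLIRES", sprintf("lg%d", 1:11), 2L),
    LOWER_PRIMATES = speciesSet("LOWER_PRIMATES", sprintf("lp%d", 1:10),
                                2L))
  species <- unlist(lapply(sets, function(s) s@members))
  for (i in 1:25) {
    st <- matrix(sample(c("present", "absent", "unevaluable"),
                        length(species), TRUE),
                 1, length(species), dimnames = list("g", species))
    mt <- maxThresholds("g", st, sets)
    expect_identical(unname(mt["m_max"]),
                     sum(st[1, sets$UPPER_GLIRES@members] == "absent"))
    expect_identical(unname(mt["n_max"]),
                     sum(st[1, sets$UPPER_PRIMATES@members] == "absent"))
    expect_identical(unname(mt["p_max"]),
                     sum(st[1, sets$LOWER_GLIRES@members] == "present"))
    expect_identical(unname(mt["q_max"]),
                     sum(st[1, sets$LOWER_PRIMATES@members] == "present"))
    expect_identical(qualityIndex(mt), as.integer(sum(mt)))
  }
  expect_identical(qualityIndex(c(m_max = 3L, n_max = 7L, p_max = 11L,
                                  q_max = 10L)), 31L)
  expect_identical(qualityIndex(c(m_max = 1L, n_max = 2L, p_max = 2L,
                                  q_max = 2L)), 7L)
})

test_that("the report round-trips scalar hit fields and honors species order", {
  fix <- screenFixture()
  res <- screenGenes(fix$genomes, fix$refSpecies, fix$source,
                     classicPredicate, fixtureSets(fix), presenceParams())
  f <- withr::local_tempfile(fileext = ".tsv")
  writeResults(res, f)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  hits <- screenHits(res)
  expect_equal(nrow(back), nrow(hits))
  expect_identical(back$gene_id, hits$gene_id)
  expect_equal(back$m_max, hits$m_max)
  expect_equal(back$s_index, hits$s_index)
  expect_equal(back$start, hits$start)
  expect_true(all(res@speciesOrder %in% names(back)))
  # orthologs of a hit are reported per species; the gene was planted as
  # lost in the upper species, so those columns are empty
  expect_true(all(back$upper_glires_01 %in% c("", NA)))
  expect_true(all(nzchar(back$lower_glires_01)))
  # empty screens still produce a header-only file
  res0 <- screenGenes(fix$genomes, fix$refSpecies, fix$source,
                      "absent_in(LOWER_GLIRES, 11)", fixtureSets(fix),
                      presenceParams())
  f0 <- withr::local_tempfile(fileext = ".tsv")
  writeResults(res0, f0)
  expect_length(readLines(f0), 1L)
})

test_that("the witness-block report lists confirming pairs for present calls", {
  fix <- screenFixture()
  res <- screenGenes(fix$genomes, fix$refSpecies, fix$source,
                     classicPredicate, fixtureSets(fix), presenceParams())
  f <- withr::local_tempfile(fileext = ".tsv")
  writeResults(res, f, includeBlocks = TRUE, genomes = fix$genomes,
               sources = fix$source)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_true("lower_glires_01_block" %in% names(back))
  expect_true(all(grepl(":", back$lower_glires_01_block)))
  expect_true(all(back$upper_glires_01_block %in% c("", NA)))
})

test_that("the screen result is identical for any worker count", {
  fix <- screenFixture()
  sets <- fixtureSets(fix)
  r1 <- screenGenes(fix$genomes, fix$refSpecies, fix$source,
                    classicPredicate, sets, presenceParams(), jobs = 1L)
  r2 <- screenGenes(fix$genomes, fix$refSpecies, fix$source,
                    classicPredicate, sets, presenceParams(), jobs = 2L)
  expect_identical(screenHits(r1), screenHits(r2))
  expect_identical(presenceCalls(r1), presenceCalls(r2))
})

test_that("a config-driven run reproduces the in-memory screen", {
  fix <- screenFixture()
  dir <- withr::local_tempdir()
  writeFixture(fix, dir, predicate = classicPredicate)
  res <- runScreen(file.path(dir, "config.ini"))
  expect_true(file.exists(file.path(dir, "hits.tsv")))
  inMem <- screenGenes(fix$genomes, fix$refSpecies, fix$source,
                       classicPredicate, fixtureSets(fix),
                       presenceParams())
  expect_identical(screenHits(res)$gene_id, screenHits(inMem)$gene_id)
  expect_error(runScreen(tempfile()), "not found")
  expect_error(screenGenes(fix$genomes, fix$refSpecies, list(),
                           classicPredicate, fixtureSets(fix)),
               "at least one homology source")
})
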