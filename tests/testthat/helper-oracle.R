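# Independent brute-force oracles and random-instance generators.
# Everything here works on plain data.frames in the table dialects and
# never calls into the package's presence machinery, so that the oracles
# stay independent of the code paths they check.

strandNum <- function(s) ifelse(as.character(s) %in% c("+", "1", "+1"),
                                1L, -1L)

# symmetric partner scan over a raw pair table
oraclePartners <- function(pairs, gene, spFrom, spTo) {
  if (is.null(pairs) || !nrow(pairs)) return(character())
  h1 <- pairs$species_a == spFrom & pairs$gene_a == gene &
    pairs$species_b == spTo
  h2 <- pairs$species_b == spFrom & pairs$gene_b == gene &
    pairs$species_a == spTo
  unique(c(pairs$gene_b[h1], pairs$gene_a[h2]))
}

oracleCandidates <- function(orth, para, gene, spFrom, spTo, allowPara) {
  cand <- oraclePartners(orth, gene, spFrom, spTo)
  if (spFrom == spTo) cand <- unique(c(cand, gene))
  if (allowPara) {
    for (o in cand)
      cand <- unique(c(cand, oraclePartners(para, o, spTo, spTo)))
  }
  sort(cand)
}

# exhaustive presence test: enumerate candidate orthologs, witness subsets
# and witness-counterpart assignments
oraclePresent <- function(gene, refDf, tgtDf, orth, para, params,
                          refSp, tgtSp) {
  refDf$mid <- (refDf$start + refDf$end) / 2
  tgtDf$mid <- (tgtDf$start + tgtDf$end) / 2
  g <- refDf[refDf$gene_id == gene, ]
  stopifnot(nrow(g) == 1L)
  nb <- refDf[refDf$biotype == "protein_coding" &
                refDf$gene_id != gene &
                refDf$seq_region == g$seq_region &
                abs(refDf$mid - g$mid) <= params@r, ]
  w <- params@witnesses
  if (nrow(nb) < w) return("unevaluable")
  cands <- oracleCandidates(orth, para, gene, refSp, tgtSp,
                            params@allowParalogOfOrtholog)
  cands <- intersect(cands, tgtDf$gene_id)
  for (xp in cands) {
    xpr <- tgtDf[tgtDf$gene_id == xp, ]
    opts <- lapply(seq_len(nrow(nb)), function(j) {
      y <- nb[j, ]
      yc <- oracleCandidates(orth, para, y$gene_id, refSp, tgtSp,
                             params@allowParalogOfOrtholog)
      yo <- tgtDf[tgtDf$gene_id %in% yc &
                    tgtDf$seq_region == xpr$seq_region &
                    abs(tgtDf$mid - xpr$mid) <= params@rMax, ]
      if (params@requireSameOrientation && nrow(yo))
        yo <- yo[strandNum(yo$strand) * strandNum(xpr$strand) ==
                   strandNum(y$strand) * strandNum(g$strand), ,
                 drop = FALSE]
      yo
    })
    has <- which(vapply(opts, nrow, 0L) > 0)
    if (w == 0L) return("present")
    if (length(has) < w) next
    if (!params@requireSameOrder) return("present")
    for (sub in utils::combn(has, w, simplify = FALSE)) {
      grid <- expand.grid(lapply(sub, function(j)
        seq_len(nrow(opts[[j]]))), KEEP.OUT.ATTRS = FALSE)
      for (ri in seq_len(nrow(grid))) {
        refMids <- c(g$mid, nb$mid[sub])
        tgtMids <- c(xpr$mid, vapply(seq_along(sub), function(q)
          opts[[sub[q]]]$mid[grid[ri, q][[1]]], numeric(1)))
        tm <- tgtMids[order(refMids)]
        if (all(diff(tm) > 0) || all(diff(tm) < 0)) return("present")
      }
    }
  }
  "absent"
}

# random instance: a reference genome plus one noisy target copy with
# relocations, dropped/duplicated orthologs and random paralogy
randomInstance <- function(seed, nRef = NULL) {
  set.seed(seed)
  if (is.null(nRef)) nRef <- sample(8:30, 1)
  starts <- sort(sample(seq(1e5, 5e6, by = 2.5e4), nRef))
  refDf <- data.frame(
    species = "ref",
    gene_id = sprintf("ref_%02d", seq_len(nRef)), gene_name = "",
    seq_region = sort(sample(c("c1", "c2"), nRef, replace = TRUE,
                             prob = c(.8, .2))),
    start = starts, end = starts + 9999,
    strand = sample(c(1L, -1L), nRef, TRUE),
    biotype = sample(c("protein_coding", "lncRNA"), nRef, TRUE,
                     prob = c(.85, .15)),
    stringsAsFactors = FALSE)

  # target: jittered copy; some genes relocated, some dropped
  keep <- stats::runif(nRef) > 0.15
  tgtStart <- refDf$start + round(stats::runif(nRef, -5e4, 5e4))
  reloc <- stats::runif(nRef) < 0.2
  tgtStart[reloc] <- sample(seq(1e5, 5e6, by = 2.5e4), sum(reloc))
  tgtRegion <- refDf$seq_region
  tgtRegion[stats::runif(nRef) < 0.1] <- "c3"
  tgtDf <- data.frame(
    species = "tgt",
    gene_id = sprintf("tgt_%02d", seq_len(nRef)), gene_name = "",
    seq_region = tgtRegion,
    start = pmax(tgtStart, 1), end = pmax(tgtStart, 1) + 9999,
    strand = ifelse(stats::runif(nRef) < 0.85, refDf$strand,
                    -refDf$strand),
    biotype = "protein_coding",
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  # de-duplicate accidental equal midpoints within a region
  dup <- duplicated(paste(tgtDf$seq_region, tgtDf$start))
  tgtDf <- tgtDf[!dup, , drop = FALSE]

  pairs <- data.frame(species_a = character(), gene_a = character(),
                      species_b = character(), gene_b = character(),
                      homology_type = character(),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nRef)) {
    tid <- sprintf("tgt_%02d", i)
    if (!(tid %in% tgtDf$gene_id)) next
    if (stats::runif(1) < 0.9)
      pairs <- rbind(pairs, data.frame(
        species_a = "ref", gene_a = refDf$gene_id[i], species_b = "tgt",
        gene_b = tid, homology_type = "ortholog_one2one",
        stringsAsFactors = FALSE))
  }
  # a few scrambled orthologs and paralog pairs
  nExtra <- sample(0:4, 1)
  if (nExtra && nrow(tgtDf) > 1) {
    pairs <- rbind(pairs, data.frame(
      species_a = "ref",
      gene_a = sample(refDf$gene_id, nExtra, replace = TRUE),
      species_b = "tgt",
      gene_b = sample(tgtDf$gene_id, nExtra, replace = TRUE),
      homology_type = "ortholog_one2many", stringsAsFactors = FALSE))
  }
  nPara <- sample(0:5, 1)
  if (nPara && nrow(tgtDf) > 1) {
    pairs <- rbind(pairs, data.frame(
      species_a = "tgt",
      gene_a = sample(tgtDf$gene_id, nPara, replace = TRUE),
      species_b = "tgt",
      gene_b = sample(tgtDf$gene_id, nPara, replace = TRUE),
      homology_type = "within_species_paralog", stringsAsFactors = FALSE))
    pairs <- pairs[!(pairs$homology_type == "within_species_paralog" &
                       pairs$gene_a == pairs$gene_b), , drop = FALSE]
  }

  rMaxVal <- sample(c(3e5, 6e5, 1e6), 1)
  params <- presenceParams(
    r = sample(c(3e5, 6e5, 1e6), 1),
    rMax = rMaxVal,
    rMin = rMaxVal * sample(c(0.5, 1), 1),
    witnesses = sample(0:3, 1),
    allowParalogOfOrtholog = stats::runif(1) < 0.5,
    requireSameOrder = stats::runif(1) < 0.4,
    requireSameOrientation = stats::runif(1) < 0.4,
    scanRPrime = stats::runif(1) < 0.3)

  list(refDf = refDf, tgtDf = tgtDf, pairs = pairs, params = params,
       genomes = list(ref = GeneTable("ref", refDf),
                      tgt = GeneTable("tgt", tgtDf)),
       source = HomologySource("rand", pairs))
}

# small deterministic two-species toy used across files: perfect synteny
# except gene x4 deleted in the target
toyGenomes <- function() {
  starts <- seq(1e5, by = 2e5, length.out = 8)
  refDf <- data.frame(
    species = "ref", gene_id = sprintf("x%d", 1:8),
    gene_name = sprintf("X%d", 1:8), seq_region = "chr1",
    start = starts, end = starts + 9999,
    strand = rep(c(1L, -1L), 4), biotype = "protein_coding",
    stringsAsFactors = FALSE)
  keep <- setdiff(1:8, 4)
  tgtDf <- refDf[keep, ]
  tgtDf$species <- "tgt"
  tgtDf$gene_id <- sprintf("y%d", keep)
  pairs <- data.frame(
    species_a = "ref", gene_a = sprintf("x%d", keep),
    species_b = "tgt", gene_b = sprintf("y%d", keep),
    homology_type = "ortholog_one2one", stringsAsFactors = FALSE)
  list(refDf = refDf, tgtDf = tgtDf, pairs = pairs,
       genomes = list(ref = GeneTable("ref", refDf),
                      tgt = GeneTable("tgt", tgtDf)),
       source = HomologySource("toy", pairs))
}
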