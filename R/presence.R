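# The elementary synteny-confirmed presence test.
#
# A reference gene X is present in a target species when
#   (i)  the target carries a candidate counterpart X' (an ortholog of X of
#        any type, optionally extended by target-side paralogs of those
#        orthologs), and
#   (ii) at least `witnesses` distinct protein-coding reference genes Y
#        within r of X have a candidate counterpart Y' within r' of X' in
#        the target.
# If (i) or (ii) fails the gene is called absent (lost).  When X has fewer
# than `witnesses` protein-coding neighbours within r on the reference side
# (short contig / contig boundary), no target genome could ever satisfy
# (ii); such genes are called `unevaluable` and excluded from loss calls by
# default.

#' Candidate counterparts of a gene in a target species
#'
#' Returns the orthologs (of any homology type) of `gene` in `speciesTo`;
#' with `allowParalogOfOrtholog = TRUE`, additionally the target-species
#' paralogs of those orthologs.  When `speciesFrom == speciesTo` the gene
#' itself is its own (trivial) counterpart, which makes the presence test of
#' a reference gene in the reference species itself well defined.
#'
#' @param source A [HomologySource].
#' @param gene Reference gene identifier.
#' @param speciesFrom,speciesTo Species keys.
#' @param allowParalogOfOrtholog Extend the candidate set by paralogs of
#'   orthologs (two-step closure).
#' @return Sorted character vector of target gene identifiers.
#' @export
candidateOrthologs <- function(source, gene, speciesFrom, speciesTo,
                               allowParalogOfOrtholog = FALSE) {
  stopifnot(is(source, "HomologySource"))
  orth <- orthologsOf(source, gene, speciesFrom, speciesTo)
  if (speciesFrom == speciesTo) orth <- union(orth, gene)
  if (allowParalogOfOrtholog && length(orth)) {
    extra <- unlist(lapply(orth, function(o)
      paralogsOf(source, o, speciesTo)), use.names = FALSE)
    orth <- union(orth, extra)
  }
  sort(unique(orth))
}

# Longest strictly-increasing chain (in both coordinates) over items
# (rm, tm); at most one item per reference gene is usable because items of
# one gene share rm and the chain is strict in rm.  Returns max length and
# the item indices of one best chain.
.maxChain <- function(rm, tm, items = seq_along(rm)) {
  n <- length(rm)
  if (!n) return(list(len = 0L, chain = integer()))
  o <- order(rm, tm)
  rm <- rm[o]; tm <- tm[o]
  f <- rep(1L, n); pre <- rep(0L, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      if (rm[i] < rm[j] && tm[i] < tm[j] && f[i] + 1L > f[j]) {
        f[j] <- f[i] + 1L
        pre[j] <- i
      }
    }
  }
  jbest <- which.max(f)
  chain <- integer()
  j <- jbest
  while (j > 0L) { chain <- c(j, chain); j <- pre[j] }
  list(len = f[jbest], chain = items[o][chain])
}

# Witness test for one candidate ortholog xp at target radius rp.
# nbRows: reference rows of the witnesses; wCands: per-witness candidate
# counterpart ids.  Returns NULL (failed) or a data.frame of witness pairs.
.witnessSupport <- function(xi, xpRow, nbRows, wCands, refIdx, tgtIdx,
                            params, rp) {
  w <- params@witnesses
  xpRegion <- tgtIdx$region[xpRow]
  xpMid <- tgtIdx$mid[xpRow]
  relX <- refIdx$strand[xi] * tgtIdx$strand[xpRow]

  itGene <- integer(); itRm <- numeric(); itTm <- numeric()
  itRef <- character(); itTgt <- character()
  for (j in seq_along(nbRows)) {
    yRow <- nbRows[j]
    cand <- wCands[[j]]
    if (!length(cand)) next
    kRows <- unname(tgtIdx$row[cand])
    kRows <- kRows[!is.na(kRows)]
    kRows <- kRows[tgtIdx$region[kRows] == xpRegion &
                     abs(tgtIdx$mid[kRows] - xpMid) <= rp]
    if (params@requireSameOrientation && length(kRows))
      kRows <- kRows[refIdx$strand[yRow] * tgtIdx$strand[kRows] == relX]
    if (!length(kRows)) next
    itGene <- c(itGene, rep(j, length(kRows)))
    itRm <- c(itRm, rep(refIdx$mid[yRow], length(kRows)))
    itTm <- c(itTm, tgtIdx$mid[kRows])
    itRef <- c(itRef, rep(refIdx$id[yRow], length(kRows)))
    itTgt <- c(itTgt, tgtIdx$id[kRows])
  }
  if (!length(itGene)) {
    if (w == 0L)
      return(data.frame(ref_gene = character(), target_gene = character(),
                        stringsAsFactors = FALSE))
    return(NULL)
  }

  if (!params@requireSameOrder) {
    firstOfGene <- !duplicated(itGene)
    if (sum(firstOfGene) < w) return(NULL)
    return(data.frame(ref_gene = itRef[firstOfGene],
                      target_gene = itTgt[firstOfGene],
                      stringsAsFactors = FALSE))
  }

  # order-preserving witnesses: a strict midpoint chain through (X, X'),
  # evaluated in the direct and the globally inverted orientation
  xr <- refIdx$mid[xi]
  bestPairs <- NULL; bestLen <- -1L
  for (dir in c(1, -1)) {
    tmd <- dir * itTm
    xtd <- dir * xpMid
    left <- which(itRm < xr & tmd < xtd)
    right <- which(itRm > xr & tmd > xtd)
    l <- .maxChain(itRm[left], tmd[left], left)
    r <- .maxChain(itRm[right], tmd[right], right)
    if (l$len + r$len > bestLen) {
      bestLen <- l$len + r$len
      sel <- c(l$chain, r$chain)
      bestPairs <- data.frame(ref_gene = itRef[sel],
                              target_gene = itTgt[sel],
                              stringsAsFactors = FALSE)
    }
  }
  if (bestLen >= w) bestPairs else NULL
}

# status computation shared by isPresent() and presenceMatrix()
.presenceStatus <- function(geneId, refIdx, tgtIdx, source, params,
                            refSpecies, tgtSpecies) {
  xi <- unname(refIdx$row[geneId])
  if (is.na(xi))
    stop("gene '", geneId, "' not found in reference species '",
         refSpecies, "'")
  nbRows <- .neighborRows(refIdx, xi, params@r)
  if (length(nbRows) < params@witnesses)
    return(list(status = "unevaluable", ortholog = "",
                pairs = .emptyPairs()))
  cands <- candidateOrthologs(source, geneId, refSpecies, tgtSpecies,
                              params@allowParalogOfOrtholog)
  cands <- cands[!is.na(tgtIdx$row[cands])]
  if (!length(cands))
    return(list(status = "absent", ortholog = "", pairs = .emptyPairs()))
  wCands <- lapply(refIdx$id[nbRows], function(y)
    candidateOrthologs(source, y, refSpecies, tgtSpecies,
                       params@allowParalogOfOrtholog))
  rGrid <- if (params@scanRPrime)
    sort(unique(seq(params@rMin, params@rMax, length.out = 5L)))
  else params@rMax
  for (rp in rGrid) {
    for (xp in cands) {
      pairs <- .witnessSupport(xi, unname(tgtIdx$row[xp]), nbRows, wCands,
                               refIdx, tgtIdx, params, rp)
      if (!is.null(pairs))
        return(list(status = "present", ortholog = xp, pairs = pairs))
    }
  }
  list(status = "absent", ortholog = "", pairs = .emptyPairs())
}

.emptyPairs <- function() {
  data.frame(ref_gene = character(), target_gene = character(),
             stringsAsFactors = FALSE)
}

#' Elementary synteny-confirmed presence test
#'
#' Tests whether reference gene `gene` is present in target species
#' `species` under homology `source` and parameters `params` (see
#' [presenceParams()]): present iff some candidate ortholog exists and at
#' least `witnesses` distinct neighbouring reference genes have candidate
#' counterparts near it.  Genes with fewer protein-coding neighbours within
#' `r` than the required witness count are `unevaluable`.
#'
#' @param gene Reference gene identifier (protein-coding).
#' @param species Target species key (a name of `genomes`); testing against
#'   the reference species itself yields `present` whenever enough
#'   neighbours exist, since every gene is its own trivial counterpart.
#' @param source A [HomologySource].
#' @param params A [PresenceParams][presenceParams()].
#' @param genomes Named list of [GeneTable]s, including the reference.
#' @param refSpecies Reference species key.
#' @return A [PresenceCall-class] object.
#' @export
isPresent <- function(gene, species, source, params, genomes, refSpecies) {
  stopifnot(is(source, "HomologySource"), is(params, "PresenceParams"))
  refTab <- genomes[[refSpecies]]
  tgtTab <- genomes[[species]]
  if (is.null(refTab)) stop("no gene table loaded for reference species '",
                            refSpecies, "'")
  if (is.null(tgtTab)) stop("no gene table loaded for species '", species,
                            "'")
  res <- .presenceStatus(gene, .geneIndex(refTab), .geneIndex(tgtTab),
                         source, params, refSpecies, species)
  new("PresenceCall", geneId = gene, species = species,
      status = res$status, orthologUsed = res$ortholog,
      witnessPairs = res$pairs)
}

#' Presence calls for many genes across many species
#'
#' Runs the elementary presence test for each gene in `genes` against each
#' species in `targets` and returns the calls as matrices.
#'
#' @inheritParams isPresent
#' @param genes Reference gene identifiers; default: all protein-coding
#'   genes of the reference, sorted by id.
#' @param targets Target species keys; default: all loaded species other
#'   than the reference.
#' @param jobs Number of worker processes (forked); results are identical
#'   for any value.
#' @return A list with `status` (character matrix genes x species with
#'   values present/absent/unevaluable) and `ortholog` (matrix of the
#'   target gene id used for each present call, `""` otherwise).
#' @export
presenceMatrix <- function(genomes, refSpecies, source, params,
                           genes = NULL, targets = NULL, jobs = 1L) {
  refTab <- genomes[[refSpecies]]
  if (is.null(refTab)) stop("no gene table loaded for reference species '",
                            refSpecies, "'")
  refIdx <- .geneIndex(refTab)
  if (is.null(genes))
    genes <- sort(refIdx$id[refIdx$coding])
  if (is.null(targets))
    targets <- setdiff(names(genomes), refSpecies)
  for (sp in targets)
    if (is.null(genomes[[sp]]))
      stop("no gene table loaded for species '", sp, "'")
  tgtIdx <- lapply(genomes[targets], .geneIndex)

  oneGene <- function(g) {
    st <- character(length(targets))
    or <- character(length(targets))
    for (k in seq_along(targets)) {
      res <- .presenceStatus(g, refIdx, tgtIdx[[k]], source, params,
                             refSpecies, targets[k])
      st[k] <- res$status
      or[k] <- res$ortholog
    }
    list(st = st, or = or)
  }
  rows <- if (jobs > 1L)
    parallel::mclapply(genes, oneGene, mc.cores = jobs)
  else lapply(genes, oneGene)

  status <- do.call(rbind, lapply(rows, `[[`, "st"))
  ortho <- do.call(rbind, lapply(rows, `[[`, "or"))
  dimnames(status) <- dimnames(ortho) <- list(genes, targets)
  list(status = status, ortholog = ortho)
}
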