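# Whole-genome screen: every protein-coding reference gene is tried against
# the predicate under each homology source; a gene becomes a hit when at
# least `minVotes` sources agree.  Per-gene maximal thresholds and the
# quality index are computed from the primary (first) source's calls.

# parameter lookup for a set: `params` is a single PresenceParams applying
# globally, or a named list keyed by set name (with an optional `.default`)
.paramsFor <- function(params, setName) {
  if (is(params, "PresenceParams")) return(params)
  p <- params[[setName]]
  if (is.null(p)) p <- params[[".default"]]
  if (is.null(p))
    stop("no presence parameters declared for set '", setName,
         "' and no '.default' entry")
  p
}

.paramsKey <- function(p) {
  paste(p@r, p@rMax, p@rMin, p@witnesses, p@allowParalogOfOrtholog,
        p@requireSameOrder, p@requireSameOrientation, p@scanRPrime,
        sep = "|")
}

#' Screen all reference genes for predicate-satisfying losses
#'
#' Drives the scan over all protein-coding genes of the reference species:
#' presence calls are computed per homology source, the gene-selection
#' predicate is evaluated per source, and genes supported by at least
#' `minVotes` sources become hits.  For each hit the maximal thresholds and
#' the quality index are computed from the primary (first) source.
#'
#' Genes that are `unevaluable` in some species (too few reference-side
#' neighbours within `r`) contribute to neither the present nor the absent
#' count of a set under the default three-valued policy; they are listed in
#' the `unevaluable` side table of the result.
#'
#' @param genomes Named list of [GeneTable]s (reference included).
#' @param refSpecies Reference species key.
#' @param sources A [HomologySource] or list of them; the first is the
#'   primary source used for reporting.
#' @param predicate Predicate text or a parsed AST (see [parsePredicate()]).
#' @param sets Named list of [SpeciesSet][speciesSet()] objects.
#' @param params A [PresenceParams][presenceParams()] applied globally, or a
#'   named list keyed by set name (optionally with a `.default` entry).
#' @param minVotes Number of sources that must support the predicate for a
#'   hit (a [votingPolicy()] may be given instead).
#' @param thresholdSets Named list describing the threshold dimensions, each
#'   entry `list(set = <set name>, mode = "absent"|"present")`; defaults to
#'   the classic four dimensions when sets named `UPPER_GLIRES`,
#'   `UPPER_PRIMATES`, `LOWER_GLIRES`, `LOWER_PRIMATES` are declared, else
#'   no thresholds.  The per-hit maxima of these counts and their sum (the
#'   quality index S) are reported.
#' @param strictTwoValued Collapse `unevaluable` calls to `absent`.
#' @param jobs Worker processes for the presence matrices; the result is
#'   identical for any value.
#' @return A [ScreenResult-class].
#' @examples
#' fix <- generateFixture(fixtureSpec(
#'   upperCounts = c(g = 2L), lowerCounts = c(g = 2L),
#'   nContigs = 1L, genesPerContig = 10L,
#'   plantedLosses = list(list(gene = 4L,
#'     species = c("upper_g_01", "upper_g_02")))))
#' sets <- fixtureSets(fix)
#' res <- screenGenes(fix$genomes, fix$refSpecies, fix$source,
#'   "absent_in(UPPER_G, 2) and present_in(LOWER_G, 2)",
#'   sets, presenceParams(witnesses = 2))
#' screenHits(res)$gene_id
#' @export
screenGenes <- function(genomes, refSpecies, sources, predicate, sets,
                        params = presenceParams(), minVotes = 1L,
                        thresholdSets = NULL, strictTwoValued = FALSE,
                        jobs = 1L) {
  if (is(sources, "HomologySource")) sources <- list(sources)
  if (!length(sources)) stop("at least one homology source is required")
  if (is.null(genomes[[refSpecies]]))
    stop("no gene table loaded for reference species '", refSpecies, "'")
  if (is(minVotes, "VotingPolicy")) {
    if (minVotes@nSources != length(sources))
      stop("voting policy declares ", minVotes@nSources,
           " sources but ", length(sources), " were supplied")
    minVotes <- minVotes@minVotes
  }
  minVotes <- as.integer(minVotes)
  if (minVotes < 1L || minVotes > length(sources))
    stop("need 1 <= minVotes <= number of sources")

  ast <- if (is.character(predicate)) parsePredicate(predicate, sets)
         else predicate
  usedSets <- .astSets(ast)
  for (s in usedSets) {
    if (is.null(sets[[s]]))
      stop("predicate references undeclared set '", s, "'")
    missing <- setdiff(sets[[s]]@members, names(genomes))
    if (length(missing))
      stop("set '", s, "' references species without gene tables: ",
           paste(missing, collapse = ", "))
  }
  if (is.null(thresholdSets))
    thresholdSets <- .defaultThresholdSets(sets)
  for (ts in thresholdSets)
    if (is.null(sets[[ts$set]]))
      stop("thresholdSets references undeclared set '", ts$set, "'")

  refIdx <- .geneIndex(genomes[[refSpecies]])
  genes <- sort(refIdx$id[refIdx$coding])

  # presence matrices per source and per distinct parameter setting,
  # restricted to the species each setting actually governs
  allSetNames <- union(usedSets, vapply(thresholdSets, `[[`, "",
                                        "set"))
  paramOfSet <- lapply(stats::setNames(allSetNames, allSetNames),
                       function(s) .paramsFor(params, s))
  keyOfSet <- vapply(paramOfSet, .paramsKey, character(1))
  matrices <- lapply(sources, function(src) {
    byKey <- list()
    for (key in unique(keyOfSet)) {
      setsHere <- allSetNames[keyOfSet == key]
      species <- unique(unlist(lapply(sets[setsHere],
                                      function(s) s@members)))
      byKey[[key]] <- presenceMatrix(
        genomes, refSpecies, src, paramOfSet[[setsHere[1]]],
        genes = genes, targets = species, jobs = jobs)
    }
    byKey
  })

  # per-source predicate verdicts
  verdicts <- matrix(FALSE, nrow = length(genes), ncol = length(sources),
                     dimnames = list(genes, NULL))
  for (si in seq_along(sources)) {
    byKey <- matrices[[si]]
    for (g in genes) {
      atomFn <- function(node) {
        set <- sets[[node$set]]
        st <- .effectiveStatus(
          byKey[[keyOfSet[[node$set]]]]$status[g, set@members],
          strictTwoValued)
        if (node$op == "present") sum(st == "present") >= node$k
        else sum(st == "absent") >= node$k
      }
      verdicts[g, si] <- .evalAST(ast, atomFn)
    }
  }
  hitIds <- genes[rowSums(verdicts) >= minVotes]

  # reporting uses the primary source
  primary <- matrices[[1L]]
  allSpecies <- sort(unique(unlist(lapply(sets[allSetNames],
                                          function(s) s@members))))
  status <- matrix("", nrow = length(genes), ncol = length(allSpecies),
                   dimnames = list(genes, allSpecies))
  ortho <- status
  for (sp in allSpecies) {
    # a species may be governed by several settings; report the first
    # threshold/predicate set that contains it
    owner <- allSetNames[vapply(sets[allSetNames],
                                function(s) sp %in% s@members,
                                logical(1))][1L]
    mat <- primary[[keyOfSet[[owner]]]]
    status[, sp] <- mat$status[genes, sp]
    ortho[, sp] <- mat$ortholog[genes, sp]
  }

  thr <- .thresholdCounts(hitIds, status, sets, thresholdSets,
                          strictTwoValued)
  hitRows <- match(hitIds, refIdx$id)
  hits <- data.frame(
    gene_id = hitIds,
    postprocessing = rep("", length(hitIds)),
    stringsAsFactors = FALSE)
  hits <- cbind(hits, thr)
  hits$s_index <- if (ncol(thr)) rowSums(thr) else integer(length(hitIds))
  hits$seq_region <- refIdx$region[hitRows]
  hits$start <- refIdx$start[hitRows]
  hits$end <- refIdx$end[hitRows]
  hits$strand <- refIdx$strand[hitRows]
  m <- S4Vectors::mcols(genomes[[refSpecies]]@genes)
  hits$gene_name <- m$gene_name[hitRows]
  hits$description <- m$description[hitRows]
  rownames(hits) <- NULL

  orthoHits <- as.data.frame(ortho[hitIds, , drop = FALSE],
                             stringsAsFactors = FALSE)
  orthoHits <- cbind(data.frame(gene_id = hitIds,
                                stringsAsFactors = FALSE), orthoHits)
  rownames(orthoHits) <- NULL

  unev <- which(status == "unevaluable", arr.ind = TRUE)
  unevaluable <- data.frame(
    gene_id = rownames(status)[unev[, 1]],
    species = colnames(status)[unev[, 2]],
    stringsAsFactors = FALSE)
  unevaluable <- unevaluable[order(unevaluable$gene_id,
                                   unevaluable$species), , drop = FALSE]
  rownames(unevaluable) <- NULL

  new("ScreenResult", hits = hits, calls = status,
      orthologs = orthoHits, unevaluable = unevaluable,
      refSpecies = refSpecies, speciesOrder = allSpecies,
      predicate = unparsePredicate(ast), nSources = length(sources),
      minVotes = minVotes, witnesses = list())
}

.defaultThresholdSets <- function(sets) {
  classic <- c(m = "UPPER_GLIRES", n = "UPPER_PRIMATES",
               p = "LOWER_GLIRES", q = "LOWER_PRIMATES")
  if (!all(classic %in% names(sets))) return(list())
  modes <- c(m = "absent", n = "absent", p = "present", q = "present")
  out <- lapply(names(classic), function(d)
    list(set = classic[[d]], mode = modes[[d]]))
  names(out) <- names(classic)
  out
}

.thresholdCounts <- function(geneIds, status, sets, thresholdSets,
                             strictTwoValued = FALSE) {
  if (!length(thresholdSets))
    return(data.frame(row.names = seq_along(geneIds))[, FALSE])
  out <- lapply(names(thresholdSets), function(d) {
    ts <- thresholdSets[[d]]
    members <- sets[[ts$set]]@members
    vapply(geneIds, function(g) {
      st <- .effectiveStatus(status[g, members], strictTwoValued)
      sum(st == ts$mode)
    }, integer(1))
  })
  names(out) <- paste0(names(thresholdSets), "_max")
  as.data.frame(out, row.names = NULL, stringsAsFactors = FALSE)
}

#' Maximal thresholds at which a hit is still identified
#'
#' For a gene already identified at the configured thresholds, the maximal
#' threshold in each dimension is simply the count of qualifying species in
#' that dimension (absent species for an "absent in at least k" dimension,
#' present species for a "present" one), because the set-level conditions
#' are monotone in k.
#'
#' @param gene Reference gene identifier.
#' @param calls Status matrix (genes x species) or [presenceMatrix()]
#'   result.
#' @param sets Named list of [SpeciesSet][speciesSet()] objects.
#' @param thresholdSets Named list of `list(set =, mode =)` dimensions, as
#'   in [screenGenes()].
#' @param strictTwoValued Collapse `unevaluable` to `absent`.
#' @return Named integer vector of per-dimension maxima (names
#'   `<dim>_max`).
#' @export
maxThresholds <- function(gene, calls, sets,
                          thresholdSets = .defaultThresholdSets(sets),
                          strictTwoValued = FALSE) {
  if (is.list(calls) && !is.null(calls$status)) calls <- calls$status
  df <- .thresholdCounts(gene, calls, sets, thresholdSets,
                         strictTwoValued)
  stats::setNames(as.integer(df[1L, ]), colnames(df))
}

#' Quality index of a prediction
#'
#' The sum S of the per-dimension maximal thresholds (e.g.
#' `m_max + n_max + p_max + q_max`): the total number of upper species
#' lacking plus lower species retaining the gene.  Higher S means a more
#' robust prediction.
#'
#' @param hit A named vector as returned by [maxThresholds()], or a one-row
#'   slice of `screenHits()` containing `*_max` columns.
#' @return Integer S.
#' @examples
#' qualityIndex(c(m_max = 3L, n_max = 7L, p_max = 11L, q_max = 10L))
#' @export
qualityIndex <- function(hit) {
  if (is.data.frame(hit)) {
    stopifnot(nrow(hit) == 1L)
    hit <- unlist(hit[grepl("_max$", names(hit))])
  }
  as.integer(sum(hit[grepl("_max$", names(hit))]))
}

#' Write screen results as a tab-separated report
#'
#' One row per hit, sorted by gene id: gene id, a free-text postprocessing
#' flag column (written empty; reserved for manual curation), the
#' per-dimension maximal thresholds, coordinates, name and description, then
#' one column per non-reference species listing the ortholog id(s) used.
#' With `includeBlocks = TRUE` the confirming witness pairs (the synteny
#' block) are appended per species.
#'
#' @param result A [ScreenResult-class].
#' @param path Output path.
#' @param includeBlocks Append witness-block columns (requires the screen to
#'   have been run through [screenGenes()] with default reporting; blocks
#'   are recomputed on demand from the stored calls if absent).
#' @param genomes,sources Needed only when `includeBlocks = TRUE`:
#'   the gene tables and the primary [HomologySource] used for the screen.
#' @param params Presence parameters used when recomputing blocks.
#' @return `path`, invisibly.
#' @export
writeResults <- function(result, path, includeBlocks = FALSE,
                         genomes = NULL, sources = NULL,
                         params = presenceParams()) {
  stopifnot(is(result, "ScreenResult"))
  hits <- result@hits
  scalarCols <- c("gene_id", "postprocessing",
                  grep("_max$", names(hits), value = TRUE),
                  "s_index", "seq_region", "start", "end", "strand",
                  "gene_name", "description")
  out <- hits[, scalarCols, drop = FALSE]
  orth <- result@orthologs
  for (sp in result@speciesOrder)
    out[[sp]] <- if (nrow(out)) orth[[sp]] else character()
  if (includeBlocks) {
    if (is.null(genomes) || is.null(sources))
      stop("includeBlocks = TRUE requires 'genomes' and 'sources'")
    src <- if (is(sources, "HomologySource")) sources else sources[[1L]]
    for (sp in result@speciesOrder) {
      out[[paste0(sp, "_block")]] <- vapply(out$gene_id, function(g) {
        call <- isPresent(g, sp, src, params, genomes, result@refSpecies)
        if (call@status != "present") return("")
        paste(paste0(call@witnessPairs$ref_gene, ":",
                     call@witnessPairs$target_gene), collapse = ",")
      }, character(1))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
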