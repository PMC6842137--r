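# S4 classes for the screen: annotation tables, homology sources, the
# parameters of the elementary presence test, species sets and results.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Per-species gene annotation table
#'
#' A `GeneTable` holds the flattened gene annotation of one species as a
#' [GenomicRanges::GRanges] (one range per gene) with metadata columns
#' `gene_id`, `gene_name`, `biotype` and `description`.  Coordinates are
#' 1-based inclusive; strand is stored as `+`/`-`.  Gene identifiers must be
#' unique within a species.
#'
#' Only `biotype == "protein_coding"` genes act as screened genes and as
#' synteny witnesses; other biotypes are retained but ignored by
#' [neighborGenes()].
#'
#' @param species Species key (single string).
#' @param records A data.frame with columns `gene_id`, `seq_region`, `start`,
#'   `end`, `strand`, and optionally `gene_name`, `biotype`, `description`.
#'   Strand may be given as `+`/`-`/`1`/`-1`/`+1`.
#' @param x A `GeneTable`.
#'
#' @return `GeneTable()` returns a validated `GeneTable` object;
#'   `speciesKey()` its species key, `geneIds()` the character vector of gene
#'   identifiers, `nGenes()` the number of genes and `geneRanges()` the
#'   underlying `GRanges`.
#'
#' @examples
#' gt <- GeneTable("mouse", data.frame(
#'   gene_id = c("g1", "g2"), seq_region = "1",
#'   start = c(100, 5000), end = c(1100, 6000),
#'   strand = c("+", "-"), biotype = "protein_coding"))
#' nGenes(gt)
#' @aliases speciesKey geneIds nGenes geneRanges
#' @export
GeneTable <- function(species, records) {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("gene_id", "seq_region", "start", "end", "strand")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    stop("gene table for '", species, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(records$gene_name)) records$gene_name <- ""
  if (is.null(records$biotype)) records$biotype <- "protein_coding"
  if (is.null(records$description)) records$description <- ""
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(records$seq_region),
    ranges = IRanges::IRanges(start = as.numeric(records$start),
                              end = as.numeric(records$end)),
    strand = .parseStrandChar(records$strand))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = as.character(records$gene_id),
    gene_name = as.character(records$gene_name),
    biotype = as.character(records$biotype),
    description = as.character(records$description))
  new("GeneTable", species = species, genes = gr)
}

setClass("GeneTable", slots = c(species = "character", genes = "GRanges"))

setValidity("GeneTable", function(object) {
  msg <- character()
  if (length(object@species) != 1L || !nzchar(object@species))
    msg <- c(msg, "'species' must be a single non-empty string")
  m <- S4Vectors::mcols(object@genes)
  for (col in c("gene_id", "gene_name", "biotype", "description"))
    if (!col %in% colnames(m))
      msg <- c(msg, paste0("metadata column '", col, "' is missing"))
  if ("gene_id" %in% colnames(m) && anyDuplicated(m$gene_id))
    msg <- c(msg, "gene_id values must be unique within a species")
  if (length(object@genes) && any(GenomicRanges::start(object@genes) < 1))
    msg <- c(msg, "gene start coordinates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneTable
#' @export
setMethod("speciesKey", "GeneTable", function(x) x@species)

#' @rdname GeneTable
#' @export
setMethod("geneIds", "GeneTable",
          function(x) S4Vectors::mcols(x@genes)$gene_id)

#' @rdname GeneTable
#' @export
setMethod("nGenes", "GeneTable", function(x) length(x@genes))

#' @rdname GeneTable
#' @export
setMethod("geneRanges", "GeneTable", function(x) x@genes)

setMethod("show", "GeneTable", function(object) {
  m <- S4Vectors::mcols(object@genes)
  cat("GeneTable for species '", object@species, "': ",
      length(object@genes), " genes (",
      sum(m$biotype == "protein_coding"), " protein_coding) on ",
      length(unique(as.character(GenomicRanges::seqnames(object@genes)))),
      " sequence region(s)\n", sep = "")
})

#' One orthology-inference result: ortholog and paralog pair tables
#'
#' A `HomologySource` stores the output of a single orthology inference
#' method as two symmetric pair tables: between-species ortholog pairs of any
#' type (`ortholog_one2one`, `ortholog_one2many`, `ortholog_many2many`) and
#' within-species paralog pairs (`within_species_paralog`).  Pairs are
#' symmetrized on construction (querying `(a, b)` and `(b, a)` gives the same
#' answer), duplicates are collapsed, and rows of unknown homology type,
#' ortholog rows within one species, paralog rows across species, and pairs
#' referencing genes missing from the supplied gene tables are dropped with a
#' message (real homology dumps routinely lag annotation, so such rows are
#' not fatal).
#'
#' @param name Label for the orthology-inference method.
#' @param pairs data.frame with columns `species_a`, `gene_a`, `species_b`,
#'   `gene_b`, `homology_type`.
#' @param genomes Optional named list of [GeneTable] objects; when given,
#'   pairs mentioning genes absent from them are dropped (and counted in a
#'   message).
#' @param x A `HomologySource`.
#' @return A validated `HomologySource`.
#' @examples
#' src <- HomologySource("demo", data.frame(
#'   species_a = "mouse", gene_a = "g1",
#'   species_b = "rat", gene_b = "r1",
#'   homology_type = "ortholog_one2one"))
#' orthologsOf(src, "r1", "rat", "mouse")
#' @aliases sourceName
#' @export
HomologySource <- function(name, pairs, genomes = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  needed <- c("species_a", "gene_a", "species_b", "gene_b", "homology_type")
  miss <- setdiff(needed, names(pairs))
  if (length(miss))
    stop("homology table '", name, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  for (col in needed) pairs[[col]] <- as.character(pairs[[col]])

  known <- c("ortholog_one2one", "ortholog_one2many", "ortholog_many2many",
             "within_species_paralog")
  bad <- !(pairs$homology_type %in% known)
  if (any(bad)) {
    message("homology source '", name, "': dropped ", sum(bad),
            " pair(s) with unknown homology_type")
    pairs <- pairs[!bad, , drop = FALSE]
  }
  isPara <- pairs$homology_type == "within_species_paralog"
  badOrtho <- !isPara & pairs$species_a == pairs$species_b
  badPara <- isPara & pairs$species_a != pairs$species_b
  if (any(badOrtho | badPara)) {
    message("homology source '", name, "': dropped ",
            sum(badOrtho | badPara),
            " pair(s) violating the ortholog/paralog species rule")
    keep <- !(badOrtho | badPara)
    pairs <- pairs[keep, , drop = FALSE]
    isPara <- isPara[keep]
  }
  if (!is.null(genomes)) {
    knownGene <- function(sp, g) {
      gt <- genomes[[sp]]
      !is.null(gt) & !is.na(match(g, geneIds(gt)))
    }
    okA <- vapply(seq_len(nrow(pairs)), function(i)
      knownGene(pairs$species_a[i], pairs$gene_a[i]), logical(1))
    okB <- vapply(seq_len(nrow(pairs)), function(i)
      knownGene(pairs$species_b[i], pairs$gene_b[i]), logical(1))
    drop <- !(okA & okB)
    if (any(drop)) {
      message("homology source '", name, "': dropped ", sum(drop),
              " pair(s) referencing genes absent from the gene tables")
      pairs <- pairs[!drop, , drop = FALSE]
      isPara <- isPara[!drop]
    }
  }
  orth <- .symmetrizePairs(pairs[!isPara, , drop = FALSE])
  para <- .symmetrizePairs(pairs[isPara, , drop = FALSE])
  new("HomologySource", name = name, orthologs = orth, paralogs = para,
      orthoIndex = .pairIndex(orth, crossSpecies = TRUE),
      paraIndex = .pairIndex(para, crossSpecies = FALSE))
}

setClass("HomologySource",
         slots = c(name = "character", orthologs = "data.frame",
                   paralogs = "data.frame", orthoIndex = "environment",
                   paraIndex = "environment"))

setValidity("HomologySource", function(object) {
  msg <- character()
  if (length(object@name) != 1L)
    msg <- c(msg, "'name' must be a single string")
  if (nrow(object@orthologs) &&
      any(object@orthologs$species_a == object@orthologs$species_b))
    msg <- c(msg, "ortholog pairs must connect two distinct species")
  if (nrow(object@paralogs) &&
      any(object@paralogs$species_a != object@paralogs$species_b))
    msg <- c(msg, "paralog pairs must connect genes of one species")
  if (length(msg)) msg else TRUE
})

#' @rdname HomologySource
#' @export
setMethod("sourceName", "HomologySource", function(x) x@name)

setMethod("show", "HomologySource", function(object) {
  cat("HomologySource '", object@name, "': ",
      nrow(object@orthologs) / 2, " ortholog pair(s), ",
      nrow(object@paralogs) / 2, " paralog pair(s)\n", sep = "")
})

# Store each pair in both orientations; collapse duplicates.
.symmetrizePairs <- function(df) {
  if (!nrow(df)) {
    return(data.frame(species_a = character(), gene_a = character(),
                      species_b = character(), gene_b = character(),
                      homology_type = character(),
                      stringsAsFactors = FALSE))
  }
  swapped <- data.frame(species_a = df$species_b, gene_a = df$gene_b,
                        species_b = df$species_a, gene_b = df$gene_a,
                        homology_type = df$homology_type,
                        stringsAsFactors = FALSE)
  out <- rbind(df[, c("species_a", "gene_a", "species_b", "gene_b",
                      "homology_type")], swapped)
  key <- paste(out$species_a, out$gene_a, out$species_b, out$gene_b,
               sep = "\t")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Hash index: (species_from, gene, species_to) -> partner gene ids
# (paralogs: (species, gene) -> partners).
.pairIndex <- function(df, crossSpecies = TRUE) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(df)) {
    keys <- if (crossSpecies)
      paste(df$species_a, df$gene_a, df$species_b, sep = "\t")
    else
      paste(df$species_a, df$gene_a, sep = "\t")
    split_b <- split(df$gene_b, keys)
    for (k in names(split_b))
      assign(k, sort(unique(split_b[[k]])), envir = env)
  }
  env
}

#' Look up homologs in a HomologySource
#'
#' `orthologsOf()` returns the orthologs (of any type) of `gene` of species
#' `speciesFrom` in species `speciesTo`; `paralogsOf()` returns the
#' within-species paralogs of `gene` in `species`.  Both relations are
#' symmetric.
#'
#' @param x A [HomologySource].
#' @param gene Gene identifier.
#' @param speciesFrom,speciesTo,species Species keys.
#' @return Sorted character vector of gene identifiers (possibly empty).
#' @export
setMethod("orthologsOf", "HomologySource",
          function(x, gene, speciesFrom, speciesTo) {
  key <- paste(speciesFrom, gene, speciesTo, sep = "\t")
  if (exists(key, envir = x@orthoIndex, inherits = FALSE))
    get(key, envir = x@orthoIndex) else character()
})

#' @rdname orthologsOf
#' @export
setMethod("paralogsOf", "HomologySource", function(x, gene, species) {
  key <- paste(species, gene, sep = "\t")
  if (exists(key, envir = x@paraIndex, inherits = FALSE))
    get(key, envir = x@paraIndex) else character()
})

#' Parameters of the elementary synteny-confirmed presence test
#'
#' @param r Reference-side vicinity radius in base pairs: witnesses are
#'   protein-coding genes whose midpoints lie within `r` of the focal gene's
#'   midpoint.  Default 1 Mbp, the scale of topologically associated domains
#'   within which local synteny is conventionally judged.
#' @param rMax Target-side upper vicinity boundary (the scan boundary
#'   \eqn{r_0}) in base pairs; default 1 Mbp.
#' @param rMin Lower boundary of the target-side scan; default `rMax`
#'   (single test).
#' @param witnesses Minimum number of confirming ortholog pairs (distinct
#'   reference witness genes); default 2.
#' @param allowParalogOfOrtholog Also accept, as candidate counterparts,
#'   target-species paralogs of orthologs of the focal/witness gene.
#' @param requireSameOrder Require the chosen witnesses to preserve relative
#'   midpoint order around the focal gene (a globally inverted block still
#'   matches).
#' @param requireSameOrientation Require each witness's strand relative to
#'   the focal gene to be conserved.
#' @param scanRPrime Evaluate the presence test over a grid of target-side
#'   radii in `[rMin, rMax]` instead of the single radius `rMax`; by
#'   monotonicity the two are equivalent, and the scan exists so that this
#'   equivalence can be asserted explicitly.
#' @return A `PresenceParams` object.
#' @examples
#' presenceParams(r = 2e6, witnesses = 3)
#' @export
presenceParams <- function(r = 1e6, rMax = 1e6, rMin = rMax,
                           witnesses = 2L,
                           allowParalogOfOrtholog = FALSE,
                           requireSameOrder = FALSE,
                           requireSameOrientation = FALSE,
                           scanRPrime = FALSE) {
  new("PresenceParams", r = as.numeric(r), rMax = as.numeric(rMax),
      rMin = as.numeric(rMin), witnesses = as.integer(witnesses),
      allowParalogOfOrtholog = isTRUE(allowParalogOfOrtholog),
      requireSameOrder = isTRUE(requireSameOrder),
      requireSameOrientation = isTRUE(requireSameOrientation),
      scanRPrime = isTRUE(scanRPrime))
}

setClass("PresenceParams",
         slots = c(r = "numeric", rMax = "numeric", rMin = "numeric",
                   witnesses = "integer",
                   allowParalogOfOrtholog = "logical",
                   requireSameOrder = "logical",
                   requireSameOrientation = "logical",
                   scanRPrime = "logical"),
         prototype = list(r = 1e6, rMax = 1e6, rMin = 1e6, witnesses = 2L,
                          allowParalogOfOrtholog = FALSE,
                          requireSameOrder = FALSE,
                          requireSameOrientation = FALSE,
                          scanRPrime = FALSE))

setValidity("PresenceParams", function(object) {
  msg <- character()
  if (object@r <= 0) msg <- c(msg, "r must be > 0")
  if (object@rMin <= 0 || object@rMin > object@rMax)
    msg <- c(msg, "need 0 < rMin <= rMax")
  if (object@witnesses < 0) msg <- c(msg, "witnesses must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PresenceParams", function(object) {
  cat(sprintf(paste0(
    "PresenceParams: r=%.3g bp, r'=[%.3g, %.3g] bp, witnesses=%d\n",
    "  paralog-of-ortholog=%s, same-order=%s, same-orientation=%s, ",
    "scan-r'=%s\n"),
    object@r, object@rMin, object@rMax, object@witnesses,
    object@allowParalogOfOrtholog, object@requireSameOrder,
    object@requireSameOrientation, object@scanRPrime))
})

#' Result of one elementary presence test
#'
#' `status` is one of `present`, `absent`, `unevaluable`.  A gene is
#' `unevaluable` when it has fewer protein-coding neighbours within `r` than
#' the required witness count (short contigs, contig boundaries), so that
#' presence could never be established regardless of the target genome.
#' For a `present` call, `orthologUsed` names the target gene that satisfied
#' the test and `witnessPairs` lists the confirming (reference, target) gene
#' pairs.
#'
#' @seealso [isPresent()]
#' @export
setClass("PresenceCall",
         slots = c(geneId = "character", species = "character",
                   status = "character", orthologUsed = "character",
                   witnessPairs = "data.frame"))

setValidity("PresenceCall", function(object) {
  ok <- object@status %in% c("present", "absent", "unevaluable")
  if (!ok) return("status must be present/absent/unevaluable")
  if (object@status == "present" && !nzchar(object@orthologUsed))
    return("a present call must name the ortholog used")
  TRUE
})

setMethod("show", "PresenceCall", function(object) {
  cat("PresenceCall: gene ", object@geneId, " in ", object@species, ": ",
      object@status, sep = "")
  if (object@status == "present")
    cat(" via ", object@orthologUsed, " (", nrow(object@witnessPairs),
        " witness pair(s))", sep = "")
  cat("\n")
})

#' A named set of species with a default presence threshold
#'
#' Species sets are the leaves of the gene-selection predicate: a gene is
#' "present in set S" when it is present in at least `k` member species.
#' `defaultK` supplies `k` for predicate atoms that omit it.
#'
#' @param name Set label, used in predicate text.
#' @param members Character vector of distinct species keys (non-empty).
#' @param defaultK Default per-set threshold, `0 <= defaultK <= |members|`.
#' @return A `SpeciesSet`.
#' @examples
#' speciesSet("UPPER_GLIRES", c("nmr", "bmr", "dmr"), defaultK = 1)
#' @export
speciesSet <- function(name, members, defaultK = 1L) {
  new("SpeciesSet", name = name, members = as.character(members),
      defaultK = as.integer(defaultK))
}

setClass("SpeciesSet",
         slots = c(name = "character", members = "character",
                   defaultK = "integer"))

setValidity("SpeciesSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!length(object@members))
    msg <- c(msg, "'members' must be non-empty")
  if (anyDuplicated(object@members))
    msg <- c(msg, "'members' must be pairwise distinct")
  if (object@defaultK < 0L || object@defaultK > length(object@members))
    msg <- c(msg, "defaultK must satisfy 0 <= defaultK <= |members|")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpeciesSet", function(object) {
  cat("SpeciesSet '", object@name, "' (k=", object@defaultK, "): ",
      paste(object@members, collapse = ", "), "\n", sep = "")
})

#' Voting policy over several orthology sources
#'
#' A gene is reported as a screen hit when the selection predicate holds
#' under at least `minVotes` of the `nSources` homology sources (e.g. "2 of
#' 3" voting; `minVotes = nSources` is consensus, `minVotes = 1` is union).
#'
#' @param nSources Number of homology sources `d`.
#' @param minVotes Required number of agreeing sources `v`, `1 <= v <= d`.
#' @return A `VotingPolicy`.
#' @export
votingPolicy <- function(nSources, minVotes = nSources) {
  new("VotingPolicy", nSources = as.integer(nSources),
      minVotes = as.integer(minVotes))
}

setClass("VotingPolicy",
         slots = c(nSources = "integer", minVotes = "integer"))

setValidity("VotingPolicy", function(object) {
  if (object@minVotes < 1L || object@minVotes > object@nSources)
    return("need 1 <= minVotes <= nSources")
  TRUE
})

#' Species group with longevity-quotient fraction boundaries
#'
#' Describes how one taxonomic group (e.g. glires or primates) is split into
#' an upper fraction (longevity quotient strictly above `upperThreshold`) and
#' a lower fraction (strictly below `lowerThreshold`).  Explicit species
#' lists may override the thresholds, e.g. when a borderline species is to be
#' excluded by hand.
#'
#' @param name Group label.
#' @param members Species keys belonging to the group (may be empty).
#' @param upperThreshold,lowerThreshold LQ boundaries in percent;
#'   `lowerThreshold <= upperThreshold`.
#' @param explicitUpper,explicitLower Optional explicit fraction membership
#'   (subsets of `members`) overriding the thresholds.
#' @return A `GroupSpec`.
#' @seealso [partitionFractions()]
#' @export
groupSpec <- function(name, members, upperThreshold, lowerThreshold,
                      explicitUpper = character(),
                      explicitLower = character()) {
  new("GroupSpec", name = name, members = as.character(members),
      upperThreshold = as.numeric(upperThreshold),
      lowerThreshold = as.numeric(lowerThreshold),
      explicitUpper = as.character(explicitUpper),
      explicitLower = as.character(explicitLower))
}

setClass("GroupSpec",
         slots = c(name = "character", members = "character",
                   upperThreshold = "numeric", lowerThreshold = "numeric",
                   explicitUpper = "character", explicitLower = "character"))

setValidity("GroupSpec", function(object) {
  msg <- character()
  if (object@lowerThreshold > object@upperThreshold)
    msg <- c(msg, "need lowerThreshold <= upperThreshold")
  if (!all(object@explicitUpper %in% object@members))
    msg <- c(msg, "explicitUpper must be a subset of members")
  if (!all(object@explicitLower %in% object@members))
    msg <- c(msg, "explicitLower must be a subset of members")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic multi-species fixture
#'
#' Describes a deterministic synthetic data set: a reference genome of
#' `nContigs * genesPerContig` protein-coding genes, plus target species in
#' four fraction roles (upper/lower x two groups), with orthologs following
#' contig-wise collinearity except where noise is requested.  Planted losses
#' remove the designated gene (and all its homology pairs) from the
#' designated species; the generator records them as ground truth.
#'
#' @param upperCounts,lowerCounts Named integer vectors of species counts per
#'   group, e.g. `c(glires = 3, primates = 7)`.
#' @param nContigs,genesPerContig Reference genome layout.
#' @param geneSpacing Mean inter-midpoint distance in base pairs (default
#'   100 kbp, a typical mammalian protein-coding gene density).
#' @param plantedLosses List of `list(gene = <reference gene index>,
#'   species = <character vector>)` entries.
#' @param rearrangementRate Probability that a target contig is shuffled
#'   (breaks synteny while keeping orthologs).
#' @param fragmentationRate Probability that a target contig is split into
#'   short 1-3 gene contigs.
#' @param one2manyRate Probability that an ortholog is duplicated in the
#'   target (one2many orthology plus a within-species paralog pair).
#' @param seed Integer seed; identical seeds give byte-identical fixtures.
#' @return A `FixtureSpec`.
#' @seealso [generateFixture()]
#' @export
fixtureSpec <- function(upperCounts = c(glires = 3L, primates = 7L),
                        lowerCounts = c(glires = 11L, primates = 10L),
                        nContigs = 2L, genesPerContig = 20L,
                        geneSpacing = 1e5,
                        plantedLosses = list(),
                        rearrangementRate = 0,
                        fragmentationRate = 0,
                        one2manyRate = 0,
                        seed = 1L) {
  new("FixtureSpec",
      upperCounts = as.integer(upperCounts) |>
        stats::setNames(names(upperCounts)),
      lowerCounts = as.integer(lowerCounts) |>
        stats::setNames(names(lowerCounts)),
      nContigs = as.integer(nContigs),
      genesPerContig = as.integer(genesPerContig),
      geneSpacing = as.numeric(geneSpacing),
      plantedLosses = plantedLosses,
      rearrangementRate = as.numeric(rearrangementRate),
      fragmentationRate = as.numeric(fragmentationRate),
      one2manyRate = as.numeric(one2manyRate),
      seed = as.integer(seed))
}

setClass("FixtureSpec",
         slots = c(upperCounts = "integer", lowerCounts = "integer",
                   nContigs = "integer", genesPerContig = "integer",
                   geneSpacing = "numeric", plantedLosses = "list",
                   rearrangementRate = "numeric",
                   fragmentationRate = "numeric",
                   one2manyRate = "numeric", seed = "integer"))

setValidity("FixtureSpec", function(object) {
  msg <- character()
  rates <- c(object@rearrangementRate, object@fragmentationRate,
             object@one2manyRate)
  if (any(rates < 0 | rates > 1))
    msg <- c(msg, "all rates must lie in [0, 1]")
  if (object@nContigs < 1L || object@genesPerContig < 1L)
    msg <- c(msg, "contig counts must be positive")
  if (object@geneSpacing <= 0)
    msg <- c(msg, "geneSpacing must be positive")
  if (is.null(names(object@upperCounts)) ||
      is.null(names(object@lowerCounts)))
    msg <- c(msg, "upperCounts and lowerCounts must be named by group")
  if (any(c(object@upperCounts, object@lowerCounts) < 0L))
    msg <- c(msg, "species counts must be non-negative")
  nGenes <- object@nContigs * object@genesPerContig
  for (pl in object@plantedLosses) {
    if (!is.list(pl) || is.null(pl$gene) || is.null(pl$species))
      msg <- c(msg, "each planted loss needs $gene and $species")
    else if (pl$gene < 1L || pl$gene > nGenes)
      msg <- c(msg, paste0("planted gene index ", pl$gene,
                           " out of range 1..", nGenes))
  }
  if (length(msg)) msg else TRUE
})

#' Result of a gene-loss screen
#'
#' Container returned by [screenGenes()].  `screenHits()` extracts the hit
#' table (one row per reference gene satisfying the predicate under the
#' voting policy, sorted by `gene_id`, with maximal thresholds and the
#' quality index); `presenceCalls()` returns the per-species status matrix
#' of the primary (first) homology source.
#'
#' @param x A `ScreenResult`.
#' @aliases screenHits presenceCalls
#' @export
setClass("ScreenResult",
         slots = c(hits = "data.frame", calls = "matrix",
                   orthologs = "data.frame", unevaluable = "data.frame",
                   refSpecies = "character", speciesOrder = "character",
                   predicate = "character", nSources = "integer",
                   minVotes = "integer", witnesses = "list"))

#' @rdname ScreenResult
#' @export
setMethod("screenHits", "ScreenResult", function(x) x@hits)

#' @rdname ScreenResult
#' @export
setMethod("presenceCalls", "ScreenResult", function(x) x@calls)

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult: ", nrow(object@hits), " hit(s) among ",
      nrow(object@calls), " screened gene(s) of '", object@refSpecies,
      "'\n  sources: ", object@nSources, " (minVotes=", object@minVotes,
      "), target species: ", length(object@speciesOrder), "\n", sep = "")
  if (nrow(object@hits))
    cat("  top hits: ",
        paste(utils::head(object@hits$gene_id, 5), collapse = ", "),
        "\n", sep = "")
})

# strand parser: accepts +/-/1/-1/+1 (numeric or character)
.parseStrandChar <- function(s) {
  s <- as.character(s)
  out <- ifelse(s %in% c("+", "1", "+1"), "+",
                ifelse(s %in% c("-", "-1"), "-", NA))
  if (anyNA(out)) stop("unrecognized strand value(s): ",
                       paste(unique(s[is.na(out)]), collapse = ", "))
  out
}
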