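# Synthetic multi-species fixtures with known ground truth.
#
# The generator emulates the input tables of a real screen: a reference
# genome laid out on contigs, target species whose gene order follows the
# reference contig-wise (conserved synteny) except where noise is requested,
# 1-to-many orthology and within-species paralogy for duplicated genes, and
# the assembly failure modes that make real screens hard: shuffled contigs
# (synteny broken, orthologs intact) and short fragmented contigs (witnesses
# impossible).  Planted losses delete the ortholog and all its homology
# rows in the designated species; the generator records exactly what was
# planted.

.FIX_GENE_LEN <- 1e4  # fixed gene length; only midpoint geometry matters

# lay out n genes along one contig: midpoint gaps ~ U(0.5, 1.5) * spacing
.layoutStarts <- function(n, spacing) {
  gaps <- stats::runif(n, 0.5, 1.5) * spacing
  mids <- 5e5 + cumsum(gaps)
  round(mids) - .FIX_GENE_LEN / 2
}

#' Generate a synthetic multi-species fixture
#'
#' Builds gene tables for a reference species plus the requested upper and
#' lower species of each group, a [HomologySource] connecting the reference
#' to every target, and a ground-truth table of the planted losses.  The
#' same seed always yields byte-identical tables; the caller's RNG state is
#' left untouched.
#'
#' @param spec A [fixtureSpec()].
#' @return A list with elements `genomes` (named list of [GeneTable]s),
#'   `source` ([HomologySource]), `truth` (data.frame `gene_id`, `species`),
#'   `roles` (named list of species keys per fraction/group role),
#'   `refSpecies` (the reference key) and `spec`.
#' @examples
#' fix <- generateFixture(fixtureSpec(upperCounts = c(g = 1L),
#'                                    lowerCounts = c(g = 1L)))
#' names(fix$genomes)
#' @export
generateFixture <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  .withSeed(spec@seed, .generateFixtureImpl(spec))
}

.generateFixtureImpl <- function(spec) {
  nG <- spec@nContigs * spec@genesPerContig
  refSpecies <- "reference"
  groups <- union(names(spec@upperCounts), names(spec@lowerCounts))
  roles <- list()
  for (g in groups) {
    nu <- if (g %in% names(spec@upperCounts)) spec@upperCounts[[g]] else 0L
    nl <- if (g %in% names(spec@lowerCounts)) spec@lowerCounts[[g]] else 0L
    if (nu) roles[[paste0("upper_", g)]] <-
        sprintf("upper_%s_%02d", g, seq_len(nu))
    if (nl) roles[[paste0("lower_", g)]] <-
        sprintf("lower_%s_%02d", g, seq_len(nl))
  }
  targets <- unlist(roles, use.names = FALSE)

  # reference layout: genes_per_contig genes on each of n_contigs contigs
  refIds <- sprintf("%s_g%03d", refSpecies, seq_len(nG))
  contigOf <- rep(sprintf("ctg%02d", seq_len(spec@nContigs)),
                  each = spec@genesPerContig)
  refStart <- unlist(lapply(seq_len(spec@nContigs), function(i)
    .layoutStarts(spec@genesPerContig, spec@geneSpacing)))
  refStrand <- sample(c(1L, -1L), nG, replace = TRUE)
  refTab <- GeneTable(refSpecies, data.frame(
    gene_id = refIds, gene_name = sub(".*_", "", refIds),
    seq_region = contigOf, start = refStart,
    end = refStart + .FIX_GENE_LEN - 1,
    strand = refStrand, biotype = "protein_coding",
    stringsAsFactors = FALSE))

  lostIn <- lapply(stats::setNames(targets, targets), function(sp)
    character())
  for (pl in spec@plantedLosses) {
    gid <- refIds[pl$gene]
    unknown <- setdiff(pl$species, targets)
    if (length(unknown))
      stop("planted loss references unknown species: ",
           paste(unknown, collapse = ", "))
    for (sp in pl$species)
      lostIn[[sp]] <- union(lostIn[[sp]], gid)
  }

  genomes <- list()
  genomes[[refSpecies]] <- refTab
  pairRows <- list()

  for (sp in targets) {
    keep <- !(refIds %in% lostIn[[sp]])
    idx <- which(keep)
    spIds <- sprintf("%s_g%03d", sp, idx)
    spContig <- contigOf[idx]
    orthoType <- rep("ortholog_one2one", length(idx))

    # per-contig order, with optional shuffling (synteny broken)
    ord <- integer(0)
    for (ctg in unique(spContig)) {
      members <- which(spContig == ctg)
      if (length(members) > 1 &&
          stats::runif(1) < spec@rearrangementRate)
        members <- sample(members)
      ord <- c(ord, members)
    }

    # optional fragmentation into 1-3 gene contigs
    outContig <- spContig
    for (ctg in unique(spContig)) {
      members <- ord[outContig[ord] == ctg]
      if (stats::runif(1) < spec@fragmentationRate) {
        i <- 1L; frag <- 1L
        while (i <= length(members)) {
          len <- sample(1:3, 1L)
          sel <- members[i:min(i + len - 1L, length(members))]
          outContig[sel] <- sprintf("%s_f%02d", ctg, frag)
          i <- i + len
          frag <- frag + 1L
        }
      }
    }

    # positions: lay out genes contig by contig in their (possibly
    # shuffled) order
    spStart <- numeric(length(idx))
    for (ctg in unique(outContig[ord])) {
      members <- ord[outContig[ord] == ctg]
      spStart[members] <- .layoutStarts(length(members), spec@geneSpacing)
    }
    spStrand <- refStrand[idx]

    # one-to-many duplication: a second copy elsewhere in the genome
    dup <- stats::runif(length(idx)) < spec@one2manyRate
    dupRows <- which(dup)
    dupIds <- character(0)
    if (length(dupRows)) {
      dupIds <- paste0(spIds[dupRows], "b")
      orthoType[dupRows] <- "ortholog_one2many"
      dupContig <- sample(unique(outContig), length(dupRows),
                          replace = TRUE)
      dupStart <- vapply(dupContig, function(ctg)
        max(spStart[outContig == ctg]) + spec@geneSpacing * 10,
        numeric(1)) + seq_along(dupRows) * spec@geneSpacing
    }

    tab <- data.frame(
      gene_id = spIds, gene_name = sub(".*_", "", refIds[idx]),
      seq_region = outContig, start = spStart,
      end = spStart + .FIX_GENE_LEN - 1,
      strand = spStrand, biotype = "protein_coding",
      stringsAsFactors = FALSE)
    if (length(dupRows)) {
      tab <- rbind(tab, data.frame(
        gene_id = dupIds, gene_name = tab$gene_name[dupRows],
        seq_region = dupContig, start = dupStart,
        end = dupStart + .FIX_GENE_LEN - 1,
        strand = spStrand[dupRows], biotype = "protein_coding",
        stringsAsFactors = FALSE))
    }
    genomes[[sp]] <- GeneTable(sp, tab)

    pairRows[[sp]] <- data.frame(
      species_a = refSpecies, gene_a = refIds[idx],
      species_b = sp, gene_b = spIds,
      homology_type = orthoType, stringsAsFactors = FALSE)
    if (length(dupRows)) {
      pairRows[[paste0(sp, "_dup")]] <- data.frame(
        species_a = c(rep(refSpecies, length(dupRows)),
                      rep(sp, length(dupRows))),
        gene_a = c(refIds[idx][dupRows], spIds[dupRows]),
        species_b = sp,
        gene_b = c(dupIds, dupIds),
        homology_type = c(rep("ortholog_one2many", length(dupRows)),
                          rep("within_species_paralog",
                              length(dupRows))),
        stringsAsFactors = FALSE)
    }
  }

  truthParts <- Filter(Negate(is.null), lapply(targets, function(sp) {
    if (!length(lostIn[[sp]])) return(NULL)
    data.frame(gene_id = sort(lostIn[[sp]]), species = sp,
               stringsAsFactors = FALSE)
  }))
  truth <- if (length(truthParts))
    do.call(rbind, c(truthParts, list(make.row.names = FALSE)))
  else data.frame(gene_id = character(), species = character(),
                  stringsAsFactors = FALSE)
  truth <- truth[order(truth$gene_id, truth$species), , drop = FALSE]
  rownames(truth) <- NULL

  source <- HomologySource("fixture",
                           do.call(rbind, c(pairRows,
                                            list(make.row.names = FALSE))))
  list(genomes = genomes, source = source, truth = truth, roles = roles,
       refSpecies = refSpecies, spec = spec)
}

#' Species sets implied by a fixture
#'
#' Convenience wrapper turning the fraction roles of a generated fixture
#' into [SpeciesSet][speciesSet()] objects ready for [screenGenes()]: one
#' `UPPER_<GROUP>` / `LOWER_<GROUP>` set per group role plus a singleton
#' `REFERENCE` set.
#'
#' @param fixture Result of [generateFixture()].
#' @return Named list of `SpeciesSet` objects.
#' @export
fixtureSets <- function(fixture) {
  sets <- lapply(names(fixture$roles), function(role)
    speciesSet(toupper(role), fixture$roles[[role]], defaultK = 1L))
  names(sets) <- toupper(names(fixture$roles))
  sets$REFERENCE <- speciesSet("REFERENCE", fixture$refSpecies,
                               defaultK = 1L)
  sets
}

#' Derive a disagreeing orthology source
#'
#' Emulates a second, imperfect orthology-inference method by randomly
#' dropping (or, optionally, retyping) a fraction of the ortholog pairs of
#' an existing source.  Used to exercise consensus/voting across sources.
#'
#' @param source A [HomologySource].
#' @param rate Fraction of ortholog pairs affected, in `[0, 1]`.
#' @param seed Integer seed (deterministic output).
#' @param retypeFraction Of the affected pairs, the fraction retyped to
#'   `ortholog_many2many` instead of dropped (default 0: all affected pairs
#'   are dropped, so `rate = 1` empties the ortholog set).
#' @return A new [HomologySource] named `<name>_degraded`.
#' @export
degradeToSecondSource <- function(source, rate, seed = 1L,
                                  retypeFraction = 0) {
  stopifnot(is(source, "HomologySource"), rate >= 0, rate <= 1)
  .withSeed(seed, {
    orth <- source@orthologs
    out <- orth
    if (nrow(orth)) {
      a <- paste(orth$species_a, orth$gene_a, sep = "\t")
      b <- paste(orth$species_b, orth$gene_b, sep = "\t")
      key <- ifelse(a <= b, paste(a, b, sep = "\t"),
                    paste(b, a, sep = "\t"))
      uk <- sort(unique(key))
      affected <- uk[stats::runif(length(uk)) < rate]
      retyped <- affected[stats::runif(length(affected)) < retypeFraction]
      dropped <- setdiff(affected, retyped)
      out <- orth[!(key %in% dropped), , drop = FALSE]
      keyKept <- key[!(key %in% dropped)]
      out$homology_type[keyKept %in% retyped] <- "ortholog_many2many"
    }
    HomologySource(paste0(source@name, "_degraded"),
                   rbind(out, source@paralogs))
  })
}

#' Write a fixture to disk in the package's table dialects
#'
#' Emits one gene table per species (`<species>.genes.tsv`), the homology
#' table (`homology.tsv`), the planted ground truth (`truth.tsv`) and a
#' ready-to-run screen configuration (`config.ini`).
#'
#' @param fixture Result of [generateFixture()].
#' @param dir Output directory (created if needed).
#' @param predicate Optional predicate text for the config; default: absent
#'   in all upper sets (k = 1) and present in all lower sets (k = 2, capped
#'   at the set size).
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(fixture, dir, predicate = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(fixture$genomes))
    writeGeneTable(fixture$genomes[[sp]],
                   file.path(dir, paste0(sp, ".genes.tsv")))
  writeHomologyTable(fixture$source, file.path(dir, "homology.tsv"))
  utils::write.table(fixture$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sets <- fixtureSets(fixture)
  if (is.null(predicate)) {
    atoms <- vapply(names(sets), function(nm) {
      if (nm == "REFERENCE") return("present_in(REFERENCE, 1)")
      k <- if (startsWith(nm, "UPPER_")) 1L
           else min(2L, length(sets[[nm]]@members))
      sprintf("%s_in(%s, %d)",
              if (startsWith(nm, "UPPER_")) "absent" else "present",
              nm, k)
    }, character(1))
    predicate <- paste(atoms, collapse = " and ")
  }
  lines <- c("[species]",
             paste0("reference = ", fixture$refSpecies),
             vapply(setdiff(names(sets), "REFERENCE"), function(nm)
               paste0(nm, " = ", paste(sets[[nm]]@members,
                                       collapse = ", ")),
               character(1)),
             "", "[params]", "r = 1000000", "r_max = 1000000",
             "witnesses = 2", "", "[predicate]", predicate, "",
             "[io]",
             paste0("gene_table.", names(fixture$genomes), " = ",
                    names(fixture$genomes), ".genes.tsv"),
             "homology_table.fixture = homology.tsv",
             "out = hits.tsv", "", "[run]", "min_votes = 1", "jobs = 1")
  writeLines(lines, file.path(dir, "config.ini"))
  invisible(dir)
}
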