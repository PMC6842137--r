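# Tab-separated readers/writers for the three table dialects:
#   gene table:        species, gene_id, gene_name, seq_region, start, end,
#                      strand, biotype [, description]
#   homology table:    species_a, gene_a, species_b, gene_b, homology_type
#   life-history:      species, common_name, mrls_years, body_mass_g
#                      [, lq_percent]

.GENE_COLS <- c("species", "gene_id", "gene_name", "seq_region",
                "start", "end", "strand", "biotype")

#' Read a per-species gene table
#'
#' Reads a tab-separated gene annotation table (UTF-8, header row) into a
#' [GeneTable].  Rows with non-numeric coordinates or `end < start` are
#' rejected with a message reporting the count; a missing file or a missing
#' mandatory column is fatal.
#'
#' @param path Path to the TSV file.
#' @param species Species key the table belongs to; rows carrying a
#'   different `species` value are rejected (with a message).
#' @return A [GeneTable].
#' @seealso [writeGeneTable()]
#' @export
readGeneTable <- function(path, species) {
  if (!file.exists(path)) stop("gene table file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  miss <- setdiff(.GENE_COLS, names(df))
  if (length(miss))
    stop("gene table ", path, " lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  n0 <- nrow(df)
  if (n0) {
    wrongSpecies <- df$species != species
    start <- suppressWarnings(as.numeric(df$start))
    end <- suppressWarnings(as.numeric(df$end))
    bad <- wrongSpecies | is.na(start) | is.na(end) | end < start
    if (any(bad))
      message("gene table ", path, ": rejected ", sum(bad),
              " malformed row(s)")
    df <- df[!bad, , drop = FALSE]
    df$start <- start[!bad]
    df$end <- end[!bad]
  }
  GeneTable(species, df)
}

#' Write a gene table in the package's TSV dialect
#'
#' Inverse of [readGeneTable()]: writing and re-reading reproduces the
#' records exactly.
#'
#' @param x A [GeneTable].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(x, path) {
  stopifnot(is(x, "GeneTable"))
  df <- as.data.frame.GeneTable(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Dialect data.frame view of a GeneTable
#'
#' @param x A [GeneTable].
#' @param ... Ignored.
#' @return A data.frame in the gene-table TSV dialect.
#' @export
as.data.frame.GeneTable <- function(x, ...) {
  g <- x@genes
  m <- S4Vectors::mcols(g)
  data.frame(species = rep(x@species, length(g)),
             gene_id = m$gene_id,
             gene_name = m$gene_name,
             seq_region = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g),
             end = GenomicRanges::end(g),
             strand = ifelse(
               as.character(GenomicRanges::strand(g)) == "-", -1L, 1L),
             biotype = m$biotype,
             description = m$description,
             stringsAsFactors = FALSE)
}

#' Read a pairwise homology table
#'
#' Reads a tab-separated homology table (columns `species_a`, `gene_a`,
#' `species_b`, `gene_b`, `homology_type`) into a [HomologySource].  Pairs
#' are symmetrized and deduplicated; rows with an unknown `homology_type`
#' are rejected with a message.
#'
#' @param path Path to the TSV file.
#' @param name Label for the orthology-inference method.
#' @param genomes Optional named list of [GeneTable]s used to drop pairs
#'   referencing unknown genes.
#' @return A [HomologySource].
#' @export
readHomologyTable <- function(path, name, genomes = NULL) {
  if (!file.exists(path)) stop("homology table file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  HomologySource(name, df, genomes = genomes)
}

#' @rdname readHomologyTable
#' @param x A [HomologySource] to write (both orientations of each pair are
#'   collapsed to one row).
#' @export
writeHomologyTable <- function(x, path) {
  stopifnot(is(x, "HomologySource"))
  df <- rbind(x@orthologs, x@paralogs)
  if (nrow(df)) {
    # keep one canonical orientation per pair
    a <- paste(df$species_a, df$gene_a, sep = "\t")
    b <- paste(df$species_b, df$gene_b, sep = "\t")
    key <- ifelse(a <= b, paste(a, b, sep = "\t"), paste(b, a, sep = "\t"))
    df <- df[!duplicated(key), , drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a life-history table
#'
#' Reads a tab-separated table with columns `species`, `common_name`,
#' `mrls_years`, `body_mass_g` and optionally `lq_percent`.  When
#' `lq_percent` is missing or empty for a row with a body mass, it is
#' computed with [computeLQ()] (unrounded).  Extra columns are kept.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with at least the columns above plus `lq_percent`.
#' @export
readLifeHistory <- function(path) {
  if (!file.exists(path)) stop("life-history file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("species", "common_name", "mrls_years", "body_mass_g")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("life-history table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  df$mrls_years <- as.numeric(df$mrls_years)
  df$body_mass_g <- as.numeric(df$body_mass_g)
  if (is.null(df$lq_percent)) df$lq_percent <- NA_real_
  df$lq_percent <- as.numeric(df$lq_percent)
  needLQ <- is.na(df$lq_percent) & !is.na(df$body_mass_g) &
    !is.na(df$mrls_years)
  if (any(needLQ))
    df$lq_percent[needLQ] <- computeLQ(df$mrls_years[needLQ],
                                       df$body_mass_g[needLQ])
  df
}
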