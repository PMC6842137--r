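# Vicinity queries on a GeneTable.  All distances in the package are
# measured between gene midpoints (start+end)/2 on the same sequence region,
# which makes the vicinity relation symmetric and insensitive to gene length.

# Plain-vector view of a GeneTable for the hot path of the presence test.
.geneIndex <- function(gt) {
  g <- gt@genes
  m <- S4Vectors::mcols(g)
  s <- GenomicRanges::start(g)
  e <- GenomicRanges::end(g)
  list(id = as.character(m$gene_id),
       region = as.character(GenomicRanges::seqnames(g)),
       start = s, end = e, mid = (s + e) / 2,
       strand = ifelse(as.character(GenomicRanges::strand(g)) == "-",
                       -1L, 1L),
       coding = m$biotype == "protein_coding",
       row = stats::setNames(seq_along(g), as.character(m$gene_id)))
}

# Row indices of protein-coding neighbours of row `i` within `radius`,
# ordered by start coordinate (ties broken by gene id for determinism).
.neighborRows <- function(idx, i, radius) {
  sel <- which(idx$coding &
                 idx$region == idx$region[i] &
                 abs(idx$mid - idx$mid[i]) <= radius)
  sel <- sel[sel != i]
  sel[order(idx$start[sel], idx$id[sel])]
}

#' Protein-coding genes in the vicinity of a gene
#'
#' Returns all protein-coding genes (other than the focal gene itself) on
#' the same sequence region whose midpoints lie within `radius` base pairs
#' of the focal gene's midpoint, ordered by start coordinate.
#'
#' @param geneId Focal gene identifier (must exist in `table`; any biotype).
#' @param table A [GeneTable].
#' @param radius Vicinity radius in base pairs (> 0).
#' @return A [GenomicRanges::GRanges] subset of `geneRanges(table)` (possibly
#'   empty), ordered by start.
#' @examples
#' gt <- GeneTable("sp", data.frame(
#'   gene_id = c("a", "b", "c"), seq_region = "1",
#'   start = c(1e6, 1.9e6, 9e6), end = c(1e6, 1.9e6, 9e6) + 1e4,
#'   strand = "+", biotype = "protein_coding"))
#' neighborGenes("a", gt, 1e6)
#' @export
neighborGenes <- function(geneId, table, radius) {
  stopifnot(is(table, "GeneTable"), radius > 0)
  idx <- .geneIndex(table)
  i <- unname(idx$row[geneId])
  if (is.na(i))
    stop("gene '", geneId, "' not found in species '", table@species, "'")
  table@genes[.neighborRows(idx, i, radius)]
}
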