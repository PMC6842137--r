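# INI-style configuration: a text file of sections, each starting with a
# section name in square brackets on its own line.  Sections used by the
# screen:
#   [species]    reference = <key>; SETNAME = sp1, sp2, ...;
#                SETNAME.k = <default k>
#   [params]     r, r_max, r_min, witnesses, allow_paralog_of_ortholog,
#                require_same_order, require_same_orientation, scan_r_prime;
#                any key may be prefixed "SETNAME." for a per-set override
#   [predicate]  the selection predicate (free text, may span lines)
#   [thresholds] m = SETNAME:absent, n = ..., p/q = SETNAME:present
#   [io]         gene_table.<species> = path; homology_table.<name> = path;
#                life_history = path; out = path
#   [run]        min_votes, jobs, strict_two_valued, with_blocks

#' Read an INI-style screen configuration
#'
#' @param path Path to the configuration file.  Relative paths in the
#'   `[io]` section are resolved against the file's directory.
#' @return A named list of sections; each section is a named list of raw
#'   string values, except `predicate`, which is the predicate text.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sections <- list()
  current <- NULL
  predicate <- character()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*[#;]", ln)) next
    if (grepl("^\\s*\\[[^]]+\\]\\s*$", ln)) {
      current <- tolower(gsub("^\\s*\\[|\\]\\s*$", "", ln))
      if (is.null(sections[[current]])) sections[[current]] <- list()
      next
    }
    if (!nzchar(trimws(ln))) next
    if (is.null(current))
      stop("configuration line ", i, " appears before any [section]")
    if (current == "predicate") {
      predicate <- c(predicate, ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop("configuration line ", i, " is not of the form key = value")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    sec <- sections[[current]]
    sec[[key]] <- val
    sections[[current]] <- sec
  }
  if (length(predicate))
    sections$predicate <- paste(predicate, collapse = "\n")
  attr(sections, "dir") <- dirname(normalizePath(path))
  sections
}

.configFlag <- function(val, default = FALSE) {
  if (is.null(val)) return(default)
  tolower(val) %in% c("1", "true", "yes", "on")
}

.configSplit <- function(val) {
  out <- trimws(strsplit(val, ",")[[1]])
  out[nzchar(out)]
}

.paramsFromConfig <- function(pars, prefix = "") {
  pick <- function(key, default) {
    v <- pars[[paste0(prefix, key)]]
    if (is.null(v) && nzchar(prefix)) v <- pars[[key]]
    if (is.null(v)) default else v
  }
  presenceParams(
    r = as.numeric(pick("r", 1e6)),
    rMax = as.numeric(pick("r_max", pick("r", 1e6))),
    rMin = as.numeric(pick("r_min", pick("r_max", pick("r", 1e6)))),
    witnesses = as.integer(pick("witnesses", 2L)),
    allowParalogOfOrtholog = .configFlag(pick("allow_paralog_of_ortholog",
                                              NULL)),
    requireSameOrder = .configFlag(pick("require_same_order", NULL)),
    requireSameOrientation = .configFlag(pick("require_same_orientation",
                                              NULL)),
    scanRPrime = .configFlag(pick("scan_r_prime", NULL)))
}

#' Run a gene-loss screen from a configuration file
#'
#' Loads the gene and homology tables named in the `[io]` section, builds
#' the species sets and presence parameters, evaluates the `[predicate]`
#' under the `[run]` voting policy and returns (and optionally writes) the
#' results.
#'
#' @param configPath Path to the configuration file (see [readConfig()]).
#' @param out Optional output TSV path overriding the config's `out` key;
#'   `NA` suppresses writing.
#' @param jobs,minVotes Optional overrides of the `[run]` section.
#' @return A [ScreenResult-class], invisibly when results are written.
#' @export
runScreen <- function(configPath, out = NULL, jobs = NULL,
                      minVotes = NULL) {
  cfg <- readConfig(configPath)
  dir <- attr(cfg, "dir")
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  io <- cfg$io
  if (is.null(io)) stop("configuration lacks an [io] section")
  spc <- cfg$species
  if (is.null(spc) || is.null(spc[["reference"]]))
    stop("configuration lacks a [species] section with a reference key")
  refSpecies <- spc[["reference"]]

  geneKeys <- grep("^gene_table\\.", names(io), value = TRUE)
  if (!length(geneKeys)) stop("no gene_table.<species> entries in [io]")
  genomes <- list()
  for (k in geneKeys) {
    sp <- sub("^gene_table\\.", "", k)
    genomes[[sp]] <- readGeneTable(resolve(io[[k]]), sp)
  }
  homKeys <- grep("^homology_table\\.", names(io), value = TRUE)
  if (!length(homKeys)) stop("no homology_table.<name> entries in [io]")
  sources <- lapply(homKeys, function(k)
    readHomologyTable(resolve(io[[k]]), sub("^homology_table\\.", "", k),
                      genomes = genomes))

  setKeys <- setdiff(names(spc), "reference")
  setKeys <- setKeys[!grepl("\\.k$", setKeys)]
  sets <- list()
  for (nm in setKeys) {
    members <- .configSplit(spc[[nm]])
    k <- spc[[paste0(nm, ".k")]]
    sets[[nm]] <- speciesSet(nm, members,
                             defaultK = if (is.null(k)) 1L
                                        else as.integer(k))
  }
  if (!"REFERENCE" %in% names(sets))
    sets$REFERENCE <- speciesSet("REFERENCE", refSpecies, defaultK = 1L)

  pars <- cfg$params
  if (is.null(pars)) pars <- character()
  perSet <- unique(sub("\\..*$", "",
                       grep("^[A-Z][A-Za-z0-9_]*\\.",
                            names(pars), value = TRUE)))
  perSet <- intersect(perSet, names(sets))
  params <- if (length(perSet)) {
    pl <- lapply(stats::setNames(perSet, perSet), function(s)
      .paramsFromConfig(pars, paste0(s, ".")))
    pl[[".default"]] <- .paramsFromConfig(pars)
    pl
  } else .paramsFromConfig(pars)

  if (is.null(cfg$predicate)) stop("configuration lacks a [predicate]")
  thr <- NULL
  if (!is.null(cfg$thresholds)) {
    thr <- lapply(cfg$thresholds, function(v) {
      parts <- trimws(strsplit(v, ":")[[1]])
      list(set = parts[1], mode = parts[2])
    })
  }
  run <- cfg$run
  if (is.null(minVotes))
    minVotes <- if (!is.null(run[["min_votes"]]))
      as.integer(run[["min_votes"]]) else 1L
  if (is.null(jobs))
    jobs <- if (!is.null(run[["jobs"]])) as.integer(run[["jobs"]]) else 1L

  res <- screenGenes(genomes, refSpecies, sources, cfg$predicate, sets,
                     params = params, minVotes = minVotes,
                     thresholdSets = thr,
                     strictTwoValued = .configFlag(run[["strict_two_valued"]]),
                     jobs = jobs)
  if (is.null(out)) out <- io[["out"]]
  if (!is.null(out) && !is.na(out)) {
    outPath <- if (grepl("^(/|[A-Za-z]:)", out)) out
               else file.path(dir, out)
    writeResults(res, outPath,
                 includeBlocks = .configFlag(run[["with_blocks"]]),
                 genomes = genomes, sources = sources,
                 params = if (is(params, "PresenceParams")) params
                          else params[[".default"]])
    return(invisible(res))
  }
  res
}
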