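#' Read clone sequences from FASTA or GenBank flat file
#'
#' FASTA goes through Biostrings; the GenBank reader is a minimal
#' flat-file parser that takes each record's name from the LOCUS line and
#' its nucleotide sequence from the ORIGIN block (features are ignored).
#'
#' @param path input file
#' @param format `"fasta"` or `"genbank"`
#' @return named character vector of DNA sequences (names = record ids)
#' @export
read_sequences <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "fasta") {
    seqs <- Biostrings::readDNAStringSet(path)
    if (length(seqs) == 0) stop("no records in ", path)
    return(stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs))))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("no records in ", path)
  rec_breaks <- c(0, which(grepl("^//", lines)))
  if (length(rec_breaks) < 2) stop("malformed GenBank file (no // terminator): ", path)
  out <- character(0)
  for (i in seq_len(length(rec_breaks) - 1)) {
    chunk <- lines[(rec_breaks[i] + 1):(rec_breaks[i + 1] - 1)]
    chunk <- chunk[nzchar(trimws(chunk))]
    if (length(chunk) == 0) next
    locus <- grep("^LOCUS", chunk, value = TRUE)
    if (length(locus) == 0) stop("malformed GenBank record ", i, ": missing LOCUS")
    id <- strsplit(trimws(sub("^LOCUS\\s+", "", locus[1])), "\\s+")[[1]][1]
    ori <- grep("^ORIGIN", chunk)
    if (length(ori) == 0) stop("malformed GenBank record '", id, "': missing ORIGIN")
    seq_lines <- chunk[(ori[1] + 1):length(chunk)]
    seq <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
    if (nchar(seq) == 0) stop("malformed GenBank record '", id, "': empty sequence")
    out[id] <- seq
  }
  if (length(out) == 0) stop("no records in ", path)
  out
}

#' Write sequences as a minimal GenBank flat file
#'
#' Emits LOCUS/ORIGIN records (no feature table) — enough for round-trip
#' fixtures and for exchanging raw clone sequences.
#'
#' @param seqs named character vector of DNA sequences
#' @param path output file
#' @return the path, invisibly
#' @export
write_genbank_minimal <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    s <- tolower(seqs[[id]])
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   SYN", id, nchar(s)), con)
    writeLines(sprintf("DEFINITION  synthetic nanobody clone %s.", id), con)
    writeLines("ORIGIN", con)
    starts <- seq(1, nchar(s), by = 60)
    for (st in starts) {
      block <- substr(s, st, min(st + 59, nchar(s)))
      tens <- substring(block, seq(1, nchar(block), 10),
                        pmin(seq(10, nchar(block) + 9, 10), nchar(block)))
      writeLines(sprintf("%9d %s", st, paste(tens, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write a cladogram as Newick
#'
#' @param tree an `ape` phylo object
#' @param path output file
#' @return the path, invisibly
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick cladogram
#'
#' @param path Newick file
#' @return an `ape` phylo object
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a report table with a reproducibility header
#'
#' All tabular outputs start with comment lines recording the package
#' version, the seed and a hash of the run configuration, so a table can be
#' regenerated byte-for-byte. Comment lines start with `#`;
#' [read_report_tsv()] skips them.
#'
#' @param df data.frame to write
#' @param path output path
#' @param seed seed used for the run (NA if none)
#' @param config optional configuration object to hash into the header
#' @return the path, invisibly
#' @export
write_report_tsv <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# nbscreen ", as.character(utils::packageVersion("nbscreen"))), con)
  writeLines(paste0("# seed=", seed), con)
  if (!is.null(config)) writeLines(paste0("# config_hash=", config_hash(config)), con)
  writeLines("# coordinates: 0-based half-open", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
read_report_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a long-format ELISA plate CSV
#'
#' Expected columns: `clone_id`, `antigen_id`, `replicate`,
#' `concentration`, `conc_unit`, `a450`, `blank` (competition plates use
#' `capture_clone`/`analyte_clone` instead of clone/antigen).
#'
#' @param path CSV file
#' @param kind `"direct"` or `"competition"`
#' @return data.frame
#' @export
read_plate_csv <- function(path, kind = c("direct", "competition")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- if (kind == "direct") {
    c("clone_id", "antigen_id", "replicate", "concentration", "conc_unit", "a450", "blank")
  } else {
    c("capture_clone", "analyte_clone", "replicate", "concentration",
      "conc_unit", "a450", "blank")
  }
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) stop("plate CSV missing columns: ", paste(missing, collapse = ", "))
  df
}

#' Read a mass-photometry event CSV
#'
#' One event per row; either a `mass_kda` column, or a `contrast` column
#' plus a calibration to convert it.
#'
#' @param path CSV file
#' @param calibration an [mp_calibrate()] fit, required when the file has
#'   contrasts only
#' @return numeric vector of masses (kDa)
#' @export
read_events_csv <- function(path, calibration = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("mass_kda" %in% names(df)) return(df$mass_kda)
  if ("contrast" %in% names(df)) {
    if (is.null(calibration)) stop("contrast-only events need a calibration")
    return(mp_apply_calibration(calibration, df$contrast))
  }
  stop("events CSV needs a mass_kda or contrast column")
}

#' Read a gel lanes CSV
#'
#' @param path CSV with columns `condition`, `replicate`, `time_min`,
#'   `band_role`, `intensity`
#' @return data.frame
#' @export
read_lanes_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("condition", "replicate", "time_min", "band_role", "intensity")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) stop("lanes CSV missing columns: ", paste(missing, collapse = ", "))
  df
}

#' Dump a bin assignment as JSON
#'
#' Serializes the competition graph (nodes, same-epitope edges, bin
#' labels), plus conflict and indeterminate pair lists, for downstream
#' consumption.
#'
#' @param assignment an [infer_bins()] result
#' @param path output JSON path
#' @param seed seed recorded in the dump
#' @return the path, invisibly
#' @export
write_binning_json <- function(assignment, path, seed = NA) {
  e <- igraph::as_edgelist(assignment$graph)
  obj <- list(
    tool = paste0("nbscreen ", as.character(utils::packageVersion("nbscreen"))),
    seed = seed,
    nodes = names(assignment$bins),
    bins = as.list(assignment$bins),
    same_epitope_edges = if (nrow(e) > 0) {
      lapply(seq_len(nrow(e)), function(i) e[i, ])
    } else list(),
    conflicts = assignment$conflicts,
    indeterminate = assignment$indeterminate,
    inferred_by_transitivity = assignment$transitive_pairs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
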