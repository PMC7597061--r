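#' Read a BioGRID tab-delimited interaction file
#'
#' Parses BioGRID TAB2 or TAB3 release files into interaction records.
#' Bait is "Interactor A" and prey is "Interactor B"; the bait-to-prey
#' direction is the basis of the directed gene network. Rows with a
#' missing Entrez identifier (empty or `"-"`) are skipped and counted.
#'
#' @param path Path to the tab-delimited file (with header).
#' @return A data.frame of interaction records with columns `bait_gene`,
#'   `prey_gene`, `bait_organism`, `prey_organism`, `source_row`, of class
#'   `lamp_records`; the number of skipped rows is in `attr(, "skipped")`.
#' @seealso [read_edge_list()] for the generic two-column input,
#'   [build_network()] for turning records into a network.
#' @export
read_biogrid_tab <- function(path) {
  if (!file.exists(path)) stop("cannot read interaction file: ", path)
  tab <- data.table::fread(path, sep = "\t", header = TRUE, quote = "",
                           colClasses = "character", data.table = FALSE)
  # TAB2 uses "Organism Interactor A", TAB3 "Organism ID Interactor A"
  col <- function(choices) {
    hit <- intersect(choices, names(tab))
    if (length(hit)) hit[1] else NA_character_
  }
  wanted <- list(
    bait_gene = col(c("Entrez Gene Interactor A")),
    prey_gene = col(c("Entrez Gene Interactor B")),
    bait_organism = col(c("Organism Interactor A", "Organism ID Interactor A")),
    prey_organism = col(c("Organism Interactor B", "Organism ID Interactor B")))
  miss <- names(wanted)[is.na(unlist(wanted))]
  if (length(miss)) {
    stop("unrecognized BioGRID header in ", path,
         "; missing column(s) for: ", paste(miss, collapse = ", "))
  }
  rec <- data.frame(
    bait_gene = tab[[wanted$bait_gene]],
    prey_gene = tab[[wanted$prey_gene]],
    bait_organism = suppressWarnings(as.integer(tab[[wanted$bait_organism]])),
    prey_organism = suppressWarnings(as.integer(tab[[wanted$prey_organism]])),
    source_row = seq_len(nrow(tab)),
    stringsAsFactors = FALSE)
  bad <- !nzchar(rec$bait_gene) | !nzchar(rec$prey_gene) |
    rec$bait_gene == "-" | rec$prey_gene == "-"
  out <- rec[!bad, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lamp_records", class(out))
  attr(out, "skipped") <- sum(bad)
  out
}

#' Read a generic directed edge list
#'
#' Canonical two-column tab-separated input: source gene, target gene.
#' Lines starting with `#` are ignored; a header line is not expected.
#' All records are stamped with the given taxon so that
#' [build_network()] keeps them.
#'
#' @param path Path to the TSV file.
#' @param taxon Integer taxon identifier stamped on every record
#'   (default 9606, human).
#' @return A `lamp_records` data.frame as in [read_biogrid_tab()].
#' @export
read_edge_list <- function(path, taxon = 9606L) {
  if (!file.exists(path)) stop("cannot read edge-list file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) {
    rec <- data.frame(bait_gene = character(0), prey_gene = character(0),
                      bait_organism = integer(0), prey_organism = integer(0),
                      source_row = integer(0), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2)) {
      stop("edge-list file ", path, " has line(s) with fewer than 2 columns")
    }
    rec <- data.frame(
      bait_gene = trimws(vapply(parts, `[`, character(1), 1)),
      prey_gene = trimws(vapply(parts, `[`, character(1), 2)),
      bait_organism = as.integer(taxon),
      prey_organism = as.integer(taxon),
      source_row = seq_along(lines),
      stringsAsFactors = FALSE)
  }
  class(rec) <- c("lamp_records", class(rec))
  attr(rec, "skipped") <- 0L
  rec
}

#' Build the directed gene network from interaction records
#'
#' Keeps only records where both interactors belong to `taxon`, adds one
#' directed bait-to-prey edge per distinct gene pair (duplicates
#' collapse), and drops self-loops unless `keep_self_loops = TRUE`.
#' Nodes are all genes that appear in a kept-taxon record, including
#' genes whose only record was a self-loop.
#'
#' @param records A `lamp_records` data.frame.
#' @param taxon Integer taxon to keep (both endpoints must match).
#' @param keep_self_loops Retain self-interactions as loop edges
#'   (default `FALSE`).
#' @return A list of class `lamp_build` with `network` (a directed
#'   igraph graph, vertex names = gene ids) and `report` (counts of
#'   kept / duplicate / self_loop / cross_species / skipped records).
#' @export
build_network <- function(records, taxon = 9606L, keep_self_loops = FALSE) {
  stopifnot(is.data.frame(records))
  skipped <- attr(records, "skipped")
  if (is.null(skipped)) skipped <- 0L
  n <- nrow(records)
  if (n == 0) {
    warning("no interaction records; returning an empty network")
    g <- igraph::make_empty_graph(0, directed = TRUE)
    report <- list(rows = 0L, kept = 0L, duplicate = 0L, self_loop = 0L,
                   cross_species = 0L, skipped = as.integer(skipped),
                   n_nodes = 0L, n_edges = 0L, taxon = as.integer(taxon))
    return(structure(list(network = g, report = report),
                     class = "lamp_build"))
  }
  cross <- records$bait_organism != taxon | records$prey_organism != taxon |
    is.na(records$bait_organism) | is.na(records$prey_organism)
  same_taxon <- records[!cross, , drop = FALSE]
  loop <- same_taxon$bait_gene == same_taxon$prey_gene
  proper <- same_taxon
  n_loop <- 0L
  if (!keep_self_loops) {
    proper <- same_taxon[!loop, , drop = FALSE]
    n_loop <- sum(loop)
  }
  dup <- duplicated(paste(proper$bait_gene, proper$prey_gene, sep = "\r"))
  edges <- proper[!dup, c("bait_gene", "prey_gene"), drop = FALSE]
  # node set: every gene seen in a same-taxon record
  nodes <- sort(unique(c(same_taxon$bait_gene, same_taxon$prey_gene)))
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  report <- list(rows = n, kept = nrow(edges), duplicate = sum(dup),
                 self_loop = n_loop, cross_species = sum(cross),
                 skipped = as.integer(skipped),
                 n_nodes = length(nodes), n_edges = nrow(edges),
                 taxon = as.integer(taxon))
  structure(list(network = g, report = report), class = "lamp_build")
}

#' @export
print.lamp_build <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<lamp_build> %d nodes, %d directed edges ",
                     "(kept %d, dup %d, self-loop %d, cross-species %d, ",
                     "skipped %d of %d rows)\n"),
              r$n_nodes, r$n_edges, r$kept, r$duplicate, r$self_loop,
              r$cross_species, r$skipped, r$rows + r$skipped))
  invisible(x)
}

#' Write a result table as annotated TSV
#'
#' Writes a data.frame as TSV preceded by `#`-prefixed header comments
#' recording the package version, a seed (if any) and MD5 hashes of the
#' input files the table was derived from. Numeric columns are rendered
#' with 17 significant digits so a write/read round trip reproduces the
#' values exactly.
#'
#' @param x A data.frame.
#' @param path Output path.
#' @param seed Optional integer seed to record.
#' @param inputs Optional named character vector of input file paths to
#'   hash into the header.
#' @export
write_lamp_table <- function(x, path, seed = NULL, inputs = character(0)) {
  stopifnot(is.data.frame(x))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  writeLines(sprintf("# lamp %s", lamp_version()), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  for (nm in names(inputs)) {
    h <- unname(tools::md5sum(inputs[[nm]]))
    writeLines(sprintf("# input %s: %s (md5 %s)", nm, inputs[[nm]], h), con)
  }
  if (nrow(x) == 0) warning("writing empty table to ", path)
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) y[[j]] <- sprintf("%.17g", y[[j]])
  }
  writeLines(paste(names(y), collapse = "\t"), con)
  if (nrow(y)) {
    writeLines(do.call(paste, c(lapply(y, as.character), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a table written by [write_lamp_table()]
#'
#' @param path Path to the TSV file.
#' @return A data.frame; header comment lines are skipped.
#' @export
read_lamp_table <- function(path) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  data.table::fread(text = paste(lines, collapse = "\n"), sep = "\t",
                    header = TRUE, data.table = FALSE)
}

#' Dump a network as a two-column edge list TSV
#'
#' The canonical plain-text serialization of the directed network;
#' [read_edge_list()] followed by [build_network()] reproduces the same
#' node and edge sets (isolated nodes are written as self-referential
#' comment lines are NOT used; networks of interest here have no
#' isolated nodes after LCC extraction).
#'
#' @param net An igraph directed graph with vertex names.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  data.table::fwrite(data.table::data.table(from = el[, 1], to = el[, 2]),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}
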