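#' Construct a gene-set collection
#'
#' A gene-set collection holds disease or pathway gene memberships: each
#' entry has an identifier, a display name, a top-level class (e.g. the
#' KEGG disease type or pathway category) and a set of gene identifiers.
#'
#' @param kind Either `"disease"` or `"pathway"`.
#' @param ids Character vector of unique entry identifiers.
#' @param names Character vector of display names (defaults to `ids`).
#' @param top_level_class Character vector of top-level class labels.
#' @param genes Named (or positional) list of character vectors, one gene
#'   set per entry. Every entry must contain at least one gene.
#' @return An object of class `lamp_gene_sets` with components `kind`,
#'   `table` (data.frame of id/name/top_level_class) and `genes` (named
#'   list of character vectors).
#' @export
gene_set_collection <- function(kind = c("disease", "pathway"), ids,
                                names = ids,
                                top_level_class = rep("unclassified", length(ids)),
                                genes) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate gene-set id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(genes) != length(ids)) {
    stop("`genes` must have one element per id")
  }
  genes <- lapply(genes, function(g) unique(as.character(g)))
  names(genes) <- ids
  sizes <- lengths(genes)
  if (any(sizes == 0)) {
    stop("gene set(s) with no genes: ",
         paste(ids[sizes == 0], collapse = ", "))
  }
  structure(
    list(kind = kind,
         table = data.frame(id = ids, name = as.character(names),
                            top_level_class = as.character(top_level_class),
                            stringsAsFactors = FALSE),
         genes = genes),
    class = "lamp_gene_sets")
}

#' @export
print.lamp_gene_sets <- function(x, ...) {
  cat(sprintf("<lamp_gene_sets> kind=%s, %d entries, %d distinct genes\n",
              x$kind, nrow(x$table), length(unique(unlist(x$genes)))))
  invisible(x)
}

#' Number of entries in a gene-set collection
#' @param x A `lamp_gene_sets` object.
#' @export
n_gene_sets <- function(x) {
  stopifnot(inherits(x, "lamp_gene_sets"))
  nrow(x$table)
}

#' Read a gene-set table from TSV
#'
#' The file must be tab-delimited with a header and columns `id`, `name`,
#' `top_level_class` and `genes`, the latter a semicolon-separated gene
#' list. Genes absent from any network are retained here; restriction to a
#' network happens at scoring time via [restrict_gene_sets()].
#'
#' @param path Path to the TSV file.
#' @param kind Either `"disease"` or `"pathway"`.
#' @return A `lamp_gene_sets` collection.
#' @export
read_gene_sets <- function(path, kind = c("disease", "pathway")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read gene-set file: ", path)
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = FALSE)
  required <- c("id", "name", "top_level_class", "genes")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("gene-set file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate gene-set id(s) in ", path, ": ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  genes <- lapply(strsplit(tab$genes, ";", fixed = TRUE), function(g) {
    g <- trimws(g)
    unique(g[nzchar(g)])
  })
  empty <- lengths(genes) == 0
  if (any(empty)) {
    warning(sum(empty), " entr(ies) with empty gene list rejected: ",
            paste(tab$id[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
    genes <- genes[!empty]
  }
  gene_set_collection(kind, tab$id, tab$name, tab$top_level_class, genes)
}

#' Write a gene-set collection to TSV
#'
#' Inverse of [read_gene_sets()]: writes `id`, `name`, `top_level_class`
#' and a semicolon-separated `genes` column.
#'
#' @param x A `lamp_gene_sets` collection.
#' @param path Output path.
#' @export
write_gene_sets <- function(x, path) {
  stopifnot(inherits(x, "lamp_gene_sets"))
  out <- x$table
  out$genes <- vapply(x$genes[out$id], paste, character(1), collapse = ";")
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Restrict gene sets to a gene universe
#'
#' Intersects every entry's gene set with `genes` and drops entries whose
#' intersection is empty. This is the screening step that restricts the
#' disease (and pathway) collections to the largest connected component
#' before any scoring.
#'
#' @param x A `lamp_gene_sets` collection.
#' @param genes Character vector, the gene universe to keep (e.g. the LCC
#'   node set).
#' @return The restricted collection; the ids of dropped entries are
#'   available through `attr(, "dropped")`.
#' @export
restrict_gene_sets <- function(x, genes) {
  stopifnot(inherits(x, "lamp_gene_sets"))
  genes <- as.character(genes)
  kept_genes <- lapply(x$genes, intersect, genes)
  keep <- lengths(kept_genes) > 0
  out <- gene_set_collection(x$kind, x$table$id[keep], x$table$name[keep],
                             x$table$top_level_class[keep],
                             kept_genes[keep])
  attr(out, "dropped") <- x$table$id[!keep]
  out
}

#' Subset a gene-set collection by id
#' @param x A `lamp_gene_sets` collection.
#' @param ids Entry identifiers to keep (order preserved).
#' @export
subset_gene_sets <- function(x, ids) {
  stopifnot(inherits(x, "lamp_gene_sets"))
  missing <- setdiff(ids, x$table$id)
  if (length(missing)) {
    stop("unknown gene-set id(s): ", paste(missing, collapse = ", "))
  }
  idx <- match(ids, x$table$id)
  gene_set_collection(x$kind, x$table$id[idx], x$table$name[idx],
                      x$table$top_level_class[idx], x$genes[idx])
}
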