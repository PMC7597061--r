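#' Enumerate disease pairs and overlapping-gene pairs
#'
#' Counts all unordered disease pairs (`n(n-1)/2`) and identifies the
#' pairs whose gene sets share at least one gene, via an inverted
#' gene-to-disease index.
#'
#' @param diseases A `lamp_gene_sets` collection (at least 2 entries).
#' @return A list with `ids`, `total_pairs`, `overlap_count` and
#'   `overlapping` (2-column character matrix of pair ids, each pair
#'   sorted and unique).
#' @export
pair_counts <- function(diseases) {
  stopifnot(inherits(diseases, "lamp_gene_sets"))
  ids <- diseases$table$id
  n <- length(ids)
  if (n < 2) stop("need at least 2 diseases")
  gene2dis <- split(rep(ids, lengths(diseases$genes)),
                    unlist(diseases$genes))
  pair_keys <- unlist(lapply(gene2dis, function(ds) {
    ds <- sort(unique(ds))
    if (length(ds) < 2) return(character(0))
    pairs <- combn(ds, 2)
    paste(pairs[1, ], pairs[2, ], sep = "\r")
  }), use.names = FALSE)
  pair_keys <- unique(pair_keys)
  overlapping <- if (length(pair_keys)) {
    do.call(rbind, strsplit(pair_keys, "\r", fixed = TRUE))
  } else {
    matrix(character(0), 0, 2)
  }
  list(ids = ids, total_pairs = choose(n, 2),
       overlap_count = nrow(overlapping), overlapping = overlapping)
}

#' Build the 2x2 overlap-by-category contingency table
#'
#' Cross-classifies every disease pair by (shares at least one gene) x
#' (shares at least one category label). Multi-label diseases count as
#' same-category when any label is shared.
#'
#' @param pairs Result of [pair_counts()].
#' @param labels A `lamp_categories` assignment covering every disease
#'   in `pairs$ids`.
#' @return A list of class `lamp_contingency` with integer cells `a`
#'   (overlapping, same category), `b` (non-overlapping, same), `c`
#'   (overlapping, different), `d` (non-overlapping, different).
#' @export
build_contingency <- function(pairs, labels) {
  stopifnot(inherits(labels, "lamp_categories"))
  ids <- pairs$ids
  gap <- setdiff(ids, names(labels$labels))
  if (length(gap)) {
    stop("disease(s) without category label: ",
         paste(head(gap, 5), collapse = ", "))
  }
  cats <- sort(unique(unlist(labels$labels[ids])))
  C <- matrix(FALSE, length(ids), length(cats),
              dimnames = list(ids, cats))
  for (d in ids) C[d, labels$labels[[d]]] <- TRUE
  same <- tcrossprod(C * 1) > 0
  overlap <- matrix(FALSE, length(ids), length(ids),
                    dimnames = list(ids, ids))
  if (nrow(pairs$overlapping)) {
    overlap[pairs$overlapping] <- TRUE
    overlap <- overlap | t(overlap)
  }
  ut <- upper.tri(same)
  tab <- structure(list(a = sum(overlap[ut] & same[ut]),
                        b = sum(!overlap[ut] & same[ut]),
                        c = sum(overlap[ut] & !same[ut]),
                        d = sum(!overlap[ut] & !same[ut])),
                   class = "lamp_contingency")
  stopifnot(tab$a + tab$b + tab$c + tab$d == pairs$total_pairs,
            tab$a + tab$c == pairs$overlap_count)
  tab
}

#' @export
print.lamp_contingency <- function(x, ...) {
  cat("<lamp_contingency>\n")
  cat(sprintf("  same category:      overlapping %d, not %d\n", x$a, x$b))
  cat(sprintf("  different category: overlapping %d, not %d\n", x$c, x$d))
  invisible(x)
}

#' Fisher's exact test on the 2x2 overlap table
#'
#' Exact hypergeometric test of whether overlapping-gene disease pairs
#' are over-represented among same-category pairs. The default
#' alternative `"greater"` tests the directional over-representation
#' hypothesis; computation is exact even at millions of pairs (the
#' conditional distribution is evaluated in log space).
#'
#' @param table A `lamp_contingency` table or a 2x2 matrix
#'   `rbind(c(a, b), c(c, d))`.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A list with `odds_ratio` (conditional MLE), `p_value`,
#'   `alternative` and possibly a `note` for degenerate margins.
#' @export
fisher_exact_2x2 <- function(table, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  m <- if (inherits(table, "lamp_contingency")) {
    rbind(c(table$a, table$b), c(table$c, table$d))
  } else {
    as.matrix(table)
  }
  stopifnot(all(dim(m) == 2), all(m >= 0), all(m == round(m)))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1,
                alternative = alternative,
                note = "degenerate margin; the table carries no information"))
  }
  ft <- stats::fisher.test(m, alternative = alternative)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       alternative = alternative)
}

#' Over-representation analysis of overlapping-gene disease pairs
#'
#' Convenience wrapper: enumerates pairs, builds the contingency table
#' against a category assignment and runs the Fisher test, returning a
#' table in the layout used for reporting (same/different category x
#' with-overlap/all).
#'
#' @param diseases A `lamp_gene_sets` collection.
#' @param labels A `lamp_categories` assignment.
#' @param alternative Passed to [fisher_exact_2x2()].
#' @return A list with `table` (data.frame), `contingency`, `fisher`.
#' @export
overlap_analysis <- function(diseases, labels,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  pairs <- pair_counts(diseases)
  tab <- build_contingency(pairs, labels)
  fis <- fisher_exact_2x2(tab, alternative)
  out <- data.frame(
    group = c("same category", "different category"),
    with_overlap = c(tab$a, tab$c),
    all_pairs = c(tab$a + tab$b, tab$c + tab$d),
    stringsAsFactors = FALSE)
  list(table = out, contingency = tab, fisher = fis,
       total_pairs = pairs$total_pairs,
       overlap_count = pairs$overlap_count)
}
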