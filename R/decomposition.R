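#' Largest weakly connected component
#'
#' Returns the induced subgraph on the largest weakly connected node set
#' (the LCC). Ties between equally sized components are broken by the
#' lexicographically smallest member gene.
#'
#' @param net A directed igraph graph with vertex names.
#' @return The induced subgraph (igraph).
#' @export
largest_weak_component <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network")
  comp <- igraph::components(net, mode = "weak")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie-break: component containing the smallest vertex name
    mins <- vapply(best, function(ci) {
      min(igraph::V(net)$name[comp$membership == ci])
    }, character(1))
    best <- best[order(mins)][1]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Bow-tie decomposition of the LCC around the LSCC
#'
#' Partitions a weakly connected directed network into the largest
#' strongly connected component (LSCC), the genes upstream of it
#' (UP_LSCC: outside the LSCC but with a directed path into it), the
#' genes downstream of it (DOWN_LSCC: reachable from the LSCC but unable
#' to return), and the remaining tendril genes (`other`). The four sets
#' are pairwise disjoint and cover the input exactly.
#'
#' @param net A weakly connected directed igraph graph (typically the
#'   LCC from [largest_weak_component()]).
#' @return A list of class `lamp_bowtie` with character-vector components
#'   `lcc`, `lscc`, `up_lscc`, `down_lscc`, `other`.
#' @export
bow_tie <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network")
  nm <- igraph::V(net)$name
  comp <- igraph::components(net, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    mins <- vapply(best, function(ci) min(nm[comp$membership == ci]),
                   character(1))
    best <- best[order(mins)][1]
  }
  lscc <- nm[comp$membership == best]
  # the LSCC is strongly connected, so reachability to/from any one
  # representative decides reachability to/from the whole set
  rep_v <- lscc[1]
  reach_in <- nm[as.integer(igraph::subcomponent(net, rep_v, mode = "in"))]
  reach_out <- nm[as.integer(igraph::subcomponent(net, rep_v, mode = "out"))]
  up <- setdiff(reach_in, lscc)
  down <- setdiff(reach_out, lscc)
  other <- setdiff(nm, c(lscc, up, down))
  structure(list(lcc = nm, lscc = sort(lscc), up_lscc = sort(up),
                 down_lscc = sort(down), other = sort(other)),
            class = "lamp_bowtie")
}

#' @export
print.lamp_bowtie <- function(x, ...) {
  cat(sprintf("<lamp_bowtie> LCC %d = LSCC %d + UP %d + DOWN %d + other %d\n",
              length(x$lcc), length(x$lscc), length(x$up_lscc),
              length(x$down_lscc), length(x$other)))
  invisible(x)
}

#' Driver nodes for structural controllability
#'
#' Computes a maximum matching on the bipartite representation of the
#' directed network (one out-copy and one in-copy per node, an edge
#' a->b linking out-a to in-b) and returns the unmatched in-copies as a
#' driver-node set. The driver count `N - |maximum matching|` is the
#' invariant quantity; the particular set depends on matching
#' tie-breaks. If the matching is perfect, a single driver node (the
#' smallest gene id) is returned by convention.
#'
#' @param net A directed igraph graph with vertex names.
#' @return Sorted character vector of driver genes; the matching size is
#'   in `attr(, "matching_size")`.
#' @export
driver_nodes <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0) return(character(0))
  nm <- igraph::V(net)$name
  if (igraph::ecount(net) == 0) {
    out <- sort(nm)
    attr(out, "matching_size") <- 0L
    return(out)
  }
  el <- igraph::as_edgelist(net, names = TRUE)
  verts <- data.frame(
    name = c(paste0("out::", nm), paste0("in::", nm)),
    type = rep(c(FALSE, TRUE), each = n),
    stringsAsFactors = FALSE)
  bg <- igraph::graph_from_data_frame(
    data.frame(from = paste0("out::", el[, 1]),
               to = paste0("in::", el[, 2]), stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  m <- igraph::max_bipartite_match(bg)
  match_vec <- m$matching[paste0("in::", nm)]
  unmatched <- nm[is.na(match_vec)]
  if (length(unmatched) == 0) unmatched <- min(nm)  # perfect matching
  out <- sort(unmatched)
  attr(out, "matching_size") <- as.integer(m$matching_size)
  out
}

#' Classify genes and summarize degrees
#'
#' Classifies every network gene into disease-only (`D\\P`), both
#' (`D&P`), pathway-only (`P\\D`) or `other` by set algebra on the union
#' of disease genes and the union of pathway genes, then computes
#' mean/median/max in- and outdegree per class and overall. Power-law
#' exponents of the positive in- and outdegree distributions are fit
#' with [power_law_exponent()] when enough distinct values exist.
#'
#' @param net A directed igraph graph with vertex names.
#' @param diseases,pathways Optional `lamp_gene_sets` collections; with
#'   neither given all genes fall in class `other`.
#' @return A list of class `lamp_degree_summary` with per-gene degree
#'   vectors, the class factor, a per-class summary data.frame (classes
#'   plus an `overall` row) and `gamma_in` / `gamma_out` estimates (NA
#'   when the fit is not defined).
#' @export
degree_summary <- function(net, diseases = NULL, pathways = NULL) {
  nm <- igraph::V(net)$name
  indeg <- igraph::degree(net, mode = "in")
  outdeg <- igraph::degree(net, mode = "out")
  dg <- if (is.null(diseases)) character(0) else
    intersect(unique(unlist(diseases$genes)), nm)
  pg <- if (is.null(pathways)) character(0) else
    intersect(unique(unlist(pathways$genes)), nm)
  cls <- rep("other", length(nm))
  cls[nm %in% setdiff(dg, pg)] <- "D\\P"
  cls[nm %in% intersect(dg, pg)] <- "D&P"
  cls[nm %in% setdiff(pg, dg)] <- "P\\D"
  cls <- factor(cls, levels = c("D\\P", "D&P", "P\\D", "other"))
  row_for <- function(sel, label) {
    din <- unname(indeg[sel])
    dout <- unname(outdeg[sel])
    if (length(din) == 0) {
      return(data.frame(class = label, n = 0L, mean_in = NA_real_,
                        median_in = NA_real_, max_in = NA_real_,
                        mean_out = NA_real_, median_out = NA_real_,
                        max_out = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(class = label, n = length(din),
               mean_in = mean(din), median_in = median(din),
               max_in = max(din),
               mean_out = mean(dout), median_out = median(dout),
               max_out = max(dout),
               stringsAsFactors = FALSE)
  }
  per_class <- do.call(rbind, lapply(levels(cls), function(l) {
    row_for(cls == l, l)
  }))
  per_class <- rbind(per_class, row_for(rep(TRUE, length(nm)), "overall"))
  fit_or_na <- function(x) {
    x <- x[x > 0]
    est <- try(power_law_exponent(x), silent = TRUE)
    if (inherits(est, "try-error")) NA_real_ else est$gamma
  }
  structure(list(indegree = setNames(as.numeric(indeg), nm),
                 outdegree = setNames(as.numeric(outdeg), nm),
                 class_of = setNames(cls, nm),
                 per_class = per_class,
                 gamma_in = fit_or_na(indeg),
                 gamma_out = fit_or_na(outdeg)),
            class = "lamp_degree_summary")
}

#' Discrete power-law exponent
#'
#' Maximum-likelihood estimate of the exponent of a discrete power law
#' \eqn{p(x) \propto x^{-\gamma}} with `x_min = 1` (zeta-function
#' normalization), plus a secondary least-squares slope of the log-log
#' empirical probability mass function.
#'
#' @param degrees Integer vector of at least 10 positive values, not all
#'   equal.
#' @return A list with `gamma` (MLE), `gamma_ls` (least-squares slope
#'   estimate), `n` and `xmin = 1`.
#' @export
power_law_exponent <- function(degrees) {
  x <- as.numeric(degrees)
  if (length(x) < 10) stop("need at least 10 values to fit an exponent")
  if (any(x < 1)) stop("degrees must be positive")
  if (length(unique(x)) == 1) stop("exponent undefined for all-equal input")
  slx <- sum(log(x))
  n <- length(x)
  nll <- function(gam) n * log(pracma::zeta(gam)) + gam * slx
  opt <- stats::optimize(nll, interval = c(1.0001, 12))
  # secondary: least squares on the log-log empirical pmf
  tab <- table(x)
  k <- as.numeric(names(tab))
  p <- as.numeric(tab) / n
  fit <- stats::lm(log(p) ~ log(k))
  list(gamma = opt$minimum, gamma_ls = -unname(stats::coef(fit)[2]),
       n = n, xmin = 1)
}

#' Betweenness-centrality ranking
#'
#' Directed shortest-path betweenness (endpoints excluded,
#' unnormalized), sorted descending with the gene id as a stable
#' tie-break, together with the count of genes whose centrality exceeds
#' zero.
#'
#' @param net A directed igraph graph with vertex names.
#' @return A list with `ranking` (data.frame gene/betweenness, sorted)
#'   and `n_positive`.
#' @export
betweenness_ranking <- function(net) {
  b <- igraph::betweenness(net, directed = igraph::is_directed(net),
                           normalized = FALSE)
  nm <- igraph::V(net)$name
  ord <- order(-b, nm)
  list(ranking = data.frame(gene = nm[ord], betweenness = as.numeric(b[ord]),
                            stringsAsFactors = FALSE),
       n_positive = sum(b > 0))
}
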