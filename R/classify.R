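#' Euclidean distance matrix between disease score vectors
#'
#' Pairwise Euclidean distances between the normalized impact score
#' (NIS) rows of a score matrix.
#'
#' @param scores A `lamp_scores` object or a numeric matrix of row
#'   vectors.
#' @return A symmetric numeric matrix with zero diagonal, row/column
#'   names = disease ids.
#' @export
distance_matrix <- function(scores) {
  m <- if (inherits(scores, "lamp_scores")) scores$nis else as.matrix(scores)
  bad <- !is.finite(m)
  if (any(bad)) {
    offenders <- rownames(m)[unique(which(bad, arr.ind = TRUE)[, 1])]
    stop("non-finite score(s) for disease(s): ",
         paste(offenders, collapse = ", "))
  }
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Ward.D2 hierarchical clustering
#'
#' Agglomerative clustering of the disease distance matrix with the
#' Ward.D2 criterion (squared-distance Ward on the supplied distances).
#' Deterministic given its input.
#'
#' @param d A symmetric distance matrix (or `dist` object).
#' @return An `hclust` tree (method tag `ward.D2`).
#' @export
ward_cluster <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
      stop("distance matrix must be symmetric")
    }
    d <- stats::as.dist(d)
  }
  if (attr(d, "Size") < 2) stop("need at least 2 items to cluster")
  stats::hclust(d, method = "ward.D2")
}

#' Choose the dendrogram cut by the difference vector
#'
#' For every candidate number of clusters k, the tree is cut and the
#' average disease distance within partitions is compared with the
#' average distance between partitions; the difference vector element
#' is \eqn{\Delta(k) = between - within} and the chosen cut is the k
#' with maximal \eqn{|\Delta(k)|} (smallest k on ties).
#'
#' Two summaries of "average" are available. The default,
#' `pooling = "cluster"`, averages per partition: the within term is
#' the unweighted mean over clusters (of size >= 2) of each cluster's
#' mean intra-cluster distance, and the between term the unweighted
#' mean over cluster pairs of each pair's mean cross distance.
#' `pooling = "pairs"` pools all within-cluster pairs into one mean and
#' all between-cluster pairs into another. The cluster-averaged form
#' is robust to single outlier diseases, whose expulsion into
#' singleton clusters can otherwise nudge the pooled means past the
#' true maximum (see the methods vignette).
#'
#' @param hc An `hclust` tree from [ward_cluster()].
#' @param d The distance matrix the tree was built from.
#' @param k_min,k_max Candidate range; `k_max` defaults to
#'   `min(leaves - 1, 40)`.
#' @param pooling `"cluster"` (default) or `"pairs"`, see above.
#' @return A list with `k`, `labels` (named integer vector at the chosen
#'   cut), `delta` (named vector over candidates, NA where a mean was
#'   undefined) and `skipped`.
#' @export
difference_vector_cut <- function(hc, d, k_min = 2L, k_max = NULL,
                                  pooling = c("cluster", "pairs")) {
  pooling <- match.arg(pooling)
  m <- as.matrix(d)
  n <- nrow(m)
  if (is.null(k_max)) k_max <- min(n - 1L, 40L)
  if (k_max > n - 1L) stop("k_max must be at most leaves - 1")
  if (k_min < 2L) stop("k_min must be at least 2")
  ut <- upper.tri(m)
  ks <- k_min:k_max
  delta <- setNames(rep(NA_real_, length(ks)), ks)
  skipped <- integer(0)
  for (i in seq_along(ks)) {
    labels <- stats::cutree(hc, k = ks[i])
    if (pooling == "pairs") {
      same <- outer(labels, labels, "==")
      w <- m[ut & same]
      b <- m[ut & !same]
      if (length(w) == 0 || length(b) == 0) {
        skipped <- c(skipped, ks[i])
        next
      }
      delta[i] <- mean(b) - mean(w)
    } else {
      cl <- sort(unique(labels))
      wm <- vapply(cl, function(c) {
        idx <- which(labels == c)
        if (length(idx) < 2) return(NA_real_)
        sub <- m[idx, idx, drop = FALSE]
        mean(sub[upper.tri(sub)])
      }, numeric(1))
      wm <- wm[!is.na(wm)]
      bm <- numeric(0)
      for (a in seq_along(cl)) {
        for (b in seq_along(cl)) {
          if (a < b) {
            bm <- c(bm, mean(m[labels == cl[a], labels == cl[b],
                               drop = FALSE]))
          }
        }
      }
      if (length(wm) == 0 || length(bm) == 0) {
        skipped <- c(skipped, ks[i])
        next
      }
      delta[i] <- mean(bm) - mean(wm)
    }
  }
  if (all(is.na(delta))) stop("no candidate cut had both means defined")
  k_star <- ks[which.max(abs(delta))]  # which.max: first (smallest k) on ties
  list(k = k_star, labels = stats::cutree(hc, k = k_star),
       delta = delta, skipped = skipped)
}

#' Assemble a category assignment
#'
#' Combines cluster labels of the scored diseases (CATG-1..CATG-k) with
#' the pre-screened CATG-0 group into a single assignment. Diseases may
#' acquire additional labels later through [apply_refinements()].
#'
#' @param cluster_labels Named integer vector disease -> cluster index
#'   (1-based), e.g. from [difference_vector_cut()].
#' @param catg0_ids Character vector of CATG-0 disease ids.
#' @return A list of class `lamp_categories` with `labels` (named list
#'   of character vectors), `n_categories` and `provenance`.
#' @export
make_category_assignment <- function(cluster_labels,
                                     catg0_ids = character(0)) {
  overlap <- intersect(names(cluster_labels), catg0_ids)
  if (length(overlap)) {
    stop("disease(s) both clustered and CATG-0: ",
         paste(overlap, collapse = ", "))
  }
  labels <- c(
    setNames(lapply(catg0_ids, function(i) "CATG-0"), catg0_ids),
    setNames(lapply(cluster_labels, function(l) paste0("CATG-", l)),
             names(cluster_labels)))
  structure(list(labels = labels,
                 n_categories = length(unique(unlist(labels))),
                 provenance = "preliminary"),
            class = "lamp_categories")
}

#' @export
print.lamp_categories <- function(x, ...) {
  cat(sprintf("<lamp_categories> %d diseases in %d categories (%s)\n",
              length(x$labels), x$n_categories, x$provenance))
  invisible(x)
}

#' Read a refinement override config
#'
#' YAML file with an `additions` mapping from disease id to the list of
#' category names to add, e.g.
#' `additions: {H00123: [CATG-10]}`. Refinement only ever adds
#' memberships; it encodes the judgment-driven dual assignments made
#' after inspecting the tSNE diagram.
#'
#' @param path Path to the YAML file.
#' @return A named list of character vectors.
#' @export
read_refinements <- function(path) {
  cfg <- yaml::read_yaml(path)
  adds <- if (!is.null(cfg$additions)) cfg$additions else cfg
  if (is.null(adds)) adds <- list()
  lapply(adds, as.character)
}

#' Apply declarative refinement overrides
#'
#' Adds (never removes) category memberships per override entry and
#' marks the assignment as refined. Every override must name an
#' existing disease and existing categories.
#'
#' @param prelim A `lamp_categories` assignment.
#' @param overrides Named list of character vectors (disease id ->
#'   categories to add), e.g. from [read_refinements()].
#' @return The refined `lamp_categories` assignment.
#' @export
apply_refinements <- function(prelim, overrides) {
  stopifnot(inherits(prelim, "lamp_categories"))
  if (length(overrides) == 0) {
    out <- prelim
    out$provenance <- "refined"
    return(out)
  }
  known_d <- names(prelim$labels)
  known_c <- unique(unlist(prelim$labels))
  bad_d <- setdiff(names(overrides), known_d)
  bad_c <- setdiff(unique(unlist(overrides)), known_c)
  offenders <- c(
    if (length(bad_d)) paste("unknown disease:", bad_d),
    if (length(bad_c)) paste("unknown category:", bad_c))
  if (length(offenders)) {
    stop("invalid refinement override(s): ",
         paste(offenders, collapse = "; "))
  }
  labels <- prelim$labels
  for (d in names(overrides)) {
    labels[[d]] <- union(labels[[d]], overrides[[d]])
  }
  structure(list(labels = labels,
                 n_categories = length(unique(unlist(labels))),
                 provenance = "refined"),
            class = "lamp_categories")
}

#' Shannon entropy of a composition
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} in bits; zero fractions contribute
#' nothing. The fractions must sum to 1.
#'
#' @param fractions Non-negative numeric vector summing to 1 (within
#'   1e-9).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(fractions) {
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1 (got ", format(sum(fractions)), ")")
  }
  p <- fractions[fractions > 0]
  -sum(p * log2(p))
}

#' Cross-tabulate two category assignments
#'
#' For each category of assignment A, the composition fractions over
#' the categories of assignment B (and vice versa), with the Shannon
#' entropy of every composition. Multi-labeled diseases are counted
#' once per (label of A, label of B) pair.
#'
#' @param a,b `lamp_categories` assignments over the same disease
#'   universe.
#' @return A list with `counts` (A categories x B categories),
#'   `composition_ab` (rows sum to 1), `entropy_ab` (bits, per A
#'   category), and the `_ba` transposed counterparts.
#' @export
category_crosstab <- function(a, b) {
  stopifnot(inherits(a, "lamp_categories"), inherits(b, "lamp_categories"))
  if (!setequal(names(a$labels), names(b$labels))) {
    if (!length(intersect(names(a$labels), names(b$labels)))) {
      stop("assignments cover disjoint disease universes")
    }
    stop("assignments must cover the same disease universe")
  }
  cats_a <- sort(unique(unlist(a$labels)))
  cats_b <- sort(unique(unlist(b$labels)))
  counts <- matrix(0L, length(cats_a), length(cats_b),
                   dimnames = list(cats_a, cats_b))
  for (d in names(a$labels)) {
    for (la in a$labels[[d]]) {
      for (lb in b$labels[[d]]) {
        counts[la, lb] <- counts[la, lb] + 1L
      }
    }
  }
  comp_ab <- sweep(counts, 1, rowSums(counts), "/")
  comp_ba <- sweep(t(counts), 1, colSums(counts), "/")
  list(counts = counts,
       composition_ab = comp_ab,
       entropy_ab = apply(comp_ab, 1, shannon_entropy),
       composition_ba = comp_ba,
       entropy_ba = apply(comp_ba, 1, shannon_entropy))
}
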