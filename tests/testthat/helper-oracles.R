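# Independent oracles built on plain edge lists and hand-rolled BFS;
# they never call the package's graph code paths.

# directed graph from a flat vector c(from1, to1, from2, to2, ...)
net_from_pairs <- function(pairs, isolated = character(0)) {
  m <- matrix(pairs, ncol = 2, byrow = TRUE)
  nodes <- unique(c(m[, 1], m[, 2], isolated))
  igraph::graph_from_data_frame(
    data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
}

random_digraph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  from <- rep(nodes, each = n)
  to <- rep(nodes, times = n)
  keep <- from != to & runif(n * n) < p
  edges <- cbind(from[keep], to[keep])
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2],
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  list(nodes = nodes, edges = edges, graph = g)
}

# BFS distances from a seed set over a raw edge list
naive_bfs_dist <- function(nodes, edges, seeds, reverse = FALSE) {
  if (reverse && nrow(edges)) edges <- edges[, 2:1, drop = FALSE]
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[seeds] <- 0
  frontier <- seeds
  s <- 0
  while (length(frontier)) {
    nxt <- unique(edges[edges[, 1] %in% frontier, 2])
    nxt <- nxt[!is.finite(dist[nxt])]
    if (!length(nxt)) break
    s <- s + 1
    dist[nxt] <- s
    frontier <- nxt
  }
  dist
}

# explicit layer sets (list indexed s+1) from BFS distances
naive_layer_sets <- function(nodes, edges, seeds, reverse = FALSE) {
  dist <- naive_bfs_dist(nodes, edges, seeds, reverse)
  dist <- dist[is.finite(dist)]
  lapply(0:max(dist), function(s) names(dist)[dist == s])
}

# IALS by direct evaluation of the layer-set formula
naive_ials <- function(nodes, edges, disease, module) {
  total <- 0
  for (g in intersect(disease, module)) {
    layers <- naive_layer_sets(nodes, edges, g)
    num <- 0
    den <- 0
    for (s in seq_along(layers)) {
      if (s == 1) next  # layer 0 carries zero weight
      cnt <- length(intersect(module, layers[[s]]))
      num <- num + cnt
      den <- den + cnt * (s - 1)
    }
    if (den > 0) total <- total + num / den
  }
  total
}

# WPS by direct evaluation over explicit reverse layer sets
naive_wps <- function(nodes, edges, module, pathway) {
  pg <- intersect(pathway, nodes)
  layers <- naive_layer_sets(nodes, edges, pg, reverse = TRUE)
  total <- 0
  for (s in seq_along(layers)) {
    total <- total +
      length(intersect(module, layers[[s]])) / length(layers[[s]]) *
      2^(-(s - 1))
  }
  total
}

# betweenness by shortest-path counting over the BFS DAG
naive_betweenness <- function(nodes, edges) {
  n <- length(nodes)
  dist <- sapply(nodes, function(s) naive_bfs_dist(nodes, edges, s))
  # dist[t, s] = d(s, t); path counts from every source
  cnt <- matrix(0, n, n, dimnames = list(nodes, nodes))  # cnt[t, s]
  for (s in nodes) {
    cnt[s, s] <- 1
    ds <- dist[, s]
    reach <- names(ds)[is.finite(ds)]
    for (lev in sort(unique(ds[reach]))) {
      if (lev == 0) next
      for (v in reach[ds[reach] == lev]) {
        preds <- edges[edges[, 2] == v, 1]
        preds <- preds[ds[preds] == lev - 1]
        cnt[v, s] <- sum(cnt[preds, s])
      }
    }
  }
  bw <- setNames(rep(0, n), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t || !is.finite(dist[t, s])) next
    for (v in nodes) {
      if (v == s || v == t) next
      if (is.finite(dist[v, s]) && is.finite(dist[t, v]) &&
          dist[v, s] + dist[t, v] == dist[t, s]) {
        bw[v] <- bw[v] + cnt[v, s] * cnt[t, v] / cnt[t, s]
      }
    }
  }
  bw
}

# one-sided/two-sided Fisher p by explicit hypergeometric enumeration
# with exact factorials (valid for totals <= ~170)
naive_fisher_p <- function(a, b, c, d, alternative = "greater") {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  prob <- function(x) {
    exp(lfactorial(r1) + lfactorial(n - r1) + lfactorial(c1) +
          lfactorial(n - c1) - lfactorial(n) - lfactorial(x) -
          lfactorial(r1 - x) - lfactorial(c1 - x) -
          lfactorial(n - r1 - c1 + x))
  }
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(support, prob, numeric(1))
  if (alternative == "greater") {
    sum(probs[support >= a])
  } else {
    p_a <- prob(a)
    sum(probs[probs <= p_a * (1 + 1e-7)])
  }
}

# end-to-end synthetic run used by several tests
run_synthetic_pipeline <- function(seed, spec = synthetic_spec(seed = seed)) {
  synth <- generate_network(spec)
  sets <- generate_gene_sets(synth)
  lcc <- largest_weak_component(synth$network)
  bt <- bow_tie(lcc)
  mods <- fast_unfolding(lcc, seed = seed)
  dis <- restrict_gene_sets(sets$diseases, bt$lcc)
  pat <- restrict_gene_sets(sets$pathways, bt$lcc)
  c0 <- screen_catg0(dis, bt)
  rem <- subset_gene_sets(dis, c0$remaining_disease_ids)
  sc <- impact_scores(lcc, rem, pat, mods)
  dm <- distance_matrix(sc)
  cut <- difference_vector_cut(ward_cluster(dm), dm)
  list(synth = synth, sets = sets, lcc = lcc, bowtie = bt,
       modules = mods, catg0 = c0, scores = sc, distance = dm,
       cut = cut)
}
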