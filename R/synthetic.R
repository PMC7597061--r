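#' Specification for the synthetic network generator
#'
#' Defines the planted structure used to exercise every pipeline stage
#' without external downloads: a directed stochastic-block core made
#' strongly connected by a cycle, upstream and downstream fringes, and
#' tendril nodes hanging off the downstream fringe — a miniature bow
#' tie. Disease groups draw their genes from group-specific core
#' blocks so that groups have distinguishable impact profiles on
#' block-concentrated pathways; a further batch of diseases is drawn
#' wholly from the downstream pool to exercise the CATG-0 screen.
#'
#' @param n_core Core (strongly connected) node count.
#' @param n_up,n_down,n_tendril Fringe node counts; tendrils attach to
#'   downstream nodes and require `n_down >= 1`.
#' @param n_blocks Planted module count inside the core.
#' @param p_in,p_out Intra-/inter-block directed edge probabilities.
#' @param n_diseases Number of planted-group diseases (excluding
#'   CATG-0 ones).
#' @param genes_per_disease Genes drawn per disease.
#' @param n_groups Planted disease groups (`<= n_blocks`).
#' @param n_catg0 Diseases drawn wholly from downstream nodes.
#' @param n_pathways,genes_per_pathway Pathway count and size; pathways
#'   cycle over blocks.
#' @param noise Per-gene probability that a planted disease gene is
#'   replaced by a random core gene.
#' @param seed Integer seed; the same spec and seed always reproduce
#'   the same data.
#' @return A validated list of class `lamp_synth_spec`.
#' @export
synthetic_spec <- function(n_core = 96L, n_up = 10L, n_down = 12L,
                           n_tendril = 4L, n_blocks = 4L,
                           p_in = 0.25, p_out = 0.02,
                           n_diseases = 40L, genes_per_disease = 6L,
                           n_groups = 4L, n_catg0 = 4L,
                           n_pathways = 12L, genes_per_pathway = 8L,
                           noise = 0.1, seed = 1L) {
  spec <- list(n_core = as.integer(n_core), n_up = as.integer(n_up),
               n_down = as.integer(n_down), n_tendril = as.integer(n_tendril),
               n_blocks = as.integer(n_blocks), p_in = p_in, p_out = p_out,
               n_diseases = as.integer(n_diseases),
               genes_per_disease = as.integer(genes_per_disease),
               n_groups = as.integer(n_groups), n_catg0 = as.integer(n_catg0),
               n_pathways = as.integer(n_pathways),
               genes_per_pathway = as.integer(genes_per_pathway),
               noise = noise, seed = as.integer(seed))
  with(spec, {
    stopifnot(n_core >= n_blocks, n_blocks >= 1, n_up >= 0, n_down >= 0,
              n_tendril >= 0, p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
              noise >= 0, noise <= 1, n_groups >= 1,
              n_diseases >= 0, genes_per_disease >= 1,
              n_pathways >= 0, genes_per_pathway >= 1)
    if (n_groups > n_blocks) {
      stop("n_groups must not exceed n_blocks (one block per group)")
    }
    if (n_tendril > 0 && n_down == 0) {
      stop("tendrils attach to downstream nodes; need n_down >= 1")
    }
    if (n_catg0 > 0 && n_down == 0) {
      stop("CATG-0 diseases need downstream nodes; set n_down >= 1")
    }
    if (genes_per_pathway > floor(n_core / n_blocks)) {
      stop("genes_per_pathway exceeds the core block size")
    }
    if (genes_per_disease > floor(n_core / n_blocks)) {
      stop("genes_per_disease exceeds the core block size")
    }
  })
  structure(spec, class = "lamp_synth_spec")
}

#' Generate a synthetic directed network with planted structure
#'
#' Builds the bow-tie network described by [synthetic_spec()]:
#' block-structured core plus a directed cycle through all core nodes
#' (ordered by block, so the cycle adds only `n_blocks` inter-block
#' edges while guaranteeing strong connectivity), upstream nodes with
#' core-pointing edges only, downstream nodes fed by the core only,
#' and tendril nodes pointing into the downstream fringe.
#'
#' @param spec A `lamp_synth_spec`.
#' @return A list of class `lamp_synthetic` with `network` (igraph),
#'   `truth` (named vectors `block` and `role`, role in
#'   core/up/down/tendril) and `spec`.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "lamp_synth_spec"))
  set.seed(spec$seed)
  core <- sprintf("core%03d", seq_len(spec$n_core))
  up <- if (spec$n_up) sprintf("up%03d", seq_len(spec$n_up)) else character(0)
  down <- if (spec$n_down) sprintf("down%03d", seq_len(spec$n_down)) else character(0)
  tend <- if (spec$n_tendril) sprintf("tend%03d", seq_len(spec$n_tendril)) else character(0)
  block_core <- rep_len(seq_len(spec$n_blocks), spec$n_core)
  block_core <- sort(block_core)
  names(block_core) <- core

  # stochastic-block edges over ordered core pairs
  from_idx <- rep(seq_len(spec$n_core), each = spec$n_core)
  to_idx <- rep(seq_len(spec$n_core), times = spec$n_core)
  keep <- from_idx != to_idx
  from_idx <- from_idx[keep]; to_idx <- to_idx[keep]
  p <- ifelse(block_core[from_idx] == block_core[to_idx],
              spec$p_in, spec$p_out)
  draw <- runif(length(p)) < p
  edges <- cbind(core[from_idx[draw]], core[to_idx[draw]])
  # cycle through block-ordered core nodes guarantees strong connectivity
  cyc <- cbind(core, c(core[-1], core[1]))
  edges <- rbind(edges, cyc)

  block <- block_core
  role <- setNames(rep("core", spec$n_core), core)
  pick_block_nodes <- function(b, k) sample(core[block_core == b], k)
  for (u in up) {
    b <- sample.int(spec$n_blocks, 1)
    k <- sample(1:2, 1)
    edges <- rbind(edges, cbind(u, pick_block_nodes(b, k)))
    block[u] <- b; role[u] <- "up"
  }
  for (d in down) {
    b <- sample.int(spec$n_blocks, 1)
    k <- sample(1:2, 1)
    edges <- rbind(edges, cbind(pick_block_nodes(b, k), d))
    block[d] <- b; role[d] <- "down"
  }
  for (t in tend) {
    target <- sample(down, 1)
    edges <- rbind(edges, cbind(t, target))
    block[t] <- block[target]; role[t] <- "tendril"
  }
  edges <- unique(edges)
  nodes <- c(core, up, down, tend)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2],
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  structure(list(network = g,
                 truth = list(block = block[nodes], role = role[nodes]),
                 spec = spec),
            class = "lamp_synthetic")
}

#' Generate disease and pathway gene sets with planted groups
#'
#' Pathways draw `genes_per_pathway` genes from one core block each
#' (cycling over blocks). Planted disease groups draw their genes from
#' a group-specific block, with each gene independently replaced by a
#' random core gene with probability `noise`; the group index is
#' stored as the disease's `top_level_class`, playing the role of the
#' reference classification in cross-tabulations. A further `n_catg0`
#' diseases are drawn purely from the downstream pool (no noise), so
#' the CATG-0 screen must flag exactly them.
#'
#' @param synth A `lamp_synthetic` network from [generate_network()].
#' @param spec Optional spec override (defaults to `synth$spec`).
#' @return A list with `diseases`, `pathways` (both `lamp_gene_sets`),
#'   and `truth` (named vectors: `group` per disease with `0` for
#'   CATG-0 plants, `pathway_block` per pathway).
#' @export
generate_gene_sets <- function(synth, spec = synth$spec) {
  stopifnot(inherits(synth, "lamp_synthetic"))
  set.seed(spec$seed + 1L)
  role <- synth$truth$role
  block <- synth$truth$block
  core <- names(role)[role == "core"]
  down <- names(role)[role == "down"]

  p_ids <- if (spec$n_pathways) sprintf("P%02d", seq_len(spec$n_pathways)) else character(0)
  p_block <- rep_len(seq_len(spec$n_blocks), spec$n_pathways)
  p_genes <- lapply(seq_len(spec$n_pathways), function(k) {
    pool <- core[block[core] == p_block[k]]
    sample(pool, spec$genes_per_pathway)
  })
  pathways <- gene_set_collection(
    "pathway", p_ids, p_ids,
    top_level_class = paste0("block-", p_block), genes = p_genes)

  d_ids <- if (spec$n_diseases) sprintf("D%03d", seq_len(spec$n_diseases)) else character(0)
  d_group <- sort(rep_len(seq_len(spec$n_groups), spec$n_diseases))
  d_genes <- lapply(seq_len(spec$n_diseases), function(l) {
    pool <- core[block[core] == d_group[l]]
    genes <- sample(pool, spec$genes_per_disease)
    flip <- runif(length(genes)) < spec$noise
    if (any(flip)) genes[flip] <- sample(core, sum(flip), replace = TRUE)
    unique(genes)
  })
  c_ids <- if (spec$n_catg0) sprintf("D_catg0_%02d", seq_len(spec$n_catg0)) else character(0)
  c_genes <- lapply(seq_len(spec$n_catg0), function(l) {
    sample(down, min(spec$genes_per_disease, length(down)))
  })
  diseases <- gene_set_collection(
    "disease", c(d_ids, c_ids), c(d_ids, c_ids),
    top_level_class = c(paste0("group-", d_group),
                        rep("group-0", spec$n_catg0)),
    genes = c(d_genes, c_genes))
  truth_group <- setNames(c(d_group, rep(0L, spec$n_catg0)),
                          c(d_ids, c_ids))
  list(diseases = diseases, pathways = pathways,
       truth = list(group = truth_group,
                    pathway_block = setNames(p_block, p_ids)))
}

#' Rand index between two labelings
#'
#' Fraction of item pairs on which two labelings agree (both together
#' or both apart). Computed from the contingency table of the two
#' labelings.
#'
#' @param a,b Equal-length label vectors over the same items.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) stop("need at least 2 items")
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_a - sum_b) / total
}

#' Adjusted Rand index between two labelings
#'
#' Rand index corrected for chance agreement (expected value 0 under
#' random labelings, 1 for identical partitions).
#'
#' @param a,b Equal-length label vectors over the same items.
#' @return Adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- sum_a * sum_b / total
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(0)
  (sum_ij - expected) / (maxi - expected)
}
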