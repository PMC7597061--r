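#' Inverse average layer summation (IALS)
#'
#' Scores the layered influence of a disease on one module. Each disease
#' gene that belongs to the module contributes the inverse of the
#' average forward-layer index of the module genes it can reach:
#' with \eqn{n_s = |M_t \cap F\_layer_s^{g_i}|} the contribution is
#' \eqn{\sum_{s\ge1} n_s / \sum_{s\ge1} n_s \cdot s}. Disease genes
#' outside the module contribute 0 (the membership indicator
#' \eqn{\delta(g_i, M_t)}), as does a gene whose forward layers contain
#' no module gene at layer 1 or beyond. Sums start at layer 1: layer 0
#' is the disease gene itself and would put zero weight in the
#' denominator.
#'
#' @param net A directed igraph graph with vertex names.
#' @param disease_genes Character vector of disease genes (network
#'   nodes).
#' @param module_genes Character vector of module genes (network nodes).
#' @return Non-negative IALS value.
#' @export
ials <- function(net, disease_genes, module_genes) {
  disease_genes <- unique(as.character(disease_genes))
  module_genes <- unique(as.character(module_genes))
  if (length(disease_genes) == 0) {
    warning("empty disease gene set; IALS = 0")
    return(0)
  }
  nm <- igraph::V(net)$name
  missing <- setdiff(c(disease_genes, module_genes), nm)
  if (length(missing)) {
    stop("gene(s) not in network: ", paste(missing, collapse = ", "))
  }
  contributors <- intersect(disease_genes, module_genes)
  total <- 0
  for (g in contributors) {
    d <- igraph::distances(net, v = g, to = module_genes, mode = "out")[1, ]
    d <- d[is.finite(d) & d >= 1]
    if (length(d)) total <- total + length(d) / sum(d)
  }
  total
}

#' Weighted proportion summation (WPS)
#'
#' Scores the layered influence of a module on one pathway. Reverse
#' layers are built from the pathway genes; the module's share of each
#' layer is summed with geometric discount:
#' \eqn{WPS = \sum_{s\ge0} |M_t \cap R\_layer_s| / |R\_layer_s| \cdot 2^{-s}}.
#' Layer 0 is exactly the pathway genes, so the layer-0 term is the
#' module's fraction of the pathway.
#'
#' @param net A directed igraph graph with vertex names.
#' @param module_genes Character vector of module genes (network nodes).
#' @param pathway_genes Character vector of pathway genes; at least one
#'   must be a network node.
#' @return WPS value in `[0, 2)`.
#' @export
wps <- function(net, module_genes, pathway_genes) {
  module_genes <- unique(as.character(module_genes))
  pathway_genes <- unique(as.character(pathway_genes))
  nm <- igraph::V(net)$name
  pg <- intersect(pathway_genes, nm)
  if (length(pg) == 0) stop("no pathway gene is present in the network")
  missing <- setdiff(module_genes, nm)
  if (length(missing)) {
    stop("module gene(s) not in network: ", paste(missing, collapse = ", "))
  }
  rl <- reverse_layers(net, pg)
  lay <- rl$layer_of
  smax <- max(lay)
  size_s <- tabulate(lay + 1L, nbins = smax + 1L)
  in_module <- lay[names(lay) %in% module_genes]
  mod_s <- tabulate(in_module + 1L, nbins = smax + 1L)
  sum(mod_s / size_s * 2^(-(0:smax)))
}

#' Impact scores of diseases on pathways
#'
#' The LAMP scoring kernel: for every disease l and pathway k,
#' \eqn{IS(D_l, P_k) = \sum_t IALS(D_l, M_t) \cdot WPS(M_t, P_k)} over
#' the modules of `partition`, followed by row-wise min-max
#' normalization \eqn{NIS = (IS - min_h) / (max_h - min_h)}. A constant
#' IS row normalizes to all zeros. Forward layers are computed once per
#' distinct disease gene (they depend only on the gene), and reverse
#' layers once per pathway.
#'
#' @param net A directed igraph graph (the LCC).
#' @param diseases,pathways `lamp_gene_sets` collections already
#'   restricted to the network's genes (see [restrict_gene_sets()]);
#'   genes absent from the network raise an error.
#' @param partition A `lamp_modules` partition of the network's genes.
#' @param chunk_size Number of disease genes per BFS batch.
#' @return A list of class `lamp_scores` with `is` and `nis` matrices
#'   (diseases x pathways), the `ials` (diseases x modules) and `wps`
#'   (modules x pathways) factors, and id vectors.
#' @export
impact_scores <- function(net, diseases, pathways, partition,
                          chunk_size = 256L) {
  stopifnot(inherits(diseases, "lamp_gene_sets"),
            inherits(pathways, "lamp_gene_sets"),
            inherits(partition, "lamp_modules"))
  nm <- igraph::V(net)$name
  memb <- partition$assignment
  if (!all(nm %in% names(memb))) {
    stop("module partition does not cover every network gene")
  }
  all_dg <- unique(unlist(diseases$genes))
  missing <- setdiff(all_dg, nm)
  if (length(missing)) {
    stop("disease gene(s) not in network (restrict collections first): ",
         paste(head(missing, 5), collapse = ", "))
  }
  all_pg <- unique(unlist(pathways$genes))
  missing <- setdiff(all_pg, nm)
  if (length(missing)) {
    stop("pathway gene(s) not in network (restrict collections first): ",
         paste(head(missing, 5), collapse = ", "))
  }
  n_mod <- partition$n_modules
  module_idx <- lapply(seq_len(n_mod), function(t) {
    which(nm %in% names(memb)[memb == t])
  })

  # per-gene IALS contribution: the gene's own module only (delta term)
  gene_contrib <- setNames(numeric(length(all_dg)), all_dg)
  gene_module <- memb[all_dg]
  for (start in seq(1, length(all_dg), by = chunk_size)) {
    chunk <- all_dg[start:min(start + chunk_size - 1L, length(all_dg))]
    d <- igraph::distances(net, v = chunk, to = igraph::V(net), mode = "out")
    for (i in seq_along(chunk)) {
      g <- chunk[i]
      dm <- d[i, module_idx[[gene_module[g]]]]
      dm <- dm[is.finite(dm) & dm >= 1]
      gene_contrib[g] <- if (length(dm)) length(dm) / sum(dm) else 0
    }
  }

  d_ids <- diseases$table$id
  A <- matrix(0, nrow = length(d_ids), ncol = n_mod,
              dimnames = list(d_ids, paste0("M", seq_len(n_mod))))
  for (l in seq_along(d_ids)) {
    genes <- diseases$genes[[d_ids[l]]]
    for (g in genes) {
      t <- gene_module[g]
      A[l, t] <- A[l, t] + gene_contrib[g]
    }
  }

  p_ids <- pathways$table$id
  W <- matrix(0, nrow = n_mod, ncol = length(p_ids),
              dimnames = list(paste0("M", seq_len(n_mod)), p_ids))
  for (k in seq_along(p_ids)) {
    rl <- reverse_layers(net, pathways$genes[[p_ids[k]]])
    lay <- rl$layer_of
    smax <- max(lay)
    size_s <- tabulate(lay + 1L, nbins = smax + 1L)
    disc <- 2^(-(0:smax))
    for (t in seq_len(n_mod)) {
      in_mod <- lay[names(lay) %in% nm[module_idx[[t]]]]
      mod_s <- tabulate(in_mod + 1L, nbins = smax + 1L)
      W[t, k] <- sum(mod_s / size_s * disc)
    }
  }

  IS <- A %*% W
  NIS <- t(apply(IS, 1, .minmax_row))
  dimnames(NIS) <- dimnames(IS)
  structure(list(is = IS, nis = NIS, ials = A, wps = W,
                 disease_ids = d_ids, pathway_ids = p_ids),
            class = "lamp_scores")
}

.minmax_row <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' @export
print.lamp_scores <- function(x, ...) {
  cat(sprintf("<lamp_scores> %d diseases x %d pathways (%d modules)\n",
              nrow(x$is), ncol(x$is), ncol(x$ials)))
  invisible(x)
}

#' Screen CATG-0 diseases
#'
#' A disease is assigned to CATG-0 when ALL of its (LCC-restricted)
#' genes lie in DOWN_LSCC: perturbing such genes can only propagate to
#' other downstream genes, never back into the strongly connected core.
#' These diseases are grouped before clustering.
#'
#' @param diseases A `lamp_gene_sets` collection restricted to the LCC.
#' @param decomp A `lamp_bowtie` decomposition of the same LCC.
#' @return A list of class `lamp_catg0` with `catg0_disease_ids`,
#'   `catg0_gene_pool` (the union of their genes, all in DOWN_LSCC) and
#'   `remaining_disease_ids`.
#' @export
screen_catg0 <- function(diseases, decomp) {
  stopifnot(inherits(diseases, "lamp_gene_sets"),
            inherits(decomp, "lamp_bowtie"))
  down <- decomp$down_lscc
  is0 <- vapply(diseases$genes, function(g) all(g %in% down), logical(1))
  ids <- diseases$table$id
  structure(list(catg0_disease_ids = ids[is0],
                 catg0_gene_pool = sort(unique(unlist(diseases$genes[is0]))),
                 remaining_disease_ids = ids[!is0]),
            class = "lamp_catg0")
}

#' @export
print.lamp_catg0 <- function(x, ...) {
  cat(sprintf("<lamp_catg0> %d CATG-0 diseases (%d pooled genes), %d remaining\n",
              length(x$catg0_disease_ids), length(x$catg0_gene_pool),
              length(x$remaining_disease_ids)))
  invisible(x)
}
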