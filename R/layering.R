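#' Forward layered network
#'
#' Multi-source BFS strata along edge direction: layer 0 is the seed
#' (source) set, and the layer of every other included gene is the
#' length of the shortest directed path from the nearest seed. Genes
#' unreachable from every seed are excluded. Edges within a layer or
#' pointing backward do not affect layer indices.
#'
#' @param net A directed igraph graph with vertex names.
#' @param sources Non-empty character vector of seed genes, all present
#'   in the network.
#' @return A list of class `lamp_layers` with `mode`, `seeds`,
#'   `layer_of` (named integer vector over included genes) and
#'   `n_layers`.
#' @export
forward_layers <- function(net, sources) {
  .layers(net, sources, mode = "forward")
}

#' Reverse layered network
#'
#' Multi-source BFS on the edge-reversed graph: layer 0 is the target
#' set and layer s holds the genes whose shortest directed path TO the
#' nearest target has length s. Equivalent to [forward_layers()] on the
#' transposed network.
#'
#' @param net A directed igraph graph with vertex names.
#' @param targets Non-empty character vector of target genes.
#' @return A `lamp_layers` object (see [forward_layers()]).
#' @export
reverse_layers <- function(net, targets) {
  .layers(net, targets, mode = "reverse")
}

.layers <- function(net, seeds, mode) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) stop("seed set is empty")
  nm <- igraph::V(net)$name
  missing <- setdiff(seeds, nm)
  if (length(missing)) {
    stop("seed gene(s) not in network: ", paste(missing, collapse = ", "))
  }
  igmode <- if (mode == "forward") "out" else "in"
  d <- igraph::distances(net, v = seeds, to = igraph::V(net), mode = igmode)
  nearest <- apply(d, 2, min)
  keep <- is.finite(nearest)
  layer_of <- setNames(as.integer(nearest[keep]), nm[keep])
  structure(list(mode = mode, seeds = seeds, layer_of = layer_of,
                 n_layers = max(layer_of) + 1L),
            class = "lamp_layers")
}

#' @export
print.lamp_layers <- function(x, ...) {
  cat(sprintf("<lamp_layers> %s from %d seed(s): %d genes in %d layer(s)\n",
              x$mode, length(x$seeds), length(x$layer_of), x$n_layers))
  invisible(x)
}

#' Genes in a given layer
#' @param x A `lamp_layers` object.
#' @param s Layer index (0-based).
#' @export
layer_genes <- function(x, s) {
  stopifnot(inherits(x, "lamp_layers"))
  names(x$layer_of)[x$layer_of == s]
}
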