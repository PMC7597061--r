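#' Two-dimensional tSNE embedding of disease score vectors
#'
#' Exact-gradient t-SNE of the NIS rows, used to visualize and QC the
#' clustering; the embedding is never consumed by the classification
#' logic itself. Defaults follow the usual visualization settings for
#' this analysis: perplexity 30, early exaggeration 12 for the first
#' 250 iterations, learning rate 200 and 3000 iterations. When fewer
#' than `3 * perplexity + 1` rows are supplied the perplexity is shrunk
#' to `floor((n - 1) / 3)` with a message.
#'
#' @param scores A `lamp_scores` object or numeric matrix of row
#'   vectors.
#' @param seed Integer seed for the random initialization.
#' @param perplexity Target perplexity of the conditional neighbor
#'   distributions.
#' @param exaggeration Early exaggeration factor.
#' @param eta Learning rate.
#' @param max_iter Number of gradient iterations.
#' @return A data.frame with columns `id`, `tsne1`, `tsne2`.
#' @export
tsne_embed <- function(scores, seed = 1L, perplexity = 30,
                       exaggeration = 12, eta = 200, max_iter = 3000) {
  X <- if (inherits(scores, "lamp_scores")) scores$nis else as.matrix(scores)
  if (any(!is.finite(X))) stop("non-finite values in score matrix")
  n <- nrow(X)
  if (n < 4) stop("need at least 4 rows to embed")
  max_perp <- floor((n - 1) / 3)
  if (perplexity > max_perp) {
    message("perplexity shrunk from ", perplexity, " to ", max_perp,
            " for n = ", n)
    perplexity <- max_perp
  }
  P <- .tsne_affinities(X, perplexity)
  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  stop_lying <- min(250L, max_iter)
  eps <- .Machine$double.eps
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= stop_lying) P * exaggeration else P
    momentum <- if (iter <= stop_lying) 0.5 else 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    L <- (Pe - pmax(Q, eps)) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- pmax(0.01,
                  ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8))
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  data.frame(id = ids, tsne1 = Y[, 1], tsne2 = Y[, 2],
             stringsAsFactors = FALSE)
}

# symmetric joint affinities with per-point precision calibrated to the
# target perplexity by bisection
.tsne_affinities <- function(X, perplexity, tol = 1e-5) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (tries in 1:64) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.eps)
}
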