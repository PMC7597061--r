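test_that("distance matrix is Euclidean, symmetric and oracle-exact", {
  X <- rbind(a = c(0, 0), b = c(3, 4))
  m <- distance_matrix(X)
  expect_equal(m["a", "b"], 5)
  expect_equal(diag(m), c(a = 0, b = 0))
  expect_equal(distance_matrix(rbind(a = c(1, 2), b = c(1, 2)))["a", "b"], 0)
  set.seed(4)
  Y <- matrix(runif(60), 10, 6, dimnames = list(paste0("d", 1:10), NULL))
  m2 <- distance_matrix(Y)
  for (i in 1:10) for (j in 1:10) {
    expect_equal(m2[i, j], sqrt(sum((Y[i, ] - Y[j, ])^2)),
                 tolerance = 1e-12)
  }
  Ybad <- Y
  Ybad[3, 2] <- NaN
  expect_error(distance_matrix(Ybad), "d3")
})

test_that("Ward.D2 clustering behaves on canonical geometries", {
  m2 <- distance_matrix(rbind(a = 0, b = 7))
  hc <- ward_cluster(m2)
  expect_equal(hc$height, 7)
  # two tight far-apart pairs merge pairwise first
  X <- rbind(a1 = c(0, 0), a2 = c(0.1, 0), b1 = c(100, 0), b2 = c(100.1, 0))
  hc4 <- ward_cluster(distance_matrix(X))
  expect_equal(sort(hc4$height[1:2]), c(0.1, 0.1))
  first_two <- vapply(1:2, function(i) {
    paste(sort(-hc4$merge[i, ]), collapse = "-")
  }, character(1))
  expect_setequal(first_two, c("1-2", "3-4"))
  expect_error(ward_cluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  # determinism
  expect_identical(ward_cluster(distance_matrix(X)),
                   ward_cluster(distance_matrix(X)))
})

test_that("difference-vector cut recovers three planted blobs", {
  set.seed(7)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  X <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(60, sd = 0.1), 30, 2), 2, centers[i, ], "+")
  }))
  rownames(X) <- paste0("p", 1:90)
  m <- distance_matrix(X)
  hc <- ward_cluster(m)
  for (pooling in c("cluster", "pairs")) {
    cut <- difference_vector_cut(hc, m, pooling = pooling)
    expect_equal(cut$k, 3)
    expect_equal(rand_index(cut$labels, rep(1:3, each = 30)), 1)
  }
})

test_that("difference vector equals brute-force pair pooling", {
  set.seed(11)
  X <- matrix(runif(48), 12, 4, dimnames = list(paste0("d", 1:12), NULL))
  m <- distance_matrix(X)
  hc <- ward_cluster(m)
  cut <- difference_vector_cut(hc, m, k_min = 2, k_max = 6,
                               pooling = "pairs")
  for (k in 2:6) {
    lab <- cutree(hc, k)
    w <- c(); b <- c()
    for (i in 1:11) for (j in (i + 1):12) {
      if (lab[i] == lab[j]) w <- c(w, m[i, j]) else b <- c(b, m[i, j])
    }
    expect_equal(cut$delta[[as.character(k)]], mean(b) - mean(w),
                 tolerance = 1e-12)
  }
  # cluster-averaged variant against its own brute force
  cutc <- difference_vector_cut(hc, m, k_min = 2, k_max = 6)
  for (k in 2:6) {
    lab <- cutree(hc, k)
    wm <- c(); bm <- c()
    for (a in sort(unique(lab))) {
      ia <- which(lab == a)
      if (length(ia) > 1) {
        wm <- c(wm, mean(m[ia, ia][upper.tri(m[ia, ia])]))
      }
      for (b2 in sort(unique(lab))) {
        if (b2 > a) bm <- c(bm, mean(m[ia, lab == b2, drop = FALSE]))
      }
    }
    expect_equal(cutc$delta[[as.character(k)]], mean(bm) - mean(wm),
                 tolerance = 1e-12)
  }
})

test_that("degenerate within-distances are handled at k = 2", {
  X <- rbind(a = c(0, 0), b = c(0, 0), c = c(9, 0))
  m <- distance_matrix(X)
  hc <- ward_cluster(m)
  cut <- difference_vector_cut(hc, m, k_min = 2, k_max = 2,
                               pooling = "pairs")
  expect_equal(cut$k, 2)
  # within pool is the identical pair: mean 0, so delta = between mean
  expect_equal(cut$delta[["2"]], 9)
})

test_that("category assembly, refinement and its guarantees", {
  labels <- c(d1 = 1L, d2 = 1L, d3 = 2L)
  prelim <- make_category_assignment(labels, catg0_ids = "d0")
  expect_equal(prelim$labels[["d0"]], "CATG-0")
  expect_equal(prelim$labels[["d3"]], "CATG-2")
  expect_equal(prelim$n_categories, 3)
  expect_equal(prelim$provenance, "preliminary")
  # dual membership added, never removed
  refined <- apply_refinements(prelim, list(d3 = "CATG-1"))
  expect_setequal(refined$labels[["d3"]], c("CATG-2", "CATG-1"))
  expect_equal(refined$provenance, "refined")
  expect_true(all(lengths(refined$labels) >= lengths(prelim$labels)))
  # empty override: identity up to provenance
  ref2 <- apply_refinements(prelim, list())
  expect_equal(ref2$labels, prelim$labels)
  expect_error(apply_refinements(prelim, list(nope = "CATG-1")), "nope")
  expect_error(apply_refinements(prelim, list(d1 = "CATG-99")), "CATG-99")
  expect_error(make_category_assignment(labels, catg0_ids = "d1"), "d1")
})

test_that("refinement configs round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("additions:", "  d3:", "    - CATG-1"), f)
  ov <- read_refinements(f)
  expect_equal(ov, list(d3 = "CATG-1"))
})

test_that("Shannon entropy evaluates and bounds correctly", {
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(shannon_entropy(c(0.7, 0.3, 0)), shannon_entropy(c(0.7, 0.3)))
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(-0.5, 1.5)), "non-negative")
  set.seed(21)
  for (i in 1:200) {
    v <- sample(2:8, 1)
    p <- runif(v)
    p <- p / sum(p)
    h <- shannon_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log2(v) + 1e-12)
  }
})

test_that("cross-tabulation composes, normalizes and scores entropy", {
  mk <- function(l) structure(list(labels = l,
                                   n_categories = length(unique(unlist(l))),
                                   provenance = "preliminary"),
                              class = "lamp_categories")
  a <- mk(list(d1 = "a1", d2 = "a1", d3 = "a1", d4 = "a1"))
  b <- mk(list(d1 = "b1", d2 = "b1", d3 = "b2", d4 = "b2"))
  xt <- category_crosstab(a, b)
  expect_equal(unname(xt$composition_ab["a1", ]), c(0.5, 0.5))
  expect_equal(unname(xt$entropy_ab[["a1"]]), 1)
  expect_true(all(abs(rowSums(xt$composition_ab) - 1) < 1e-12))
  expect_true(all(abs(rowSums(xt$composition_ba) - 1) < 1e-12))
  # identical assignments: point masses, zero entropy
  xt2 <- category_crosstab(b, b)
  expect_true(all(xt2$entropy_ab == 0))
  disjoint <- mk(list(e1 = "x"))
  expect_error(category_crosstab(a, disjoint), "disjoint")
})

test_that("tSNE embedding is reproducible and separates planted clusters", {
  set.seed(13)
  X <- rbind(matrix(rnorm(40, mean = 0, sd = 0.05), 20, 2),
             matrix(rnorm(40, mean = 5, sd = 0.05), 20, 2))
  rownames(X) <- paste0("d", 1:40)
  e1 <- suppressMessages(tsne_embed(X, seed = 3, max_iter = 400))
  e2 <- suppressMessages(tsne_embed(X, seed = 3, max_iter = 400))
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 40)
  y <- as.matrix(e1[, c("tsne1", "tsne2")])
  cent1 <- colMeans(y[1:20, ]); cent2 <- colMeans(y[21:40, ])
  sep <- sqrt(sum((cent1 - cent2)^2))
  rad <- mean(c(sqrt(rowSums(sweep(y[1:20, ], 2, cent1)^2)),
                sqrt(rowSums(sweep(y[21:40, ], 2, cent2)^2))))
  expect_gt(sep, rad)
  Xbad <- X
  Xbad[1, 1] <- Inf
  expect_error(suppressMessages(tsne_embed(Xbad, seed = 1)), "non-finite")
})
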