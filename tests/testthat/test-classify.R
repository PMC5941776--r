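test_that("two opposite-class samples are both prototypes with cost zero", {
  fit <- opf(rbind(c(0, 0), c(1, 1)), c("CG", "PG"))
  expect_identical(sort(fit$prototypes), 1:2)
  expect_equal(fit$cost, c(0, 0))
  expect_identical(predict(fit, c(0.1, 0)), "CG")
  expect_identical(predict(fit, c(0.9, 1)), "PG")
})

test_that("single-class training falls back to one prototype", {
  set.seed(8)
  x <- matrix(rnorm(20), 10, 2)
  fit <- opf(x, rep("CG", 10))
  expect_identical(fit$prototypes, 1L)
  expect_identical(unique(predict(fit, matrix(rnorm(10), 5, 2))), "CG")
})

test_that("path-max costs match exhaustive path enumeration (random 6-node sets)", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (trial in 1:100) {
    x <- matrix(runif(12), 6, 2)
    y <- sample(c("A", "B"), 6, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- setdiff(c("A", "B"), y[1])
    fit <- opf(x, y)
    d <- as.matrix(dist(x))
    # independent prototype oracle: endpoints of inter-class MST edges
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::mst(g)
    el <- igraph::as_edgelist(mst, names = FALSE)
    inter <- el[y[el[, 1]] != y[el[, 2]], , drop = FALSE]
    expect_identical(sort(fit$prototypes), sort(unique(as.integer(inter))))
    # exhaustive minimax path costs from the prototype set
    expect_equal(fit$cost, oracle_opf_costs(d, fit$prototypes),
                 tolerance = 1e-12)
    # assigned labels trace back to prototypes: prototypes keep their own
    expect_identical(fit$labels[fit$prototypes], y[fit$prototypes])
  }
})

test_that("OPF classifies its own distinct training samples perfectly", {
  set.seed(12)
  x <- matrix(rnorm(60), 30, 2)
  y <- rep(c("CG", "PG"), 15)
  fit <- opf(x, y)
  expect_identical(predict(fit, x), y)
  # stored scan order is nondecreasing in cost with zero-cost prototypes first
  expect_true(all(diff(fit$cost[fit$order]) >= 0))
  expect_true(all(fit$cost[fit$prototypes] == 0))
})

test_that("early-stopping prediction equals a full scan", {
  set.seed(13)
  b <- blob_data(n_per_class = 25, sdev = 1.5, gap = 2, seed = 13)
  fit <- opf(b$x, b$y)
  queries <- matrix(rnorm(40, 1), 20, 2)
  full_scan <- apply(queries, 1, function(q) {
    val <- pmax(fit$cost, sqrt(colSums((t(fit$x) - q)^2)))
    # ties resolve to the earliest sample in cost order
    cand <- which(val == min(val))
    fit$labels[cand[which.min(match(cand, fit$order))]]
  })
  expect_identical(predict(fit, queries), unname(full_scan))
})

test_that("all three classifiers separate well-separated Gaussian blobs", {
  b <- blob_data(n_per_class = 50, sdev = 0.1, gap = 10, seed = 2)
  test <- blob_data(n_per_class = 20, sdev = 0.1, gap = 10, seed = 3)
  expect_identical(predict(opf(b$x, b$y), test$x), test$y)
  svm_m <- svm_fit(b$x, b$y, cost = 1, gamma = 0.5)
  expect_identical(as.character(predict(svm_m, test$x)), test$y)
  nb_m <- nb_fit(b$x, b$y)
  expect_identical(as.character(predict(nb_m, as.data.frame(test$x))), test$y)
})

test_that("Naive Bayes boundary sits between symmetric classes; variance floor holds", {
  set.seed(21)
  x <- cbind(c(rnorm(40, -5), rnorm(40, 5)), rep(1, 80)) # constant feature
  y <- rep(c("neg", "pos"), each = 40)
  fit <- nb_fit(x, y)
  expect_identical(as.character(predict(fit, data.frame(V1 = 1, V2 = 1))), "pos")
  expect_identical(as.character(predict(fit, data.frame(V1 = -1, V2 = 1))), "neg")
  expect_true(all(vapply(fit$tables, function(tb) all(tb[, 2] > 0), TRUE)))
})

test_that("SVM grid selection is deterministic and finds a separating model", {
  b <- blob_data(n_per_class = 30, sdev = 0.5, gap = 6, seed = 4)
  val <- blob_data(n_per_class = 10, sdev = 0.5, gap = 6, seed = 5)
  s1 <- svm_select(b$x, b$y, val$x, val$y)
  s2 <- svm_select(b$x, b$y, val$x, val$y)
  expect_identical(s1, s2)
  expect_equal(s1$val_error, 0)
  fit <- svm_fit(b$x, b$y, s1$cost, s1$gamma)
  expect_identical(as.character(predict(fit, val$x)), val$y)
})
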