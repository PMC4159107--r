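test_that("sample distance is the cosine distance", {
  expect_equal(sample_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(sample_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(sample_distance(c(1, 2), c(3, 6)), 0)          # scale invariance
  expect_equal(sample_distance(c(1, 0), c(-1, 0)), 2)          # antipodal
  expect_error(sample_distance(c(1, 2), c(1, 2, 3)), "lengths")
  expect_error(sample_distance(c(0, 0), c(1, 2)), "zero-norm")
})

test_that("cosine distance properties hold on random vectors", {
  set.seed(77)
  for (i in 1:50) {
    p <- sample(2:8, 1)
    a <- rnorm(p); b <- rnorm(p)
    d <- sample_distance(a, b)
    expect_gte(d, 0); expect_lte(d, 2)
    expect_equal(d, sample_distance(b, a), tolerance = 1e-12)
    expect_equal(sample_distance(a, a), 0, tolerance = 1e-12)
    expect_equal(sample_distance(runif(1, 0.1, 10) * a, b), d,
                 tolerance = 1e-12)
  }
})

test_that("1-NN predicts by brute-force minimal distance", {
  set.seed(4)
  train <- matrix(rnorm(15), 5, 3)
  labs <- c("NT", "PT", "MT", "PT", "NT")
  expect_identical(predict_nn1(train, labs, train[3, ]), "MT")
  expect_identical(predict_nn1(train[1, , drop = FALSE], "PT", rnorm(3)), "PT")
  for (i in 1:10) {
    q <- rnorm(3)
    d <- apply(train, 1, oracle_cosine, b = q)
    expect_identical(predict_nn1(train, labs, q), labs[which.min(d)])
  }
})

test_that("5-NN vote takes the majority, nearest-representative on ties", {
  # unanimous neighborhood
  train <- rbind(diag(3) + 0.01, diag(3) + 0.02, diag(3) + 0.03)
  labs <- rep(c("A", "B", "C"), 3)
  q <- c(1, 0.01, 0.01)
  expect_identical(predict_vote5(train, labs, q), "A")

  # 2-2-1 tie: the tied label with the nearest representative wins
  base <- c(1, 0)
  ang <- function(t) c(cos(t), sin(t))
  train2 <- rbind(ang(0.10), ang(0.30), ang(0.15), ang(0.35), ang(0.50))
  labs2 <- c("A", "A", "B", "B", "C")
  # neighbors of q sorted: A(0.10), B(0.15), A(0.30), B(0.35), C(0.50)
  # A and B tie 2-2; A's representative is nearest
  expect_identical(predict_vote5(train2, labs2, base), "A")

  expect_warning(predict_vote5(train2[1:3, ], labs2[1:3], base), "truncated")
})

test_that("5-NN vote agrees with an exhaustive tally on random fixtures", {
  set.seed(9)
  for (i in 1:10) {
    train <- matrix(rnorm(36), 12, 3)
    labs <- sample(c("NT", "PT", "MT"), 12, replace = TRUE)
    q <- rnorm(3)
    d <- apply(train, 1, oracle_cosine, b = q)
    top5 <- labs[order(d)[1:5]]
    tab <- table(top5)
    tied <- names(tab)[tab == max(tab)]
    want <- if (length(tied) == 1) tied else top5[top5 %in% tied][1]
    expect_identical(predict_vote5(train, labs, q), want)
  }
})

test_that("nearest-centroid matches independent centroid computation", {
  set.seed(6)
  train <- matrix(rnorm(30, mean = 3), 10, 3)
  labs <- rep(c("NT", "PT"), each = 5)
  ctr_nt <- colMeans(train[1:5, ]); ctr_pt <- colMeans(train[6:10, ])
  expect_identical(predict_centroid(train, labs, ctr_nt,
                                    class_order = c("NT", "PT")), "NT")
  for (i in 1:10) {
    q <- rnorm(3, mean = 3)
    want <- if (oracle_cosine(ctr_nt, q) <= oracle_cosine(ctr_pt, q)) "NT" else "PT"
    expect_identical(predict_centroid(train, labs, q, c("NT", "PT")), want)
  }
  # symmetric tie goes to the earlier class in class_order
  train2 <- rbind(c(1, 0), c(0, 1))
  expect_identical(predict_centroid(train2, c("X", "Y"), c(1, 1), c("X", "Y")),
                   "X")
  expect_identical(predict_centroid(train2, c("X", "Y"), c(1, 1), c("Y", "X")),
                   "Y")
})

test_that("all engines agree in the one-training-sample-per-class limit", {
  train <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  labs <- c("NT", "PT", "MT")
  q <- c(0, 1, 0)
  expect_identical(predict_nn1(train, labs, q), "PT")
  expect_identical(suppressWarnings(predict_vote5(train, labs, q)), "PT")
  expect_identical(predict_centroid(train, labs, q, labs), "PT")
})

test_that("jackknife isolates the held-out sample", {
  # two identical samples with different labels predict each other: accuracy 0
  vals <- matrix(c(1, 2, 1, 2), 2, 2,
                 dimnames = list(c("p1", "p2"), c("s1", "s2")))
  lem <- labeled_expression_matrix(vals, c("A", "B"), c("A", "B"))
  jk <- jackknife(lem, c("p1", "p2"), engine = "nn1")
  expect_equal(unname(jk$accuracy["nn1"]), 0)
  expect_equal(nrow(jk$predictions), 2)

  # separable synthetic data: perfect 1-NN accuracy, one record per sample
  sim <- simulate_expression_dataset(
    expression_sim_config(n_samples_per_class = c(NT = 15, PT = 12, MT = 8),
                          effect_size = 6, n_null = 10, seed = 5))
  inf <- sim$truth$probe_id[sim$truth$role == "informative"]
  jk2 <- jackknife(sim$matrix, inf, engine = c("nn1", "vote5", "centroid"))
  expect_equal(nrow(jk2$predictions), 35)
  expect_equal(unname(jk2$accuracy["nn1"]), 1)
})

test_that("a sample's own label never leaks into its own prediction", {
  sim <- simulate_expression_dataset(
    expression_sim_config(n_samples_per_class = c(NT = 8, PT = 8, MT = 6),
                          n_null = 6, seed = 13))
  lem <- sim$matrix
  feats <- lem$probe_ids[1:6]
  base <- jackknife(lem, feats, engine = c("nn1", "vote5", "centroid"))
  for (i in c(1, 10, 20)) {
    labs2 <- as.character(lem$labels)
    labs2[i] <- setdiff(lem$class_order, labs2[i])[1]
    lem2 <- labeled_expression_matrix(lem$values, labs2, lem$class_order)
    mut <- jackknife(lem2, feats, engine = c("nn1", "vote5", "centroid"))
    for (e in c("nn1", "vote5", "centroid"))
      expect_identical(mut$predictions[[e]][i], base$predictions[[e]][i],
                       info = paste("engine", e, "sample", i))
  }
})

test_that("accuracy and confusion counts follow the defining formula", {
  expect_equal(accuracy(list(TP = 5, TN = 5, FP = 0, FN = 0)), 1)
  expect_equal(accuracy(list(TP = 3, TN = 4, FP = 2, FN = 1)), 0.7)
  expect_equal(accuracy(list(TP = 0, TN = 0, FP = 1, FN = 1)), 0)
  expect_error(accuracy(list(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")

  true <- c("A", "A", "B", "B", "C")
  pred <- c("A", "B", "B", "B", "A")
  cc <- confusion_counts(true, pred, positive = "A")
  expect_equal(cc, list(TP = 1, TN = 2, FP = 1, FN = 1))
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, length(true))
  # micro-summed one-vs-rest accuracy reproduces mean correctness
  for (cl in c("A", "B", "C")) {
    cci <- confusion_counts(true, pred, cl)
    expect_equal((cci$TP + cci$FN), sum(true == cl))
  }
})

test_that("pairwise accuracy restricts to the two phases and ignores others", {
  preds <- data.frame(
    sample_id = paste0("s", 1:6),
    true = c("NT", "NT", "MT", "MT", "PT", "PT"),
    nn1 = c("NT", "MT", "MT", "NT", "PT", "NT"),
    stringsAsFactors = FALSE)
  expect_equal(pairwise_accuracy(preds, "nn1", "NT", "MT"), 0.5)  # 2 of 4
  # flipping a PT (third-class) prediction leaves the NT-vs-MT value unchanged
  preds2 <- preds; preds2$nn1[5] <- "MT"
  expect_equal(pairwise_accuracy(preds2, "nn1", "NT", "MT"), 0.5)
  expect_equal(pairwise_accuracy(preds, "nn1", "PT", "MT"), 0.5)  # 2 of 4
  expect_error(pairwise_accuracy(preds, "nn1", "XX", "YY"), "empty")
})
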