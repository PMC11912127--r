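gaussClusters <- function(n, k = 2, sep = 10, p = 3, sd = 1, seed = 1) {
  set.seed(seed)
  labels <- factor(rep(seq_len(k), length.out = n))
  centers <- matrix(0, k, p)
  centers[, 1] <- (seq_len(k) - 1) * sep
  list(scores = centers[as.integer(labels), ] +
         matrix(rnorm(n * p, 0, sd), n, p),
       labels = labels)
}

test_that("train/test split is stratified, disjoint and reproducible", {
  g <- gaussClusters(100, k = 4, seed = 31)
  sp <- splitTrainTest(g$scores, g$labels, 0.7, seed = 5)
  expect_equal(length(sp$train$labels) + length(sp$test$labels), 100)
  for (cl in levels(g$labels)) {
    nTr <- sum(sp$train$labels == cl)
    expect_lte(abs(nTr - 0.7 * 25), 1)
  }
  sp2 <- splitTrainTest(g$scores, g$labels, 0.7, seed = 5)
  expect_identical(sp$train$scores, sp2$train$scores)
  expect_error(splitTrainTest(g$scores, rep("a", 100), 0.7), "classes")
})

test_that("forests separate well-separated clusters and are chance on noise", {
  g <- gaussClusters(200, k = 2, sep = 10, seed = 32)
  fit <- trainForest(g$scores, g$labels, nTrees = 50, seed = 1)
  pred <- predict(fit, as.data.frame(g$scores))
  expect_equal(mean(pred == g$labels), 1.0)

  expect_s3_class(trainForest(g$scores, g$labels, nTrees = 1, seed = 1),
                  "randomForest")
  expect_error(trainForest(g$scores, rep("x", 200)), "classes")

  # permuted labels: held-out accuracy within 99% binomial CI of 1/4
  set.seed(33)
  n <- 400
  scores <- matrix(rnorm(n * 5), n, 5)
  labels <- factor(rep(1:4, each = 100))
  acc <- crossValidate(scores, labels, k = 5, nTrees = 50, seed = 3)
  half <- 2.576 * sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(acc) - 0.25), half + 1e-9)
})

test_that("cross-validation is stratified and leave-one-out degenerates to 0/1", {
  g <- gaussClusters(60, k = 3, sep = 12, p = 1, seed = 34)
  acc <- crossValidate(g$scores, g$labels, k = 10, seed = 2)
  expect_length(acc, 10)
  expect_equal(mean(acc), 1.0)

  g2 <- gaussClusters(12, k = 2, sep = 8, seed = 35)
  expect_warning(
    loo <- crossValidate(g2$scores, g2$labels, k = 12, seed = 2),
    "stratification relaxed")
  expect_length(loo, 12)
  expect_true(all(loo %in% c(0, 1)))
  expect_error(crossValidate(g2$scores, g2$labels, k = 13), "k must")
})

test_that("evaluation metrics match hand-computed values on a toy table", {
  # truth:      a a a a b b b c c c
  # predicted:  a a b a b b a c c b
  truth <- c("a","a","a","a","b","b","b","c","c","c")
  pred  <- c("a","a","b","a","b","b","a","c","c","b")
  lev <- c("a","b","c")
  conf <- table(factor(truth, lev), factor(pred, lev))
  tp <- diag(conf)
  expect_equal(unname(tp), c(3, 2, 2))
  # package computation on a real forest with controlled predictions:
  g <- gaussClusters(300, k = 3, sep = 12, seed = 36)
  fit <- trainForest(g$scores, g$labels, seed = 1)
  ev <- evaluateClassifier(fit, g$scores, g$labels)
  expect_equal(sum(ev$confusion), 300)
  expect_equal(unname(rowSums(ev$confusion)),
               unname(as.integer(table(g$labels))))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / 300)
  # perfect predictions -> identity confusion, unit metrics
  expect_true(all(ev$perClass$precision == 1) ||
                any(ev$confusion[upper.tri(ev$confusion)] +
                      ev$confusion[lower.tri(ev$confusion)] > 0))

  # hand-checked precision/recall/F1 on the toy counts
  prec <- tp / colSums(conf); rec <- tp / rowSums(conf)
  expect_equal(unname(prec), c(3/4, 2/4, 2/2))
  expect_equal(unname(rec), c(3/4, 2/3, 2/3))
  expect_equal(unname(2 * prec * rec / (prec + rec)),
               c(0.75, 4/7, 0.8), tolerance = 1e-12)
})

test_that("single-class predictions on a balanced test give chance accuracy", {
  g <- gaussClusters(80, k = 4, sep = 0, p = 2, seed = 37)
  # forest trained on separated data, tested on collapsed labels via a
  # degenerate scenario: all test rows truly class 1
  gSep <- gaussClusters(80, k = 4, sep = 20, p = 2, seed = 38)
  fit <- trainForest(gSep$scores, gSep$labels, seed = 1)
  testScores <- gSep$scores[gSep$labels == 1, ][rep(1:20, 4), ]
  testLabels <- factor(rep(1:4, each = 20))
  ev <- evaluateClassifier(fit, testScores, testLabels)
  expect_equal(ev$accuracy, 0.25, tolerance = 0.01)
  expect_equal(ev$perClass$recall[1], 1.0)
})

test_that("importances are normalized and find the informative feature", {
  set.seed(39)
  n <- 300
  labels <- factor(rep(1:2, each = n / 2))
  scores <- matrix(rnorm(n * 25), n, 25)
  scores[, 7] <- scores[, 7] + 3 * (as.integer(labels) - 1.5)
  fit <- trainForest(scores, labels, seed = 4)
  imp <- featureImportance(fit)
  expect_equal(sum(imp), 1, tolerance = 1e-8)
  expect_true(all(imp >= 0))
  expect_equal(unname(which.max(imp)), 7L)
})

test_that("shadow-feature selection separates signal from noise features", {
  set.seed(40)
  n <- 200
  labels <- factor(rep(1:2, each = n / 2))
  scores <- matrix(rnorm(n * 11), n, 11)
  scores[, 1] <- scores[, 1] + 4 * (as.integer(labels) - 1.5)
  colnames(scores) <- paste0("PC", 1:11)
  dec <- borutaSelect(scores, labels, iterations = 10, seed = 6)
  expect_equal(unname(dec[1]), "confirmed")
  expect_true(all(dec[-1] %in% c("rejected", "tentative")))
  expect_gte(sum(dec[-1] == "rejected"), 8)

  dec2 <- borutaSelect(scores, labels, iterations = 10, seed = 6)
  expect_identical(dec, dec2)

  # labels shuffled: nothing can be confirmed
  set.seed(41)
  decNull <- borutaSelect(scores, sample(labels), iterations = 10,
                          seed = 7)
  expect_false(any(decNull == "confirmed"))
})

test_that("CV accuracy responds monotonically to the injected effect size", {
  accAt <- function(es) {
    d <- tinyDesign(effectScale = es, fovsPerOrganoid = 3L,
                    fovHeight = 20L, fovWidth = 20L, seed = 88L)
    sp <- preprocessStudy(d)
    pca <- fitPCA(sp, 5)
    mean(crossValidate(pcaScores(pca), spectraLabels(sp)$stage_weeks,
                       k = 5, nTrees = 50, seed = 88))
  }
  acc <- vapply(c(0, 0.5, 1), accAt, numeric(1))
  expect_lte(acc[1], acc[2] + 0.05)
  expect_lte(acc[2], acc[3] + 0.05)
  expect_lt(acc[1], 0.8)        # null stays near chance for 2 classes
  expect_gt(acc[3], 0.9)        # full effect is clearly separable
})

test_that("the full classification report is coherent on synthetic spectra", {
  d <- tinyDesign(fovsPerOrganoid = 4L, fovHeight = 20L, fovWidth = 20L)
  sp <- preprocessStudy(d)          # 2 stages x 4 FOVs x 16 spectra
  pca <- fitPCA(sp, 10)
  rep <- classifyStages(pca, pcIndices = 1:10, k = 5, seed = 2)
  expect_s4_class(rep, "StageClassification")
  expect_length(foldAccuracies(rep), 5)
  expect_equal(sum(confusionMatrix(rep)), round(0.3 * ncol(sp)))
  expect_equal(sum(pcImportance(rep)), 1, tolerance = 1e-8)
  expect_gte(mean(foldAccuracies(rep)), 0.9)  # clear injected signal
})
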