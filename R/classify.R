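# Stratified fold assignment: within each class, spectra are dealt to
# folds in a random order so every fold has near-equal class composition.
.stratifiedFolds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  set.seed(seed)
  fold <- integer(length(labels))
  counts <- table(labels)
  if (min(counts) < k) {
    warning("some class has fewer members than folds; ",
            "stratification relaxed to a global random assignment")
    fold <- sample(rep_len(seq_len(k), length(labels)))
  } else {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  fold
}

#' Stratified train/test split
#'
#' Splits the score rows into disjoint training and testing sets (70/30 by
#' default), stratified by class so per-class proportions are preserved to
#' within one row; reproducible from the seed.
#'
#' @param scores numeric matrix, spectra x features.
#' @param labels class label per row (>= 2 classes, each with >= 2 rows).
#' @param trainFraction fraction assigned to training, in (0, 1).
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{test}, each a list
#'   holding \code{scores} and \code{labels}.
#' @export
splitTrainTest <- function(scores, labels, trainFraction = 0.7, seed = 1L) {
  labels <- as.factor(labels)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie in (0, 1)")
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (min(table(labels)) < 2L)
    stop("every class needs at least 2 rows")
  set.seed(seed)
  trainIdx <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    nTrain <- max(1L, round(trainFraction * length(idx)))
    nTrain <- min(nTrain, length(idx) - 1L)   # keep both sides nonempty
    trainIdx <- c(trainIdx, sample(idx, nTrain))
  }
  testIdx <- setdiff(seq_along(labels), trainIdx)
  list(train = list(scores = scores[trainIdx, , drop = FALSE],
                    labels = labels[trainIdx]),
       test = list(scores = scores[testIdx, , drop = FALSE],
                   labels = labels[testIdx]))
}

#' Train a random-forest classifier
#'
#' Fits an ensemble of decision trees (50 by default) on PC scores;
#' deterministic given the seed. Tree hyperparameters other than the
#' ensemble size stay at the \pkg{randomForest} defaults.
#'
#' @param scores numeric matrix, spectra x features.
#' @param labels class label per row (>= 2 classes).
#' @param nTrees ensemble size.
#' @param seed integer seed.
#' @return a \code{randomForest} fit.
#' @export
trainForest <- function(scores, labels, nTrees = 50L, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("need at least 2 classes to train")
  set.seed(seed)
  randomForest::randomForest(x = as.data.frame(scores), y = labels,
                             ntree = as.integer(nTrees))
}

#' Stratified k-fold cross-validation accuracy
#'
#' Splits the rows into k stratified folds, trains a forest on each
#' training complement and scores the held-out fold; returns the k fold
#' accuracies (report them as mean +/- SD).
#'
#' @inheritParams trainForest
#' @param k number of folds (>= 2, <= number of rows). The stage analyses
#'   use k = 10 or k = 30.
#' @return numeric vector of k fold accuracies.
#' @export
crossValidate <- function(scores, labels, k = 10L, nTrees = 50L,
                          seed = 1L) {
  labels <- droplevels(as.factor(labels))
  k <- as.integer(k)
  if (k < 2L || k > length(labels))
    stop("k must lie in [2, number of rows]")
  fold <- .stratifiedFolds(labels, k, seed)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    te <- fold == f
    fit <- trainForest(scores[!te, , drop = FALSE], labels[!te],
                       nTrees = nTrees, seed = seed + f)
    pred <- predict(fit, as.data.frame(scores[te, , drop = FALSE]))
    acc[f] <- mean(as.character(pred) == as.character(labels[te]))
  }
  acc
}

#' Hold-out evaluation of a fitted forest
#'
#' Predicts the test rows and reports the confusion matrix (rows = true
#' class, columns = predicted class), per-class precision, recall and F1,
#' and the overall accuracy. A test label never seen in training keeps its
#' own confusion row (all off-diagonal).
#'
#' @param forest a fitted \code{randomForest}.
#' @param testScores,testLabels held-out rows and their labels.
#' @return list with \code{confusion}, \code{perClass} (data.frame),
#'   \code{accuracy}.
#' @export
evaluateClassifier <- function(forest, testScores, testLabels) {
  pred <- as.character(predict(forest, as.data.frame(testScores)))
  truth <- as.character(testLabels)
  lev <- sort(unique(c(truth, pred, as.character(forest$classes))))
  confusion <- table(factor(truth, lev), factor(pred, lev))
  confusion <- matrix(as.integer(confusion), length(lev), length(lev),
                      dimnames = list(true = lev, predicted = lev))
  tp <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), NA_real_)
  rec <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec), NA_real_)
  list(confusion = confusion,
       perClass = data.frame(class = lev, precision = prec, recall = rec,
                             f1 = f1, row.names = NULL),
       accuracy = sum(tp) / sum(confusion))
}

#' Impurity-based feature importances
#'
#' Mean decrease in Gini impurity per feature, normalized to sum to 1;
#' the weights of the importance-weighted loading signature.
#'
#' @param forest a fitted \code{randomForest}.
#' @return named nonnegative numeric vector summing to 1.
#' @export
featureImportance <- function(forest) {
  imp <- randomForest::importance(forest, type = 2)[, 1L]
  imp <- pmax(imp, 0)
  if (sum(imp) == 0) imp[] <- 1 / length(imp) else imp <- imp / sum(imp)
  imp
}

#' Shadow-feature (Boruta-style) relevance selection
#'
#' Each iteration appends a permuted ("shadow") copy of every feature,
#' fits a forest on the augmented matrix, and marks the real features
#' whose importance beats the best shadow importance. After all
#' iterations, a per-feature binomial test against hit probability 1/2
#' classifies features as \code{confirmed} (significantly more hits),
#' \code{rejected} (significantly fewer) or \code{tentative}.
#'
#' @inheritParams trainForest
#' @param iterations number of shadow rounds (default 10).
#' @param alpha two-sided significance level for the binomial decision.
#' @return named character vector over features with values
#'   \code{"confirmed"}, \code{"tentative"}, \code{"rejected"}; the hit
#'   counts are attached as attribute \code{"hits"}.
#' @export
borutaSelect <- function(scores, labels, iterations = 10L, nTrees = 50L,
                         seed = 1L, alpha = 0.05) {
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  scores <- as.matrix(scores)
  p <- ncol(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("PC", seq_len(p))
  labels <- droplevels(as.factor(labels))
  hits <- integer(p)
  set.seed(seed)
  for (it in seq_len(iterations)) {
    shadow <- apply(scores, 2L, sample)
    colnames(shadow) <- paste0("shadow_", colnames(scores))
    aug <- as.data.frame(cbind(scores, shadow))
    fit <- randomForest::randomForest(x = aug, y = labels,
                                      ntree = as.integer(nTrees))
    imp <- randomForest::importance(fit, type = 2)[, 1L]
    thr <- max(imp[(p + 1L):(2L * p)])
    hits <- hits + as.integer(imp[seq_len(p)] > thr)
  }
  pMore <- pbinom(hits - 1L, iterations, 0.5, lower.tail = FALSE)
  pLess <- pbinom(hits, iterations, 0.5)
  decision <- ifelse(pMore < alpha, "confirmed",
                     ifelse(pLess < alpha, "rejected", "tentative"))
  names(decision) <- colnames(scores)
  attr(decision, "hits") <- stats::setNames(hits, colnames(scores))
  decision
}

#' Full classification analysis of a PCA model
#'
#' Runs the complete classification protocol on selected PC scores:
#' stratified k-fold cross-validation for the accuracy estimate (mean and
#' SD over folds), a stratified 70/30 hold-out split whose test confusion
#' matrix and per-class metrics are reported, impurity importances of the
#' hold-out forest, and optionally shadow-feature relevance decisions.
#'
#' @param pca a \linkS4class{RamanPCA}.
#' @param labelColumn label column to predict (\code{"stage_weeks"} or
#'   \code{"line"}).
#' @param pcIndices 1-based components used as features (e.g. \code{1:25}
#'   for the stage analyses, \code{2:20} for the cell-line comparison).
#' @param nTrees ensemble size (default 50).
#' @param k cross-validation folds (default 10; the four-stage analysis
#'   also uses 30).
#' @param trainFraction hold-out training fraction (default 0.7).
#' @param boruta logical; run shadow-feature selection as well.
#' @param borutaIterations shadow rounds (default 10).
#' @param seed integer seed.
#' @return a \linkS4class{StageClassification}.
#' @export
classifyStages <- function(pca, labelColumn = "stage_weeks",
                           pcIndices = 1:25, nTrees = 50L, k = 10L,
                           trainFraction = 0.7, boruta = FALSE,
                           borutaIterations = 10L, seed = 1L) {
  if (!labelColumn %in% names(pca@labels))
    stop("unknown label column: ", labelColumn)
  labels <- as.factor(pca@labels[[labelColumn]])
  sc <- selectComponents(pca, pcIndices)
  acc <- crossValidate(sc, labels, k = k, nTrees = nTrees, seed = seed)
  sp <- splitTrainTest(sc, labels, trainFraction = trainFraction,
                       seed = seed)
  fit <- trainForest(sp$train$scores, sp$train$labels, nTrees = nTrees,
                     seed = seed)
  ev <- evaluateClassifier(fit, sp$test$scores, sp$test$labels)
  dec <- character(0)
  if (boruta)
    dec <- c(borutaSelect(sc, labels, iterations = borutaIterations,
                          nTrees = nTrees, seed = seed))
  new("StageClassification", foldAccuracies = acc,
      confusion = ev$confusion, perClass = ev$perClass,
      importances = featureImportance(fit), boruta = dec,
      config = list(labelColumn = labelColumn, pcIndices = pcIndices,
                    nTrees = as.integer(nTrees), k = as.integer(k),
                    trainFraction = trainFraction, seed = as.integer(seed),
                    borutaIterations = as.integer(borutaIterations)))
}
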