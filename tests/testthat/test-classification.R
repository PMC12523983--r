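# Boosted-tree classification, confusion/TPR reporting, regrouping,
# clustering and PCA.

toy_profiles <- function(n_per_class = 15, gap = 6, seed = 17,
                         classes = c("A", "B")) {
  set.seed(seed)
  k <- length(classes)
  n <- k * n_per_class
  f1 <- rnorm(n, rep(seq(0, gap * (k - 1), by = gap), each = n_per_class), 1)
  f2 <- rnorm(n)
  f3 <- rnorm(n)
  data.frame(track_id = as.character(seq_len(n)),
             class = rep(classes, each = n_per_class),
             f1 = f1, f2 = f2, f3 = f3, stringsAsFactors = FALSE)
}

test_that("training is deterministic under a fixed seed", {
  prof <- toy_profiles()
  test <- toy_profiles(seed = 18)
  m1 <- train_classifier(prof, c("f1", "f2", "f3"), n_trees = 30, seed = 5)
  m2 <- train_classifier(prof, c("f1", "f2", "f3"), n_trees = 30, seed = 5)
  expect_identical(predict(m1, test), predict(m2, test))
})

test_that("training contracts: class counts and feature schema", {
  prof <- toy_profiles()
  expect_error(train_classifier(prof[prof$class == "A", ], c("f1", "f2")),
               "parameter error")
  small <- prof[c(1, 16, 17), ]   # class A has a single cell
  expect_error(train_classifier(small, c("f1", "f2")), "parameter error")
  m <- train_classifier(prof, c("f1", "f2", "f3"), n_trees = 10)
  bad <- toy_profiles(seed = 3)
  names(bad)[3] <- "g1"
  expect_error(predict(m, bad), "schema error")
})

test_that("a widely separated two-class population classifies perfectly", {
  train <- toy_profiles(n_per_class = 60, gap = 10, seed = 21)
  test <- toy_profiles(gap = 10, seed = 22)
  m <- train_classifier(train, c("f1", "f2", "f3"), n_trees = 50, seed = 1)
  conf <- evaluate_classifier(m, test)
  expect_equal(unname(conf$tpr), c(100, 100))
  expect_equal(conf$macro_tpr, 100)
})

test_that("training-set evaluation of a deep model memorises (TPR 100)", {
  train <- toy_profiles(gap = 1.5, seed = 30, n_per_class = 20)
  m <- train_classifier(train, c("f1", "f2", "f3"), n_trees = 300,
                        max_depth = 6, seed = 2)
  conf <- evaluate_classifier(m, train)
  expect_equal(unname(conf$tpr), c(100, 100))
})

test_that("confusion rows reproduce test counts and TPR matches brute-force counting", {
  train <- toy_profiles(gap = 2, seed = 40, n_per_class = 25,
                        classes = c("A", "B", "C"))
  test <- toy_profiles(gap = 2, seed = 41, n_per_class = 10,
                       classes = c("A", "B", "C"))
  m <- train_classifier(train, c("f1", "f2", "f3"), n_trees = 60, seed = 3)
  conf <- evaluate_classifier(m, test)
  expect_equal(unname(rowSums(conf$confusion)), rep(10, 3))
  pred <- predict(m, test)
  for (cl in c("A", "B", "C")) {
    hits <- sum(pred == cl & test$class == cl)
    expect_equal(unname(conf$tpr[cl]), 100 * hits / 10)
  }
  expect_true(all(conf$tpr >= 0 & conf$tpr <= 100))
  # unseen class in test is a contract violation
  test$class[1] <- "D"
  expect_error(evaluate_classifier(m, test), "unseen")
})

test_that("permuted labels classify at chance level on the motility fixture", {
  prof <- cached_motility_fixture(seed = 1)$profiles
  res <- feature_selection(prof)
  tprs <- sapply(1:10, function(s) {
    set.seed(s)
    perm <- prof
    perm$class <- sample(perm$class)
    is_test <- stratified_split(perm$class, 0.3, seed = s)
    m <- train_classifier(perm[!is_test, ], res, seed = s, n_trees = 60)
    evaluate_classifier(m, perm[is_test, ])$macro_tpr
  })
  # two classes: chance is 50%; average over permutations to tame the
  # small-test-set variance
  expect_lt(abs(mean(tprs) - 50), 15)
})

test_that("regrouping commutes with scoring and drops unmapped classes", {
  prof <- toy_profiles(classes = c("L1", "L2", "L3"), gap = 4)
  mapping <- c(L1 = "cancer", L2 = "cancer", L3 = "healthy")
  regrouped <- regroup_labels(prof, mapping)
  expect_equal(nrow(regrouped), nrow(prof))
  expect_setequal(unique(regrouped$class), c("cancer", "healthy"))
  # pre-grouped labels give identical separation scores
  pre <- prof
  pre$class <- unname(mapping[pre$class])
  s1 <- separation_scores(regrouped, features = c("f1", "f2", "f3"))
  s2 <- separation_scores(pre, features = c("f1", "f2", "f3"))
  expect_equal(s1, s2)
  # unmapped class dropped with a warning; identity mapping is a no-op
  expect_warning(sub <- regroup_labels(prof, mapping[1:2]), "dropped")
  expect_equal(nrow(sub), 30)
  ident <- regroup_labels(prof, c(L1 = "L1", L2 = "L2", L3 = "L3"))
  expect_equal(ident, prof)
  expect_error(suppressWarnings(regroup_labels(prof, c(Z = "z"))),
               "parameter error")
})

test_that("Ward clustering recovers well-separated blobs and co-assigns duplicates", {
  set.seed(8)
  n <- 12
  blob <- data.frame(
    track_id = as.character(1:(2 * n)), class = NA_character_,
    f1 = c(rnorm(n, 0, 0.3), rnorm(n, 10, 0.3)),
    f2 = c(rnorm(n, 0, 0.3), rnorm(n, 10, 0.3)),
    stringsAsFactors = FALSE)
  cl <- hierarchical_clusters(blob, c("f1", "f2"), k = 2)
  expect_equal(length(unique(cl[1:n])), 1)
  expect_equal(length(unique(cl[(n + 1):(2 * n)])), 1)
  expect_false(cl[1] == cl[n + 1])
  # k = n: every cell its own cluster
  expect_equal(sort(hierarchical_clusters(blob, c("f1", "f2"),
                                          k = 2 * n)), 1:(2 * n))
  expect_error(hierarchical_clusters(blob, c("f1", "f2"), k = 100),
               "parameter error")
  # indiscernibles: duplicated cells always co-cluster
  dup <- rbind(blob, blob)
  cld <- hierarchical_clusters(dup, c("f1", "f2"), k = 2)
  expect_equal(cld[1:(2 * n)], cld[(2 * n + 1):(4 * n)])
})

test_that("PCA scores: rank-1 data, sign convention, zero-variance drops", {
  set.seed(6)
  t_param <- rnorm(20)
  lineal <- data.frame(track_id = as.character(1:20), class = NA,
                       f1 = 2 * t_param, f2 = -t_param, f3 = 0.5 * t_param)
  p <- pca_scores(lineal, c("f1", "f2", "f3"), n_components = 2)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-10)
  # deterministic sign: largest-magnitude loading positive
  expect_gt(max(p$loadings[, 1]), 0)
  p2 <- pca_scores(lineal, c("f1", "f2", "f3"), n_components = 2)
  expect_identical(p$scores, p2$scores)
  # zero-variance column dropped with a warning
  lineal$f4 <- 7
  expect_warning(p3 <- pca_scores(lineal, c("f1", "f2", "f3", "f4")),
                 "dropped")
  expect_equal(ncol(p3$loadings), 2)
  expect_error(suppressWarnings(pca_scores(lineal, c("f4"), 1)),
               "parameter error")
})

test_that("the PCA explained-variance spectrum is rotation invariant", {
  set.seed(14)
  m <- matrix(rnorm(40 * 4), 40, 4) %*% diag(c(3, 2, 1, 0.5))
  rot <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  d1 <- as.data.frame(m); d2 <- as.data.frame(m %*% rot)
  names(d1) <- names(d2) <- paste0("f", 1:4)
  # covariance PCA: the spectrum is a property of the point cloud itself
  p1 <- pca_scores(cbind(track_id = "x", class = NA, d1), paste0("f", 1:4),
                   4, scale = FALSE)
  p2 <- pca_scores(cbind(track_id = "x", class = NA, d2), paste0("f", 1:4),
                   4, scale = FALSE)
  expect_equal(p1$explained_variance, p2$explained_variance, tolerance = 1e-8)
})

test_that("stratified splits are seeded and respect class proportions", {
  labels <- rep(c("A", "B"), c(30, 10))
  s1 <- stratified_split(labels, 0.3, seed = 4)
  s2 <- stratified_split(labels, 0.3, seed = 4)
  expect_identical(s1, s2)
  expect_equal(sum(s1[labels == "A"]), 9)
  expect_equal(sum(s1[labels == "B"]), 3)
})
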