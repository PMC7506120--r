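fake_features <- function(n_normal, n_epi) {
  data.frame(epoch_id = seq_len(n_normal + n_epi),
             label = rep(c("normal", "epileptiform"), c(n_normal, n_epi)))
}

test_that("the stratified split reproduces the clinical 2/3-1/3 bookkeeping", {
  ft <- fake_features(100, 540)
  sp <- split_dataset(ft, 1 / 3, seed = 7)
  counts <- function(d) table(factor(d$label, c("normal", "epileptiform")))
  expect_equal(as.vector(counts(sp$train)), c(66, 360))
  expect_equal(as.vector(counts(sp$test)), c(34, 180))
  expect_equal(nrow(sp$train) + nrow(sp$test), 640)
  expect_length(intersect(sp$train$epoch_id, sp$test$epoch_id), 0)
  # determinism
  sp2 <- split_dataset(ft, 1 / 3, seed = 7)
  expect_identical(sp$test$epoch_id, sp2$test$epoch_id)
  # degenerate fractions
  sp0 <- split_dataset(ft, 0, seed = 1)
  expect_equal(nrow(sp0$train), 640)
  expect_error(split_dataset(fake_features(2, 50), 1 / 3), "stratification")
})

test_that("confusion-matrix metrics match their definitions", {
  m <- metrics_from_confusion(list(tp = 179, fn = 1, fp = 1, tn = 33))
  expect_equal(round(unname(m), 2), c(99.44, 97.06, 99.07))
  expect_error(metrics_from_confusion(list(tp = 0, fn = 0, fp = 1, tn = 5)),
               "undefined")
})

test_that("roc_auc equals the Mann-Whitney statistic and handles edge cases", {
  labs <- c(rep(FALSE, 10), rep(TRUE, 10))
  expect_equal(roc_auc(as.numeric(labs), labs)$auc, 1)
  expect_equal(roc_auc(1 - as.numeric(labs), labs)$auc, 0)
  expect_warning(const <- roc_auc(rep(1, 20), labs), "constant")
  expect_equal(const$auc, 0.5)
  for (s in 1:20) {
    set.seed(s)
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    scores <- round(rnorm(n1 + n0), 1)          # ties likely
    labels <- c(rep(TRUE, n1), rep(FALSE, n0))
    got <- roc_auc(scores, labels)$auc
    # brute-force U statistic
    pos <- scores[labels]; neg <- scores[!labels]
    u <- 0
    for (p in pos) for (q in neg) u <- u + (p > q) + 0.5 * (p == q)
    expect_equal(got, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- rnorm(200)
  labels <- runif(200) < plogis(scores)
  got <- roc_auc(scores, labels == 1)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("classifiers separate separable blobs and not shuffled labels", {
  set.seed(2)
  n <- 120
  ft <- data.frame(
    epoch_id = 1:(2 * n),
    label = rep(c("normal", "epileptiform"), each = n),
    psd_energy = c(rnorm(n, 0), rnorm(n, 8)),
    lam2 = c(rnorm(n, 0), rnorm(n, -8)))
  sp <- split_dataset(ft, 1 / 3, seed = 3)
  for (cl in c("rf", "svm")) {
    rep <- train_classify(sp$train, sp$test, cl, c("psd_energy", "lam2"),
                          seed = 3)
    expect_equal(rep$accuracy, 100)
    expect_equal(rep$auc, 1)
  }
  # shuffled labels: no predictive ability
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    ft$label <- sample(ft$label)
    sp <- split_dataset(ft, 1 / 3, seed = s)
    suppressWarnings(
      train_classify(sp$train, sp$test, "rf", c("psd_energy", "lam2"),
                     seed = s)$auc)
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  expect_error(train_classify(sp$train[sp$train$label == "normal", ],
                              sp$test, "rf", "psd_energy"),
               "training error")
})

test_that("regularity ratio divides energy by small-scale divergence", {
  expect_equal(regularity_ratio(100, 0.5), 200)
  got <- regularity_ratio(c(10, 20, 30), c(0.5, 0, -1))
  expect_equal(got[1], 20)
  expect_true(all(is.na(got[2:3])))
})

test_that("epileptiform epochs have the larger mean regularity ratio", {
  ft <- cached_features()
  ratio <- regularity_ratio(ft$psd_energy, ft$lam1)
  m <- tapply(ratio, ft$label, mean, na.rm = TRUE)
  expect_gt(m[["epileptiform"]], m[["normal"]])
})

test_that("density overlap matches closed-form Gaussian tails", {
  set.seed(5)
  far <- density_overlap(rnorm(2000, 20, 1), rnorm(2000, 0, 1))
  expect_lt(far$tail_pos, 0.01)
  expect_lt(far$tail_neg, 0.01)
  x <- rnorm(2000)
  same <- density_overlap(x, x)
  expect_equal(same$tail_pos, 50, tolerance = 0.1)
  expect_equal(same$tail_neg, 50, tolerance = 0.1)
  # N(2,1) vs N(0,1): tails ~ Phi(-1) = 15.87%
  two <- density_overlap(rnorm(2000, 2, 1), rnorm(2000, 0, 1))
  expect_lt(abs(two$tail_pos - 15.87), 1.5)
  expect_lt(abs(two$tail_neg - 15.87), 1.5)
  expect_error(density_overlap(rnorm(5), rnorm(100)), "20")
})

test_that("two features classify at least as well as the ratio threshold", {
  ft <- cached_features()
  sp <- split_dataset(ft, 1 / 3, seed = 11)
  rep2 <- train_classify(sp$train, sp$test, "rf", c("psd_energy", "lam1"),
                         seed = 11)
  # best single threshold on the regularity ratio, chosen on train
  tr_ratio <- regularity_ratio(sp$train$psd_energy, sp$train$lam1)
  te_ratio <- regularity_ratio(sp$test$psd_energy, sp$test$lam1)
  ths <- sort(unique(tr_ratio))
  acc <- vapply(ths, function(th) {
    mean((tr_ratio > th) == (sp$train$label == "epileptiform"), na.rm = TRUE)
  }, 0)
  th <- ths[which.max(acc)]
  acc_ratio <- 100 * mean((te_ratio > th) == (sp$test$label == "epileptiform"),
                          na.rm = TRUE)
  # allow a one-epoch finite-sample tie margin
  expect_gte(rep2$accuracy, acc_ratio - 100 / nrow(sp$test))
})
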