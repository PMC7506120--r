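# Feature assembly, stratified splitting, RF/SVM classification and the
# clinical performance metrics. The learners themselves come from
# randomForest and e1071; the positive class is "epileptiform" throughout.

#' Per-epoch feature vector
#'
#' Runs the full feature chain on one epoch: filtering, strongest-channel
#' selection, the 0.5-25 Hz PSD band energy, and the channel-averaged SDLE
#' features (lambda at the three scaling-region scales, their mean, the
#' attractor size and error-doubling time).
#'
#' @param epoch An [eeg_epoch].
#' @param cfg A [preprocess_config].
#' @param ... Passed to [epoch_sdle()].
#' @return One-row data frame: `epoch_id`, `label`, `subtype`,
#'   `psd_energy`, `lam1`, `lam2`, `lam3`, `lam_bar`, `eps_inf`, `T_db`.
#' @export
epoch_features <- function(epoch, cfg = preprocess_config(), ...) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  filt <- filter_epoch(epoch, cfg)
  sel <- select_strongest(filt, min(cfg$n_strongest, nrow(filt$data)))
  psd <- epoch_psd_feature(sel)
  fit <- epoch_sdle(sel, cfg = cfg, filter = FALSE, ...)
  f <- fit$features
  data.frame(epoch_id = epoch$epoch_id,
             label = if (is.null(epoch$label)) NA_character_ else epoch$label,
             subtype = if (is.null(epoch$subtype)) NA_character_
                       else paste(epoch$subtype, collapse = "+"),
             psd_energy = psd, lam1 = f$lam1, lam2 = f$lam2, lam3 = f$lam3,
             lam_bar = f$lam_bar, eps_inf = f$eps_inf,
             T_db = as.numeric(f$T_db),
             stringsAsFactors = FALSE)
}

#' Feature table for a set of epochs
#'
#' @param epochs List of [eeg_epoch] objects.
#' @param cfg A [preprocess_config].
#' @param progress Print a dot every 50 epochs.
#' @param ... Passed to [epoch_features()].
#' @return Data frame, one row per epoch.
#' @export
feature_table <- function(epochs, cfg = preprocess_config(),
                          progress = FALSE, ...) {
  rows <- vector("list", length(epochs))
  for (i in seq_along(epochs)) {
    rows[[i]] <- epoch_features(epochs[[i]], cfg, ...)
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  do.call(rbind, rows)
}

#' Stratified train/test split
#'
#' Splits a feature table into training and testing sets, stratified per
#' class: each class contributes `ceiling(class_n * test_fraction)` test
#' epochs (so 100 normal + 540 epileptiform at one third give 66/34 and
#' 360/180). The shuffle is seeded and the split is disjoint and
#' exhaustive.
#'
#' @param features Data frame with a `label` column.
#' @param test_fraction Fraction of each class put in the test set
#'   (default 1/3).
#' @param seed Integer seed for the shuffle.
#' @return List with `train` and `test` data frames.
#' @export
split_dataset <- function(features, test_fraction = 1 / 3, seed = 1) {
  labs <- unique(features$label)
  if (length(labs) < 2 && test_fraction > 0 && test_fraction < 1)
    stop("both classes must be present to stratify")
  if (any(table(features$label) < 3) && test_fraction > 0)
    stop("stratification error: a class has fewer than 3 members")
  set.seed(seed)
  test_idx <- unlist(lapply(labs, function(lb) {
    idx <- which(features$label == lb)
    n_test <- min(length(idx), ceiling(length(idx) * test_fraction))
    if (n_test == 0) return(integer(0))
    sample(idx, n_test)
  }))
  if (length(test_idx) == 0)
    return(list(train = features, test = features[integer(0), , drop = FALSE]))
  list(train = features[-test_idx, , drop = FALSE],
       test = features[sort(test_idx), , drop = FALSE])
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/total, as percentages. Raw ratios are returned; rounding to two
#' decimals happens only in the print method.
#'
#' @param cm Named list or vector with `tp`, `fn`, `fp`, `tn`.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`
#'   (percent).
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.list(cm)
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  if (tp + fn <= 0 || tn + fp <= 0)
    stop("undefined metric: empty margin in the confusion matrix")
  c(sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / (tp + fn + fp + tn))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values as thresholds (ties step simultaneously),
#' accumulating (FPR, TPR) points, and integrates the AUC trapezoidally.
#' Equals the Mann-Whitney statistic U/(n1 n2).
#'
#' @param scores Numeric scores, larger = more likely positive.
#' @param labels Logical or factor/character; `TRUE`/`"epileptiform"` is
#'   the positive class.
#' @return List with `roc` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  if (length(unique(scores)) == 1L) {
    warning("constant scores: AUC 0.5")
    return(list(roc = data.frame(fpr = c(0, 1), tpr = c(0, 1)), auc = 0.5))
  }
  o <- order(scores, decreasing = TRUE)
  pos <- pos[o]; s <- scores[o]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(s, fromLast = TRUE)      # threshold boundaries (ties)
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels == "epileptiform" | labels == "1" | labels == 1
}

#' Train and evaluate a classifier on a feature split
#'
#' Fits a random forest (100 trees, majority vote) or an RBF-kernel SVM on
#' the training features and evaluates on the test set. Features are
#' z-scored with means/SDs fitted on the training set only. ROC scores are
#' the RF class-probability vote fraction or the SVM signed margin.
#'
#' @param train,test Data frames from [split_dataset()].
#' @param classifier `"rf"` or `"svm"`.
#' @param feature_set Character vector of feature column names, e.g.
#'   `c("psd_energy", "lam2")`.
#' @param seed Integer seed (bagging/numerics).
#' @param ntree Trees for the random forest (default 100).
#' @return Object of class `classification_report`: confusion counts,
#'   sensitivity/specificity/accuracy (percent), ROC points, AUC.
#' @export
train_classify <- function(train, test, classifier = c("rf", "svm"),
                           feature_set = c("psd_energy", "lam2"),
                           seed = 1, ntree = 100) {
  classifier <- match.arg(classifier)
  stopifnot(all(feature_set %in% names(train)))
  if (length(unique(train$label)) < 2)
    stop("training error: single-class training set")
  xtr <- as.matrix(train[, feature_set, drop = FALSE])
  xte <- as.matrix(test[, feature_set, drop = FALSE])
  mu <- colMeans(xtr)
  sg <- apply(xtr, 2, stats::sd)
  sg[sg == 0] <- 1
  xtr <- scale(xtr, mu, sg)
  xte <- scale(xte, mu, sg)
  ytr <- factor(train$label, levels = c("normal", "epileptiform"))
  yte <- factor(test$label, levels = c("normal", "epileptiform"))
  set.seed(seed)
  if (classifier == "rf") {
    fit <- randomForest::randomForest(xtr, ytr, ntree = ntree)
    pred <- stats::predict(fit, xte)
    scores <- stats::predict(fit, xte, type = "prob")[, "epileptiform"]
  } else {
    fit <- e1071::svm(xtr, ytr, kernel = "radial", scale = FALSE)
    pred <- stats::predict(fit, xte, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # orient the margin so larger = epileptiform
    scores <- if (grepl("^epileptiform", colnames(dv)[1])) dv[, 1] else -dv[, 1]
  }
  cm <- list(tp = sum(pred == "epileptiform" & yte == "epileptiform"),
             fn = sum(pred == "normal" & yte == "epileptiform"),
             fp = sum(pred == "epileptiform" & yte == "normal"),
             tn = sum(pred == "normal" & yte == "normal"))
  metrics <- metrics_from_confusion(cm)
  ra <- roc_auc(scores, yte == "epileptiform")
  structure(list(classifier = toupper(classifier),
                 feature_set = feature_set, confusion = cm,
                 sensitivity = metrics[["sensitivity"]],
                 specificity = metrics[["specificity"]],
                 accuracy = metrics[["accuracy"]],
                 roc = ra$roc, auc = ra$auc,
                 n_train = nrow(train), n_test = nrow(test),
                 settings = if (classifier == "rf")
                   list(ntree = ntree, seed = seed)
                 else list(kernel = "radial", cost = 1, seed = seed)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("%s classifier on (%s): n_train = %d, n_test = %d\n",
              x$classifier, paste(x$feature_set, collapse = ", "),
              x$n_train, x$n_test))
  cm <- x$confusion
  cat(sprintf("  confusion: TP %d  FN %d  FP %d  TN %d\n",
              cm$tp, cm$fn, cm$fp, cm$tn))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%  AUC %.4f\n",
              x$sensitivity, x$specificity, x$accuracy, x$auc))
  invisible(x)
}

#' Regularity ratio PSD / lambda(eps1)
#'
#' A single-parameter measure of the regularity (predictability) of an EEG
#' epoch: high spectral energy (synchronized firing) combined with slow
#' small-scale divergence gives a large ratio, so epileptiform discharges
#' score higher on average than normal background. Epochs with
#' `lam1 <= 0` are returned as `NA` (flagged, excluded from density
#' analyses).
#'
#' @param psd_energy Numeric vector of PSD band energies.
#' @param lam1 Numeric vector of small-scale SDLEs.
#' @return Numeric vector of ratios, `NA` where `lam1 <= 0`.
#' @export
regularity_ratio <- function(psd_energy, lam1) {
  out <- psd_energy / lam1
  out[!is.finite(out) | lam1 <= 0] <- NA_real_
  out
}

#' Misclassification tails of two regularity-ratio densities
#'
#' Gaussian kernel densities (Silverman bandwidth) are estimated for the
#' positive (epileptiform) and negative (normal) ratio samples and their
#' crossing between the class medians is located; each class's empirical
#' mass on the wrong side of the crossing is returned, in percent (the
#' density smoothing only places the threshold, so the tail probabilities
#' carry no bandwidth bias). These tails are lower bounds on the
#' misclassification probabilities of any single-threshold rule on the
#' ratio.
#'
#' @param ratios_pos,ratios_neg Numeric samples (>= 20 each; `NA` dropped).
#' @return List with `tail_pos` (positive-class mass on the negative
#'   side, percent), `tail_neg`, `crossing`, and `flag` (`TRUE` when no
#'   crossing was found between the modes and 0/0 is returned).
#' @export
density_overlap <- function(ratios_pos, ratios_neg) {
  ratios_pos <- ratios_pos[is.finite(ratios_pos)]
  ratios_neg <- ratios_neg[is.finite(ratios_neg)]
  if (length(ratios_pos) < 20 || length(ratios_neg) < 20)
    stop("need at least 20 finite samples per class")
  rng <- range(ratios_pos, ratios_neg)
  pad <- 0.1 * diff(rng)
  grid <- seq(rng[1] - pad, rng[2] + pad, length.out = 2048)
  dp <- stats::density(ratios_pos, bw = "nrd0", from = grid[1],
                       to = grid[length(grid)], n = length(grid))
  dn <- stats::density(ratios_neg, bw = "nrd0", from = grid[1],
                       to = grid[length(grid)], n = length(grid))
  # the crossing is located on extra-smoothed densities (one pooled
  # bandwidth, twice the mean Silverman value): smoothing both classes
  # with a common kernel leaves the crossing between comparable-spread
  # modes in place while damping the wiggles that would jitter a
  # sign-change search
  bw2 <- 2 * mean(c(stats::bw.nrd0(ratios_pos), stats::bw.nrd0(ratios_neg)))
  dps <- stats::density(ratios_pos, bw = bw2, from = grid[1],
                        to = grid[length(grid)], n = length(grid))
  dns <- stats::density(ratios_neg, bw = bw2, from = grid[1],
                        to = grid[length(grid)], n = length(grid))
  med <- sort(c(stats::median(ratios_pos), stats::median(ratios_neg)))
  between <- dps$x >= med[1] & dps$x <= med[2]
  sgn <- sign(dps$y[between] - dns$y[between])
  nz <- which(between)[sgn != 0]
  sgn <- sgn[sgn != 0]
  flips <- which(diff(sgn) != 0)
  if (length(flips) == 0) {
    if (med[1] == med[2]) {
      crossing <- med[1]
    } else {
      return(list(tail_pos = 0, tail_neg = 0, crossing = NA_real_,
                  flag = TRUE))
    }
  } else {
    at <- (dps$x[nz[flips]] + dps$x[nz[flips + 1L]]) / 2
    crossing <- at[which.min(abs(at - mean(med)))]
  }
  pos_upper <- stats::median(ratios_pos) >= stats::median(ratios_neg)
  # the kernel densities locate the crossing; the tail probabilities are
  # the empirical masses on the wrong side (free of bandwidth bias)
  mass <- function(samples, upper) {
    100 * mean(if (upper) samples > crossing else samples < crossing)
  }
  list(tail_pos = mass(ratios_pos, upper = !pos_upper),
       tail_neg = mass(ratios_neg, upper = pos_upper),
       crossing = crossing, flag = FALSE)
}
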