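#' In-fold selection of the most discriminative regions
#'
#' Ranks cortical regions by the absolute unadjusted Cohen's d between
#' training patients and training controls, keeps the top
#' \code{ceiling(k_percent/100 * N_cortical)}, and appends the
#' \code{always_include} set (e.g. a fixed subcortical block). Selection
#' uses training subjects only, so held-out data never influence it.
#'
#' @param train_ctrl_maps,train_pt_maps training-split maps
#'   (subjects x regions) for controls and patients.
#' @param k_percent percentage of cortical regions kept, in (0, 100].
#' @param always_include region indices always added (default none).
#' @param cortical region indices eligible for ranking (default: all
#'   regions not in \code{always_include}).
#' @return sorted integer vector of selected region indices.
#' @export
select_top_regions <- function(train_ctrl_maps, train_pt_maps, k_percent,
                               always_include = integer(0),
                               cortical = NULL) {
  check_scalar(k_percent, "k_percent", lower = 1e-9, upper = 100)
  N <- ncol(train_ctrl_maps)
  if (ncol(train_pt_maps) != N) stop_bad_arg("map dimensions differ")
  if (is.null(cortical)) cortical <- setdiff(seq_len(N), always_include)
  n_keep <- ceiling(k_percent / 100 * length(cortical))
  m_c <- colMeans(train_ctrl_maps[, cortical, drop = FALSE])
  m_p <- colMeans(train_pt_maps[, cortical, drop = FALSE])
  v_c <- apply(train_ctrl_maps[, cortical, drop = FALSE], 2L, var)
  v_p <- apply(train_pt_maps[, cortical, drop = FALSE], 2L, var)
  n_c <- nrow(train_ctrl_maps)
  n_p <- nrow(train_pt_maps)
  sp <- sqrt(((n_c - 1) * v_c + (n_p - 1) * v_p) / (n_c + n_p - 2))
  d <- abs((m_p - m_c) / pmax(sp, 1e-300))
  keep <- cortical[order(d, decreasing = TRUE)[seq_len(n_keep)]]
  sort(unique(c(keep, always_include)))
}

auc_from_scores <- function(scores, labels_positive) {
  pos <- scores[labels_positive]
  neg <- scores[!labels_positive]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

stratified_folds <- function(labels_positive, n_folds) {
  fold <- integer(length(labels_positive))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(labels_positive == cls)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Cross-validated case-control classification
#'
#' Repeated stratified k-fold cross-validation of a linear support-vector
#' classifier on regional maps. Within every training fold, regions are
#' selected by \code{\link{select_top_regions}} and features standardized
#' by training statistics (leakage-free); accuracy is averaged over folds,
#' AUC computed from signed decision values pooled across the iteration's
#' folds.
#'
#' @param maps subjects x regions matrix.
#' @param labels "control"/"patient" per subject.
#' @param k_percent feature-selection percentage.
#' @param always_include,cortical see \code{\link{select_top_regions}}.
#' @param n_folds folds (reference protocol: 4).
#' @param n_iterations CV repetitions (reference protocol: 1000).
#' @param cost SVM regularization C (default 1).
#' @param seed integer seed.
#' @return object of class \code{classifier_report}: list with
#'   per-iteration \code{accuracy} and \code{auc}, their summaries, and the
#'   configuration.
#' @export
crossval_classify <- function(maps, labels, k_percent = 10,
                              always_include = integer(0), cortical = NULL,
                              n_folds = 4L, n_iterations = 1000L,
                              cost = 1, seed = 1L) {
  check_matrix(maps, "maps")
  y_pos <- labels == "patient"
  if (min(sum(y_pos), sum(!y_pos)) < n_folds)
    stop_bad_arg("both classes need at least n_folds subjects")
  with_seed(seed, {
    acc <- auc <- numeric(n_iterations)
    for (it in seq_len(n_iterations)) {
      fold <- stratified_folds(y_pos, n_folds)
      fold_acc <- numeric(n_folds)
      dec_all <- numeric(length(y_pos))
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        te <- !tr
        if (length(unique(y_pos[te])) < 2L || length(unique(y_pos[tr])) < 2L)
          stop("internal error: single-class fold despite stratification")
        feats <- select_top_regions(
          maps[tr & !y_pos, , drop = FALSE], maps[tr & y_pos, , drop = FALSE],
          k_percent, always_include, cortical)
        mu <- colMeans(maps[tr, feats, drop = FALSE])
        sdv <- pmax(apply(maps[tr, feats, drop = FALSE], 2L, sd), 1e-12)
        Xtr <- sweep(sweep(maps[tr, feats, drop = FALSE], 2L, mu), 2L, sdv, `/`)
        Xte <- sweep(sweep(maps[te, feats, drop = FALSE], 2L, mu), 2L, sdv, `/`)
        ytr <- factor(ifelse(y_pos[tr], "patient", "control"),
                      levels = c("control", "patient"))
        fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = cost,
                          scale = FALSE)
        pr <- predict(fit, Xte, decision.values = TRUE)
        dec <- drop(attr(pr, "decision.values"))
        # orient decision values so larger = more patient-like
        dec_tr <- drop(attr(predict(fit, Xtr, decision.values = TRUE),
                            "decision.values"))
        if (mean(dec_tr[y_pos[tr]]) < mean(dec_tr[!y_pos[tr]])) dec <- -dec
        dec_all[te] <- dec
        fold_acc[f] <- mean((pr == "patient") == y_pos[te])
      }
      acc[it] <- mean(fold_acc)
      auc[it] <- auc_from_scores(dec_all, y_pos)
    }
    structure(list(
      accuracy = acc, auc = auc,
      accuracy_summary = c(mean = mean(acc), sd = sd(acc),
                           min = min(acc), max = max(acc)),
      auc_summary = c(mean = mean(auc), sd = sd(auc),
                      min = min(auc), max = max(auc)),
      config = list(k_percent = k_percent, n_folds = n_folds,
                    n_iterations = n_iterations, cost = cost,
                    always_include = always_include, cortical = cortical)),
      class = "classifier_report")
  })
}

#' @export
print.classifier_report <- function(x, ...) {
  a <- x$accuracy_summary
  u <- x$auc_summary
  cat(sprintf(
    "case-control classifier (top %g%% features, %d-fold CV, %d iterations)\n",
    x$config$k_percent, x$config$n_folds, x$config$n_iterations))
  cat(sprintf("  accuracy: %.1f%% +/- %.1f%% [%.1f%%-%.1f%%]\n",
              100 * a["mean"], 100 * a["sd"], 100 * a["min"], 100 * a["max"]))
  cat(sprintf("  AUC:      %.2f +/- %.2f [%.2f-%.2f]\n",
              u["mean"], u["sd"], u["min"], u["max"]))
  if (!is.null(x$p_accuracy))
    cat(sprintf("  permutation p: accuracy %.4g, AUC %.4g\n",
                x$p_accuracy, x$p_auc))
  invisible(x)
}

#' Permutation significance of classifier performance
#'
#' Reruns the entire cross-validation pipeline (including in-fold feature
#' selection) under randomly shuffled labels; for tractability each
#' permutation uses a reduced number of CV iterations
#' (\code{perm_iterations}, default 10).
#'
#' @inheritParams crossval_classify
#' @param n_perm number of label permutations (reference protocol: 1000).
#' @param perm_iterations CV iterations per permutation.
#' @param observed optionally a precomputed \code{classifier_report} for
#'   the true labels (avoids recomputation).
#' @return the observed \code{classifier_report} augmented with
#'   \code{p_accuracy}, \code{p_auc}, and the permutation metric vectors.
#' @export
permutation_significance <- function(maps, labels, k_percent = 10,
                                     always_include = integer(0),
                                     cortical = NULL, n_folds = 4L,
                                     n_iterations = 100L, n_perm = 1000L,
                                     perm_iterations = 10L, cost = 1,
                                     seed = 1L, observed = NULL) {
  if (is.null(observed))
    observed <- crossval_classify(maps, labels, k_percent, always_include,
                                  cortical, n_folds, n_iterations, cost,
                                  seed = child_seed(seed, 0L))
  obs_acc <- observed$accuracy_summary["mean"]
  obs_auc <- observed$auc_summary["mean"]
  perm_acc <- perm_auc <- numeric(n_perm)
  for (pm in seq_len(n_perm)) {
    lab_p <- with_seed(child_seed(seed, pm), sample(labels))
    rep_p <- crossval_classify(maps, lab_p, k_percent, always_include,
                               cortical, n_folds, perm_iterations, cost,
                               seed = child_seed(seed, 500000L + pm))
    perm_acc[pm] <- rep_p$accuracy_summary["mean"]
    perm_auc[pm] <- rep_p$auc_summary["mean"]
  }
  observed$p_accuracy <- (1 + sum(perm_acc >= obs_acc)) / (n_perm + 1)
  observed$p_auc <- (1 + sum(perm_auc >= obs_auc)) / (n_perm + 1)
  observed$perm_accuracy <- perm_acc
  observed$perm_auc <- perm_auc
  observed
}
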