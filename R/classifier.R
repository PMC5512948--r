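# Linear classification of enhancer classes from sequence-pattern features:
# DRM densities, the full k-mer spectrum, or TF-motif densities. The k-mer
# spectrum kernel is realized as explicit 4^k count features with a linear
# model, which is mathematically identical for fixed k and makes per-k-mer
# weight extraction a direct read of the primal coefficients.

#' Enumerate all k-mers with GC annotation
#'
#' All 4^k DNA words in lexicographic order with their GC fraction. For
#' k = 6 the GC bins have exactly 64 (gc 0 or 1), 384 (1/6 or 5/6), 960
#' (2/6 or 4/6) and 1280 (3/6) members.
#'
#' @param k word length (>= 1).
#' @return data.frame with columns `kmer` and `gc`.
#' @export
enumerate_kmers <- function(k) {
  stopifnot(k >= 1)
  words <- Biostrings::mkAllStrings(DNA_BASES, k)
  gc <- vapply(strsplit(words, ""), function(ch) mean(ch %in% c("G", "C")),
               numeric(1))
  data.frame(kmer = words, gc = gc, stringsAsFactors = FALSE)
}

#' k-mer spectrum of sequences
#'
#' Sliding-window counts of every k-mer in each sequence, forward strand
#' only by default; windows containing ambiguous bases are skipped.
#' `collapse_revcomp` merges each reverse-complement pair into its
#' lexicographically smaller member (palindromic k-mers stay single).
#'
#' @param seqs character vector or `DNAStringSet`.
#' @param k word length.
#' @param collapse_revcomp merge reverse-complement pairs?
#' @return integer matrix, one row per sequence, k-mer columns in
#'   lexicographic order.
#' @export
kmer_spectrum <- function(seqs, k = 6, collapse_revcomp = FALSE) {
  if (!inherits(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  if (collapse_revcomp) {
    km <- colnames(m)
    canon <- pmin(km, revcomp(km))
    m <- t(rowsum(t(m), group = canon))
    m <- m[, sort(unique(canon)), drop = FALSE]
  }
  m
}

#' Build a feature matrix for enhancer classification
#'
#' The three feature schemes of the pipeline: per-bp densities of the four
#' DRMs (`"drm"`), raw k-mer spectrum counts (`"kmer"`; regions are expected
#' to be length-normalized, e.g. 600 bp, so counts are proportional to
#' densities), or per-bp densities of a set of TF motifs (`"tfmotif"`,
#' scanned at the TF-motif default cutoff `alpha = 1e-4`).
#'
#' @param seqs character vector of region sequences.
#' @param features `"drm"`, `"kmer"` or `"tfmotif"`.
#' @param k k-mer length for `"kmer"`.
#' @param pwms named list of [pwm()] objects for `"tfmotif"`.
#' @param params [scan_params()] for motif scanning (the `"tfmotif"` scheme
#'   overrides `alpha` to `tf_alpha`).
#' @param tf_alpha match cutoff for TF-motif scanning.
#' @param collapse_revcomp for `"kmer"`: merge reverse-complement pairs.
#' @return numeric matrix, one row per sequence, named feature columns.
#' @export
feature_matrix <- function(seqs, features = c("kmer", "drm", "tfmotif"),
                           k = 6, pwms = NULL, params = scan_params(),
                           tf_alpha = 1e-4, collapse_revcomp = FALSE) {
  features <- match.arg(features)
  if (features == "kmer")
    return(kmer_spectrum(seqs, k, collapse_revcomp = collapse_revcomp))
  if (features == "drm") pwms <- drm_pwms()
  else {
    if (is.null(pwms)) stop("tfmotif features need a list of PWMs")
    params <- scan_params(background = params$background,
                          pseudocount = params$pseudocount,
                          alpha = tf_alpha,
                          both_strands = params$both_strands)
  }
  lens <- nchar(seqs)
  codes <- lapply(seqs, seq_to_codes)
  out <- vapply(pwms, function(p) {
    eng <- scan_engine(p, params)  # calibrate once per motif
    vapply(codes, count_hits_engine, integer(1), eng = eng) / lens
  }, numeric(length(seqs)))
  out <- matrix(out, nrow = length(seqs),
                dimnames = list(NULL, names(pwms)))
  out
}

#' Positive/negative label factor for stacked feature matrices
#'
#' Levels are `c("neg", "pos")` so the positive class is the second level,
#' the convention [train_linear()] expects.
#' @param n_pos,n_neg numbers of positive and negative examples (stacked in
#'   that order).
#' @export
make_labels <- function(n_pos, n_neg) {
  factor(c(rep("pos", n_pos), rep("neg", n_neg)), levels = c("neg", "pos"))
}

#' Train a linear (hinge-loss) SVM
#'
#' L1-loss linear support vector machine solved by dual coordinate descent,
#' with the bias handled as an augmented regularized feature. Deterministic
#' given `seed` (which fixes the coordinate sweep order) and the data.
#'
#' @param x numeric feature matrix (rows = examples, named columns).
#' @param y two-level factor; the second level (`"pos"` under
#'   [make_labels()]) is the positive class.
#' @param cost soft-margin cost C (default 1).
#' @param seed integer seed for the sweep order.
#' @param tol convergence tolerance on the maximal projected gradient.
#' @param max_epochs cap on passes over the data.
#' @param bias_scale value of the augmented bias feature.
#' @return object of class `linear_svm`: `weights` (named), `bias`,
#'   `alpha`, `cost`, `levels`, `converged`, `epochs`.
#' @export
train_linear <- function(x, y, cost = 1, seed = 1L, tol = 1e-4,
                         max_epochs = 2000, bias_scale = 1) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2)
    stop("training data must contain exactly two classes")
  yy <- ifelse(y == levels(y)[2], 1, -1)
  set.seed(seed)
  n <- nrow(x)
  order <- vapply(1:13, function(i) sample.int(n), integer(n))
  fit <- dcd_svm_fit(t(as.matrix(x)), yy, cost, bias_scale, order, tol,
                     max_epochs)
  structure(list(weights = stats::setNames(fit$weights, colnames(x)),
                 bias = fit$bias, alpha = fit$alpha, cost = cost,
                 levels = levels(y), converged = fit$converged,
                 epochs = fit$epochs, seed = seed),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("linear SVM:", length(x$weights), "features, C =", x$cost,
      "|", if (x$converged) "converged" else "NOT converged",
      "in", x$epochs, "epochs\n")
  invisible(x)
}

#' @export
predict.linear_svm <- function(object, newdata,
                               type = c("decision", "class"), ...) {
  type <- match.arg(type)
  d <- drop(as.matrix(newdata) %*% object$weights) + object$bias
  if (type == "decision") return(unname(d))
  factor(ifelse(d > 0, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' @export
coef.linear_svm <- function(object, ...) {
  c(`(bias)` = object$bias, object$weights)
}

# ---- ROC / PR machinery ----------------------------------------------------
# per-fold curves come from pROC; averaging across folds is done here on a
# fixed grid because pROC has no multi-curve averaging.

roc_curve <- function(scores, labels) {
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c("neg", "pos"), direction = "<", quiet = TRUE)
  fpr <- rev(1 - r$specificities)
  tpr <- rev(r$sensitivities)
  list(fpr = fpr, tpr = tpr, auc = as.numeric(r$auc))
}

pr_curve <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  pos <- labels[ord] == "pos"
  tp <- cumsum(pos)
  precision <- tp / seq_along(tp)
  recall <- tp / sum(pos)
  # average precision: mean of precision at each positive example
  auc <- mean(precision[pos])
  list(recall = c(0, recall), precision = c(1, precision), auc = auc)
}

interp_grid <- function(xs, ys, grid, right = FALSE) {
  # step-function evaluation of an empirical curve at grid points: the ROC
  # staircase is right-continuous in FPR (f = 0); the PR step takes the
  # precision of the next achieved recall (f = 1), matching the average-
  # precision integral. Linear interpolation would systematically inflate
  # the area of coarse staircases.
  stats::approx(xs, ys, xout = grid, ties = max, rule = 2,
                method = "constant", f = as.numeric(right))$y
}

stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  assign <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cross-validated classification with averaged ROC/PR curves
#'
#' Stratified k-fold cross-validation of [train_linear()] with held-out ROC
#' and precision-recall curves per fold. Averaged curves are vertical means
#' on a fixed 101-point FPR (or recall) grid, evaluating each fold's
#' empirical step curve at the grid points, with min/max bands; AUCs are
#' reported per fold and as their mean.
#'
#' @param x feature matrix.
#' @param y two-level factor labels (second level = positive class).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed (fold assignment + solver sweeps).
#' @param cost soft-margin cost C.
#' @param ... further arguments to [train_linear()].
#' @return object of class `broadscan_cv`: per-fold AUCs, averaged curves,
#'   mean AUCs, fold assignment, trained per-fold models.
#' @export
cross_validate <- function(x, y, folds = 10, seed = 1L, cost = 1, ...) {
  y <- as.factor(y)
  if (any(table(y) < folds))
    stop("need at least `folds` examples in each class")
  fold <- stratified_folds(y, folds, seed)
  grid <- seq(0, 1, length.out = 101)
  roc_tpr <- pr_prec <- matrix(NA_real_, folds, length(grid))
  auc_roc <- auc_pr <- numeric(folds)
  models <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    stopifnot(nlevels(droplevels(y[!tr])) == 2)  # guaranteed by stratification
    m <- train_linear(x[tr, , drop = FALSE], y[tr], cost = cost,
                      seed = seed + f, ...)
    sc <- predict(m, x[!tr, , drop = FALSE])
    rc <- roc_curve(sc, y[!tr])
    pc <- pr_curve(sc, y[!tr])
    auc_roc[f] <- rc$auc
    auc_pr[f] <- pc$auc
    roc_tpr[f, ] <- interp_grid(rc$fpr, rc$tpr, grid)
    pr_prec[f, ] <- interp_grid(pc$recall, pc$precision, grid, right = TRUE)
    models[[f]] <- m
  }
  structure(list(
    folds = folds, fold_assignment = fold, seed = seed, cost = cost,
    auc_roc = auc_roc, auc_pr = auc_pr,
    mean_auc_roc = mean(auc_roc), mean_auc_pr = mean(auc_pr),
    roc = list(fpr = grid, tpr = colMeans(roc_tpr),
               tpr_min = apply(roc_tpr, 2, min),
               tpr_max = apply(roc_tpr, 2, max)),
    pr = list(recall = grid, precision = colMeans(pr_prec),
              precision_min = apply(pr_prec, 2, min),
              precision_max = apply(pr_prec, 2, max)),
    models = models), class = "broadscan_cv")
}

#' @export
print.broadscan_cv <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV: ROC AUC = %.3f (range %.3f-%.3f), PR AUC = %.3f | C = %g, seed = %d\n",
    x$folds, x$mean_auc_roc, min(x$auc_roc), max(x$auc_roc),
    x$mean_auc_pr, x$cost, x$seed))
  invisible(x)
}

#' @export
plot.broadscan_cv <- function(x, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "False positive rate", ylab = "True positive rate",
                   main = sprintf("Averaged ROC (AUC = %.3f)", x$mean_auc_roc), ...)
    graphics::polygon(c(x$roc$fpr, rev(x$roc$fpr)),
                      c(x$roc$tpr_min, rev(x$roc$tpr_max)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(x$roc$fpr, x$roc$tpr, lwd = 2, col = "steelblue4")
    graphics::abline(0, 1, lty = 2, col = "grey")
  } else {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "Recall", ylab = "Precision",
                   main = sprintf("Averaged PR (AUC = %.3f)", x$mean_auc_pr), ...)
    graphics::polygon(c(x$pr$recall, rev(x$pr$recall)),
                      c(x$pr$precision_min, rev(x$pr$precision_max)),
                      col = grDevices::adjustcolor("firebrick", 0.3),
                      border = NA)
    graphics::lines(x$pr$recall, x$pr$precision, lwd = 2, col = "firebrick4")
  }
  invisible(x)
}

#' Serialize a cross-validation result to JSON
#' @param cv a `broadscan_cv` object.
#' @param path output file.
#' @export
write_cv_json <- function(cv, path) {
  jsonlite::write_json(cv[c("folds", "seed", "cost", "auc_roc", "auc_pr",
                            "mean_auc_roc", "mean_auc_pr", "roc", "pr")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compare two cross-validated classifiers
#'
#' Two-sided paired t-test on per-fold ROC AUCs. The original analysis never
#' names its classifier-comparison test; this paired-fold test is a clearly
#' labeled stand-in. Identical per-fold AUCs return P = 1 by convention.
#'
#' @param cv1,cv2 `broadscan_cv` objects with the same number of folds.
#' @return list: `p_value`, `mean_diff`, `method`.
#' @export
compare_classifiers <- function(cv1, cv2) {
  if (cv1$folds != cv2$folds)
    stop("fold counts differ; paired comparison undefined")
  d <- cv1$auc_roc - cv2$auc_roc
  p <- if (stats::sd(d) == 0) 1
  else stats::t.test(d)$p.value
  list(p_value = p, mean_diff = mean(d),
       method = "paired t-test on per-fold ROC AUCs (stand-in test)")
}

#' Average per-k-mer SVM weights across replicate models
#'
#' Averages the primal weight vectors of models trained against replicate
#' negative sets and joins each k-mer's GC fraction — the weight table used
#' to relate classifier importance to GC content.
#'
#' @param models list of `linear_svm` (or `broadscan_cv`, whose fold models
#'   are pooled) sharing one feature space of k-mer names.
#' @return data.frame of class `kmer_weight_table`: `kmer`, `weight`, `gc`.
#' @export
extract_weights <- function(models) {
  pool <- list()
  for (m in models) {
    if (inherits(m, "broadscan_cv")) pool <- c(pool, m$models)
    else pool <- c(pool, list(m))
  }
  nm <- names(pool[[1]]$weights)
  for (m in pool)
    if (!identical(names(m$weights), nm))
      stop("models do not share a feature space")
  w <- rowMeans(vapply(pool, `[[`, numeric(length(nm)), "weights"))
  gc <- vapply(strsplit(nm, ""), function(ch) mean(ch %in% c("G", "C")),
               numeric(1))
  out <- data.frame(kmer = nm, weight = unname(w), gc = gc,
                    stringsAsFactors = FALSE)
  class(out) <- c("kmer_weight_table", "data.frame")
  out
}

#' Spearman correlation of k-mer weight (or enrichment) with GC content
#'
#' @param table a `kmer_weight_table` from [extract_weights()], or for
#'   `enrichment_gc_correlation` the per-k-mer data.frame from
#'   [all_kmer_enrichment()].
#' @return list: `rho`, `p_value`, `n`.
#' @export
weight_gc_correlation <- function(table) {
  ct <- suppressWarnings(
    stats::cor.test(table$weight, table$gc, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(table))
}

#' @rdname weight_gc_correlation
#' @export
enrichment_gc_correlation <- function(table) {
  ok <- !is.na(table$log2_fe)
  ct <- suppressWarnings(
    stats::cor.test(table$log2_fe[ok], table$gc[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
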