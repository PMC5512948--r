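test_that("k-mer enumeration is lexicographic with exact GC bin sizes", {
  km <- enumerate_kmers(6)
  expect_equal(nrow(km), 4096)
  expect_false(is.unsorted(km$kmer))
  expect_equal(as.integer(table(km$gc)),
               c(64, 384, 960, 1280, 960, 384, 64))
  km1 <- enumerate_kmers(1)
  expect_equal(km1$kmer, c("A", "C", "G", "T"))
  expect_equal(as.integer(table(km1$gc)), c(2, 2))
})

test_that("k-mer spectra match a naive dictionary-count oracle", {
  s <- kmer_spectrum("AAAAAA", 6)
  expect_equal(sum(s), 1)
  expect_equal(unname(s[1, "AAAAAA"]), 1)
  s <- kmer_spectrum("ACGTACGT", 6)
  expect_equal(s[1, c("ACGTAC", "CGTACG", "GTACGT")], c(ACGTAC = 1, CGTACG = 1, GTACGT = 1))
  expect_equal(sum(s), 3)
  # windows containing N are skipped
  expect_equal(sum(kmer_spectrum("ACGNACGT", 4)), 1)
  set.seed(19)
  seq <- random_dna_string(2000, 0.45)
  sp <- kmer_spectrum(seq, 6)[1, ]
  oracle <- table(substring(seq, 1:1995, 6:2000))
  expect_equal(sum(sp), 1995)
  expect_equal(unname(sp[names(oracle)]), as.integer(oracle))
})

test_that("reverse-complement collapsing merges paired k-mer counts", {
  sp <- kmer_spectrum("GCGCGC", 6, collapse_revcomp = TRUE)
  expect_equal(sum(sp), 1)
  full <- kmer_spectrum(c("ACGTTT", "AAACGT"), 4)
  col <- kmer_spectrum(c("ACGTTT", "AAACGT"), 4, collapse_revcomp = TRUE)
  expect_equal(sum(col), sum(full))
  # AAAC and its reverse complement GTTT collapse to one column
  expect_equal(col[2, "AAAC"], full[2, "AAAC"] + full[2, "GTTT"] )
  expect_false("GTTT" %in% colnames(col))
})

test_that("the linear SVM separates separable data and negates under label flip", {
  set.seed(2)
  n <- 40
  x <- cbind(f1 = c(rnorm(n / 2, 5), rnorm(n / 2, -5)), f2 = rnorm(n))
  y <- make_labels(n / 2, n / 2)
  m <- train_linear(x, y, cost = 1, seed = 1, tol = 1e-6)
  expect_true(m$converged)
  expect_equal(unname(predict(m, x, type = "class")), unname(y))
  # flipping labels negates the decision function
  yf <- factor(ifelse(y == "pos", "neg", "pos"), levels = c("neg", "pos"))
  mf <- train_linear(x, yf, cost = 1, seed = 1, tol = 1e-6)
  expect_equal(mf$weights, -m$weights, tolerance = 1e-4)
  expect_equal(mf$bias, -m$bias, tolerance = 1e-4)
  expect_error(train_linear(x, factor(rep("pos", n))), "two classes")
})

test_that("the solver matches an independent quadratic-program solution", {
  skip_if_not_installed("kernlab")
  set.seed(5)
  n <- 20
  x <- cbind(a = rnorm(n, rep(c(1, -1), each = n / 2)), b = rnorm(n))
  y <- make_labels(n / 2, n / 2)
  cost <- 1
  m <- train_linear(x, y, cost = cost, seed = 3, tol = 1e-9,
                    max_epochs = 200000)
  # dual of the same formulation (bias as augmented unit feature):
  # min 0.5 a'Qa - e'a, 0 <= a <= C, with Q = yy' .* (XX' + 1)
  yy <- ifelse(y == "pos", 1, -1)
  K <- x %*% t(x) + 1
  Q <- (yy %o% yy) * K
  qp <- kernlab::ipop(c = matrix(-1, n), H = Q, A = t(rep(1, n)), b = 0,
                      l = rep(0, n), u = rep(cost, n), r = n * cost)
  a <- kernlab::primal(qp)
  w_qp <- colSums(a * yy * x)
  b_qp <- sum(a * yy)
  expect_equal(unname(m$weights), unname(w_qp), tolerance = 1e-4)
  expect_equal(m$bias, b_qp, tolerance = 1e-4)
})

test_that("the solver agrees with libsvm on well-separated data", {
  skip_if_not_installed("e1071")
  set.seed(8)
  n <- 60
  x <- cbind(f1 = c(rnorm(n / 2, 3), rnorm(n / 2, -3)),
             f2 = rnorm(n), f3 = rnorm(n))
  y <- make_labels(n / 2, n / 2)
  m <- train_linear(x, y, cost = 1, seed = 1, tol = 1e-8,
                    max_epochs = 100000)
  sv <- e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE)
  w_sv <- drop(t(sv$coefs) %*% sv$SV)
  cosine <- sum(m$weights * w_sv) /
    sqrt(sum(m$weights^2) * sum(w_sv^2))
  # up to libsvm's internal label orientation
  expect_gt(abs(cosine), 0.99)
})

test_that("cross-validation is stratified, calibrated, and order-invariant", {
  set.seed(7)
  n <- 300
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- make_labels(n / 2, n / 2)
  # informative feature: AUC approaches 1 as noise vanishes
  x1 <- x
  x1[, 1] <- ifelse(y == "pos", 1, -1) + rnorm(n, 0, 1e-3)
  cv1 <- cross_validate(x1, y, folds = 10, seed = 4)
  expect_gt(cv1$mean_auc_roc, 0.99)
  expect_gt(cv1$mean_auc_pr, 0.99)
  # uninformative features: AUC near 1/2
  cv0 <- cross_validate(x, y, folds = 10, seed = 4)
  expect_lt(abs(cv0$mean_auc_roc - 0.5), 0.12)
  # fold structure: stratified partition
  expect_equal(sort(unique(cv0$fold_assignment)), 1:10)
  tab <- table(cv0$fold_assignment, y)
  expect_true(all(tab == n / 20))
  # permuting feature columns (with names) leaves the result unchanged
  perm <- sample(10)
  cvp <- cross_validate(x1[, perm], y, folds = 10, seed = 4)
  expect_equal(cvp$auc_roc, cv1$auc_roc)
  expect_equal(cvp$mean_auc_pr, cv1$mean_auc_pr)
  # determinism of the whole CVResult
  cvr <- cross_validate(x1, y, folds = 10, seed = 4)
  expect_identical(cvr$roc, cv1$roc)
  expect_identical(cvr$auc_roc, cv1$auc_roc)
})

test_that("averaged ROC curve integrates to nearly the mean fold AUC", {
  set.seed(13)
  n <- 1000
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- make_labels(n / 2, n / 2)
  x[, 1] <- x[, 1] + ifelse(y == "pos", 1, 0)
  cv <- cross_validate(x, y, folds = 5, seed = 2)
  auc_from_curve <- sum(diff(cv$roc$fpr) *
                          (utils::head(cv$roc$tpr, -1) + utils::tail(cv$roc$tpr, -1)) / 2)
  expect_equal(auc_from_curve, cv$mean_auc_roc, tolerance = 0.01)
  # min/max band brackets the mean curve
  expect_true(all(cv$roc$tpr_min - 1e-12 <= cv$roc$tpr &
                    cv$roc$tpr <= cv$roc$tpr_max + 1e-12))
  # averaged curve is monotone nondecreasing
  expect_true(all(diff(cv$roc$tpr) >= -1e-12))
})

test_that("classifier comparison returns 1 for identical results and detects gaps", {
  set.seed(3)
  n <- 200
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- make_labels(n / 2, n / 2)
  cv <- cross_validate(x, y, folds = 5, seed = 1)
  expect_equal(compare_classifiers(cv, cv)$p_value, 1)
  # a real AUC gap is detected
  x1 <- x
  x1[, 1] <- x1[, 1] + ifelse(y == "pos", 2, 0)
  cv1 <- cross_validate(x1, y, folds = 5, seed = 1)
  cmp <- compare_classifiers(cv1, cv)
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$mean_diff, 0.2)
  cv3 <- cross_validate(x, y, folds = 4, seed = 1)
  expect_error(compare_classifiers(cv1, cv3), "fold counts")
})

test_that("weight extraction averages replicate models and joins GC", {
  set.seed(6)
  n <- 80
  km <- enumerate_kmers(3)
  x <- matrix(rpois(n * 64, 2), n, 64, dimnames = list(NULL, km$kmer))
  y <- make_labels(n / 2, n / 2)
  m1 <- train_linear(x, y, seed = 1)
  tab1 <- extract_weights(list(m1))
  expect_equal(nrow(tab1), 64)
  expect_equal(tab1$weight, unname(m1$weights))
  expect_equal(tab1$gc, km$gc)
  # identical models average to any single model
  expect_equal(extract_weights(list(m1, m1))$weight, tab1$weight)
  m2 <- train_linear(x, y, seed = 2)
  tab12 <- extract_weights(list(m1, m2))
  expect_equal(tab12$weight, (unname(m1$weights) + unname(m2$weights)) / 2)
  # mismatched feature spaces are rejected
  x2 <- x[, 1:32]
  expect_error(extract_weights(list(m1, train_linear(x2, y, seed = 1))),
               "feature space")
})

test_that("weight-GC correlation is exact on constructed tables", {
  km <- enumerate_kmers(4)
  tab <- data.frame(kmer = km$kmer, weight = km$gc, gc = km$gc)
  expect_equal(weight_gc_correlation(tab)$rho, 1)
  tab$weight <- -km$gc
  expect_equal(weight_gc_correlation(tab)$rho, -1)
  enr <- data.frame(kmer = km$kmer, gc = km$gc, log2_fe = km$gc + 0)
  expect_equal(enrichment_gc_correlation(enr)$rho, 1)
})
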