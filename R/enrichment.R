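# Fold-enrichment statistics of motif occurrences across region sets.

#' Fold enrichment of motif counts between two region sets
#'
#' `FE = mean(pos counts) / mean(neg counts)`, with a two-sided Wilcoxon
#' rank-sum P-value on the count distributions. Depletion is displayed as a
#' signed fold (`-1/FE` when FE < 1); all computation is on log2(FE). A zero
#' negative mean gives the undefined-enrichment sentinel (`NA`) unless a
#' pseudocount is supplied (added to every count in both sets).
#'
#' @param pos_counts,neg_counts per-region motif counts.
#' @param motif motif name recorded in the result.
#' @param pseudocount optional count pseudocount for small runs (default 0).
#' @param p_value compute the rank-sum P? (skippable for bulk k-mer runs).
#' @return list of class `enrichment_result`: `motif`, `fe`, `log2_fe`,
#'   `signed_fold`, `p_value`, `mean_pos`, `mean_neg`, `n_pos`, `n_neg`.
#' @export
fold_enrichment <- function(pos_counts, neg_counts, motif = "motif",
                            pseudocount = 0, p_value = TRUE) {
  if (length(pos_counts) == 0 || length(neg_counts) == 0)
    stop("both count vectors must be nonempty")
  mp <- mean(pos_counts) + pseudocount
  mn <- mean(neg_counts) + pseudocount
  fe <- if (mn == 0) NA_real_ else mp / mn
  if (!is.na(fe) && fe == 0) fe <- NA_real_  # zero positive mean: undefined log2
  p <- if (p_value)
    suppressWarnings(stats::wilcox.test(pos_counts, neg_counts)$p.value)
  else NA_real_
  structure(list(motif = motif, fe = fe, log2_fe = log2(fe),
                 signed_fold = if (is.na(fe)) NA_real_
                               else if (fe >= 1) fe else -1 / fe,
                 p_value = p, mean_pos = mean(pos_counts),
                 mean_neg = mean(neg_counts),
                 n_pos = length(pos_counts), n_neg = length(neg_counts)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s: FE = %.3g (%.3g-fold signed), log2(FE) = %.3f, P = %.3g\n",
              x$motif, x$fe, x$signed_fold, x$log2_fe, x$p_value))
  invisible(x)
}

#' Fold enrichment against replicate negative sets
#'
#' Computes log2(FE) of the positive set against each of several independent
#' negative sets and summarizes their mean, standard deviation and standard
#' error. Rank-sum P-values are reported per replicate.
#'
#' @param pos_counts per-region counts in the positive set.
#' @param neg_counts_list list of per-region count vectors (>= 2 replicates).
#' @param motif motif name.
#' @param pseudocount optional count pseudocount.
#' @return list of class `replicate_enrichment`: `motif`,
#'   `replicate_log2_fe`, `mean_log2_fe`, `sd_log2_fe`, `se_log2_fe`,
#'   `p_values`.
#' @export
replicate_enrichment <- function(pos_counts, neg_counts_list,
                                 motif = "motif", pseudocount = 0) {
  if (length(neg_counts_list) < 2) stop("need >= 2 replicate negative sets")
  reps <- lapply(neg_counts_list, fold_enrichment, pos_counts = pos_counts,
                 motif = motif, pseudocount = pseudocount)
  l2 <- vapply(reps, `[[`, numeric(1), "log2_fe")
  if (anyNA(l2))
    warning("undefined enrichment in ", sum(is.na(l2)), " replicate(s)")
  structure(list(motif = motif, replicate_log2_fe = l2,
                 mean_log2_fe = mean(l2), sd_log2_fe = stats::sd(l2),
                 se_log2_fe = stats::sd(l2) / sqrt(length(l2)),
                 p_values = vapply(reps, `[[`, numeric(1), "p_value")),
            class = "replicate_enrichment")
}

#' @export
print.replicate_enrichment <- function(x, ...) {
  cat(sprintf("%s: mean log2(FE) = %.3f (SD %.3f, SE %.3f) over %d negative sets\n",
              x$motif, x$mean_log2_fe, x$sd_log2_fe, x$se_log2_fe,
              length(x$replicate_log2_fe)))
  invisible(x)
}

#' Fold enrichment of every k-mer between two sequence sets
#'
#' Counts all 4^k k-mers by sliding window in each region's sequence
#' (forward strand by default, see [kmer_spectrum()]) and computes per-k-mer
#' fold enrichment of the positive over the negative set, flagging k-mers
#' whose log2(FE) lies beyond 1 or 2 standard deviations of the mean over
#' defined k-mers.
#'
#' @param pos_seqs,neg_seqs character vectors of region sequences (length
#'   normalization, e.g. to 600 bp, is the caller's responsibility).
#' @param k word length (default 6).
#' @param collapse_revcomp merge reverse-complement k-mer pairs?
#' @param p_values compute per-k-mer rank-sum P-values (slower)?
#' @param pseudocount optional count pseudocount.
#' @return data.frame with one row per k-mer: `kmer`, `gc`, `mean_pos`,
#'   `mean_neg`, `fe`, `log2_fe`, `p_value`, `beyond_1sd`, `beyond_2sd`.
#' @export
all_kmer_enrichment <- function(pos_seqs, neg_seqs, k = 6,
                                collapse_revcomp = FALSE, p_values = TRUE,
                                pseudocount = 0) {
  pos <- kmer_spectrum(pos_seqs, k, collapse_revcomp = collapse_revcomp)
  neg <- kmer_spectrum(neg_seqs, k, collapse_revcomp = collapse_revcomp)
  mp <- colMeans(pos) + pseudocount
  mn <- colMeans(neg) + pseudocount
  fe <- ifelse(mn == 0, NA_real_, mp / mn)
  fe[!is.na(fe) & fe == 0] <- NA_real_
  l2 <- log2(fe)
  pv <- rep(NA_real_, length(fe))
  if (p_values) {
    for (j in seq_along(pv))
      pv[j] <- suppressWarnings(
        stats::wilcox.test(pos[, j], neg[, j])$p.value)
  }
  mu <- mean(l2, na.rm = TRUE)
  sdev <- stats::sd(l2, na.rm = TRUE)
  km <- enumerate_kmers(k)
  stopifnot(identical(km$kmer, colnames(pos)))
  data.frame(kmer = km$kmer, gc = km$gc, mean_pos = unname(mp),
             mean_neg = unname(mn), fe = unname(fe), log2_fe = unname(l2),
             p_value = pv,
             beyond_1sd = !is.na(l2) & abs(l2 - mu) > sdev,
             beyond_2sd = !is.na(l2) & abs(l2 - mu) > 2 * sdev,
             stringsAsFactors = FALSE)
}

#' Spearman correlation of motif density with breadth of activity
#'
#' Per-enhancer motif density (hits per bp) against breadth, with the
#' tie-corrected Spearman rank correlation.
#'
#' @param catalog a `synthetic_catalog` or list with `enhancers` + `genome`.
#' @param x a [pwm()] object.
#' @param params a [scan_params()] object.
#' @return list: `rho`, `p_value`, `densities` (per-enhancer data.frame).
#' @export
density_breadth_correlation <- function(catalog, x, params = scan_params()) {
  enh <- catalog$enhancers
  if (length(unique(enh$breadth)) < 3)
    stop("need >= 3 distinct breadth values")
  d <- count_per_bp(enh, catalog$genome, x, params)
  if (stats::sd(d$density) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, densities = d))
  ct <- suppressWarnings(
    stats::cor.test(d$density, enh$breadth, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       densities = cbind(d, breadth = enh$breadth))
}

#' Spearman correlation of enhancer GC content with breadth of activity
#'
#' Also reports a breadth-binned summary in the style of activity-bin plots:
#' bins are labeled by the highest breadth they contain, with mean GC and
#' occupancy per bin. Default bin edges aim for near-equal occupancy.
#'
#' @param catalog a `synthetic_catalog` (or list with `enhancers`, `genome`).
#' @param bin_edges optional increasing breadth edges; bins are
#'   `(e[i], e[i+1]]`. Default: deciles of the breadth distribution.
#' @return list: `rho`, `p_value`, `per_enhancer`, `bins` (data.frame
#'   label, n, mean_gc).
#' @export
gc_breadth_correlation <- function(catalog, bin_edges = NULL) {
  enh <- catalog$enhancers
  gc <- gc_content(region_sequences(enh, catalog$genome))
  ct <- suppressWarnings(
    stats::cor.test(gc, enh$breadth, method = "spearman"))
  if (is.null(bin_edges)) {
    bin_edges <- unique(stats::quantile(enh$breadth, seq(0, 1, 0.1)))
    bin_edges[1] <- bin_edges[1] - 1  # open lower edge of first bin
  }
  bin <- cut(enh$breadth, bin_edges, include.lowest = FALSE)
  label <- tapply(enh$breadth, bin, max)
  bins <- data.frame(label = as.integer(label),
                     n = as.integer(table(bin)),
                     mean_gc = as.numeric(tapply(gc, bin, mean)))
  stopifnot(sum(bins$n) == nrow(enh))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       per_enhancer = data.frame(id = enh$id, breadth = enh$breadth, gc = gc,
                                 stringsAsFactors = FALSE),
       bins = bins)
}
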