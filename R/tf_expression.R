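# TF motif composition (GC, CpG) versus breadth of TF expression.

#' GC and CpG content of a PWM
#'
#' Probability-weighted expectations over the motif model:
#' `gc = mean_i [p_i(G) + p_i(C)]` and
#' `cpg = (1/(L-1)) * sum_i p_i(C) * p_(i+1)(G)` (the expected CG
#' dinucleotide rate per bp of a word drawn from the PWM). The CpG rate is
#' undefined (`NA`) for single-position motifs. `consensus = TRUE` instead
#' counts on the consensus sequence.
#'
#' @param x a [pwm()] object.
#' @param consensus use the consensus string instead of the probability
#'   expectation?
#' @return a fraction (`motif_gc`) or per-bp rate (`motif_cpg`).
#' @export
motif_gc <- function(x, consensus = FALSE) {
  if (consensus) return(gc_content(pwm_consensus(x)))
  mean(x["G", ] + x["C", ])
}

#' @rdname motif_gc
#' @export
motif_cpg <- function(x, consensus = FALSE) {
  L <- ncol(x)
  if (L < 2) return(NA_real_)
  if (consensus) return(cpg_per_bp(pwm_consensus(x)))
  sum(x["C", -L] * x["G", -1]) / (L - 1)
}

#' TSPS of a TF complex
#'
#' A motif bound by a complex takes the greater of its components' tissue
#' specificity scores, on the assumption that a complex cannot have wider
#' expression than its most specific component.
#'
#' @param component_tsps nonempty numeric vector of component scores.
#' @export
resolve_complex_tsps <- function(component_tsps) {
  if (length(component_tsps) == 0) stop("empty component list")
  max(component_tsps)
}

#' Per-TF motif composition from a TF table
#'
#' Joins a TF table (tf_name, tsps, comma-separated motif_ids) with a PWM
#' collection and computes each TF's mean motif GC and CpG content (mean
#' over its motifs). TFs are classified broad (TSPS < 1) or specific
#' (TSPS >= 1; the boundary is specific). Motifs referenced by no TF and
#' TFs whose motifs are missing from the collection are dropped with a
#' warning, mirroring the discard rule for unpairable records.
#'
#' @param table data.frame with columns `tf_name`, `tsps`, `motif_ids`.
#' @param pwms named list of [pwm()] objects.
#' @param consensus passed to [motif_gc()] / [motif_cpg()].
#' @return data.frame: `tf_name`, `tsps`, `breadth_class`, `mean_gc`,
#'   `mean_cpg`, `n_motifs`.
#' @export
tf_composition <- function(table, pwms, consensus = FALSE) {
  rows <- vector("list", nrow(table))
  dropped <- character(0)
  for (i in seq_len(nrow(table))) {
    ids <- strsplit(table$motif_ids[i], ",")[[1]]
    ids <- trimws(ids)
    found <- ids[ids %in% names(pwms)]
    if (length(found) == 0) {
      dropped <- c(dropped, table$tf_name[i])
      next
    }
    rows[[i]] <- data.frame(
      tf_name = table$tf_name[i], tsps = table$tsps[i],
      breadth_class = if (table$tsps[i] >= 1) "specific" else "broad",
      mean_gc = mean(vapply(pwms[found], motif_gc, numeric(1),
                            consensus = consensus)),
      mean_cpg = mean(vapply(pwms[found], motif_cpg, numeric(1),
                             consensus = consensus)),
      n_motifs = length(found), stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning(length(dropped), " TF(s) dropped with no matching motif: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  unused <- setdiff(names(pwms),
                    trimws(unlist(strsplit(table$motif_ids, ","))))
  if (length(unused))
    warning(length(unused), " motif(s) referenced by no TF")
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Compare motif composition between broad and specific TFs
#'
#' Group means of mean motif GC and CpG content for broadly expressed
#' (TSPS < 1) versus context-specific (TSPS >= 1) TFs, with two-sided
#' Wilcoxon rank-sum P-values.
#'
#' @param records data.frame from [tf_composition()] (columns
#'   `breadth_class`, `mean_gc`, `mean_cpg`).
#' @return list: `means` (2 x 2 data.frame), `p_gc`, `p_cpg`, `n_broad`,
#'   `n_specific`.
#' @export
compare_composition <- function(records) {
  cls <- records$breadth_class
  if (length(unique(cls)) < 2)
    stop("both broad and specific TFs are required")
  b <- records[cls == "broad", ]
  s <- records[cls == "specific", ]
  list(means = data.frame(
         class = c("broad", "specific"),
         mean_gc = c(mean(b$mean_gc), mean(s$mean_gc)),
         mean_cpg = c(mean(b$mean_cpg), mean(s$mean_cpg)),
         stringsAsFactors = FALSE),
       p_gc = suppressWarnings(
         stats::wilcox.test(b$mean_gc, s$mean_gc)$p.value),
       p_cpg = suppressWarnings(
         stats::wilcox.test(b$mean_cpg, s$mean_cpg)$p.value),
       n_broad = nrow(b), n_specific = nrow(s))
}

#' Squared semipartial correlation of CpG content beyond GC
#'
#' Does CpG content explain breadth of TF expression beyond GC content?
#' Computes `sr2 = R2(response ~ GC + CpG) - R2(response ~ GC)` with the
#' incremental F statistic `F = sr2 * (n - 3) / (1 - R2_full)` on (1, n - 3)
#' degrees of freedom. The response is either the continuous TSPS or the
#' broad/specific dummy coding (specific = 1). Exactly collinear GC and CpG
#' give `sr2 = 0` with `collinear = TRUE` (a deterministic CpG adds nothing).
#'
#' @param records data.frame with `tsps`, `mean_gc`, `mean_cpg` (and
#'   `breadth_class` when `response = "broad-specific-dummy"`, otherwise
#'   derived from tsps >= 1).
#' @param response `"tsps-continuous"` or `"broad-specific-dummy"`.
#' @return list: `sr2`, `f`, `df`, `p_value`, `r2_full`, `r2_reduced`, `n`.
#' @export
semipartial_cpg_given_gc <- function(records,
                                     response = c("tsps-continuous",
                                                  "broad-specific-dummy")) {
  response <- match.arg(response)
  n <- nrow(records)
  if (n < 4) stop("need at least 4 records")
  y <- if (response == "tsps-continuous") records$tsps
       else as.numeric(records$tsps >= 1)
  gc <- records$mean_gc
  cpg <- records$mean_cpg
  if (stats::sd(gc) == 0 || stats::sd(cpg) == 0 || stats::sd(y) == 0)
    stop("constant predictor or response")
  if (abs(stats::cor(gc, cpg)) >= 1 - 1e-12) {
    # CpG carries no information beyond GC when the two are collinear: the
    # incremental variance explained is exactly zero (flagged, since the
    # semipartial correlation itself is degenerate here)
    r2 <- summary(stats::lm(y ~ gc))$r.squared
    return(list(sr2 = 0, f = 0, df = c(1, n - 3), p_value = 1,
                r2_full = r2, r2_reduced = r2, n = n, collinear = TRUE))
  }
  r2_reduced <- summary(stats::lm(y ~ gc))$r.squared
  r2_full <- summary(stats::lm(y ~ gc + cpg))$r.squared
  sr2 <- r2_full - r2_reduced
  f <- sr2 * (n - 3) / (1 - r2_full)
  list(sr2 = sr2, f = f, df = c(1, n - 3),
       p_value = stats::pf(f, 1, n - 3, lower.tail = FALSE),
       r2_full = r2_full, r2_reduced = r2_reduced, n = n, collinear = FALSE)
}
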