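# PWM scanning with exact P-value threshold calibration.
#
# Window scores live on an integer lattice: every log-odds entry is rounded
# to SCORE_GRAN bits before any scoring or tail-probability computation, so
# the dynamic-programming score distribution, the calibrated threshold and
# the per-window scores are all exactly consistent with one another (and with
# a brute-force enumeration over the same rounded entries).

SCORE_GRAN <- 1e-3

int_score_matrix <- function(x, params) {
  round(log_odds(x, params) / SCORE_GRAN)
}

seq_to_codes <- function(sequence) {
  if (inherits(sequence, "XString")) sequence <- as.character(sequence)
  chars <- strsplit(toupper(sequence), "")[[1]]
  match(chars, DNA_BASES)  # ambiguous bases -> NA
}

# Exact distribution of the lattice window score under the i.i.d. background:
# convolution of per-position score distributions over the integer lattice.
int_score_distribution <- function(si, background) {
  L <- ncol(si)
  p <- 1
  mn <- 0L
  for (i in seq_len(L)) {
    s <- si[, i]
    smin <- min(s)
    p2 <- numeric(length(p) + max(s) - smin)
    for (b in 1:4) {
      idx <- seq_along(p) + (s[b] - smin)
      p2[idx] <- p2[idx] + p * background[b]
    }
    p <- p2
    mn <- mn + smin
  }
  keep <- p > 0
  list(score = (mn + which(keep) - 1L), prob = p[keep])
}

#' Exact tail probability of a PWM score
#'
#' Probability that a random word of the motif's length, drawn i.i.d. from
#' the background nucleotide frequencies, scores at least `s`. Computed
#' exactly by dynamic programming over the integerized score lattice (no
#' sampling); equals brute-force enumeration over all 4^L words.
#'
#' @param x a [pwm()] object.
#' @param params a [scan_params()] object.
#' @param s score in bits.
#' @return the tail probability `P(score(W) >= s)`.
#' @export
exact_tail_probability <- function(x, params, s) {
  si <- int_score_matrix(x, params)
  d <- int_score_distribution(si, params$background)
  thr <- ceiling(s / SCORE_GRAN - 1e-9)
  sum(d$prob[d$score >= thr])
}

#' Calibrated score threshold for a match P-value cutoff
#'
#' Returns the smallest achievable window score `s*` such that
#' `P(score(W) >= s*) < alpha` under the background model, with the tail
#' probability computed exactly. If even the maximal score has tail
#' probability `>= alpha` (as for the perfect TATATA word at `alpha = 1/4096`
#' under a 42% GC background), no threshold exists and an error of class
#' `broadscan_no_threshold` is signalled; [scan()] treats that case as "no
#' hits possible".
#'
#' @inheritParams exact_tail_probability
#' @return threshold score in bits, with attribute `tail_probability`.
#' @export
score_threshold <- function(x, params) {
  si <- int_score_matrix(x, params)
  d <- int_score_distribution(si, params$background)
  ord <- order(d$score, decreasing = TRUE)
  tails <- cumsum(d$prob[ord])
  # alpha = 1 admits every word (tail probability 1 is not < 1, but the
  # cutoff "P < 1" is vacuous at the full-support score)
  ok <- if (params$alpha >= 1) rep(TRUE, length(tails)) else
    tails < params$alpha
  if (!any(ok)) {
    stop(structure(class = c("broadscan_no_threshold", "error", "condition"),
                   list(message = sprintf(
                     "no achievable score for '%s' has tail probability < %g",
                     pwm_name(x), params$alpha), call = sys.call(-1))))
  }
  k <- max(which(ok))  # lowest achievable score still under alpha
  structure(d$score[ord][k] * SCORE_GRAN, tail_probability = tails[k])
}

window_int_scores <- function(codes, si) {
  L <- ncol(si)
  n <- length(codes) - L + 1
  if (n < 1) return(integer(0))
  sc <- rep(0L, n)
  bad <- rep(FALSE, n)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + n - 1)]
    na <- is.na(cj)
    bad <- bad | na
    cj[na] <- 1L
    sc <- sc + si[cbind(cj, j)]
  }
  sc[bad] <- NA_integer_
  sc
}

#' Scan a sequence for PWM matches
#'
#' Slides the motif over every window of the sequence (both strands when
#' `params$both_strands`) and reports windows whose score meets the
#' calibrated threshold for `params$alpha`. Overlapping hits are all
#' reported, and a palindromic motif (e.g. the GC or TA repeat) yields one
#' hit per strand at a single genomic site, so such occurrences are counted
#' twice. Windows containing ambiguous bases are disqualified. A sequence
#' shorter than the motif yields an empty hit set.
#'
#' @param sequence character or Biostrings `DNAString`.
#' @param x a [pwm()] object.
#' @param params a [scan_params()] object.
#' @param region_id id recorded in the output.
#' @return data.frame with columns `region_id`, `offset` (0-based start on
#'   the forward strand), `strand`, `score` (bits, on the scoring lattice)
#'   and `site` (the matched subsequence, reverse-complemented for minus
#'   strand hits).
#' @export
scan <- function(sequence, x, params = scan_params(), region_id = "seq") {
  empty <- data.frame(region_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      site = character(), stringsAsFactors = FALSE)
  thr <- tryCatch(score_threshold(x, params),
                  broadscan_no_threshold = function(e) NULL)
  if (is.null(thr)) return(empty)
  thr_int <- round(thr / SCORE_GRAN)
  codes <- seq_to_codes(sequence)
  si <- int_score_matrix(x, params)
  L <- ncol(si)
  if (length(codes) < L) return(empty)
  chars <- strsplit(toupper(as.character(sequence)), "")[[1]]

  hit_rows <- function(si_strand, strand) {
    sc <- window_int_scores(codes, si_strand)
    off <- which(!is.na(sc) & sc >= thr_int)
    if (length(off) == 0) return(empty)
    site <- vapply(off, function(i) paste(chars[i:(i + L - 1)], collapse = ""),
                   character(1))
    if (strand == "-") site <- revcomp(site)
    data.frame(region_id = region_id, offset = off - 1L, strand = strand,
               score = sc[off] * SCORE_GRAN, site = site,
               stringsAsFactors = FALSE)
  }

  out <- hit_rows(si, "+")
  if (params$both_strands) {
    si_rc <- si[4:1, rev(seq_len(L)), drop = FALSE]
    out <- rbind(out, hit_rows(si_rc, "-"))
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# calibrated scanning state reused across many regions: integer score
# matrices for both strands plus the lattice threshold (NULL when no
# achievable score passes alpha, i.e. zero hits everywhere)
scan_engine <- function(x, params) {
  thr <- tryCatch(score_threshold(x, params),
                  broadscan_no_threshold = function(e) NULL)
  if (is.null(thr)) return(NULL)
  si <- int_score_matrix(x, params)
  list(si = si, si_rc = si[4:1, rev(seq_len(ncol(si))), drop = FALSE],
       thr_int = round(thr / SCORE_GRAN), L = ncol(si),
       both = params$both_strands)
}

count_hits_engine <- function(codes, eng) {
  if (is.null(eng) || length(codes) < eng$L) return(0L)
  sc <- window_int_scores(codes, eng$si)
  n <- sum(!is.na(sc) & sc >= eng$thr_int)
  if (eng$both) {
    sc <- window_int_scores(codes, eng$si_rc)
    n <- n + sum(!is.na(sc) & sc >= eng$thr_int)
  }
  as.integer(n)
}

#' Motif hit counts and densities per region
#'
#' Counts calibrated PWM matches in each region's sequence and divides by
#' region length, giving the counts-per-bp densities used as classifier
#' features and for fold-enrichment statistics.
#'
#' @param regions region data.frame (see [regions()]).
#' @param genome named `DNAStringSet` (or named character vector).
#' @param x a [pwm()] object.
#' @param params a [scan_params()] object.
#' @return data.frame with columns `id`, `count`, `density` (hits per bp),
#'   one row per input region, in input order.
#' @export
count_per_bp <- function(regions, genome, x, params = scan_params()) {
  seqs <- region_sequences(regions, genome)
  eng <- scan_engine(x, params)  # calibrate once for all regions
  counts <- vapply(seqs, function(s) count_hits_engine(seq_to_codes(s), eng),
                   integer(1))
  data.frame(id = regions$id, count = counts,
             density = counts / (regions$end - regions$start),
             stringsAsFactors = FALSE)
}
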