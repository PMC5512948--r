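# Independent oracles and small fixture builders used across the suite.

# random column-stochastic PWM
random_pwm <- function(L, seed = NULL, name = "rand") {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rgamma(4 * L, 1), 4)
  pwm(sweep(m, 2, colSums(m), "/"), name = name)
}

# all 4^L words as an integer code matrix (rows = words, cols = positions)
all_word_codes <- function(L) {
  as.matrix(expand.grid(rep(list(1:4), L)))
}

# brute-force tail probability over all 4^L words, scoring each word by
# summing the integerized (1e-3 bit) log-odds entries -- the package's
# documented score definition -- independently of the DP convolution.
enum_tail_probability <- function(x, params, s) {
  si <- round(log_odds(x, params) / 1e-3)
  L <- ncol(si)
  w <- all_word_codes(L)
  isc <- rowSums(matrix(si[cbind(as.vector(w), rep(seq_len(L), each = nrow(w)))],
                        nrow(w)))
  bgp <- apply(w, 1, function(v) prod(params$background[v]))
  sum(bgp[isc >= ceiling(s / 1e-3 - 1e-9)])
}

# naive rescoring scan oracle: slide over every window on both strands,
# score against the integerized matrix directly, keep score >= threshold
naive_scan_count <- function(sequence, x, params) {
  thr <- tryCatch(score_threshold(x, params),
                  broadscan_no_threshold = function(e) NULL)
  if (is.null(thr)) return(0L)
  si <- round(log_odds(x, params) / 1e-3)
  thr_int <- round(thr / 1e-3)
  L <- ncol(si)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars) - L + 1
  if (n < 1) return(0L)
  hits <- 0L
  strands <- if (params$both_strands) c("+", "-") else "+"
  for (i in seq_len(n)) {
    win <- chars[i:(i + L - 1)]
    for (str in strands) {
      word <- if (str == "+") win else rev(c(A = "T", C = "G", G = "C", T = "A")[win])
      code <- match(word, c("A", "C", "G", "T"))
      if (anyNA(code)) next
      if (sum(si[cbind(code, seq_len(L))]) >= thr_int) hits <- hits + 1L
    }
  }
  hits
}

# exact two-sided rank-sum p-value by enumeration over all assignments
enum_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  ws <- apply(idx, 2, function(j) sum(r[j]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

random_dna_string <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small deterministic test genome + regions
tiny_genome <- function(seed = 42, n_chrom = 2, len = 20000, gc = 0.42) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(
    vapply(seq_len(n_chrom), function(i) random_dna_string(len, gc),
           character(1)))
  names(g) <- paste0("chr", seq_len(n_chrom))
  g
}
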