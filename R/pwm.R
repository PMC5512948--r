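DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' A PWM is stored as a 4 x L numeric matrix of per-position nucleotide
#' probabilities with rows `A`, `C`, `G`, `T`, plus a `name` attribute.
#' Columns must each sum to 1.
#'
#' @param probs numeric matrix, 4 rows (A,C,G,T) by L >= 1 columns of
#'   probabilities, or an L x 4 matrix which is transposed on input.
#' @param name motif name.
#' @return an object of class `pwm`.
#' @export
pwm <- function(probs, name = "motif") {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4 && ncol(probs) == 4) probs <- t(probs)
  if (nrow(probs) != 4) stop("PWM must have 4 nucleotide rows (A,C,G,T)")
  if (ncol(probs) < 1) stop("PWM must have at least one position")
  if (any(probs < 0)) stop("PWM probabilities must be nonnegative")
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 1e-9)) stop("each PWM position must sum to 1")
  rownames(probs) <- DNA_BASES
  colnames(probs) <- NULL
  structure(probs, name = name, class = c("pwm", "matrix"))
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM '", attr(x, "name"), "' (", ncol(x), " bp), consensus ",
      pwm_consensus(x), "\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' @rdname pwm
#' @param x a `pwm` object.
#' @export
pwm_length <- function(x) ncol(x)

#' @rdname pwm
#' @export
pwm_name <- function(x) attr(x, "name")

#' Consensus sequence of a PWM (highest-probability base per position,
#' ties broken in A<C<G<T order).
#' @param x a `pwm` object.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x, 2, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @param x a `pwm` object.
#' @return a `pwm` on the opposite strand.
#' @export
pwm_revcomp <- function(x) {
  rc <- x[4:1, rev(seq_len(ncol(x))), drop = FALSE]
  pwm(rc, name = attr(x, "name"))
}

#' PWM from an exact sequence
#'
#' Builds a probability-one PWM matching `seq` exactly.
#' @param seq a DNA string over A/C/G/T.
#' @param name motif name.
#' @export
pwm_from_sequence <- function(seq, name = seq) {
  bases <- strsplit(toupper(seq), "")[[1]]
  if (!all(bases %in% DNA_BASES)) stop("sequence must be over A/C/G/T")
  m <- matrix(0, 4, length(bases), dimnames = list(DNA_BASES, NULL))
  m[cbind(match(bases, DNA_BASES), seq_along(bases))] <- 1
  pwm(m, name = name)
}

#' Dinucleotide repeat motif PWMs
#'
#' The four 6 bp dinucleotide repeat motifs (DRMs) are modeled as invariant
#' PWMs with probability one for the repeat base at each position:
#' CACACA, GAGAGA, GCGCGC and TATATA. The GC and TA repeats are their own
#' reverse complements.
#'
#' @param repeat_unit one of `"CA"`, `"GA"`, `"GC"`, `"TA"`.
#' @param n_repeats number of repeat units (default 3, i.e. a 6 bp motif).
#' @return a `pwm` object.
#' @export
drm_pwm <- function(repeat_unit = c("CA", "GA", "GC", "TA"), n_repeats = 3) {
  repeat_unit <- match.arg(repeat_unit)
  seq <- paste(rep(repeat_unit, n_repeats), collapse = "")
  pwm_from_sequence(seq, name = paste0(repeat_unit, "-DRM"))
}

#' All four DRM PWMs as a named list
#' @param n_repeats number of repeat units per motif.
#' @export
drm_pwms <- function(n_repeats = 3) {
  units <- c("CA", "GA", "GC", "TA")
  stats::setNames(lapply(units, drm_pwm, n_repeats = n_repeats), units)
}

#' Log-odds score matrix of a PWM
#'
#' Scores are log2 odds of the regularized motif model against the background:
#' `score(i,b) = log2(p'(i,b) / background(b))` with
#' `p'(i,b) = (p(i,b) + pseudocount * background(b)) / (1 + pseudocount)`,
#' the background-proportional pseudocount convention. All entries are finite
#' for pseudocount > 0 and positive background.
#'
#' @param x a `pwm` object.
#' @param params a [scan_params()] object (background, pseudocount).
#' @return a 4 x L matrix of scores in bits, rows A,C,G,T.
#' @export
log_odds <- function(x, params = scan_params()) {
  bg <- params$background
  if (any(bg <= 0)) stop("background frequencies must all be positive")
  c0 <- params$pseudocount
  if (c0 <= 0) stop("pseudocount must be positive")
  p <- sweep(unclass(x), 1, c0 * bg, "+") / (1 + c0)
  log2(sweep(p, 1, bg, "/"))
}

#' Scan parameters
#'
#' Background nucleotide frequencies, pseudocount, match P-value cutoff and
#' strand handling for PWM scanning. The default background is the human
#' genomic composition (42% GC: A=T=0.29, C=G=0.21); the default pseudocount
#' is 0.001 and the default match cutoff is P < 1/1024, the calibration under
#' which all four perfect DRM words pass while inexact matches are minimized.
#'
#' @param background length-4 numeric (A,C,G,T) summing to 1, or a single GC
#'   fraction expanded as A=T=(1-gc)/2, C=G=gc/2.
#' @param pseudocount regularization weight added in proportion to background.
#' @param alpha match P-value cutoff; a window is a hit when the exact tail
#'   probability of its score under the background model is `< alpha`.
#' @param both_strands scan both strands?
#' @return an object of class `scan_params`.
#' @export
scan_params <- function(background = 0.42, pseudocount = 0.001,
                        alpha = 1 / 1024, both_strands = TRUE) {
  if (length(background) == 1) {
    gc <- background
    if (gc <= 0 || gc >= 1) stop("GC fraction must be in (0,1)")
    background <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  }
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9)
    stop("background must be 4 frequencies summing to 1")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  structure(list(background = stats::setNames(as.numeric(background), DNA_BASES),
                 pseudocount = pseudocount, alpha = alpha,
                 both_strands = isTRUE(both_strands)),
            class = "scan_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat("scan_params: bg(A,C,G,T) =", paste(signif(x$background, 4), collapse = ", "),
      "| pseudocount =", x$pseudocount, "| alpha =", signif(x$alpha, 6),
      "|", if (x$both_strands) "both strands" else "forward strand", "\n")
  invisible(x)
}

#' Read motifs from JASPAR-style PFM text
#'
#' Parses the JASPAR 2016 textual PFM format: a `>` header line per motif
#' followed by four rows `A [ n n ... ]` ... `T [ ... ]` of counts (bare
#' whitespace-separated rows without the base letter are also accepted, in
#' A,C,G,T order). Counts are normalized to probabilities per column.
#'
#' @param path file path.
#' @return named list of `pwm` objects.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no '>' motif headers found in ", path)
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    block <- lines[from:to]
    if (length(block) != 4) stop("motif block must have 4 base rows")
    rows <- lapply(block, function(ln) {
      ln <- gsub("^[ACGTacgt]", "", trimws(ln))
      ln <- gsub("[][]", " ", ln)
      as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])
    })
    counts <- do.call(rbind, rows)
    probs <- sweep(counts, 2, colSums(counts), "/")
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "[[:space:]]+")[[1]][1]
    out[[name]] <- pwm(probs, name = name)
  }
  out
}

#' Write motifs as JASPAR-style PFM text
#'
#' @param pwms list of `pwm` objects.
#' @param path output file.
#' @param scale counts scale (probabilities are multiplied by this integer).
#' @export
write_jaspar_pfm <- function(pwms, path, scale = 100) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", attr(p, "name")), con)
    m <- round(unclass(p) * scale)
    for (b in DNA_BASES)
      writeLines(sprintf("%s [ %s ]", b, paste(m[b, ], collapse = " ")), con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal format
#'
#' Parses the MEME minimal motif format (`MOTIF` name lines followed by a
#' `letter-probability matrix` block of L rows x 4 columns in A,C,G,T order).
#' @param path file path.
#' @return named list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  idx <- grep("^MOTIF", lines)
  if (length(idx) == 0) stop("no MOTIF records found in ", path)
  out <- list()
  for (i in seq_along(idx)) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[idx[i]])), "[[:space:]]+")[[1]][1]
    end <- if (i < length(idx)) idx[i + 1] - 1 else length(lines)
    block <- lines[idx[i]:end]
    hdr <- grep("letter-probability matrix", block)
    if (length(hdr) != 1) stop("motif ", name, ": missing letter-probability matrix")
    rows <- list()
    for (ln in block[-seq_len(hdr)]) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]]))
      if (length(v) != 4 || anyNA(v)) break
      rows[[length(rows) + 1]] <- v
    }
    probs <- t(do.call(rbind, rows))
    probs <- sweep(probs, 2, colSums(probs), "/")  # tolerate rounded rows
    out[[name]] <- pwm(probs, name = name)
  }
  out
}
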