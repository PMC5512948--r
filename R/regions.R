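# Genomic regions are plain data.frames with columns chrom, start, end, id
# (plus breadth for enhancer catalogs), in BED convention: 0-based,
# half-open. Interval overlap queries go through IRanges.

#' Construct a region table
#'
#' @param chrom chromosome names.
#' @param start 0-based inclusive start coordinates.
#' @param end exclusive end coordinates.
#' @param id region identifiers (defaults to `region_1`, ...).
#' @param breadth optional activity-breadth integers (>= 1), the number of
#'   cellular contexts in which each enhancer is active.
#' @return data.frame of class `broadscan_regions`.
#' @export
regions <- function(chrom, start, end, id = NULL, breadth = NULL) {
  if (is.null(id)) id <- paste0("region_", seq_along(chrom))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0)) stop("start coordinates must be >= 0")
  if (any(end <= start)) stop("end must exceed start (0-based half-open)")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   id = as.character(id), stringsAsFactors = FALSE)
  if (!is.null(breadth)) {
    breadth <- as.integer(breadth)
    if (any(breadth < 1)) stop("breadth must be >= 1")
    df$breadth <- breadth
  }
  class(df) <- c("broadscan_regions", "data.frame")
  df
}

as_regions <- function(df) {
  regions(df$chrom, df$start, df$end, df$id, df$breadth)
}

region_lengths <- function(regions) regions$end - regions$start

regions_to_iranges <- function(r) {
  # 1-based closed for IRanges; names carry the chromosome for per-chrom work
  IRanges::IRanges(start = r$start + 1L, end = r$end)
}

#' Count overlaps between two region sets
#'
#' Overlap is >= 1 bp, per chromosome. Used for exclusion-list screening.
#' @param query,subject region data.frames.
#' @return integer vector: overlaps in `subject` per row of `query`.
#' @export
count_region_overlaps <- function(query, subject) {
  hits <- integer(nrow(query))
  if (nrow(subject) == 0 || nrow(query) == 0) return(hits)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (length(si) == 0) next
    hits[qi] <- IRanges::countOverlaps(
      regions_to_iranges(query[qi, , drop = FALSE]),
      regions_to_iranges(subject[si, , drop = FALSE]))
  }
  hits
}

#' Read / write BED region files
#'
#' BED convention: 0-based half-open, tab-separated, no header. Column 4 is
#' the region id; column 5, when present, carries the activity-breadth
#' integer. Writing a sorted table and re-reading it round-trips exactly.
#'
#' @param path file path.
#' @return for `read_bed`, a region data.frame.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  regions(df[[1]], df[[2]], df[[3]],
          id = if (ncol(df) >= 4) df[[4]] else NULL,
          breadth = if (ncol(df) >= 5) df[[5]] else NULL)
}

#' @rdname read_bed
#' @param regions region data.frame.
#' @export
write_bed <- function(regions, path) {
  cols <- intersect(c("chrom", "start", "end", "id", "breadth"),
                    names(regions))
  utils::write.table(regions[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract region sequences from a genome
#'
#' @param regions region data.frame.
#' @param genome named Biostrings `DNAStringSet` or named character vector.
#' @return character vector of sequences, named by region id.
#' @export
region_sequences <- function(regions, genome) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (!all(regions$chrom %in% names(genome)))
    stop("regions reference chromosomes absent from the genome")
  if (any(regions$end > lens[regions$chrom]))
    stop("regions extend beyond chromosome ends")
  seqs <- as.character(Biostrings::subseq(genome[regions$chrom],
                                          start = regions$start + 1L,
                                          end = regions$end))
  stats::setNames(seqs, regions$id)
}

#' GC content and CpG rate of sequences
#'
#' `gc_content` is (#G + #C) / (#unambiguous bases); `cpg_per_bp` is the
#' number of CG dinucleotides divided by (length - 1). All-ambiguous
#' sequences return `NA`.
#'
#' @param x character vector of DNA sequences (or `DNAStringSet`).
#' @return numeric vector.
#' @export
gc_content <- function(x) {
  if (!inherits(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  f <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  tot <- rowSums(f)
  out <- (f[, "C"] + f[, "G"]) / tot
  out[tot == 0] <- NA_real_
  unname(out)
}

#' @rdname gc_content
#' @export
cpg_per_bp <- function(x) {
  if (!inherits(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  w <- Biostrings::width(x)
  if (any(w < 2)) stop("CpG rate needs sequences of length >= 2")
  cg <- Biostrings::vcountPattern("CG", x)
  unname(cg / (w - 1))
}

#' Resize regions to a fixed length about their centers
#'
#' Every region is expanded or contracted to `target_len` while keeping its
#' original center `(start + end) %/% 2`; with an odd remainder the extra
#' base goes rightward (`start = center - floor(L/2)`). Regions whose
#' resized window would leave the chromosome are an error by default, or
#' clipped to the chromosome with a warning when `on_oob = "clip"` (clipped
#' regions are then shorter than `target_len`).
#'
#' @param regions region data.frame.
#' @param target_len target length in bp (>= 1).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param on_oob `"error"` or `"clip"` for out-of-bounds resized windows.
#' @return resized region data.frame (breadth carried through).
#' @export
resize_centered <- function(regions, target_len = 600, chrom_lengths,
                            on_oob = c("error", "clip")) {
  on_oob <- match.arg(on_oob)
  if (target_len < 1) stop("target_len must be >= 1")
  center <- (regions$start + regions$end) %/% 2L
  start <- center - target_len %/% 2L
  end <- start + as.integer(target_len)
  lim <- unname(chrom_lengths[regions$chrom])
  oob <- start < 0L | end > lim
  if (any(oob)) {
    if (on_oob == "error")
      stop(sum(oob), " resized region(s) exceed chromosome bounds (",
           paste(utils::head(regions$id[oob], 3), collapse = ", "), " ...)")
    warning(sum(oob), " resized region(s) clipped to chromosome bounds")
    start <- pmax(start, 0L)
    end <- pmin(end, lim)
  }
  out <- regions
  out$start <- start
  out$end <- end
  as_regions(out)
}

#' Split an enhancer catalog into broad and narrow classes
#'
#' The broad set contains the top `top_frac` of the catalog by breadth of
#' activity, using a strict-inequality cutoff: the breadth boundary `b` is
#' the smallest value such that at most `top_frac * n` records have breadth
#' strictly greater than `b` (mirroring "active in more than 45 contexts").
#' The narrow set is a uniform random sample of records with
#' `breadth == narrow_breadth`, sized to match the broad set. The output is
#' invariant to the input row order for a fixed seed.
#'
#' @param catalog region data.frame with a `breadth` column.
#' @param top_frac fraction in (0,1) defining the broad class (default 0.05).
#' @param narrow_breadth breadth value defining narrow candidates (default 1).
#' @param seed integer seed for the narrow-set sampling.
#' @return list with elements `broad`, `narrow` (region data.frames) and
#'   `cutoff` (the breadth boundary; broad means breadth > cutoff).
#' @export
split_by_breadth <- function(catalog, top_frac = 0.05, narrow_breadth = 1L,
                             seed = 1L) {
  if (nrow(catalog) == 0) stop("catalog is empty")
  if (top_frac <= 0 || top_frac >= 1) stop("top_frac must be in (0,1)")
  ord <- order(catalog$id)  # order-invariance for a fixed seed
  catalog <- catalog[ord, , drop = FALSE]
  n <- nrow(catalog)
  tab <- sort(unique(catalog$breadth))
  n_above <- vapply(tab, function(b) sum(catalog$breadth > b), integer(1))
  cand <- tab[n_above <= top_frac * n]
  if (length(cand) == 0) stop("no breadth cutoff leaves <= top_frac of records")
  cutoff <- min(cand)
  broad <- catalog[catalog$breadth > cutoff, , drop = FALSE]
  if (nrow(broad) == 0) stop("broad set is empty at cutoff ", cutoff)
  narrow_pool <- catalog[catalog$breadth == narrow_breadth, , drop = FALSE]
  if (nrow(narrow_pool) < nrow(broad))
    stop("only ", nrow(narrow_pool), " narrow candidates for a broad set of ",
         nrow(broad))
  set.seed(seed)
  pick <- sample(nrow(narrow_pool), nrow(broad))
  narrow <- narrow_pool[sort(pick), , drop = FALSE]
  list(broad = as_regions(broad), narrow = as_regions(narrow),
       cutoff = cutoff)
}

sample_positions <- function(chrom_lengths, len, n) {
  # uniform over all feasible (chrom, start): chromosome weighted by slots
  slots <- pmax(chrom_lengths - len + 1, 0)
  if (sum(slots) == 0) return(NULL)
  ch <- sample(names(chrom_lengths), n, replace = TRUE, prob = slots)
  st <- floor(stats::runif(n) * slots[ch])
  data.frame(chrom = ch, start = as.integer(st), stringsAsFactors = FALSE)
}

#' Length-matched random background regions
#'
#' Places, for each input region, a random region of the same length,
#' uniformly among feasible genome positions, avoiding a set of exclusion
#' intervals and previously placed outputs (strict >= 1 bp non-overlap). By
#' default placement is unconstrained across chromosomes; `same_chrom = TRUE`
#' keeps each region on its source chromosome.
#'
#' @param regions region data.frame to match.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param exclusions region data.frame of intervals the output must avoid
#'   (e.g. the positive set plus all known enhancers).
#' @param seed integer seed.
#' @param same_chrom keep each shuffled region on its own chromosome?
#' @param max_tries rejection-sampling cap per region.
#' @return region data.frame of shuffled regions (ids suffixed `_shuf`).
#' @export
shuffle_length_matched <- function(regions, chrom_lengths,
                                   exclusions = NULL, seed = 1L,
                                   same_chrom = FALSE, max_tries = 10000) {
  set.seed(seed)
  if (is.null(exclusions))
    exclusions <- regions("chr_none", 0, 1)[0, , drop = FALSE]
  placed <- vector("list", nrow(regions))
  lens <- region_lengths(regions)
  occupied <- exclusions
  for (i in seq_len(nrow(regions))) {
    len <- lens[i]
    cl <- if (same_chrom) chrom_lengths[regions$chrom[i]] else chrom_lengths
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      pos <- sample_positions(cl, len, 1)
      if (is.null(pos)) break
      cand <- regions(pos$chrom, pos$start, pos$start + len,
                      id = paste0(regions$id[i], "_shuf"))
      if (count_region_overlaps(cand, occupied) == 0) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place a length-", len, " region for '", regions$id[i],
           "' within ", max_tries, " tries")
    placed[[i]] <- cand
    occupied <- rbind(occupied[, c("chrom", "start", "end", "id")],
                      cand[, c("chrom", "start", "end", "id")])
  }
  as_regions(do.call(rbind, placed))
}

#' GC-matched random background regions
#'
#' For each input region, samples a region on the same chromosome with the
#' same length whose GC content is within `gc_tolerance` of the input's,
#' avoiding exclusion intervals, by rejection sampling. Per-region failures
#' after `max_tries` draws are collected; the run aborts if more than
#' `max_fail_frac` of regions fail.
#'
#' @param regions region data.frame to match.
#' @param genome named `DNAStringSet`.
#' @param exclusions region data.frame to avoid (may be NULL).
#' @param gc_tolerance maximum |GC(out) - GC(in)| (default 0.02).
#' @param seed integer seed.
#' @param max_tries rejection cap per region (default 10000).
#' @param max_fail_frac abort when more than this fraction of regions fail.
#' @return region data.frame (ids suffixed `_gcm`); failed region ids are
#'   attached as attribute `failed`.
#' @export
sample_gc_matched <- function(regions, genome, exclusions = NULL,
                              gc_tolerance = 0.02, seed = 1L,
                              max_tries = 10000, max_fail_frac = 0.01) {
  if (gc_tolerance <= 0) stop("gc_tolerance must be > 0")
  set.seed(seed)
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  if (is.null(exclusions))
    exclusions <- regions("chr_none", 0, 1)[0, , drop = FALSE]
  # cumulative GC / unambiguous-base counts per chromosome: window GC in O(1)
  gc_cum <- lapply(as.character(genome), function(s) {
    ch <- strsplit(s, "")[[1]]
    list(gc = c(0, cumsum(ch %in% c("G", "C"))),
         ok = c(0, cumsum(ch %in% DNA_BASES)))
  })
  window_gc <- function(ch, st, len) {
    cs <- gc_cum[[ch]]
    nok <- cs$ok[st + len + 1] - cs$ok[st + 1]
    if (nok == 0) return(NA_real_)
    (cs$gc[st + len + 1] - cs$gc[st + 1]) / nok
  }
  target_gc <- gc_content(region_sequences(regions, genome))
  placed <- vector("list", nrow(regions))
  failed <- character(0)
  occupied <- exclusions
  for (i in seq_len(nrow(regions))) {
    len <- region_lengths(regions)[i]
    ch <- regions$chrom[i]
    nslots <- chrom_lengths[[ch]] - len + 1
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      st <- floor(stats::runif(1) * nslots)
      gc <- window_gc(ch, st, len)
      if (is.na(gc) || abs(gc - target_gc[i]) > gc_tolerance) next
      cand <- regions(ch, st, st + len, id = paste0(regions$id[i], "_gcm"))
      if (count_region_overlaps(cand, occupied) > 0) next
      ok <- TRUE
      break
    }
    if (ok) {
      placed[[i]] <- cand
      occupied <- rbind(occupied[, c("chrom", "start", "end", "id")],
                        cand[, c("chrom", "start", "end", "id")])
    } else {
      failed <- c(failed, regions$id[i])
    }
  }
  if (length(failed) > max_fail_frac * nrow(regions))
    stop(length(failed), " of ", nrow(regions),
         " regions could not be GC-matched within tolerance ", gc_tolerance)
  out <- as_regions(do.call(rbind, placed[!vapply(placed, is.null, logical(1))]))
  attr(out, "failed") <- failed
  out
}
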