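# Synthetic enhancer catalogs with known planted structure.
#
# One global seed drives every stage; each stage reseeds at a fixed offset
# from it, so stages are independently reproducible and the whole catalog is
# bit-identical for identical (config, seed).

STAGE_OFFSET <- c(genome = 101L, enhancers = 202L, gc = 303L,
                  plant = 404L, tf = 505L)

stage_seed <- function(config, stage) {
  (config$seed + STAGE_OFFSET[[stage]]) %% .Machine$integer.max
}

#' Simulation configuration
#'
#' Parameters of the synthetic enhancer-catalog generator. Defaults emulate
#' the structure of the CAGE-defined human enhancer catalog the pipeline is
#' designed for: a 42% GC background genome; a breadth-of-activity
#' distribution with 15% of enhancers active in a single context and a
#' geometric tail over 2..60 contexts calibrated so the top 5% of enhancers
#' are active in more than 45 contexts; positive length-breadth and
#' GC-breadth couplings; and a GC dinucleotide-repeat motif planted rare
#' (most enhancers carry none, as observed for DRMs in real catalogs) but
#' at a 4:1 broad:narrow per-bp density ratio.
#'
#' @param seed integer master seed.
#' @param n_chromosomes,chrom_length genome shape (bp).
#' @param background_gc genomic GC fraction in (0,1).
#' @param n_enhancers catalog size.
#' @param breadth_distribution numeric vector of proportions named by
#'   breadth value, summing to 1; `NULL` uses the calibrated default above.
#' @param base_length,length_breadth_slope,length_noise_sd,min_length
#'   enhancer length model: `base + slope * (breadth - 1) + N(0, sd)` bp,
#'   truncated below at `min_length`.
#' @param gc_breadth_slope per-context GC shift: an enhancer of breadth b is
#'   resampled at GC `background_gc + slope * (b - 1)`.
#' @param planted_motifs list of planting specs, each
#'   `list(seq =, density_narrow =, density_broad =)` with per-bp densities
#'   for breadth 1 and for the broad cutoff; density interpolates linearly in
#'   breadth between them and is clamped beyond.
#' @param broad_cutoff breadth above which an enhancer is "broad" (default
#'   45, i.e. broad means active in more than 45 of the possible contexts).
#' @param n_tfs,tf_broad_frac TF table size and fraction of broadly
#'   expressed TFs (defaults 563 and 313/563).
#' @param tf_gc_mean,tsps_gc_association TF motif GC model: broad-TF motifs
#'   target mean GC `tf_gc_mean + association/2`, specific-TF motifs
#'   `tf_gc_mean - association/2` (defaults give 51% vs 40%); an association
#'   of 0 is the null configuration.
#' @param tf_gc_sd between-TF spread of target motif GC.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 4L,
                              chrom_length = 2e6,
                              background_gc = 0.42,
                              n_enhancers = 5000L,
                              breadth_distribution = NULL,
                              base_length = 200,
                              length_breadth_slope = 2,
                              length_noise_sd = 40,
                              min_length = 50,
                              gc_breadth_slope = 0.001,
                              planted_motifs = list(
                                list(seq = "GCGCGC",
                                     density_narrow = 0.0002,
                                     density_broad = 0.0008)),
                              broad_cutoff = 45L,
                              n_tfs = 563L,
                              tf_broad_frac = 313 / 563,
                              tf_gc_mean = 0.455,
                              tsps_gc_association = 0.11,
                              tf_gc_sd = 0.08) {
  if (chrom_length <= 0) stop("chrom_length must be positive")
  if (background_gc <= 0 || background_gc > 1)
    stop("background_gc must be in (0,1]")
  if (is.null(breadth_distribution))
    breadth_distribution <- default_breadth_distribution()
  if (abs(sum(breadth_distribution) - 1) > 1e-9)
    stop("breadth_distribution proportions must sum to 1")
  for (pm in planted_motifs)
    if (pm$density_narrow < 0 || pm$density_broad < 0)
      stop("planted motif densities must be >= 0")
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

#' Default breadth-of-activity distribution
#'
#' 15% of the mass at breadth 1, and a geometric decay over breadths 2..60
#' with the decay rate calibrated (by root finding) so that the top 5% of
#' enhancers lie above breadth 45. The true breadth distribution of the real
#' catalog is not published beyond these two anchors; the geometric tail is
#' a modeling choice.
#'
#' @param p_single mass at breadth 1.
#' @param max_breadth largest breadth value.
#' @param top_frac mass above `cutoff`.
#' @param cutoff breadth boundary of the broad class.
#' @return named numeric vector of proportions summing to 1.
#' @export
default_breadth_distribution <- function(p_single = 0.15, max_breadth = 60L,
                                         top_frac = 0.05, cutoff = 45L) {
  b <- 2:max_breadth
  tail_frac <- function(q) {
    w <- q^(b - 2)
    sum(w[b > cutoff]) / sum(w) - top_frac / (1 - p_single)
  }
  q <- stats::uniroot(tail_frac, c(0.5, 0.999999), tol = 1e-12)$root
  w <- q^(b - 2)
  probs <- c(p_single, (1 - p_single) * w / sum(w))
  stats::setNames(probs, c(1L, b))
}

#' Simulate a background genome
#'
#' I.i.d. nucleotides with `P(G) = P(C) = background_gc / 2` and
#' `P(A) = P(T) = (1 - background_gc) / 2`, deterministic given the config
#' seed.
#'
#' @param config a [simulation_config()].
#' @return named `DNAStringSet` of `n_chromosomes` chromosomes.
#' @export
simulate_genome <- function(config) {
  set.seed(stage_seed(config, "genome"))
  gc <- config$background_gc
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
    paste(sample(DNA_BASES, config$chrom_length, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0("chr", seq_len(config$n_chromosomes))
  out
}

random_dna <- function(n, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = probs)
}

planting_density <- function(pm, breadth, broad_cutoff) {
  f <- pmin(pmax((breadth - 1) / (broad_cutoff + 1 - 1), 0), 1)
  pm$density_narrow + f * (pm$density_broad - pm$density_narrow)
}

#' Simulate an enhancer catalog on a genome
#'
#' Draws breadth values from the configured distribution, lengths increasing
#' with breadth, and places non-overlapping enhancer intervals uniformly on
#' the genome. Each enhancer's sequence is then locally resampled at
#' `background_gc + gc_breadth_slope * (breadth - 1)` (so the GC-breadth
#' coupling is separable from motif planting), and planted motifs are
#' written over background bases (no insertions) at per-bp densities
#' interpolated between the narrow and broad class densities, without
#' overlapping or abutting one another (a 1 bp separation keeps planted
#' repeat sites from fusing into longer runs; rejection sampling, capped
#' retries).
#'
#' @param config a [simulation_config()].
#' @param genome optional genome from [simulate_genome()]; generated from
#'   the config when missing.
#' @return list of class `synthetic_catalog`: `genome` (with enhancer loci
#'   rewritten), `enhancers` (region data.frame with breadth), `truth`
#'   (planted-motif positions: chrom, start, end, motif, enhancer id) and
#'   `config`.
#' @export
simulate_enhancers <- function(config, genome = NULL) {
  if (is.null(genome)) genome <- simulate_genome(config)
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))

  set.seed(stage_seed(config, "enhancers"))
  n <- config$n_enhancers
  bvals <- as.integer(names(config$breadth_distribution))
  breadth <- sample(bvals, n, replace = TRUE,
                    prob = config$breadth_distribution)
  max_motif <- max(c(1, vapply(config$planted_motifs,
                               function(pm) nchar(pm$seq), numeric(1))))
  lens <- round(config$base_length +
                  config$length_breadth_slope * (breadth - 1) +
                  stats::rnorm(n, 0, config$length_noise_sd))
  lens <- pmax(lens, max(config$min_length, max_motif))
  if (max(lens) > min(chrom_lengths))
    stop("chrom_length smaller than the longest enhancer")

  ch_out <- character(n)
  st_out <- integer(n)
  occupied <- lapply(chrom_lengths, function(x) logical(x))
  chroms <- names(chrom_lengths)
  for (i in order(lens, decreasing = TRUE)) {
    ok <- FALSE
    for (try in 1:10000) {
      ch <- sample(chroms, 1, prob = chrom_lengths - lens[i] + 1)
      st <- floor(stats::runif(1) * (chrom_lengths[[ch]] - lens[i] + 1))
      span <- (st + 1):(st + lens[i])
      if (!any(occupied[[ch]][span])) {
        occupied[[ch]][span] <- TRUE
        ch_out[i] <- ch
        st_out[i] <- st
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("enhancer placement failed: genome too crowded")
  }
  enh <- regions(ch_out, st_out, st_out + lens,
                 id = sprintf("enh_%05d", seq_len(n)), breadth = breadth)

  # per-region GC resampling
  set.seed(stage_seed(config, "gc"))
  chars <- lapply(as.character(genome), function(s) strsplit(s, "")[[1]])
  target_gc <- pmin(pmax(config$background_gc +
                           config$gc_breadth_slope * (breadth - 1),
                         0.01), 0.99)
  for (i in seq_len(n)) {
    idx <- (enh$start[i] + 1):enh$end[i]
    chars[[enh$chrom[i]]][idx] <- random_dna(length(idx), target_gc[i])
  }

  # motif planting: overwrite bases in place, motifs non-overlapping
  set.seed(stage_seed(config, "plant"))
  truth <- list()
  for (i in seq_len(n)) {
    len <- enh$end[i] - enh$start[i]
    taken <- logical(len)
    for (pm in config$planted_motifs) {
      L <- nchar(pm$seq)
      if (L > len) next
      dens <- planting_density(pm, breadth[i], config$broad_cutoff)
      k <- stats::rpois(1, dens * len)
      for (m in seq_len(k)) {
        done <- FALSE
        for (try in 1:1000) {
          off <- sample.int(len - L + 1, 1) - 1L
          # reserve a 1 bp margin so planted sites never abut: two abutting
          # repeat motifs would fuse into a longer run and create scan
          # matches beyond the sites recorded in the truth table
          span <- max(off, 1):min(off + L + 1, len)
          if (!any(taken[span])) {
            taken[span] <- TRUE
            gstart <- enh$start[i] + off
            chars[[enh$chrom[i]]][(gstart + 1):(gstart + L)] <-
              strsplit(pm$seq, "")[[1]]
            truth[[length(truth) + 1]] <- data.frame(
              chrom = enh$chrom[i], start = gstart, end = gstart + L,
              motif = pm$seq, id = enh$id[i], stringsAsFactors = FALSE)
            done <- TRUE
            break
          }
        }
        if (!done)
          stop("motif planting infeasible for '", pm$seq, "' in ", enh$id[i],
               ": density too high for non-overlapping placement")
      }
    }
  }
  genome_out <- Biostrings::DNAStringSet(
    vapply(chars, paste, character(1), collapse = ""))
  names(genome_out) <- names(genome)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               motif = character(), id = character(), stringsAsFactors = FALSE)
  structure(list(genome = genome_out, enhancers = enh, truth = truth,
                 config = config),
            class = "synthetic_catalog")
}

#' @export
print.synthetic_catalog <- function(x, ...) {
  cat("synthetic catalog:", nrow(x$enhancers), "enhancers on",
      length(x$genome), "chromosomes (",
      sum(Biostrings::width(x$genome)), "bp );",
      nrow(x$truth), "planted motif sites\n")
  invisible(x)
}

#' Simulate a TF motif / tissue-specificity table
#'
#' Generates `n_tfs` transcription factors, each broadly expressed (tissue
#' specificity score TSPS < 1) with probability `tf_broad_frac` or
#' context-specific (TSPS >= 1) otherwise, together with 1-3 PWMs per TF.
#' Motif GC content targets differ between the groups by
#' `tsps_gc_association` (broad higher for a positive association; 0 gives
#' the null configuration with no group difference).
#'
#' @param config a [simulation_config()].
#' @return list: `table` (data.frame tf_name, tsps, motif_ids), `pwms`
#'   (named list of [pwm()] objects).
#' @export
simulate_tf_table <- function(config) {
  if (config$n_tfs < 2) stop("n_tfs must be >= 2")
  set.seed(stage_seed(config, "tf"))
  n <- config$n_tfs
  broad <- stats::runif(n) < config$tf_broad_frac
  tsps <- ifelse(broad, stats::runif(n, 0, 1), stats::runif(n, 1, 5))
  target <- config$tf_gc_mean +
    ifelse(broad, 1, -1) * config$tsps_gc_association / 2 +
    stats::rnorm(n, 0, config$tf_gc_sd)
  target <- pmin(pmax(target, 0.05), 0.95)
  pwms <- list()
  motif_ids <- character(n)
  for (i in seq_len(n)) {
    k <- sample(1:3, 1)
    ids <- sprintf("M%04d_%d", i, seq_len(k))
    for (j in seq_len(k)) {
      L <- sample(8:12, 1)
      gc_i <- pmin(pmax(target[i] + stats::rnorm(L, 0, 0.05), 0.01), 0.99)
      cols <- vapply(gc_i, function(g) {
        cons <- sample(c("S", "W"), 1, prob = c(g, 1 - g))  # GC vs AT consensus
        spread <- c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2) * 0.4
        pick <- if (cons == "S") sample(c(2, 3), 1) else sample(c(1, 4), 1)
        spread[pick] <- spread[pick] + 0.6
        spread / sum(spread)
      }, numeric(4))
      pwms[[ids[j]]] <- pwm(cols, name = ids[j])
    }
    motif_ids[i] <- paste(ids, collapse = ",")
  }
  table <- data.frame(tf_name = sprintf("TF%04d", seq_len(n)), tsps = tsps,
                      motif_ids = motif_ids, stringsAsFactors = FALSE)
  list(table = table, pwms = pwms)
}

#' Simulate per-TF composition with a known semipartial CpG effect
#'
#' Generates TF records (tsps-like continuous response, mean motif GC and
#' CpG) in which GC explains `r2_gc` of the response variance and the
#' component of CpG orthogonal to GC explains a further `sr2_cpg` — the
#' planted squared semipartial correlation that
#' [semipartial_cpg_given_gc()] should recover.
#'
#' @param n number of TFs.
#' @param r2_gc variance share of GC.
#' @param sr2_cpg planted squared semipartial correlation of CpG given GC.
#' @param gc_cpg_cor correlation between GC and CpG.
#' @param seed integer seed.
#' @return data.frame with columns `tf_name`, `tsps`, `mean_gc`, `mean_cpg`.
#' @export
simulate_tf_composition <- function(n = 500, r2_gc = 0.2, sr2_cpg = 0.1,
                                    gc_cpg_cor = 0.6, seed = 1L) {
  if (r2_gc + sr2_cpg >= 1) stop("r2_gc + sr2_cpg must be < 1")
  set.seed(seed)
  g <- stats::rnorm(n)
  u <- stats::rnorm(n)  # CpG component orthogonal to GC
  y <- sqrt(r2_gc) * g + sqrt(sr2_cpg) * u +
    stats::rnorm(n, 0, sqrt(1 - r2_gc - sr2_cpg))
  data.frame(tf_name = sprintf("TF%04d", seq_len(n)),
             tsps = y - min(y),  # shift to the nonnegative TSPS scale
             mean_gc = 0.45 + 0.08 * g,
             mean_cpg = 0.04 + 0.015 * (gc_cpg_cor * g +
                                          sqrt(1 - gc_cpg_cor^2) * u),
             stringsAsFactors = FALSE)
}

#' Write / read a TF table (TSV: tf_name, tsps, motif_ids)
#' @param table data.frame as produced by [simulate_tf_table()].
#' @param path file path.
#' @export
write_tf_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tf_table
#' @export
read_tf_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
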