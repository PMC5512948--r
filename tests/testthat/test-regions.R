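test_that("region construction enforces 0-based half-open invariants", {
  expect_error(regions("chr1", -1, 5), ">= 0")
  expect_error(regions("chr1", 5, 5), "exceed")
  expect_error(regions("chr1", 0, 10, breadth = 0), "breadth")
  r <- regions("chr1", 0, 10, id = "a", breadth = 3)
  expect_equal(r$end - r$start, 10)
})

test_that("BED round-trip is byte-stable for sorted input", {
  r <- regions(c("chr1", "chr1", "chr2"), c(0, 500, 10),
               c(300, 1100, 600), id = c("e1", "e2", "e3"),
               breadth = c(1, 46, 12))
  p1 <- withr::local_tempfile(fileext = ".bed")
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(r, p1)
  back <- read_bed(p1)
  expect_equal(as.data.frame(back), as.data.frame(r))
  write_bed(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("centered resize preserves centers with the rightward rounding rule", {
  cl <- c(chr1 = 100000)
  # length-600 region is unchanged
  r <- resize_centered(regions("chr1", 1000, 1600), 600, cl)
  expect_equal(c(r$start, r$end), c(1000, 1600))
  # length-297 (the CAGE mean) becomes exactly 600
  r <- resize_centered(regions("chr1", 1000, 1297), 600, cl)
  expect_equal(r$end - r$start, 600)
  expect_equal(r$start, (1000 + 1297) %/% 2 - 300)
  # odd target length: extra base rightward of the center
  r <- resize_centered(regions("chr1", 100, 200), 5, cl)
  expect_equal(c(r$start, r$end), c(150 - 2, 150 + 3))
  # out-of-bounds: error by default, clip on request
  expect_error(resize_centered(regions("chr1", 100, 400), 600, cl), "bounds")
  expect_warning(
    rc <- resize_centered(regions("chr1", 100, 400), 600, cl, on_oob = "clip"),
    "clipped")
  expect_equal(rc$start, 0)
})

test_that("split_by_breadth matches a sort-and-slice oracle and is order-invariant", {
  set.seed(21)
  n <- 1000
  breadth <- sample(c(1L, sample(1:60, n - 1, replace = TRUE,
                                 prob = 0.85^(1:60))))
  cat <- regions(rep("chr1", n), seq(0, by = 700, length.out = n),
                 seq(600, by = 700, length.out = n), breadth = breadth)
  sp <- split_by_breadth(cat, top_frac = 0.05, seed = 7)
  # strict-inequality cutoff oracle
  cuts <- sort(unique(breadth))
  oracle_cut <- min(cuts[vapply(cuts, function(b) sum(breadth > b),
                                numeric(1)) <= 0.05 * n])
  expect_equal(sp$cutoff, oracle_cut)
  expect_true(all(sp$broad$breadth > oracle_cut))
  expect_true(all(sp$narrow$breadth == 1))
  expect_equal(nrow(sp$broad), nrow(sp$narrow))
  expect_length(intersect(sp$broad$id, sp$narrow$id), 0)
  # invariance to input order at the same seed
  sp2 <- split_by_breadth(cat[sample(n), ], top_frac = 0.05, seed = 7)
  expect_equal(sort(sp2$broad$id), sort(sp$broad$id))
  expect_equal(sort(sp2$narrow$id), sort(sp$narrow$id))
})

test_that("split_by_breadth degenerate and infeasible cases error cleanly", {
  allsame <- regions(rep("chr1", 10), 0:9 * 100, 0:9 * 100 + 50,
                     breadth = rep(5L, 10))
  # all breadths equal: no value has anything strictly above it, so the
  # cutoff is that breadth and the broad set is empty
  expect_error(split_by_breadth(allsame, 0.05), "empty")
  few_narrow <- regions(rep("chr1", 10), 0:9 * 100, 0:9 * 100 + 50,
                        breadth = c(rep(50L, 4), rep(10L, 5), 1L))
  expect_error(split_by_breadth(few_narrow, top_frac = 0.5), "narrow")
})

test_that("length-matched shuffling conserves lengths and avoids exclusions", {
  g <- tiny_genome(seed = 5, n_chrom = 2, len = 20000)
  cl <- stats::setNames(Biostrings::width(g), names(g))
  r <- regions(c("chr1", "chr1", "chr2"), c(100, 5000, 300),
               c(700, 5900, 1500), id = c("a", "b", "c"))
  excl <- regions(c("chr1", "chr2"), c(0, 0), c(3000, 10000))
  out <- shuffle_length_matched(r, cl, exclusions = excl, seed = 3)
  expect_equal(sort(out$end - out$start), sort(r$end - r$start))
  expect_equal(sum(count_region_overlaps(out, excl)), 0)
  expect_equal(sum(count_region_overlaps(out, out)), nrow(out))  # self only
  # determinism
  out2 <- shuffle_length_matched(r, cl, exclusions = excl, seed = 3)
  expect_identical(as.data.frame(out), as.data.frame(out2))
})

test_that("shuffling into a single feasible slot finds it", {
  cl <- c(chr1 = 1000)
  # exclusions leave exactly [400, 500) free
  excl <- regions(c("chr1", "chr1"), c(0, 500), c(400, 1000))
  r <- regions("chr1", 0, 100, id = "x")
  out <- shuffle_length_matched(r, cl, exclusions = excl, seed = 1)
  expect_equal(c(out$start, out$end), c(400, 500))
  # and an infeasible request fails with the length named
  r2 <- regions("chr1", 0, 200, id = "y")
  expect_error(shuffle_length_matched(r2, cl, exclusions = excl, seed = 1,
                                      max_tries = 200), "200")
})

test_that("uniform placement: single region start is uniform over free slots", {
  cl <- c(chr1 = 1000)
  r <- regions("chr1", 0, 100, id = "u")
  starts <- vapply(1:400, function(s) {
    shuffle_length_matched(r, cl, seed = s)$start
  }, numeric(1))
  # starts live on [0, 900]; chi-square over 5 equal bins
  expect_true(all(starts >= 0 & starts <= 900))
  ct <- table(cut(starts, breaks = seq(-0.5, 900.5, length.out = 6)))
  p <- stats::chisq.test(ct)$p.value
  expect_gt(p, 0.001)
})

test_that("GC-matched sampling honors tolerance, chromosome and exclusions", {
  g <- tiny_genome(seed = 9, n_chrom = 2, len = 30000)
  set.seed(2)
  starts <- sample(0:29000, 20)
  r <- regions(sample(c("chr1", "chr2"), 20, replace = TRUE), starts,
               starts + 300, id = sprintf("r%02d", 1:20))
  out <- sample_gc_matched(r, g, exclusions = r, gc_tolerance = 0.02,
                           seed = 4)
  expect_equal(nrow(out), 20)
  expect_equal(out$chrom, r$chrom)  # paired chromosome identity
  expect_equal(out$end - out$start, r$end - r$start)
  gc_in <- gc_content(region_sequences(r, g))
  gc_out <- gc_content(region_sequences(out, g))
  expect_true(all(abs(gc_in - gc_out) <= 0.02 + 1e-12))
  expect_equal(sum(count_region_overlaps(out, r)), 0)
})

test_that("GC-matching an impossible target exercises the failure path", {
  g <- tiny_genome(seed = 1, n_chrom = 1, len = 5000, gc = 0.42)
  # write an all-G region into the genome and ask for its match
  s <- as.character(g[[1]])
  substr(s, 1001, 1300) <- strrep("G", 300)
  g <- Biostrings::DNAStringSet(c(chr1 = s))
  r <- regions("chr1", 1000, 1300, id = "allG")
  expect_error(sample_gc_matched(r, g, exclusions = r, gc_tolerance = 0.02,
                                 seed = 1, max_tries = 300), "GC-matched")
})

test_that("GC-matched negatives are distributionally null against positives", {
  g <- tiny_genome(seed = 77, n_chrom = 2, len = 40000)
  set.seed(5)
  starts <- sample(0:39000, 60)
  r <- regions(sample(c("chr1", "chr2"), 60, replace = TRUE), starts,
               starts + 400, id = sprintf("p%02d", 1:60))
  hits <- 0
  for (s in 1:20) {
    out <- sample_gc_matched(r, g, gc_tolerance = 0.02, seed = s)
    p <- stats::wilcox.test(gc_content(region_sequences(r, g)),
                            gc_content(region_sequences(out, g)))$p.value
    if (p > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)  # ~null design: >= 90% of seeds non-significant
})

test_that("gc_content and cpg_per_bp follow their definitions", {
  expect_equal(gc_content("GCGC"), 1.0)
  expect_equal(cpg_per_bp("GCGC"), 1 / 3)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(cpg_per_bp("ATAT"), 0.0)
  expect_true(is.na(gc_content("NNNN")))
  # ambiguous bases are excluded from the GC denominator
  expect_equal(gc_content("GCNN"), 1.0)
  set.seed(8)
  s <- random_dna_string(10000, gc = 0.42)
  expect_equal(gc_content(s), 0.42, tolerance = 0.02)
})
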