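test_that("BED round trip preserves a random interval set", {
  pk <- random_peaks(300, seed = 11)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(pk, path)
  back <- read_bed(path)
  expect_equal(back$chrom, pk$chrom)
  expect_equal(back$start, pk$start)
  expect_equal(back$end, pk$end)
  expect_equal(back$id, pk$id)
})

test_that("BED parsing rejects malformed lines with a line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tok", "chr1\t100\t100\tempty"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("chr1\t0\t100"), path)
  simple <- read_bed(path)
  expect_equal(simple$start, 0L)
  expect_equal(simple$end, 100L)
  writeLines(c("chr1\t0"), path)
  expect_error(read_bed(path), "line 1")
})

test_that("intersect reports half-open overlaps and matches brute force", {
  a <- peak_set("chr1", 0L, 100L, id = "a1")
  b <- peak_set("chr1", c(50L, 100L), c(150L, 200L), id = c("b1", "b2"))
  ov <- intersect_peaks(a, b)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$id_b, "b1")
  expect_equal(ov$overlap_bp, 50L)
  for (seed in 1:5) {
    x <- random_peaks(120, seed = seed)
    y <- random_peaks(120, seed = seed + 100)
    expect_identical(sorted_pairs(intersect_peaks(x, y)),
                     sorted_pairs(brute_intersect(x, y)))
  }
})

test_that("intersect is reflexive and monotone in min_overlap_bp", {
  x <- random_peaks(150, seed = 21)
  self <- intersect_peaks(x, x)
  expect_true(all(x$id %in% self$id_a[self$id_a == self$id_b]))
  loose <- sorted_pairs(intersect_peaks(x, x, min_overlap_bp = 1L))
  strict <- intersect_peaks(x, x, min_overlap_bp = 50L)
  expect_true(all(sorted_pairs(strict) %in% loose))
  expect_true(all(strict$overlap_bp >= 50L))
})

test_that("stitching merges runs within the gap and matches union-find", {
  pk <- peak_set("chr1", c(0L, 200L), c(100L, 300L))
  st <- stitch_peaks(pk, 12500L)
  expect_equal(nrow(st), 1L)
  expect_equal(c(st$start, st$end), c(0L, 300L))
  expect_equal(st$n_constituents, 2L)
  far <- peak_set("chr1", c(0L, 20000L), c(100L, 20100L))
  expect_equal(nrow(stitch_peaks(far, 12500L)), 2L)
  expect_error(stitch_peaks(pk, -1L), "gap_bp")
  for (seed in 1:5) {
    x <- random_peaks(80, seed = seed + 30, span = 20000L)
    got <- stitch_peaks(x, 500L)
    got_key <- sort(vapply(got$constituents,
                           function(m) paste(sort(m), collapse = ","), ""))
    want <- brute_stitch(x, 500L)
    expect_identical(got_key, sort(want$members))
  }
})

test_that("nearest TSS distance picks the minimal absolute distance", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      tss = c(4000L, 9000L), strand = "+",
                      stringsAsFactors = FALSE)
  r <- peak_set("chr1", 4950L, 5050L, id = "r1")   # midpoint 5000
  nd <- nearest_tss_distance(r, genes)
  expect_equal(nd$gene_id, "gA")
  expect_equal(nd$abs_distance, 1000L)
  exact <- peak_set("chr1", 3950L, 4050L, id = "r2") # midpoint == TSS
  expect_equal(nearest_tss_distance(exact, genes)$abs_distance, 0L)
  expect_error(nearest_tss_distance(r, genes[0, ]), "empty")
  # random instances vs exhaustive scan
  set.seed(9)
  g2 <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                   tss = sample.int(100000L, 20), strand = "+",
                   stringsAsFactors = FALSE)
  rp <- random_peaks(50, seed = 77, chroms = "chr1")
  nd2 <- nearest_tss_distance(rp, g2)
  mid <- (rp$start + rp$end) %/% 2L
  for (i in seq_len(nrow(rp))) {
    expect_equal(nd2$abs_distance[i], min(abs(mid[i] - g2$tss)))
  }
})

test_that("regulatory-domain association matches a hand-enumerated layout", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1",
    tss = c(100000L, 300000L, 320000L), strand = c("+", "+", "-"),
    stringsAsFactors = FALSE)
  # hand-derived domains: g1 [0, 295000), g2 [101000, 319000),
  # g3 [301000, 1320000)
  regions <- peak_set(
    rep("chr1", 4),
    c(96000L, 150000L, 310000L, 5000000L),
    c(96100L, 150100L, 310050L, 5000100L),
    id = c("in_basal_g1", "between_g1_g2", "between_g2_g3", "far"))
  assoc <- associate_regions_to_genes(regions, genes)
  got <- split(assoc$gene_id, assoc$region_id)
  expect_equal(sort(got[["in_basal_g1"]]), "g1")
  expect_equal(sort(got[["between_g1_g2"]]), c("g1", "g2"))
  expect_equal(sort(got[["between_g2_g3"]]), c("g2", "g3"))
  expect_false("far" %in% assoc$region_id)
})
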