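test_that("HGR calling requires triple support and keeps the GR footprint", {
  gr <- list(`6` = peak_set("chr1", c(100L, 500L), c(200L, 600L),
                            id = c("grA", "grB")))
  atac <- list(`6` = peak_set("chr1", 150L, 250L, id = "at1"))
  k27 <- list(`6` = peak_set("chr1", 0L, 1000L, id = "k1"))
  out <- call_hgrs(gr, atac, k27)
  expect_equal(nrow(out), 1L)                      # grB lacks ATAC support
  expect_equal(c(out$start, out$end), c(100L, 200L))  # GR footprint kept
  expect_equal(out$constituent_gr, "grA")
  expect_equal(out$timepoints, "6")
})

test_that("HGR calling matches a brute-force triple-overlap oracle", {
  for (seed in 1:4) {
    gr <- random_peaks(60, seed = seed)
    atac <- random_peaks(60, seed = seed + 50)
    k27 <- random_peaks(60, seed = seed + 90)
    out <- call_hgrs(list(`6` = gr), list(`6` = atac), list(`6` = k27))
    want <- gr$id[gr$id %in% brute_intersect(gr, atac)$id_a &
                    gr$id %in% brute_intersect(gr, k27)$id_a]
    got <- as.character(unlist(strsplit(out$constituent_gr, ",")))
    expect_setequal(got, as.character(want))
  }
})

test_that("HGR set is invariant to timepoint processing order", {
  gr1 <- random_peaks(40, seed = 7)
  gr2 <- random_peaks(40, seed = 8)
  open <- random_peaks(80, seed = 9)
  a <- call_hgrs(list(`6` = gr1, `24` = gr2),
                 list(`6` = open, `24` = open),
                 list(`6` = open, `24` = open))
  b <- call_hgrs(list(`24` = gr2, `6` = gr1),
                 list(`24` = open, `6` = open),
                 list(`24` = open, `6` = open))
  expect_equal(a[, c("chrom", "start", "end", "timepoints")],
               b[, c("chrom", "start", "end", "timepoints")])
  expect_warning(
    call_hgrs(list(`6` = gr1, `24` = gr2), list(`6` = open),
              list(`6` = open, `24` = open)),
    "skipped")
})

test_that("PWM scanning finds the consensus at full score on both strands", {
  pwm <- gre_pwm()
  consensus <- "GGTACAGGATGTTCT"
  max_score <- sum(apply(pwm, 2, max))
  flank <- strrep("T", 20)
  hit <- scan_pwm(paste0(flank, consensus, flank), pwm)
  expect_true(hit$hit)
  expect_equal(hit$score, max_score, tolerance = 1e-9)
  expect_equal(hit$position, 21L)
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(consensus, "")[[1]]), collapse = ""))
  hit_rc <- scan_pwm(paste0(flank, rc, flank), pwm)
  expect_equal(hit_rc$score, max_score, tolerance = 1e-9)
  expect_equal(hit_rc$strand, "-")
  expect_false(scan_pwm("ACGT", pwm)$hit)   # shorter than the motif
})

test_that("PWM scan maxima equal exhaustive per-offset rescoring", {
  pwm <- gre_pwm()
  bases <- c("A", "C", "G", "T")
  L <- ncol(pwm)
  rescore <- function(s) {
    chars <- strsplit(s, "")[[1]]
    best <- -Inf
    for (strand_seq in list(chars, rev(chartr("ACGT", "TGCA", chars)))) {
      for (off in seq_len(length(strand_seq) - L + 1)) {
        sc <- 0
        for (j in seq_len(L)) {
          b <- match(strand_seq[off + j - 1], bases)
          sc <- sc + if (is.na(b)) min(pwm[, j]) else pwm[b, j]
        }
        best <- max(best, sc)
      }
    }
    best
  }
  set.seed(31)
  for (i in 1:10) {
    s <- paste(sample(c(bases, "N"), 300, replace = TRUE,
                      prob = c(rep(0.24, 4), 0.04)), collapse = "")
    expect_equal(scan_pwm(s, pwm, threshold_frac = 0)$score, rescore(s),
                 tolerance = 1e-9)
  }
})

test_that("GRE-response enrichment handles planted and degenerate designs", {
  # planted: all GRE HGRs enhanced, no non-GRE enhanced
  hgrs <- data.frame(id = sprintf("h%02d", 1:20),
                     has_gre = rep(c(TRUE, FALSE), each = 10),
                     stringsAsFactors = FALSE)
  res <- gre_response_enrichment(hgrs, enhanced_ids = sprintf("h%02d", 1:10))
  expect_equal(res$odds_ratio, Inf)
  expect_lt(res$p, 0.05)
  # label shuffling destroys the signal
  set.seed(14)
  ors <- replicate(20, {
    shuffled <- hgrs
    shuffled$has_gre <- sample(shuffled$has_gre)
    r <- gre_response_enrichment(shuffled, sprintf("h%02d", 1:10))
    r$p
  })
  expect_gt(mean(ors > 0.05), 0.5)
  expect_error(gre_response_enrichment(
    data.frame(id = "h1", has_gre = TRUE), "h1"), "non-GRE")
})

test_that("directional HGR-DEG distance test detects planted proximity", {
  set.seed(15)
  up <- data.frame(gene_id = sprintf("u%02d", 1:30), chrom = "chr1",
                   tss = seq(100000L, by = 100000L, length.out = 30),
                   strand = "+", stringsAsFactors = FALSE)
  down <- data.frame(gene_id = sprintf("d%02d", 1:30), chrom = "chr1",
                     tss = seq(150000L, by = 100000L, length.out = 30) +
                       sample(30000:50000, 30), strand = "+",
                     stringsAsFactors = FALSE)
  # enhanced HGRs sit within 2 kb of up-gene TSSs
  enh <- peak_set("chr1", up$tss + 1000L, up$tss + 1500L,
                  id = sprintf("e%02d", 1:30))
  res <- hgr_deg_distance_test(list(enhanced = enh),
                               list(up = up, down = down))
  expect_equal(res$hgr_direction, "enhanced")
  expect_gt(res$D, 0.5)
  expect_lt(res$p, 0.01)
})
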