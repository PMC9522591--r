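test_that("simulation config validates its fields", {
  expect_error(sim_config(frac_responsive = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(activity_factor = -1), "activity_factor")
  expect_error(sim_config(timepoints = c(2, 6)), "0 h")
  expect_error(sim_config(n_genes = 0), "n_genes")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 40, n_regions = 150, n_genes = 50,
                    n_patients = 20, n_loops = 100)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$genome$sequences, b$genome$sequences)
  expect_identical(a$counts$atac$counts, b$counts$atac$counts)
  expect_identical(a$cohort$betas, b$cohort$betas)
  expect_identical(a$screen$table, b$screen$table)
  expect_identical(a$loops$loops, b$loops$loops)
})

test_that("the toy genome has disjoint sorted peaks and full GRE planting", {
  cfg <- sim_config(seed = 41, n_regions = 10, n_genes = 20)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$peaks), 10L)
  by_chrom <- split(g$peaks, g$peaks$chrom)
  for (d in by_chrom) {
    if (nrow(d) < 2) next
    expect_true(all(diff(d$start) > 0))
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))   # disjoint
  }
  # every GRE-flagged peak has a PWM hit at the default threshold
  big <- simulate_genome(sim_config(seed = 42, n_regions = 400))
  hits <- vapply(big$roles$gre_ids, function(id) {
    scan_pwm(big$sequences[[id]], big$pwm)$hit
  }, NA)
  expect_true(all(hits))
  expect_error(simulate_genome(sim_config(seed = 1, n_regions = 100000)),
               "too large")
})

test_that("null count simulation has no systematic treated/control shift", {
  cfg <- sim_config(seed = 43, frac_responsive = 0, frac_se_planted = 0,
                    n_regions = 2000)
  g <- simulate_genome(cfg)
  tr <- make_truth(cfg, g)
  cm <- simulate_counts(cfg, g, tr)$atac
  sf <- size_factors(cm$counts)
  q <- sweep(cm$counts, 2, sf, "/")
  treated <- cm$samples$timepoint > 0
  ratio <- log2((rowMeans(q[, treated]) + 0.5) /
                  (rowMeans(q[, !treated]) + 0.5))
  expect_lt(abs(mean(ratio)), 0.05)
})

test_that("planted chromatin effects land in the expected NB interval", {
  cfg <- sim_config(seed = 44, n_regions = 2000)
  g <- simulate_genome(cfg)
  tr <- make_truth(cfg, g)
  cm <- simulate_counts(cfg, g, tr)$atac
  sf <- size_factors(cm$counts)
  q <- sweep(cm$counts, 2, sf, "/")
  treated <- cm$samples$timepoint == 24
  ctrl <- cm$samples$timepoint == 0
  ratio <- rowMeans(q[tr$atac_enhanced, treated]) /
    rowMeans(q[tr$atac_enhanced, ctrl])
  expect_gte(mean(ratio), 3.0)
  expect_lte(mean(ratio), 5.3)
  expect_gte(mean(ratio >= 3.0 & ratio <= 5.3), 0.8)
})

test_that("a zero-depth configuration yields all-zero columns", {
  cfg <- sim_config(seed = 45, n_regions = 50, n_genes = 20, depth_mean = 0)
  g <- simulate_genome(cfg)
  cm <- simulate_counts(cfg, g, make_truth(cfg, g))
  expect_true(all(cm$atac$counts == 0))
})

test_that("loop simulation hits the promoter fraction without self-loops", {
  cfg <- sim_config(seed = 46, n_regions = 600, n_genes = 150,
                    n_loops = 800, frac_responsive = 0.05)
  g <- simulate_genome(cfg)
  tr <- make_truth(cfg, g)
  sim <- simulate_loops(cfg, g, tr)
  ann <- annotate_loops(sim$loops, g$genes)
  frac <- mean(ann$class == "distal_promoter")
  expect_gte(frac, 0.30)
  expect_lte(frac, 0.40)
  expect_false(any(sim$loops$startA == sim$loops$startB &
                     sim$loops$chrA == sim$loops$chrB &
                     sim$loops$endA == sim$loops$endB))
  # planted pairs whose peak is clear of promoters are distal->promoter
  pl <- sim$truth$planted_pairs
  nd <- g$roles$nearest
  far <- nd$id[nd$abs_distance > 5000]
  pl <- pl[pl$peak %in% far, , drop = FALSE]
  expect_gt(nrow(pl), 0L)
  pk <- g$peaks[match(pl$peak[1], g$peaks$id), ]
  first <- ann[match(paste(pk$chrom, pk$start),
                     paste(ann$chrA, ann$startA)), ]
  expect_equal(first$class, "distal_promoter")
  expect_true(grepl(pl$gene[1], first$genesB))
})

test_that("STARR simulation excludes uncovered regions from RNA", {
  cfg <- sim_config(seed = 47, n_regions = 300, starr_dna_coverage = 2)
  g <- simulate_genome(cfg)
  st <- simulate_starr(cfg, g, make_truth(cfg, g))
  expect_true(any(st$dna == 0))
  expect_true(all(st$rna[st$dna == 0, ] == 0))
})

test_that("cohort simulation validates the resistant fraction", {
  cfg <- sim_config(seed = 48, n_regions = 100, n_genes = 30)
  g <- simulate_genome(cfg)
  bad <- cfg; bad$frac_resistant <- 1
  expect_error(simulate_cohort(bad, g, g$roles$gr_ids), "frac_resistant")
})

test_that("study files round-trip through standard parsers", {
  cfg <- sim_config(seed = 49, n_regions = 80, n_genes = 30,
                    n_patients = 20, n_variants = 10, n_loops = 60)
  study <- simulate_study(cfg)
  d <- withr::local_tempdir()
  paths <- write_study(study, d)
  # BED round trip
  back <- read_bed(paths[["peaks"]])
  expect_equal(back$start, study$genome$peaks$start)
  expect_equal(back$id, study$genome$peaks$id)
  # FASTA round trip through Biostrings
  fa <- Biostrings::readDNAStringSet(paths[["sequences"]])
  expect_identical(as.character(fa[study$genome$peaks$id[1]]),
                   setNames(study$genome$sequences[study$genome$peaks$id[1]],
                            study$genome$peaks$id[1]))
  # VCF parses with an independent reader and preserves genotypes
  vcf <- vcfR::read.vcfR(paths[["vcf"]], verbose = FALSE)
  expect_equal(nrow(vcf@fix), cfg$n_variants)
  gt <- vcfR::extract.gt(vcf, as.numeric = FALSE)
  dos_back <- matrix(match(gt, c("0/0", "0/1", "1/1")) - 1L, nrow(gt),
                     dimnames = dimnames(gt))
  expect_equal(unname(dos_back[study$cohort$variants$variant, ]),
               unname(study$cohort$dosages))
  # deterministic bytes under a fixed seed
  d2 <- withr::local_tempdir()
  write_study(simulate_study(cfg), d2)
  m1 <- tools::md5sum(list.files(d, full.names = TRUE))
  m2 <- tools::md5sum(list.files(d2, full.names = TRUE))
  expect_identical(unname(m1), unname(m2))
})
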