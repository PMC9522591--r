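test_that("resistance stratification rules behave as documented", {
  ph <- setNames(as.numeric(1:10), sprintf("p%02d", 1:10))
  cls <- stratify_resistance(ph)
  expect_equal(sum(cls == "resistant"), 5L)
  expect_equal(sum(cls == "sensitive"), 5L)
  labs <- setNames(rep(c("sensitive", "resistant"), 5), names(ph))
  expect_identical(stratify_resistance(ph, "provided", labels = labs), labs)
  expect_error(stratify_resistance(ph, "threshold", value = 100),
               "degenerate")
})

test_that("LD r-squared matches the correlation oracle", {
  g1 <- c(0, 1, 2, 1, 0, 2, 1, 1)
  expect_equal(ld_r2(g1, g1), 1)
  expect_equal(ld_r2(g1, 2 - g1), 1)    # perfect negative LD
  set.seed(34)
  a <- rbinom(100, 2, 0.3); b <- rbinom(100, 2, 0.3)
  expect_equal(ld_r2(a, b), cor(a, b)^2, tolerance = 1e-12)
  expect_true(is.na(ld_r2(rep(1, 10), rbinom(10, 2, 0.5))))
  expect_error(ld_r2(c(1, NA, NA, NA), c(1, 1, 1, 1)), "3 non-missing")
})

test_that("variant association recovers a planted additive effect", {
  set.seed(35)
  n <- 100
  dos <- rbind(var_a = rbinom(n, 2, 0.3), var_b = rbinom(n, 2, 0.3),
               var_mono = rep(1, n))
  colnames(dos) <- sprintf("p%03d", 1:n)
  pheno <- setNames(1 * dos["var_a", ] + rnorm(n, 0, 1), colnames(dos))
  res <- variant_phenotype_association(dos, pheno)
  beta_a <- res$beta[res$variant == "var_a"]
  expect_gte(beta_a, 0.6)
  expect_lte(beta_a, 1.4)
  expect_lt(res$q[res$variant == "var_a"], 0.05)
  expect_true(is.na(res$beta[res$variant == "var_mono"]))
  # permuted phenotype is null
  perm <- variant_phenotype_association(dos[1:2, , drop = FALSE],
                                        setNames(sample(pheno), names(pheno)))
  expect_true(all(perm$p > 0.001, na.rm = TRUE))
})

test_that("allele scoring is negative for a GRE-disrupting substitution", {
  pwm <- gre_pwm()
  seqs <- paste0(strrep("A", 30), "GGTACAGGATGTTCT", strrep("A", 30))
  # position 40 is the T opening TGTTCT; substituting it breaks a half-site
  res <- allele_delta_score(seqs, 40L, "T", "A", pwm)
  expect_lt(res$delta, 0)
  expect_lte(res$delta, -2)
  # a substitution far from the motif leaves the best score unchanged
  neutral <- allele_delta_score(seqs, 5L, "A", "C", pwm)
  expect_equal(neutral$delta, 0)
  expect_error(allele_delta_score(seqs, 40L, "G", "A", pwm), "reference")
})

test_that("methylation concordance is exact under planted anti-correlation", {
  cfg <- sim_config(seed = 36, n_regions = 300, n_genes = 80,
                    n_patients = 30, meth_concordant_frac = 1)
  g <- simulate_genome(cfg)
  univ <- setdiff(g$roles$gr_ids, g$roles$closed_gr)
  coh <- simulate_cohort(cfg, g, univ)
  classes <- setNames(coh$samples$class, coh$samples$sample)
  # use the generator's planted sites directly with their true directions
  sites <- data.frame(site = coh$truth$resistance_sites,
                      log2fc = ifelse(coh$truth$resistance_sites %in%
                                        coh$truth$occluded, -2, 2),
                      stringsAsFactors = FALSE)
  res <- methylation_concordance(sites, g$peaks, coh$probes, coh$betas,
                                 classes)
  expect_equal(res$fraction, 1.0)
  # independent betas are concordant about half the time
  set.seed(37)
  ind_betas <- matrix(runif(nrow(coh$betas) * ncol(coh$betas)),
                      nrow(coh$betas),
                      dimnames = dimnames(coh$betas))
  res_ind <- methylation_concordance(sites, g$peaks, coh$probes, ind_betas,
                                     classes)
  expect_gt(res_ind$fraction, 0.35)
  expect_lt(res_ind$fraction, 0.65)
})

test_that("fine-mapping lands on the planted causal GRE variant", {
  cfg <- sim_config(seed = 38, n_regions = 300, n_genes = 80,
                    n_patients = 100)
  res <- run_gc_pipeline(cfg)
  fm <- res$cohort$finemapped
  expect_true("var_causal" %in% fm$variant)
  causal <- fm[fm$variant == "var_causal", ]
  expect_lt(causal$delta_score, 0)
  expect_lte(causal$delta_score, -2)
  assoc <- res$cohort$association
  expect_lt(assoc$q[assoc$variant == "var_causal"], 0.05)
})

test_that("the prioritization funnel is monotone and keeps a full passer", {
  candidates <- data.frame(site = c("s1", "s2"), n_sgrnas = c(5L, 5L),
                           mean_log2fc = c(1, 0.5), rho = c(0.01, 0.01),
                           p = c(0.01, 0.01), q = c(0.02, 0.02),
                           hgr_id = c("h1", "h2"), stringsAsFactors = FALSE)
  site_peaks <- peak_set("chr1", c(10000L, 50000L), c(11000L, 51000L),
                         id = c("s1", "s2"))
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      tss = c(12000L, 52000L), strand = "+",
                      stringsAsFactors = FALSE)
  out <- prioritize_hgrs(candidates, site_peaks, genes,
                         deg_ids = c("gA", "gB"),
                         resistance_genes = "gA")
  expect_true(all(diff(unname(out$stage_counts)) <= 0))
  expect_equal(out$table$site, "s1")
  expect_equal(out$table$gene_id, "gA")
  expect_error(prioritize_hgrs(candidates, site_peaks, genes, "gA",
                               character(0)), "empty resistance")
})
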