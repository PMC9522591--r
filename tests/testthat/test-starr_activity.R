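test_that("downsampling equalizes totals and is identity on equal inputs", {
  set.seed(17)
  x <- matrix(rpois(300, 50), 100, 3,
              dimnames = list(sprintf("r%03d", 1:100), c("h0", "h6", "h24")))
  x[, 2] <- x[, 2] * 2L
  ds <- downsample_libraries(x, seed = 5)
  expect_true(all(colSums(ds) == min(colSums(x))))
  jmin <- which.min(colSums(x))
  expect_identical(ds[, jmin], x[, jmin])    # minimum library untouched
  expect_true(all(ds <= x))
  # identity when totals are already equal
  eq <- matrix(c(10L, 20L, 20L, 10L), 2, 2,
               dimnames = list(c("a", "b"), c("c1", "c2")))
  expect_identical(downsample_libraries(eq, seed = 1), eq)
  # determinism
  expect_identical(downsample_libraries(x, seed = 5), ds)
  expect_false(identical(downsample_libraries(x, seed = 6)[, 2], ds[, 2]))
  zero <- eq; zero[, 1] <- 0L
  expect_error(downsample_libraries(zero, seed = 1), "zero-total")
})

test_that("downsampling preserves expected per-region proportions", {
  set.seed(18)
  x <- matrix(rpois(200, 100), 100, 2,
              dimnames = list(sprintf("r%03d", 1:100), c("a", "b")))
  x[, 2] <- x[, 2] * 3L
  prop_before <- x[, 2] / sum(x[, 2])
  means <- rowMeans(sapply(1:100, function(s) {
    downsample_libraries(x, seed = s)[, 2]
  }))
  prop_after <- means / sum(means)
  expect_lt(max(abs(prop_after - prop_before) / pmax(prop_before, 1e-6)),
            0.25)
  expect_lt(abs(sum(means) - min(colSums(x))), 1e-9)
})

test_that("binomial caller is inactive when RNA matches DNA proportions", {
  dna <- setNames(rep(100L, 50), sprintf("r%02d", 1:50))
  rna <- setNames(rep(100L, 50), sprintf("r%02d", 1:50))
  out <- call_active_binomial(dna, rna)
  expect_false(any(out$active))
  expect_true(all(out$p > 0.3))
})

test_that("binomial caller recovers planted activity and respects min_dna", {
  cfg <- sim_config(seed = 21, n_regions = 800, n_genes = 200)
  g <- simulate_genome(cfg)
  tr <- make_truth(cfg, g)
  st <- simulate_starr(cfg, g, tr)
  ds <- downsample_libraries(st$rna, seed = 2)
  calls <- call_active_binomial(st$dna, ds[, "h24"])
  planted <- st$truth$active_gc[st$dna[st$truth$active_gc] >= 50]
  expect_gte(mean(calls$active[match(planted, calls$region)]), 0.9)
  # regions below the DNA floor are never called
  low <- calls$region[calls$dna < 10]
  expect_false(any(calls$active[calls$region %in% low]))
})

test_that("null STARR libraries stay at the nominal false-positive rate", {
  cfg <- sim_config(seed = 22, n_regions = 2000, frac_starr_active = 0)
  g <- simulate_genome(cfg)
  st <- simulate_starr(cfg, g, make_truth(cfg, g))
  ds <- downsample_libraries(st$rna, seed = 3)
  frac <- mean(call_active_binomial(st$dna, ds[, "h6"])$active)
  expect_lte(frac, 0.003)
})

test_that("count-model caller is empty on identical libraries", {
  set.seed(23)
  base <- matrix(rpois(400 * 7, 80), 400, 7,
                 dimnames = list(sprintf("r%03d", 1:400),
                                 c(paste0("rna", 1:4), paste0("in", 1:3))))
  out <- call_active_countmodel(base[, 1:4], base[, 5:7])
  expect_lte(mean(out$active), 0.01)
  expect_error(call_active_countmodel(base[, 1, drop = FALSE],
                                      base[, 5:7]), "replicates")
})

test_that("condition-specificity classes partition the active sets", {
  cfg <- sim_config(seed = 24, n_regions = 600, n_genes = 150)
  g <- simulate_genome(cfg)
  st <- simulate_starr(cfg, g, make_truth(cfg, g))
  ds <- downsample_libraries(st$rna, seed = 4)
  act <- lapply(colnames(ds), function(cc) {
    d <- call_active_binomial(st$dna, ds[, cc])
    d$region[d$active]
  })
  names(act) <- colnames(ds)
  cls <- classify_condition_specificity(st$regions, act$h0, act$h6, act$h24)
  cl <- setNames(cls$class, cls$region)
  # 0h actives are exactly the h0_specific plus shared classes
  expect_setequal(act$h0, cls$region[cl[cls$region] %in%
                                       c("h0_specific", "shared")])
  # active at 6 h only -> GC_specific; active at 0 and 24 h -> shared
  gc_only <- setdiff(union(act$h6, act$h24), act$h0)
  expect_true(all(cl[gc_only] %in% c("GC_specific", "shared")))
  both <- intersect(act$h0, act$h24)
  expect_true(all(cl[both] == "shared"))
})

test_that("planted STARR enrichment battery points the right way", {
  cfg <- sim_config(seed = 25, n_regions = 800, n_genes = 200)
  res <- run_gc_pipeline(cfg)
  tests <- res$starr$tests
  expect_gt(tests$responsive_fisher$odds_ratio, 1)
  expect_gt(tests$gre_chisq$fold, 1)
  expect_lt(tests$gre_chisq$p, 0.05)
})
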