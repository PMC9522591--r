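make_nb <- function(m, mu, size, cols, seed) {
  set.seed(seed)
  x <- matrix(rnbinom(m * cols, mu = mu, size = size), m,
              dimnames = list(sprintf("f%04d", seq_len(m)),
                              sprintf("s%d", seq_len(cols))))
  x
}

test_that("size factors follow the median-of-ratios definition", {
  c1 <- c(100L, 200L, 400L)
  counts <- cbind(s1 = c1, s2 = c1)
  rownames(counts) <- c("a", "b", "c")
  expect_equal(unname(size_factors(counts)), c(1, 1))
  doubled <- cbind(s1 = c1, s2 = 2L * c1)
  rownames(doubled) <- c("a", "b", "c")
  expect_equal(unname(size_factors(doubled)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # scale equivariance of factor ratios (the shared geometric-mean
  # reference absorbs a c^{1/n} renormalization)
  x <- make_nb(200, 300, 10, 4, seed = 1) + 1L
  sf <- size_factors(x)
  x2 <- x; x2[, 2] <- x2[, 2] * 3L
  sf2 <- size_factors(x2)
  expect_equal(unname(sf2[2] / sf2[1]), unname(3 * sf[2] / sf[1]),
               tolerance = 1e-12)
  # feature permutation invariance
  expect_equal(size_factors(x[sample(nrow(x)), ]), sf)
  zeros <- matrix(0L, 3, 2, dimnames = list(letters[1:3], c("s1", "s2")))
  expect_error(size_factors(zeros), "all-positive")
})

test_that("size factors agree with the DESeq2 reference on random data", {
  x <- make_nb(500, 400, 15, 6, seed = 2) + 1L
  ours <- size_factors(x)
  ref <- DESeq2::estimateSizeFactorsForMatrix(x)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("dispersion estimates recover the generative alpha", {
  # Poisson data: alpha should collapse to the floor
  set.seed(3)
  pois <- matrix(rpois(800 * 50, 500), 800,
                 dimnames = list(sprintf("f%d", 1:800),
                                 sprintf("s%d", 1:50)))
  d_pois <- estimate_dispersion(pois, rep(1, 50))
  expect_lte(median(d_pois), 0.01)
  # NB alpha = 0.05, 10 replicates
  nb <- make_nb(2000, 500, 1 / 0.05, 10, seed = 4)
  d_nb <- estimate_dispersion(nb, rep(1, 10))
  expect_gte(median(d_nb), 0.025)
  expect_lte(median(d_nb), 0.1)
  # constant feature sits at the floor
  const <- rbind(nb[1:50, ], konst = rep(400L, 10))
  d_c <- estimate_dispersion(const, rep(1, 10))
  expect_equal(unname(d_c["konst"]), 1e-8)
  one_rep <- nb[, 1, drop = FALSE]
  expect_error(estimate_dispersion(one_rep, 1, groups = "g1"), "replicates")
})

test_that("NB Wald test is calibrated under the null", {
  x <- make_nb(5000, rep(rlnorm(5000, log(500), 1), 8), 20, 8, seed = 42)
  res <- diff_test(x, rep(c("a", "b"), each = 4), "b", "a")
  expect_lt(abs(mean(res$log2fc)), 0.05)
  frac_p <- mean(res$p < 0.01)
  expect_gte(frac_p, 0.005)
  expect_lte(frac_p, 0.02)
  expect_lte(mean(res$q < 0.01), 0.02)
  expect_true(all(res$q >= res$p - 1e-12))
  expect_error(diff_test(x, rep("a", 8), "b", "a"), "empty group")
})

test_that("NB Wald test recovers a planted 4-fold effect", {
  m <- 3000
  set.seed(43)
  mu0 <- rlnorm(m, log(500), 1)
  idx <- sample(m, 300)
  eff <- rep(1, m); eff[idx] <- 4
  counts <- sapply(1:8, function(j) {
    rnbinom(m, mu = mu0 * (if (j > 4) eff else 1), size = 20)
  })
  dimnames(counts) <- list(sprintf("f%d", 1:m), sprintf("s%d", 1:8))
  res <- diff_test(counts, rep(c("a", "b"), each = 4), "b", "a")
  expect_gte(mean(res$log2fc[idx]), 1.6)
  expect_lte(mean(res$log2fc[idx]), 2.4)
  sens <- mean(res$q[idx] < 0.01 & abs(res$log2fc[idx]) >= 1)
  expect_gte(sens, 0.9)
})

test_that("responsive classification thresholds and contrast union", {
  r6 <- data.frame(feature = c("g1", "g2", "g3"),
                   log2fc = c(1.5, 3.4, 1.2), q = c(0.005, 0.02, 0.004),
                   direction = c("enhanced", "enhanced", "enhanced"),
                   stringsAsFactors = FALSE)
  r24 <- data.frame(feature = c("g1", "g2", "g3"),
                    log2fc = c(0.2, 3.2, -1.8), q = c(0.5, 0.001, 0.002),
                    direction = c("enhanced", "enhanced", "reduced"),
                    stringsAsFactors = FALSE)
  out <- classify_responsive(list(`6h` = r6, `24h` = r24), q_max = 0.01,
                             min_fold = 2)
  # g1 significant only at 6h -> in the union; g2 only at 24h (q=0.02 at 6h)
  expect_setequal(out$feature, c("g1", "g2", "g3"))
  expect_equal(out$contrasts[out$feature == "g1"], "6h")
  expect_equal(out$contrasts[out$feature == "g2"], "24h")
  expect_equal(out$contrasts[out$feature == "g3"], "24h,6h")
  # fold filter: q fine but fold below 2 is excluded
  strict <- classify_responsive(list(`6h` = r6), q_max = 0.01, min_fold = 4)
  expect_false("g1" %in% strict$feature)
  # q threshold: huge fold with q above cutoff is excluded
  highfc <- data.frame(feature = "gX", log2fc = 10, q = 0.02,
                       direction = "enhanced", stringsAsFactors = FALSE)
  expect_equal(nrow(classify_responsive(list(c1 = highfc), 0.01, 2)), 0L)
})
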