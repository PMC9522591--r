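## Negative-binomial differential testing of region/gene counts.
##
## The model is deliberately transparent: median-of-ratios size factors,
## method-of-moments dispersion with 50/50 shrinkage toward a fitted
## mean-dispersion trend, and a Wald test on normalized group means.
## All contrasts in this pipeline are two-group.

#' Assemble a count matrix with sample metadata
#'
#' @param counts integer matrix, features x samples (dimnames required).
#' @param samples data.frame with one row per column of `counts`; must carry
#'   a `sample` column matching `colnames(counts)` plus whatever grouping
#'   columns (condition, timepoint, replicate, assay) the analysis uses.
#' @return list with class `count_matrix` (elements `counts`, `samples`).
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry feature and sample dimnames")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!"sample" %in% names(samples)) stop("samples needs a 'sample' column")
  if (!identical(sort(colnames(counts)), sort(as.character(samples$sample)))) {
    stop("sample metadata must cover every count column")
  }
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over features of the ratio of its count to
#' the feature's geometric mean, using only features with no zero count.
#'
#' @param counts features x samples matrix.
#' @return named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  pos <- rowSums(counts <= 0) == 0L
  if (!any(pos)) {
    stop("no feature with all-positive counts; pseudo-reference fallback is disabled")
  }
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2L, function(col) exp(median(col - ref)))
  setNames(sf, colnames(counts))
}

#' Per-feature NB dispersion estimates
#'
#' Method-of-moments on normalized counts, pooled across replicate groups so
#' real treatment effects do not masquerade as dispersion, then shrunk 50/50
#' toward a mean-dispersion trend a0 + a1/mu fitted by least squares over
#' features with positive raw estimates. Features whose raw estimate is zero
#' (at or below Poisson variance) are set to the floor of 1e-8.
#'
#' @param counts features x samples matrix.
#' @param factors per-sample size factors.
#' @param groups factor/character grouping of samples into replicate groups;
#'   defaults to a single group.
#' @return numeric vector of per-feature dispersions (alpha in
#'   Var = mu + alpha * mu^2).
#' @export
estimate_dispersion <- function(counts, factors, groups = NULL) {
  counts <- as.matrix(counts)
  if (is.null(groups)) groups <- rep("all", ncol(counts))
  groups <- as.character(groups)
  tab <- table(groups)
  if (!any(tab >= 2L)) stop("dispersion needs >= 2 replicates in some group")
  q <- sweep(counts, 2L, factors, "/")
  use <- names(tab)[tab >= 2L]
  ss <- rep(0, nrow(counts)); mm <- rep(0, nrow(counts)); dfree <- 0
  mu_all <- rowMeans(q)
  for (g in use) {
    cols <- which(groups == g)
    qg <- q[, cols, drop = FALSE]
    mg <- rowMeans(qg)
    vg <- apply(qg, 1L, var)
    w <- length(cols) - 1L
    ss <- ss + w * vg
    mm <- mm + w * mg
    dfree <- dfree + w
  }
  v <- ss / dfree
  mu <- mm / dfree
  raw <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  fitable <- raw > 0 & mu > 0
  if (sum(fitable) >= 10L) {
    fit <- lm(raw[fitable] ~ I(1 / mu[fitable]))
    a0 <- max(coef(fit)[1L], 0)
    a1 <- max(coef(fit)[2L], 0)
  } else {
    a0 <- if (any(fitable)) median(raw[fitable]) else 0
    a1 <- 0
  }
  trend <- ifelse(mu > 0, a0 + a1 / mu, a0)
  alpha <- ifelse(raw > 0, 0.5 * raw + 0.5 * trend, 0)
  pmax(alpha, 1e-8)
}

#' NB Wald test between two sample groups
#'
#' Group means are fitted on normalized counts; the log2 fold change uses a
#' +0.5 pseudocount in both groups, and its standard error comes from the
#' NB delta method: Var(log mu_hat) = (1/n^2) * sum_j (1/(s_j mu) + alpha)
#' per group, summed over the two groups and propagated to log2.
#'
#' @param counts features x samples matrix.
#' @param factors per-sample size factors.
#' @param alpha per-feature dispersions.
#' @param group character/factor of length ncol(counts).
#' @param treated,reference the two group labels to contrast.
#' @return data.frame: feature, base_mean, log2fc (treated vs reference),
#'   se, wald_stat, p, q, direction (`enhanced`/`reduced`).
#' @export
nb_wald_test <- function(counts, factors, alpha, group, treated, reference) {
  counts <- as.matrix(counts)
  group <- as.character(group)
  it <- which(group == treated)
  ir <- which(group == reference)
  if (length(it) == 0L || length(ir) == 0L) {
    stop(sprintf("empty group in contrast %s vs %s", treated, reference))
  }
  q <- sweep(counts, 2L, factors, "/")
  mu_t <- rowMeans(q[, it, drop = FALSE])
  mu_r <- rowMeans(q[, ir, drop = FALSE])
  log2fc <- log2((mu_t + 0.5) / (mu_r + 0.5))
  var_log <- function(mu, idx) {
    s <- factors[idx]
    sapply(seq_along(mu), function(i) {
      sum(1 / (s * (mu[i] + 0.5)) + alpha[i]) / length(idx)^2
    })
  }
  v <- var_log(mu_t, it) + var_log(mu_r, ir)
  se <- sqrt(v) / log(2)
  wald <- log2fc / se
  p <- 2 * pnorm(-abs(wald))
  data.frame(
    feature = rownames(counts),
    base_mean = rowMeans(q),
    log2fc = log2fc,
    se = se,
    wald_stat = wald,
    p = p,
    q = bh_fdr(p),
    direction = ifelse(log2fc >= 0, "enhanced", "reduced"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Run a two-group differential analysis end to end
#'
#' Convenience wrapper: size factors, dispersion (grouped by `group`), Wald
#' test for `treated` vs `reference`.
#'
#' @inheritParams nb_wald_test
#' @return DifferentialResult data.frame (see [nb_wald_test()]).
#' @export
diff_test <- function(counts, group, treated, reference) {
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf, groups = group)
  nb_wald_test(counts, sf, disp, group, treated, reference)
}

#' Threshold differential results into responsive calls
#'
#' A feature is responsive iff q < `q_max` and |log2fc| >= log2(`min_fold`).
#' When several contrasts are supplied (e.g. the 6 h and 24 h expression
#' contrasts) the responsive universe is their union, keeping each feature's
#' most significant record; `timepoint` records which contrasts supported it.
#'
#' @param results one DifferentialResult data.frame or a named list of them.
#' @param q_max FDR ceiling (default 0.01).
#' @param min_fold minimum fold change (default 1: no fold filter).
#' @return data.frame of responsive features with direction and supporting
#'   contrast labels.
#' @export
classify_responsive <- function(results, q_max = 0.01, min_fold = 1) {
  if (is.data.frame(results)) results <- list(contrast = results)
  min_l2 <- log2(min_fold)
  picked <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    keep <- !is.na(r$q) & r$q < q_max & abs(r$log2fc) >= min_l2
    if (!any(keep)) return(NULL)
    cbind(r[keep, , drop = FALSE], contrast = nm, stringsAsFactors = FALSE)
  })
  picked <- do.call(rbind, picked)
  if (is.null(picked) || nrow(picked) == 0L) {
    return(data.frame(feature = character(), log2fc = numeric(),
                      q = numeric(), direction = character(),
                      contrasts = character(), stringsAsFactors = FALSE))
  }
  supp <- vapply(split(picked$contrast, picked$feature),
                 function(x) paste(sort(unique(x)), collapse = ","), "")
  best <- picked[order(picked$q), , drop = FALSE]
  best <- best[!duplicated(best$feature), , drop = FALSE]
  out <- data.frame(feature = best$feature, log2fc = best$log2fc, q = best$q,
                    direction = best$direction,
                    contrasts = unname(supp[best$feature]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
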