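# Brute-force and closed-form oracles, independent of the implementation
# paths they check.

# all-pairs interval overlap
brute_intersect <- function(a, b, min_overlap = 1L) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_overlap) {
        out[[length(out) + 1L]] <- data.frame(
          id_a = a$id[i], id_b = b$id[j], overlap_bp = ov,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
                      overlap_bp = integer()))
  }
  do.call(rbind, out)
}

# union-find stitching
brute_stitch <- function(peaks, gap) {
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || peaks$chrom[i] != peaks$chrom[j]) next
      gap_ij <- max(peaks$start[i], peaks$start[j]) -
        min(peaks$end[i], peaks$end[j])
      if (gap_ij <= gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comps <- split(seq_len(n), roots)
  do.call(rbind, lapply(comps, function(idx) {
    data.frame(chrom = peaks$chrom[idx[1L]], start = min(peaks$start[idx]),
               end = max(peaks$end[idx]),
               members = paste(sort(peaks$id[idx]), collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

# exact Fisher p by explicit enumeration over lchoose-based probabilities
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  lp <- vapply(lo:hi, function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }, 0)
  p <- exp(lp)
  p_obs <- p[a - lo + 1L]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# binomial upper tail by explicit log-space term summation
binom_tail_oracle <- function(x, n, p0) {
  if (x == 0) return(1)
  k <- x:n
  sum(exp(lchoose(n, k) + k * log(p0) + (n - k) * log1p(-p0)))
}

# K-S D by brute-force sup over pooled points
ks_D_brute <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, 0))
}

# CDF of the j-th order statistic of k uniforms, by numerical integration
# of its density (independent of pbeta)
order_stat_cdf_oracle <- function(r, j, k) {
  dens <- function(t) {
    j * choose(k, j) * t^(j - 1) * (1 - t)^(k - j)
  }
  integrate(dens, 0, r, rel.tol = 1e-10)$value
}

# random peak set on a toy genome
random_peaks <- function(n, seed, chroms = c("chr1", "chr2"),
                         span = 100000L, max_w = 500L) {
  set.seed(seed)
  start <- sample.int(span, n)
  w <- sample.int(max_w, n)
  peak_set(sample(chroms, n, replace = TRUE), start, start + w,
           id = sprintf("r%03d", seq_len(n)))
}

sorted_pairs <- function(d) {
  if (nrow(d) == 0L) return(character(0))
  sort(paste(d$id_a, d$id_b, d$overlap_bp, sep = "|"))
}
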