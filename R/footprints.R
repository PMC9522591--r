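## Transposase-insertion footprint scoring at TF motif sites, permutation
## differential occupancy between conditions, and the AP-1 depletion test.
## No insertion-bias correction is applied: profiles are consumed as given,
## with a hook (`correct` argument) left for a bias model.

#' Footprint score of an insertion profile
#'
#' Each site's insertion-count vector over the window (positions centered
#' on the motif) is normalized to mean 1; the score is mean(flank) -
#' mean(core), where the core spans `core_halfwidth` positions either side
#' of the center and the flank the `flank_bp` positions adjacent to the
#' core on each side. A deeper insertion dip at the motif (protection by a
#' bound factor) gives a higher score; the score is invariant to global
#' sequencing depth. All-zero sites are skipped.
#'
#' @param profile matrix, sites x window positions, of insertion counts.
#' @param core_halfwidth half-width of the motif core in bp (default 7,
#'   suiting a 15-bp motif).
#' @param flank_bp flank width each side of the core (default 20).
#' @return list: `per_site` scores (NA for skipped sites), `aggregate`
#'   (mean over scored sites), `n_sites`.
#' @export
footprint_score <- function(profile, core_halfwidth = 7L, flank_bp = 20L) {
  profile <- as.matrix(profile)
  w <- ncol(profile)
  center <- (w + 1L) %/% 2L
  core_idx <- (center - core_halfwidth):(center + core_halfwidth)
  left_flank <- (min(core_idx) - flank_bp):(min(core_idx) - 1L)
  right_flank <- (max(core_idx) + 1L):(max(core_idx) + flank_bp)
  if (min(left_flank) < 1L || max(right_flank) > w) {
    stop("window too narrow for core + flank geometry")
  }
  per_site <- apply(profile, 1L, function(v) {
    m <- mean(v)
    if (m == 0) return(NA_real_)
    v <- v / m
    mean(v[c(left_flank, right_flank)]) - mean(v[core_idx])
  })
  ok <- !is.na(per_site)
  list(per_site = per_site,
       aggregate = if (any(ok)) mean(per_site[ok]) else NA_real_,
       n_sites = sum(ok))
}

#' Differential footprint occupancy between two conditions
#'
#' For each TF, the statistic is the aggregate-score difference
#' delta = aggregate(b) - aggregate(a) over the same site set. Significance
#' comes from a site-level permutation: each site's pair of per-site scores
#' is randomly label-swapped, and p is the fraction of permutations with
#' |delta_perm| >= |delta| (add-one corrected). q across TFs by BH.
#'
#' @param profiles named list per TF: each a list with matrices `a` and `b`
#'   (sites x positions, same sites in both conditions).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @param core_halfwidth,flank_bp geometry passed to [footprint_score()].
#' @return data.frame: tf, delta, p, q.
#' @export
differential_footprint <- function(profiles, n_perm = 1000L, seed = 1L,
                                   core_halfwidth = 7L, flank_bp = 20L) {
  if (n_perm < 100L) stop("need >= 100 permutations")
  set.seed(seed)
  rows <- lapply(names(profiles), function(tf) {
    pa <- footprint_score(profiles[[tf]]$a, core_halfwidth, flank_bp)
    pb <- footprint_score(profiles[[tf]]$b, core_halfwidth, flank_bp)
    ok <- !is.na(pa$per_site) & !is.na(pb$per_site)
    sa <- pa$per_site[ok]; sb <- pb$per_site[ok]
    delta <- mean(sb) - mean(sa)
    n <- length(sa)
    hits <- 0L
    for (k in seq_len(n_perm)) {
      swap <- runif(n) < 0.5
      d <- mean(ifelse(swap, sa, sb)) - mean(ifelse(swap, sb, sa))
      if (abs(d) >= abs(delta)) hits <- hits + 1L
    }
    data.frame(tf = tf, delta = delta, p = (hits + 1) / (n_perm + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' AP-1 footprint x reduced-accessibility enrichment
#'
#' Fisher's exact on {AP-1 footprint, none} x {reduced-responsive, not}
#' over accessible chromatin sites, testing whether AP-1-bound sites
#' preferentially lose accessibility after GC treatment.
#'
#' @param site_ids all accessible-site ids.
#' @param ap1_ids ids carrying an AP-1 footprint.
#' @param reduced_ids ids with reduced-responsive accessibility.
#' @return list: `table`, `odds_ratio`, `p`.
#' @export
ap1_site_depletion_test <- function(site_ids, ap1_ids, reduced_ids) {
  ap1 <- site_ids %in% ap1_ids
  red <- site_ids %in% reduced_ids
  a <- sum(ap1 & red); b <- sum(ap1 & !red)
  c_ <- sum(!ap1 & red); d <- sum(!ap1 & !red)
  if ((a + b) == 0L || (c_ + d) == 0L) stop("empty AP-1 stratum")
  ft <- fisher_exact(a, b, c_, d)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("ap1", "no_ap1"), c("reduced", "not")))
  list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p)
}
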