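## CRISPRi tiling-screen analysis: per-sgRNA enrichment after drug
## selection (NB differential engine) and element-level aggregation by
## alpha-robust-rank aggregation with permutation calibration, mirroring
## how screen sites are ranked by aggregate log2 fold change.

#' Per-sgRNA enrichment, post-selection vs baseline
#'
#' Long-format screen table in, per-sgRNA differential result out (NB Wald
#' via the shared engine). Enrichment is one-sided on the positive
#' direction; `p_one` is the upper-tail p used downstream by the rank
#' aggregation.
#'
#' @param screen data.frame with columns sgrna, site (or `control` flag via
#'   site == "control"), arm (`baseline`/`selected`), replicate, count.
#' @param q_max enrichment FDR cutoff (default 0.05).
#' @return data.frame: sgrna, site, log2fc, p, q, p_one, enriched.
#' @export
sgrna_enrichment <- function(screen, q_max = 0.05) {
  need <- c("sgrna", "site", "arm", "replicate", "count")
  if (!all(need %in% names(screen))) {
    stop("screen table needs columns: ", paste(need, collapse = ", "))
  }
  screen$samp <- paste(screen$arm, screen$replicate, sep = "_")
  samples <- unique(screen[, c("samp", "arm")])
  if (any(table(samples$arm) < 2L)) stop("need >= 2 replicates per arm")
  sgrnas <- sort(unique(screen$sgrna))
  counts <- matrix(0L, nrow = length(sgrnas), ncol = nrow(samples),
                   dimnames = list(sgrnas, samples$samp))
  counts[cbind(match(screen$sgrna, sgrnas),
               match(screen$samp, samples$samp))] <- screen$count
  res <- diff_test(counts, samples$arm, treated = "selected",
                   reference = "baseline")
  map <- unique(screen[, c("sgrna", "site")])
  res$site <- map$site[match(res$feature, map$sgrna)]
  data.frame(sgrna = res$feature, site = res$site, log2fc = res$log2fc,
             p = res$p, q = res$q,
             p_one = pnorm(-res$wald_stat),
             enriched = !is.na(res$q) & res$q < q_max & res$log2fc > 0,
             stringsAsFactors = FALSE)
}

#' Alpha-RRA score for one set of percentile ranks
#'
#' rho = min over the j significant leading ranks of
#' BetaCDF(r(j); j, k - j + 1); 1 when no sgRNA passes alpha.
#' @param r sorted ascending percentile ranks in (0, 1].
#' @param j_max number of leading ranks considered (sgRNAs with p < alpha).
#' @return rho in (0, 1].
#' @keywords internal
rra_rho <- function(r, j_max) {
  k <- length(r)
  if (j_max == 0L) return(1)
  j <- seq_len(min(j_max, k))
  min(pbeta(r[j], j, k - j + 1))
}

#' Aggregate sgRNA enrichment to screen elements by alpha-RRA
#'
#' sgRNAs are percentile-ranked by one-sided enrichment p (ties broken by
#' sgRNA id); each site's rho is the alpha-RRA minimum over its leading
#' ranks, considering only sgRNAs with p < `alpha`. A permutation p per
#' site comes from `n_perm` random draws of matched size from the pooled
#' rank list. Sites are ranked by mean log2 fold change (the primary
#' ordering), with rho and its permutation p as companion evidence.
#'
#' @param enrich data.frame from [sgrna_enrichment()] (control sgRNAs,
#'   site == "control", are excluded from site aggregation but stay in the
#'   rank pool).
#' @param alpha per-sgRNA significance gate (default 0.05).
#' @param n_perm permutations per site-size class (default 1000).
#' @param seed integer seed.
#' @return data.frame sorted by decreasing mean_log2fc: site, n_sgrnas,
#'   mean_log2fc, rho, p, q.
#' @export
aggregate_sites_rra <- function(enrich, alpha = 0.05, n_perm = 1000L,
                                seed = 1L) {
  ord <- order(enrich$p_one, enrich$sgrna)
  n <- nrow(enrich)
  pr <- numeric(n)
  pr[ord] <- seq_len(n) / n
  enrich$rank_pct <- pr
  sites <- enrich[enrich$site != "control", , drop = FALSE]
  if (nrow(sites) == 0L) stop("no targeting sgRNAs")
  by_site <- split(sites, sites$site)
  if (any(vapply(by_site, nrow, 0L) == 0L)) stop("site with zero sgRNAs")
  obs <- lapply(by_site, function(d) {
    r <- sort(d$rank_pct)
    j_max <- sum(d$p_one < alpha)
    data.frame(site = d$site[1L], n_sgrnas = nrow(d),
               mean_log2fc = mean(d$log2fc),
               rho = rra_rho(r, j_max), stringsAsFactors = FALSE)
  })
  obs <- do.call(rbind, obs)
  # permutation null per site size, drawing matched-k rank sets from the pool
  set.seed(seed)
  pool_r <- enrich$rank_pct
  pool_p <- enrich$p_one
  null_by_k <- lapply(sort(unique(obs$n_sgrnas)), function(k) {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, k)
      rra_rho(sort(pool_r[idx]), sum(pool_p[idx] < alpha))
    }, 0)
  })
  names(null_by_k) <- as.character(sort(unique(obs$n_sgrnas)))
  obs$p <- vapply(seq_len(nrow(obs)), function(i) {
    nulls <- null_by_k[[as.character(obs$n_sgrnas[i])]]
    (sum(nulls <= obs$rho[i]) + 1) / (n_perm + 1)
  }, 0)
  obs$q <- bh_fdr(obs$p)
  obs <- obs[order(-obs$mean_log2fc, obs$site), , drop = FALSE]
  rownames(obs) <- NULL
  obs
}

#' Summarize control sgRNAs as pseudo-elements
#'
#' Groups control sgRNAs into random pseudo-sites of size `k` and reports
#' where their mean log2 fold changes fall in the ranked site list — a
#' calibration check that controls sit mid-ranking.
#'
#' @param enrich data.frame from [sgrna_enrichment()].
#' @param aggregates output of [aggregate_sites_rra()].
#' @param k pseudo-site size (default 5).
#' @param seed integer seed.
#' @return data.frame: pseudo_site, mean_log2fc, rank_percentile (within
#'   the real site ranking).
#' @export
control_pseudo_sites <- function(enrich, aggregates, k = 5L, seed = 1L) {
  ctrl <- enrich[enrich$site == "control", , drop = FALSE]
  if (nrow(ctrl) < k) stop("not enough control sgRNAs")
  set.seed(seed)
  idx <- sample(nrow(ctrl))
  ngrp <- floor(nrow(ctrl) / k)
  grp <- rep(seq_len(ngrp), each = k)
  mfc <- tapply(ctrl$log2fc[idx[seq_along(grp)]], grp, mean)
  pct <- vapply(mfc, function(m) mean(aggregates$mean_log2fc > m), 0)
  data.frame(pseudo_site = sprintf("ctrl_%d", seq_len(ngrp)),
             mean_log2fc = as.numeric(mfc), rank_percentile = pct,
             stringsAsFactors = FALSE)
}

#' Select candidate screen sites on HGRs
#'
#' Sites with positive mean log2 fold change whose interval overlaps an
#' HGR.
#'
#' @param aggregates output of [aggregate_sites_rra()].
#' @param site_peaks peak set giving each site's interval (ids = site ids).
#' @param hgrs HGR peak set.
#' @return subset of `aggregates` with an `hgr_id` column.
#' @export
select_candidate_sites <- function(aggregates, site_peaks, hgrs) {
  pos <- aggregates[aggregates$mean_log2fc > 0, , drop = FALSE]
  if (nrow(pos) == 0L || nrow(hgrs) == 0L) {
    pos$hgr_id <- character(0)
    return(pos)
  }
  sp <- site_peaks[site_peaks$id %in% pos$site, , drop = FALSE]
  ov <- intersect_peaks(sp, peak_set(hgrs$chrom, hgrs$start, hgrs$end,
                                     id = hgrs$id))
  hit <- vapply(split(ov$id_b, ov$id_a),
                function(x) paste(sort(unique(x)), collapse = ","), "")
  pos <- pos[pos$site %in% names(hit), , drop = FALSE]
  pos$hgr_id <- unname(hit[pos$site])
  pos
}
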