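## ATAC-STARR-seq activity calling: library downsampling, a binomial caller
## of RNA output vs DNA input, a replicate count-model caller, condition
## specificity classes and the downstream enrichment battery.

#' Downsample RNA libraries to a common depth
#'
#' Each condition's library is reduced to the minimum library total by
#' seeded sampling of read units without replacement (sequential
#' hypergeometric draws over regions), so totals are exactly equal
#' afterwards and per-region expected proportions are preserved.
#'
#' @param rna_counts matrix, regions x conditions, of RNA output counts.
#' @param seed integer seed.
#' @return matrix of the same shape with equalized column totals.
#' @export
downsample_libraries <- function(rna_counts, seed = 1L) {
  rna_counts <- as.matrix(rna_counts)
  if (ncol(rna_counts) < 2L) stop("need >= 2 conditions")
  totals <- colSums(rna_counts)
  if (any(totals == 0)) stop("zero-total library cannot be downsampled")
  target <- min(totals)
  out <- rna_counts
  set.seed(seed)
  for (j in seq_len(ncol(rna_counts))) {
    if (totals[j] == target) next
    counts <- rna_counts[, j]
    remaining <- totals[j]
    draw <- target
    for (i in seq_along(counts)) {
      if (draw == 0) { out[i:length(counts), j] <- 0; break }
      x <- rhyper(1, counts[i], remaining - counts[i], draw)
      out[i, j] <- x
      draw <- draw - x
      remaining <- remaining - counts[i]
    }
  }
  out
}

#' Binomial STARR-seq activity caller
#'
#' Per region, with x its RNA count, n the condition's total RNA reads and
#' p0 its DNA-input proportion, activity requires an upper-tail binomial
#' p below `p_max` and DNA coverage of at least `min_dna` (the proportion
#' test is unstable at low input coverage).
#'
#' @param dna_counts named vector of DNA input counts per region.
#' @param rna_counts named vector of RNA output counts (one condition,
#'   downsampled).
#' @param p_max significance cutoff (default 0.001).
#' @param min_dna minimum DNA count (default 10).
#' @return data.frame: region, dna, rna, p, active.
#' @export
call_active_binomial <- function(dna_counts, rna_counts, p_max = 0.001,
                                 min_dna = 10L) {
  regions <- names(dna_counts)
  stopifnot(!is.null(regions), identical(regions, names(rna_counts)))
  total_dna <- sum(dna_counts)
  total_rna <- sum(rna_counts)
  p0 <- dna_counts / total_dna
  ok <- dna_counts > 0
  p <- rep(NA_real_, length(dna_counts))
  p[ok] <- binomial_upper_tail(rna_counts[ok], total_rna, p0[ok])
  data.frame(region = regions, dna = as.integer(dna_counts),
             rna = as.integer(rna_counts), p = p,
             active = !is.na(p) & p < p_max & dna_counts >= min_dna,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count-model STARR-seq activity caller
#'
#' NB differential test of RNA-output replicates against pooled-input
#' replicates (the same engine as the chromatin differential analysis);
#' active regions have q < `q_max` with positive log2 fold change.
#'
#' @param rna_reps matrix, regions x RNA replicates.
#' @param input_reps matrix, regions x input replicates.
#' @param q_max FDR cutoff (default 0.05).
#' @return data.frame: region, log2fc, p, q, active.
#' @export
call_active_countmodel <- function(rna_reps, input_reps, q_max = 0.05) {
  if (ncol(rna_reps) < 2L || ncol(input_reps) < 2L) {
    stop("need >= 2 replicates per side")
  }
  stopifnot(identical(rownames(rna_reps), rownames(input_reps)))
  counts <- cbind(rna_reps, input_reps)
  colnames(counts) <- c(sprintf("rna_%d", seq_len(ncol(rna_reps))),
                        sprintf("input_%d", seq_len(ncol(input_reps))))
  group <- rep(c("rna", "input"), c(ncol(rna_reps), ncol(input_reps)))
  res <- diff_test(counts, group, treated = "rna", reference = "input")
  data.frame(region = res$feature, log2fc = res$log2fc, p = res$p, q = res$q,
             active = !is.na(res$q) & res$q < q_max & res$log2fc > 0,
             stringsAsFactors = FALSE)
}

#' Classify STARR-seq condition specificity
#'
#' GC-active = union of the 6 h and 24 h active sets (merged by >= 1 bp
#' overlap). Classes: `GC_specific` (GC-active with no overlapping 0 h
#' active site), `h0_specific` (0 h active with no overlapping GC-active
#' site), `shared`, `inactive`.
#'
#' @param regions peak set of all assayed regions.
#' @param active_0h,active_6h,active_24h character vectors of active region
#'   ids per condition.
#' @return data.frame: region id and class.
#' @export
classify_condition_specificity <- function(regions, active_0h, active_6h,
                                           active_24h) {
  gc_ids <- union(active_6h, active_24h)
  sub <- function(ids) {
    regions[regions$id %in% ids, , drop = FALSE]
  }
  overlap_ids <- function(a_ids, b_ids) {
    a <- sub(a_ids); b <- sub(b_ids)
    if (nrow(a) == 0L || nrow(b) == 0L) return(character(0))
    unique(intersect_peaks(a, b)$id_a)
  }
  gc_touch_0h <- overlap_ids(gc_ids, active_0h)
  h0_touch_gc <- overlap_ids(active_0h, gc_ids)
  cls <- rep("inactive", nrow(regions))
  cls[regions$id %in% gc_ids] <- "GC_specific"
  cls[regions$id %in% active_0h] <- "h0_specific"
  cls[regions$id %in% union(gc_touch_0h, h0_touch_gc)] <- "shared"
  data.frame(region = regions$id, class = cls, stringsAsFactors = FALSE)
}

#' Downstream STARR-seq enrichment battery
#'
#' Three tests: (i) Fisher's exact of responsive-vs-not accessibility by
#' GC-active-vs-not activity; (ii) chi-square comparing GRE fractions in
#' GC-specific vs 0 h-specific actives, with the fold ratio of fractions;
#' (iii) K-S comparing distances to upregulated-DEG TSSs of GC-specific vs
#' 0 h-specific actives.
#'
#' @param regions peak set of assayed regions.
#' @param classes data.frame from [classify_condition_specificity()].
#' @param responsive_ids region ids with responsive accessibility.
#' @param gre_ids region ids bearing a GRE.
#' @param up_genes gene models of upregulated DEGs.
#' @return list with elements `responsive_fisher`, `gre_chisq`, `deg_ks`
#'   (each NULL with a warning when a class is empty).
#' @export
starr_enrichment_tests <- function(regions, classes, responsive_ids,
                                   gre_ids, up_genes) {
  cls <- setNames(classes$class, classes$region)[regions$id]
  gc_active <- cls %in% c("GC_specific", "shared")
  responsive <- regions$id %in% responsive_ids
  out <- list(responsive_fisher = NULL, gre_chisq = NULL, deg_ks = NULL)
  if (any(gc_active) && any(!gc_active)) {
    ft <- fisher_exact(sum(responsive & gc_active),
                       sum(!responsive & gc_active),
                       sum(responsive & !gc_active),
                       sum(!responsive & !gc_active))
    out$responsive_fisher <- ft
  } else warning("empty activity stratum; Fisher test skipped")
  gcs <- regions$id[cls == "GC_specific"]
  h0s <- regions$id[cls == "h0_specific"]
  if (length(gcs) > 0L && length(h0s) > 0L) {
    g1 <- sum(gcs %in% gre_ids); g0 <- sum(h0s %in% gre_ids)
    tab <- matrix(c(g1, length(gcs) - g1, g0, length(h0s) - g0), 2,
                  byrow = TRUE)
    cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
    frac1 <- g1 / length(gcs); frac0 <- g0 / length(h0s)
    out$gre_chisq <- list(p = unname(cs$p.value),
                          fold = if (frac0 > 0) frac1 / frac0 else Inf,
                          frac_gc_specific = frac1, frac_0h_specific = frac0)
    if (!is.null(up_genes) && nrow(up_genes) >= 1L) {
      d_gc <- nearest_tss_distance(
        regions[regions$id %in% gcs, , drop = FALSE], up_genes)$abs_distance
      d_h0 <- nearest_tss_distance(
        regions[regions$id %in% h0s, , drop = FALSE], up_genes)$abs_distance
      d_gc <- d_gc[!is.na(d_gc)]; d_h0 <- d_h0[!is.na(d_h0)]
      if (length(d_gc) >= 2L && length(d_h0) >= 2L) {
        out$deg_ks <- ks_two_sample(d_gc, d_h0)
      }
    }
  } else warning("empty specificity class; chi-square/K-S skipped")
  out
}
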