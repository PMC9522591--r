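## Super-enhancer calling: rank ordering of stitched H3K27ac regions with a
## tangent ("hockey-stick") cutoff, and classification of GC-responsive SEs.

#' Call super-enhancers by rank-ordered signal and tangent cutoff
#'
#' Regions are sorted by ascending signal; ranks and signals are min-max
#' scaled to [0, 1] and the cutoff falls at the first point where the
#' discrete slope of the scaled curve exceeds `slope_min` (the tangent rule
#' with unit slope by default). Regions at or above the cutoff are
#' super-enhancers.
#'
#' @param regions data.frame of stitched regions with an `id` column.
#' @param signal numeric vector of total (input-normalized) H3K27ac signal.
#' @param slope_min tangent slope threshold (default 1).
#' @return `regions` augmented with columns `signal`, `rank` (1 = highest
#'   signal) and `is_se`.
#' @export
rank_and_cutoff <- function(regions, signal, slope_min = 1) {
  n <- nrow(regions)
  if (n < 3L) stop("need >= 3 regions to place a tangent cutoff")
  if (length(signal) != n) stop("signal length must match regions")
  if (any(signal < 0)) stop("signal must be non-negative")
  ord <- order(signal, regions$id)   # ascending; ties resolved by id
  s <- signal[ord]
  out <- regions
  out$signal <- signal
  out$rank <- rank(-signal, ties.method = "first")
  if (max(s) == min(s)) {
    warning("all signals equal; no super-enhancers called")
    out$is_se <- FALSE
    return(out)
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  slope <- diff(y) / diff(x)
  cross <- which(slope > slope_min)
  is_se_sorted <- rep(FALSE, n)
  if (length(cross) > 0L) {
    cut_idx <- cross[1L] + 1L          # first point after the slope exceeds
    is_se_sorted[cut_idx:n] <- TRUE
  }
  out$is_se <- FALSE
  out$is_se[ord] <- is_se_sorted
  out
}

#' Classify reproducible GC-responsive super-enhancers
#'
#' A candidate SE is any region called SE at a treated timepoint; it is
#' reproducible iff overlapping (>= 1 bp) SE calls exist at two or more
#' treated timepoints. Reproducible SEs absent at 0 h are `de_novo`; those
#' overlapping a 0 h SE are `pre_established` when the treated/0 h
#' stitched-signal ratio is at least `fold_min`, otherwise `baseline`
#' (excluded from the GC-responsive set).
#'
#' @param se_by_timepoint named list (names = timepoint labels, "0" for
#'   untreated) of data.frames from [rank_and_cutoff()] with chrom/start/end,
#'   `signal` and `is_se` columns.
#' @param fold_min pre-established fold threshold (default 2).
#' @param min_timepoints reproducibility requirement (default 2 treated
#'   timepoints).
#' @return data.frame of GC-responsive SEs: merged interval, supporting
#'   treated timepoints, class, and fold change vs 0 h (NA when no 0 h SE).
#' @export
call_gc_responsive_se <- function(se_by_timepoint, fold_min = 2,
                                  min_timepoints = 2L) {
  tps <- names(se_by_timepoint)
  treated <- setdiff(tps, "0")
  if (length(treated) < 2L) stop("need SE calls for >= 2 treated timepoints")
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      id = character(), timepoints = character(),
                      class = character(), fold_change_vs_0h = numeric(),
                      stringsAsFactors = FALSE)
  tr_se <- lapply(treated, function(tp) {
    d <- se_by_timepoint[[tp]]
    d <- d[d$is_se, , drop = FALSE]
    if (nrow(d) > 0L) d$timepoint <- tp
    d
  })
  all_tr <- do.call(rbind, lapply(tr_se, function(d) {
    d[, c("chrom", "start", "end", "signal", "timepoint"), drop = FALSE]
  }))
  if (is.null(all_tr) || nrow(all_tr) == 0L) return(empty)
  gr <- GenomicRanges::GRanges(all_tr$chrom,
                               IRanges::IRanges(all_tr$start + 1L, all_tr$end))
  merged <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  grp <- S4Vectors::subjectHits(hits)
  se0 <- se_by_timepoint[["0"]]
  se0 <- if (!is.null(se0)) se0[se0$is_se, , drop = FALSE] else NULL
  gr0 <- if (!is.null(se0) && nrow(se0) > 0L) {
    GenomicRanges::GRanges(se0$chrom, IRanges::IRanges(se0$start + 1L, se0$end))
  } else NULL
  rows <- lapply(seq_along(merged), function(i) {
    members <- all_tr[grp == i, , drop = FALSE]
    tp_sup <- sort(unique(members$timepoint))
    if (length(tp_sup) < min_timepoints) return(NULL)
    sig_tr <- max(members$signal)
    chrom <- as.character(GenomicRanges::seqnames(merged))[i]
    start <- GenomicRanges::start(merged)[i] - 1L
    end <- GenomicRanges::end(merged)[i]
    fold <- NA_real_
    cls <- "de_novo"
    if (!is.null(gr0)) {
      ov0 <- S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gr0, merged[i]))
      if (length(ov0) > 0L) {
        sig0 <- max(se0$signal[ov0])
        fold <- sig_tr / sig0
        cls <- if (fold >= fold_min) "pre_established" else "baseline"
      }
    }
    data.frame(chrom = chrom, start = start, end = end,
               timepoints = paste(tp_sup, collapse = ","),
               class = cls, fold_change_vs_0h = fold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[out$class != "baseline", , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out$id <- sprintf("gcse_%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "id", "timepoints", "class",
          "fold_change_vs_0h")]
}
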