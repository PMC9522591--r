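## High-confidence GR regulatory sites (HGRs): GR ChIP peaks supported by
## ATAC and H3K27ac at the same timepoint, GRE motif annotation, and the
## enrichment tests that tie them to responsive chromatin and genes.

#' The canonical glucocorticoid response element PWM
#'
#' A fixed 15-column log-odds matrix (base 2, uniform 0.25 background)
#' encoding the palindromic nuclear-receptor element GR binds: two 6-bp
#' half-sites (GGTACA ... TGTTCT) separated by a 3-bp spacer. Consensus
#' bases carry probability 0.85 (0.05 elsewhere); spacer columns are
#' uniform. This is a canonical-consensus construction, not a matrix fitted
#' to data.
#'
#' @return 4 x 15 numeric matrix, rownames A/C/G/T, of log2 odds scores.
#' @export
gre_pwm <- function() {
  consensus <- strsplit("GGTACANNNTGTTCT", "")[[1]]
  bases <- c("A", "C", "G", "T")
  probs <- sapply(consensus, function(b) {
    if (b == "N") rep(0.25, 4)
    else ifelse(bases == b, 0.85, 0.05)
  })
  rownames(probs) <- bases
  colnames(probs) <- NULL
  log2(probs / 0.25)
}

#' Best PWM hit in a sequence
#'
#' Scores every offset on both strands with a log-odds PWM; `N` (or any
#' non-ACGT character) scores as the worst base of its column. A hit is
#' declared when the best score reaches `threshold_frac` of the maximal
#' achievable PWM score.
#'
#' @param sequence a single DNA string (character).
#' @param pwm 4 x L log-odds matrix with rownames A/C/G/T.
#' @param threshold_frac fraction of the maximal achievable score required
#'   for a hit (default 0.8).
#' @return list: `hit` (logical), `score`, `position` (1-based offset on the
#'   given sequence), `strand`; `hit = FALSE` with NA fields when the
#'   sequence is shorter than the motif.
#' @export
scan_pwm <- function(sequence, pwm, threshold_frac = 0.8) {
  L <- ncol(pwm)
  seq_up <- toupper(sequence)
  n <- nchar(seq_up)
  miss <- list(hit = FALSE, score = NA_real_, position = NA_integer_,
               strand = NA_character_)
  if (n < L) return(miss)
  max_score <- sum(apply(pwm, 2L, max))
  score_strand <- function(s) {
    chars <- strsplit(s, "")[[1]]
    idx <- match(chars, c("A", "C", "G", "T"))
    worst <- apply(pwm, 2L, min)
    n_off <- length(chars) - L + 1L
    scores <- numeric(n_off)
    for (j in seq_len(L)) {
      b <- idx[j:(j + n_off - 1L)]
      col <- pwm[, j]
      sc <- col[b]
      sc[is.na(b)] <- worst[j]
      scores <- scores + sc
    }
    scores
  }
  revcomp <- function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  fwd <- score_strand(seq_up)
  rev <- score_strand(revcomp(seq_up))
  best_f <- which.max(fwd); best_r <- which.max(rev)
  if (fwd[best_f] >= rev[best_r]) {
    best <- fwd[best_f]; pos <- best_f; strand <- "+"
  } else {
    best <- rev[best_r]
    pos <- n - L + 2L - best_r   # map back to forward-strand offset
    strand <- "-"
  }
  list(hit = best >= threshold_frac * max_score, score = unname(best),
       position = as.integer(pos), strand = strand)
}

#' Call high-confidence GR sites (HGRs)
#'
#' Per timepoint, a GR peak qualifies iff it overlaps (>= 1 bp) both an
#' ATAC peak and an H3K27ac peak at that timepoint. The final set is the
#' union over timepoints of qualifying GR peaks, merged when overlapping,
#' keeping the supporting-timepoint list. The HGR footprint is always the
#' GR peak (or a merge of overlapping GR peaks), never the ATAC or H3K27ac
#' interval.
#'
#' @param gr_peaks,atac_peaks,k27_peaks named lists of peak sets, one entry
#'   per timepoint label; timepoints missing any assay are skipped with a
#'   warning.
#' @return peak-set-like data.frame with columns chrom, start, end, id,
#'   timepoints (comma-joined supporting labels), constituent_gr (comma-
#'   joined original GR peak ids).
#' @export
call_hgrs <- function(gr_peaks, atac_peaks, k27_peaks) {
  tps <- names(gr_peaks)
  qual <- list()
  for (tp in sort(tps)) {
    if (is.null(atac_peaks[[tp]]) || is.null(k27_peaks[[tp]])) {
      warning(sprintf("timepoint %s missing an assay; skipped", tp))
      next
    }
    g <- gr_peaks[[tp]]
    if (nrow(g) == 0L) next
    hit_a <- unique(intersect_peaks(g, atac_peaks[[tp]])$id_a)
    hit_k <- unique(intersect_peaks(g, k27_peaks[[tp]])$id_a)
    keep <- g[g$id %in% intersect(hit_a, hit_k), , drop = FALSE]
    if (nrow(keep) > 0L) {
      keep$timepoint <- tp
      qual[[tp]] <- keep
    }
  }
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      id = character(), timepoints = character(),
                      constituent_gr = character(), stringsAsFactors = FALSE)
  if (length(qual) == 0L) return(empty)
  allq <- do.call(rbind, lapply(qual, function(d) {
    d[, c("chrom", "start", "end", "id", "timepoint"), drop = FALSE]
  }))
  gr <- GenomicRanges::GRanges(allq$chrom,
                               IRanges::IRanges(allq$start + 1L, allq$end))
  merged <- GenomicRanges::reduce(gr)
  grp <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(gr, merged))
  tp_by <- vapply(split(allq$timepoint, grp),
                  function(x) paste(sort(unique(x)), collapse = ","), "")
  gr_by <- vapply(split(allq$id, grp),
                  function(x) paste(sort(unique(x)), collapse = ","), "")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    id = sprintf("hgr_%d", seq_along(merged)),
    timepoints = unname(tp_by[as.character(seq_along(merged))]),
    constituent_gr = unname(gr_by[as.character(seq_along(merged))]),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate HGRs with GRE motif presence
#'
#' @param hgrs HGR data.frame from [call_hgrs()].
#' @param sequences named character vector of DNA sequences, one per HGR id
#'   (or per region covering the HGR).
#' @param pwm log-odds matrix (default [gre_pwm()]).
#' @param threshold_frac hit threshold as fraction of max score.
#' @return `hgrs` with columns `has_gre` and `best_motif_score`.
#' @export
annotate_gre <- function(hgrs, sequences, pwm = gre_pwm(),
                         threshold_frac = 0.8) {
  res <- lapply(hgrs$id, function(i) {
    s <- sequences[[i]]
    if (is.null(s) || is.na(s)) return(list(hit = FALSE, score = NA_real_))
    scan_pwm(s, pwm, threshold_frac)
  })
  hgrs$has_gre <- vapply(res, function(r) isTRUE(r$hit), logical(1))
  hgrs$best_motif_score <- vapply(res, function(r) r$score %||% NA_real_,
                                  numeric(1))
  hgrs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' GRE x responsive-chromatin enrichment
#'
#' Tests whether GRE-bearing HGRs preferentially carry enhanced chromatin
#' responses: Fisher's exact on the 2x2 of {GRE, no GRE} x
#' {enhanced-responsive, not}.
#'
#' @param hgrs HGR data.frame with `has_gre`.
#' @param enhanced_ids ids of HGRs overlapping enhanced-responsive chromatin.
#' @return list: `table` (2x2 matrix), `odds_ratio`, `p`.
#' @export
gre_response_enrichment <- function(hgrs, enhanced_ids) {
  gre <- hgrs$has_gre
  enh <- hgrs$id %in% enhanced_ids
  if (!any(gre) || all(gre)) stop("need both GRE and non-GRE HGRs")
  a <- sum(gre & enh); b <- sum(gre & !enh)
  c_ <- sum(!gre & enh); d <- sum(!gre & !enh)
  ft <- fisher_exact(a, b, c_, d)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("gre", "no_gre"), c("enhanced", "not")))
  list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p)
}

#' Distance-to-DEG K-S tests for directional HGRs
#'
#' For HGRs with enhanced chromatin responses, compares the distribution of
#' distances to the nearest upregulated-gene TSS against distances to the
#' nearest downregulated-gene TSS (and the reduced/down analogue):
#' concordant wiring shows up as a shift toward the concordant direction.
#'
#' @param hgrs_by_direction named list (`enhanced`, `reduced`) of HGR
#'   data.frames.
#' @param degs_by_direction named list (`up`, `down`) of gene-model
#'   data.frames.
#' @return data.frame with one row per (hgr_direction) pairing: D and p of
#'   the concordant-vs-discordant distance comparison.
#' @export
hgr_deg_distance_test <- function(hgrs_by_direction, degs_by_direction) {
  pairing <- list(enhanced = c("up", "down"), reduced = c("down", "up"))
  rows <- lapply(names(pairing), function(dir) {
    h <- hgrs_by_direction[[dir]]
    if (is.null(h) || nrow(h) == 0L) return(NULL)
    conc_genes <- degs_by_direction[[pairing[[dir]][1L]]]
    disc_genes <- degs_by_direction[[pairing[[dir]][2L]]]
    if (is.null(conc_genes) || nrow(conc_genes) < 2L ||
        is.null(disc_genes) || nrow(disc_genes) < 2L) {
      stop("need >= 2 genes in each DEG direction")
    }
    d_conc <- nearest_tss_distance(h, conc_genes)$abs_distance
    d_disc <- nearest_tss_distance(h, disc_genes)$abs_distance
    ok <- !is.na(d_conc) & !is.na(d_disc)
    kt <- ks_two_sample(d_conc[ok], d_disc[ok])
    data.frame(hgr_direction = dir, concordant_deg = pairing[[dir]][1L],
               D = kt$D, p = kt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
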