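## HiChIP loop annotation and linkage of responsive chromatin to DEG
## promoters. Loops arrive as anchor pairs with q-values (already filtered
## to q < 0.01 upstream); anchors are classed promoter/distal by TSS
## proximity and linkage statistics are computed on unambiguous
## distal -> promoter loops only.

#' Read a loop table
#'
#' Seven tab-separated columns with header:
#' chrA, startA, endA, chrB, startB, endB, q.
#'
#' @param path TSV path.
#' @return data.frame of loops with a `loop_id` column.
#' @export
read_loops <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrA", "startA", "endA", "chrB", "startB", "endB", "q")
  if (!all(need %in% names(d))) {
    stop("loop table needs columns: ", paste(need, collapse = ", "))
  }
  d$loop_id <- sprintf("loop_%d", seq_len(nrow(d)))
  d
}

anchor_peakset <- function(loops, side) {
  suf <- if (side == 1L) "A" else "B"
  peak_set(loops[[paste0("chr", suf)]], loops[[paste0("start", suf)]],
           loops[[paste0("end", suf)]],
           id = sprintf("%s_%s", loops$loop_id, suf))
}

#' Annotate loop anchors as promoter or distal
#'
#' An anchor is a promoter anchor iff it overlaps any TSS within
#' `promoter_window_bp`; the genes whose promoter windows it touches are
#' recorded. Loop class is `distal_promoter`, `promoter_promoter`,
#' or `distal_distal`. Self-loops (identical anchors) are rejected.
#'
#' @param loops loop data.frame (see [read_loops()]).
#' @param genes gene models.
#' @param promoter_window_bp half-width of the promoter window around each
#'   TSS (default 2000).
#' @return `loops` with columns classA/classB (promoter/distal),
#'   genesA/genesB (comma-joined gene ids) and `class`.
#' @export
annotate_loops <- function(loops, genes, promoter_window_bp = 2000L) {
  validate_gene_models(genes)
  self <- loops$chrA == loops$chrB & loops$startA == loops$startB &
    loops$endA == loops$endB
  if (any(self)) {
    warning(sprintf("%d self-loops rejected", sum(self)))
    loops <- loops[!self, , drop = FALSE]
  }
  if (nrow(loops) == 0L) {
    loops$classA <- loops$classB <- loops$genesA <- loops$genesB <-
      loops$class <- character(0)
    return(loops)
  }
  prom <- peak_set(genes$chrom,
                   pmax(genes$tss - promoter_window_bp, 0L),
                   genes$tss + promoter_window_bp,
                   id = genes$gene_id)
  side_genes <- function(side) {
    anch <- anchor_peakset(loops, side)
    ov <- intersect_peaks(anch, prom)
    g <- vapply(split(ov$id_b, ov$id_a),
                function(x) paste(sort(unique(x)), collapse = ","), "")
    out <- setNames(rep("", nrow(loops)), anch$id)
    out[names(g)] <- g
    # anchor ids were sorted inside peak_set; restore loop order
    out[sprintf("%s_%s", loops$loop_id, if (side == 1L) "A" else "B")]
  }
  loops$genesA <- unname(side_genes(1L))
  loops$genesB <- unname(side_genes(2L))
  loops$classA <- ifelse(nzchar(loops$genesA), "promoter", "distal")
  loops$classB <- ifelse(nzchar(loops$genesB), "promoter", "distal")
  loops$class <- ifelse(
    loops$classA == "promoter" & loops$classB == "promoter",
    "promoter_promoter",
    ifelse(loops$classA == "distal" & loops$classB == "distal",
           "distal_distal", "distal_promoter"))
  loops
}

#' Link responsive chromatin to DEG promoters through loops
#'
#' Restricts to unambiguous distal -> promoter loops, classes the distal
#' anchor by overlap with enhanced/reduced responsive H3K27ac sites and the
#' promoter genes by DEG direction, and tests with Fisher's exact whether
#' enhanced sites loop preferentially to upregulated promoters (2x2 of
#' {enhanced, reduced} x {up, down}; the odds ratio is oriented
#' enhanced-to-up). Each (loop, gene) pair counts once.
#'
#' @param annotated loops from [annotate_loops()].
#' @param degs data.frame with columns gene_id, direction (`up`/`down`).
#' @param responsive_k27 peak set of responsive H3K27ac sites with a
#'   `direction` column (`enhanced`/`reduced`).
#' @param hgrs optional HGR peak set; when given, the fraction of
#'   DEG-promoter loops whose distal anchor overlaps an HGR is reported.
#' @return list: `table` (2x2), `odds_ratio`, `p`, `n_deg_loops`,
#'   `frac_deg_loops_with_hgr`, `frac_degs_looped`.
#' @export
loop_deg_linkage <- function(annotated, degs, responsive_k27, hgrs = NULL) {
  dp <- annotated[annotated$class == "distal_promoter", , drop = FALSE]
  empty <- list(table = matrix(0L, 2, 2,
                               dimnames = list(c("enhanced", "reduced"),
                                               c("up", "down"))),
                odds_ratio = NA_real_, p = NA_real_, n_deg_loops = 0L,
                frac_deg_loops_with_hgr = NA_real_,
                frac_degs_looped = NA_real_)
  if (nrow(dp) == 0L) {
    warning("no distal-promoter loops")
    return(empty)
  }
  distal_side <- ifelse(dp$classA == "distal", 1L, 2L)
  distal <- peak_set(
    ifelse(distal_side == 1L, dp$chrA, dp$chrB),
    ifelse(distal_side == 1L, dp$startA, dp$startB),
    ifelse(distal_side == 1L, dp$endA, dp$endB),
    id = dp$loop_id)
  site_dir <- function(direction) {
    sites <- responsive_k27[responsive_k27$direction == direction, , drop = FALSE]
    if (nrow(sites) == 0L) return(character(0))
    unique(intersect_peaks(distal, peak_set(sites$chrom, sites$start,
                                            sites$end, id = sites$id))$id_a)
  }
  enh_loops <- site_dir("enhanced")
  red_loops <- setdiff(site_dir("reduced"), enh_loops)
  prom_genes <- ifelse(dp$classA == "promoter", dp$genesA, dp$genesB)
  gene_list <- strsplit(prom_genes, ",", fixed = TRUE)
  pairs <- data.frame(
    loop_id = rep(dp$loop_id, lengths(gene_list)),
    gene_id = unlist(gene_list), stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  pairs <- merge(pairs, degs[, c("gene_id", "direction")], by = "gene_id")
  n_deg_loops <- length(unique(pairs$loop_id))
  if (nrow(pairs) == 0L) {
    warning("no DEG-promoter loops")
    return(empty)
  }
  pairs$site <- ifelse(pairs$loop_id %in% enh_loops, "enhanced",
                       ifelse(pairs$loop_id %in% red_loops, "reduced", NA))
  tabd <- pairs[!is.na(pairs$site), , drop = FALSE]
  a <- sum(tabd$site == "enhanced" & tabd$direction == "up")
  b <- sum(tabd$site == "enhanced" & tabd$direction == "down")
  c_ <- sum(tabd$site == "reduced" & tabd$direction == "up")
  d <- sum(tabd$site == "reduced" & tabd$direction == "down")
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("enhanced", "reduced"), c("up", "down")))
  if (sum(tab) == 0L) {
    or <- NA_real_; p <- NA_real_
  } else {
    ft <- fisher_exact(a, b, c_, d)
    or <- ft$odds_ratio; p <- ft$p
  }
  frac_hgr <- NA_real_
  if (!is.null(hgrs) && nrow(hgrs) > 0L && n_deg_loops > 0L) {
    deg_distal <- distal[distal$id %in% pairs$loop_id, , drop = FALSE]
    hit <- unique(intersect_peaks(
      deg_distal, peak_set(hgrs$chrom, hgrs$start, hgrs$end, id = hgrs$id))$id_a)
    frac_hgr <- length(hit) / n_deg_loops
  }
  frac_degs <- if (nrow(degs) > 0L) {
    length(intersect(unique(pairs$gene_id), degs$gene_id)) / nrow(degs)
  } else NA_real_
  list(table = tab, odds_ratio = or, p = p, n_deg_loops = n_deg_loops,
       frac_deg_loops_with_hgr = frac_hgr, frac_degs_looped = frac_degs)
}
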