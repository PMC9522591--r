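#' @import stats
#' @importFrom utils read.table write.table head
NULL

## ---- peak-set representation -------------------------------------------
## A peak set is a plain data.frame with columns chrom, start, end, id and
## optionally strand, using BED conventions: 0-based, half-open [start, end).

#' Construct a peak set
#'
#' Validates and sorts a data.frame of genomic intervals (0-based, half-open).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `start` 0-based inclusive, `end` exclusive.
#' @param id optional unique identifiers; generated as `peak_<n>` if missing.
#' @param strand optional strand, one of `"+"`, `"-"`, `"."`.
#' @return A data.frame with class `peak_set`, sorted by (chrom, start, end).
#' @export
peak_set <- function(chrom, start, end, id = NULL, strand = NULL) {
  if (length(chrom) == 0L) {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     id = character(), strand = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("peak_set", "data.frame")
    return(df)
  }
  if (length(chrom) == 1L) chrom <- rep(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(!nzchar(chrom))) stop("chrom names must be non-empty")
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop(sprintf("interval %d has start >= end (%d >= %d)", bad,
                 start[bad], end[bad]))
  }
  if (any(start < 0)) stop("negative start coordinate")
  if (is.null(id)) id <- sprintf("peak_%d", seq_along(chrom))
  if (anyDuplicated(id)) stop("interval ids must be unique")
  if (is.null(strand)) strand <- rep(".", length(chrom))
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), id = as.character(id),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end, df$id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Convert a peak set to a GRanges
#'
#' Internal bridge to GenomicRanges; BED half-open coordinates become the
#' 1-based closed convention GRanges uses.
#' @param peaks peak-set data.frame.
#' @return GRanges with an `id` metadata column.
#' @keywords internal
peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    id = peaks$id)
}

#' Read a BED file into a peak set
#'
#' Accepts BED3+ (chrom, start, end, and optionally name, score, strand).
#' Input need not be sorted; the returned set is sorted by (chrom, start).
#'
#' @param path path to a BED file (plain text, tab-separated).
#' @return A `peak_set` data.frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(peak_set(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("BED parse error at line %d: fewer than 3 fields",
                 which(nf < 3L)[1L]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("BED parse error at line %d: non-integer coordinate",
                 which(is.na(start) | is.na(end))[1L]))
  }
  if (any(start >= end)) {
    stop(sprintf("BED parse error at line %d: start >= end",
                 which(start >= end)[1L]))
  }
  id <- if (all(nf >= 4L)) vapply(fields, `[[`, "", 4L) else NULL
  strand <- if (all(nf >= 6L)) vapply(fields, `[[`, "", 6L) else NULL
  peak_set(chrom, start, end, id = id, strand = strand)
}

#' Write a peak set to BED
#'
#' Output is sorted by (chrom, start) and written as BED6 with score 0.
#'
#' @param peaks peak-set data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$id, 0L,
                    peaks$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene models from TSV
#'
#' Five columns: gene_id, chrom, tss, strand, biotype.
#' @param path TSV path with header.
#' @return data.frame of gene models.
#' @export
read_gene_models <- function(path) {
  g <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_gene_models(g)
  g
}

validate_gene_models <- function(genes) {
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(genes))) {
    stop("gene models need columns: ", paste(need, collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  invisible(genes)
}

## ---- interval algebra ---------------------------------------------------

#' Overlapping interval pairs between two peak sets
#'
#' Reports every pair (a, b) whose overlap is at least `min_overlap_bp`.
#'
#' @param a,b peak-set data.frames.
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @return data.frame with columns `id_a`, `id_b`, `overlap_bp`.
#' @export
intersect_peaks <- function(a, b, min_overlap_bp = 1L) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
                      overlap_bp = integer(), stringsAsFactors = FALSE))
  }
  gra <- peaks_to_granges(a)
  grb <- peaks_to_granges(b)
  hits <- GenomicRanges::findOverlaps(gra, grb,
                                      minoverlap = as.integer(min_overlap_bp))
  qa <- S4Vectors::queryHits(hits)
  sb <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[qa], b$end[sb]) - pmax(a$start[qa], b$start[sb])
  data.frame(id_a = a$id[qa], id_b = b$id[sb], overlap_bp = as.integer(ov),
             stringsAsFactors = FALSE)
}

#' Stitch nearby peaks into regions
#'
#' Merges same-chromosome peaks whose inter-peak gap is at most `gap_bp`
#' (ROSE-style stitching; the super-enhancer default is 12500 bp).
#'
#' @param peaks peak-set data.frame.
#' @param gap_bp maximum gap closed by stitching.
#' @return data.frame of stitched regions with columns chrom, start, end, id,
#'   n_constituents and a list-column `constituents` of member peak ids.
#' @export
stitch_peaks <- function(peaks, gap_bp) {
  if (gap_bp < 0) stop("gap_bp must be >= 0")
  if (nrow(peaks) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      id = character(), n_constituents = integer())
    out$constituents <- list()
    return(out)
  }
  gr <- peaks_to_granges(peaks)
  red <- GenomicRanges::reduce(gr, min.gapwidth = as.integer(gap_bp) + 1L)
  hits <- GenomicRanges::findOverlaps(gr, red, maxgap = as.integer(gap_bp))
  members <- split(peaks$id[S4Vectors::queryHits(hits)],
                   S4Vectors::subjectHits(hits))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    id = sprintf("stitched_%d", seq_along(red)),
    n_constituents = lengths(members),
    stringsAsFactors = FALSE)
  out$constituents <- unname(members)
  out
}

#' Distance to the nearest TSS
#'
#' For each region, the minimal absolute distance from the region midpoint to
#' any TSS, with ties broken by the lexicographically smaller gene id. The
#' signed distance is midpoint minus TSS.
#'
#' @param regions peak-set data.frame.
#' @param genes gene-model data.frame (gene_id, chrom, tss, strand).
#' @return data.frame with columns id, gene_id, distance (signed),
#'   abs_distance.
#' @export
nearest_tss_distance <- function(regions, genes) {
  if (nrow(genes) == 0L) stop("empty gene set")
  validate_gene_models(genes)
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  mid <- (regions$start + regions$end) %/% 2L
  res <- lapply(seq_len(nrow(regions)), function(i) {
    cand <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0L) return(c(gene = NA_character_, dist = NA_character_))
    d <- mid[i] - cand$tss
    j <- which.min(abs(d))  # genes sorted by id => ties pick smaller id
    c(gene = cand$gene_id[j], dist = as.character(d[j]))
  })
  out <- data.frame(id = regions$id,
                    gene_id = vapply(res, `[[`, "", 1L),
                    distance = as.integer(vapply(res, `[[`, "", 2L)),
                    stringsAsFactors = FALSE)
  out$abs_distance <- abs(out$distance)
  out
}

#' Associate regions to genes by regulatory domains
#'
#' Implements the basal-plus-extension association rule: each gene gets a
#' basal domain of 5 kb upstream and 1 kb downstream of its TSS
#' (strand-aware), extended in both directions up to `max_extension_bp` or
#' until the neighboring gene's basal domain. A region is associated with
#' every gene whose regulatory domain it overlaps.
#'
#' @param regions peak-set data.frame.
#' @param genes gene-model data.frame.
#' @param upstream_bp,downstream_bp basal domain geometry (defaults 5000/1000).
#' @param max_extension_bp maximum extension (default 1 Mb).
#' @return data.frame with columns region_id, gene_id (one row per pair).
#' @export
associate_regions_to_genes <- function(regions, genes,
                                       upstream_bp = 5000L,
                                       downstream_bp = 1000L,
                                       max_extension_bp = 1000000L) {
  validate_gene_models(genes)
  empty <- data.frame(region_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0L || nrow(genes) == 0L) return(empty)
  plus <- genes$strand == "+"
  basal_start <- ifelse(plus, genes$tss - upstream_bp, genes$tss - downstream_bp)
  basal_end <- ifelse(plus, genes$tss + downstream_bp, genes$tss + upstream_bp)
  basal_start <- pmax(basal_start, 0L)
  dom <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    tss = genes$tss,
                    basal_start = as.integer(basal_start),
                    basal_end = as.integer(basal_end),
                    stringsAsFactors = FALSE)
  dom <- dom[order(dom$chrom, dom$tss, dom$gene_id), , drop = FALSE]
  dom$dom_start <- dom$basal_start
  dom$dom_end <- dom$basal_end
  for (ch in unique(dom$chrom)) {
    idx <- which(dom$chrom == ch)
    for (k in seq_along(idx)) {
      i <- idx[k]
      lo <- max(dom$tss[i] - max_extension_bp, 0L)
      hi <- dom$tss[i] + max_extension_bp
      if (k > 1L) lo <- max(lo, max(dom$basal_end[idx[seq_len(k - 1L)]]))
      if (k < length(idx)) hi <- min(hi, min(dom$basal_start[idx[(k + 1L):length(idx)]]))
      # the basal domain is always retained, even when neighbors overlap it
      dom$dom_start[i] <- min(dom$basal_start[i], lo)
      dom$dom_end[i] <- max(dom$basal_end[i], hi)
    }
  }
  dgr <- GenomicRanges::GRanges(dom$chrom,
                                IRanges::IRanges(dom$dom_start + 1L, dom$dom_end))
  rgr <- peaks_to_granges(regions)
  hits <- GenomicRanges::findOverlaps(rgr, dgr)
  out <- data.frame(region_id = regions$id[S4Vectors::queryHits(hits)],
                    gene_id = dom$gene_id[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$region_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
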