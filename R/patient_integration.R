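## Cohort-level analyses: resistance-associated accessibility (inter- and
## intra-subtype), methylation concordance, HGR enrichment, LD-based
## fine-mapping of regulatory variants with allele-specific GRE scoring,
## and the final candidate-HGR prioritization funnel.

#' Stratify a cohort by resistance phenotype
#'
#' @param phenotype named numeric vector (higher = more resistant, e.g.
#'   LC50).
#' @param rule `"median_split"`, `"threshold"` (with `value`), or
#'   `"provided"` (with `labels`).
#' @param value threshold for the threshold rule.
#' @param labels named character vector (`sensitive`/`resistant`) for the
#'   provided rule.
#' @return named character vector of class labels.
#' @export
stratify_resistance <- function(phenotype,
                                rule = c("median_split", "threshold",
                                         "provided"),
                                value = NULL, labels = NULL) {
  rule <- match.arg(rule)
  if (rule == "provided") {
    if (is.null(labels)) stop("provided rule needs labels")
    labels <- labels[names(phenotype)]
    if (anyNA(labels)) stop("labels must cover every sample")
    return(labels)
  }
  cut <- if (rule == "median_split") median(phenotype) else value
  if (is.null(cut)) stop("threshold rule needs a value")
  out <- ifelse(phenotype > cut, "resistant", "sensitive")
  if (length(unique(out)) < 2L) {
    stop("degenerate split: one class is empty")
  }
  setNames(out, names(phenotype))
}

#' Resistance-associated differential accessibility
#'
#' NB differential test of resistant vs sensitive patients, run on all
#' samples (inter-subtype arm) and within every subtype having at least
#' `min_subtype_n` samples and both classes represented (intra-subtype
#' arms). The result is the union of q < `q_max` sites with arm provenance;
#' direction `occluded_in_resistant` means lower accessibility in resistant
#' patients (negative log2fc).
#'
#' @param counts peaks x patients accessibility matrix.
#' @param classes named character vector (`sensitive`/`resistant`).
#' @param subtypes named character vector of subtype labels.
#' @param q_max FDR cutoff (default 0.1).
#' @param min_subtype_n minimum samples for an intra-subtype arm (default 4).
#' @return data.frame: site, arm, log2fc, q, direction.
#' @export
resistance_accessibility <- function(counts, classes, subtypes,
                                     q_max = 0.1, min_subtype_n = 4L) {
  classes <- classes[colnames(counts)]
  subtypes <- subtypes[colnames(counts)]
  run_arm <- function(cols, arm) {
    cl <- classes[cols]
    if (min(table(factor(cl, c("sensitive", "resistant")))) < 2L) {
      warning(sprintf("arm %s skipped: < 2 samples per class", arm))
      return(NULL)
    }
    res <- diff_test(counts[, cols, drop = FALSE], cl,
                     treated = "resistant", reference = "sensitive")
    keep <- !is.na(res$q) & res$q < q_max
    if (!any(keep)) return(NULL)
    data.frame(site = res$feature[keep], arm = arm,
               log2fc = res$log2fc[keep], q = res$q[keep],
               stringsAsFactors = FALSE)
  }
  hits <- list(run_arm(colnames(counts), "inter_subtype"))
  for (st in sort(unique(subtypes))) {
    cols <- colnames(counts)[subtypes == st]
    if (length(cols) < min_subtype_n) {
      warning(sprintf("subtype %s too small; intra-subtype arm skipped", st))
      next
    }
    hits <- c(hits, list(run_arm(cols, paste0("intra_subtype:", st))))
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(site = character(), arm = character(),
                      log2fc = numeric(), q = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  # one row per site: most significant arm wins; arms recorded
  arms <- vapply(split(out$arm, out$site),
                 function(x) paste(sort(unique(x)), collapse = ";"), "")
  out <- out[order(out$q), , drop = FALSE]
  out <- out[!duplicated(out$site), , drop = FALSE]
  out$arm <- unname(arms[out$site])
  out$direction <- ifelse(out$log2fc < 0, "occluded_in_resistant",
                          "open_in_resistant")
  out <- out[order(out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Methylation concordance with accessibility differences
#'
#' A CpG probe overlapping a resistance site is concordant when the sign of
#' its mean beta difference (resistant - sensitive) is opposite to the sign
#' of the site's accessibility log2fc (resistant vs sensitive) — methylation
#' up where chromatin closes. Probes at sites with zero accessibility
#' difference, or with zero beta difference, are excluded from the
#' denominator.
#'
#' @param resistance_sites data.frame from [resistance_accessibility()].
#' @param site_peaks peak set giving site intervals (ids = site ids).
#' @param probes data.frame: probe, chrom, pos (0-based bp).
#' @param betas probes x patients matrix of methylation beta values.
#' @param classes named class vector (`sensitive`/`resistant`).
#' @return list: `per_probe` data.frame (probe, site, beta_diff, log2fc,
#'   concordant) and `fraction`.
#' @export
methylation_concordance <- function(resistance_sites, site_peaks, probes,
                                    betas, classes) {
  if (any(betas < 0 | betas > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  sp <- site_peaks[site_peaks$id %in% resistance_sites$site, , drop = FALSE]
  if (nrow(sp) == 0L || nrow(probes) == 0L) {
    warning("no probes overlap resistance sites")
    return(list(per_probe = NULL, fraction = NA_real_))
  }
  pr <- peak_set(probes$chrom, probes$pos, probes$pos + 1L, id = probes$probe)
  ov <- intersect_peaks(pr, sp)
  if (nrow(ov) == 0L) {
    warning("no probes overlap resistance sites")
    return(list(per_probe = NULL, fraction = NA_real_))
  }
  classes <- classes[colnames(betas)]
  res_cols <- classes == "resistant"
  bd <- rowMeans(betas[, res_cols, drop = FALSE], na.rm = TRUE) -
    rowMeans(betas[, !res_cols, drop = FALSE], na.rm = TRUE)
  lfc <- setNames(resistance_sites$log2fc, resistance_sites$site)
  per <- data.frame(probe = ov$id_a, site = ov$id_b,
                    beta_diff = unname(bd[ov$id_a]),
                    log2fc = unname(lfc[ov$id_b]), stringsAsFactors = FALSE)
  per <- per[per$log2fc != 0 & per$beta_diff != 0, , drop = FALSE]
  per$concordant <- sign(per$beta_diff) == -sign(per$log2fc)
  list(per_probe = per,
       fraction = if (nrow(per) > 0L) mean(per$concordant) else NA_real_)
}

#' Resistance-site enrichment at HGRs
#'
#' Fisher's exact on {resistance site, other peak} x {overlaps HGR, not}
#' over the accessible-peak universe.
#'
#' @param all_peaks peak set of the accessibility universe.
#' @param resistance_site_ids ids of resistance-associated peaks.
#' @param hgrs HGR peak set.
#' @return list: `table`, `odds_ratio`, `p`.
#' @export
hgr_resistance_enrichment <- function(all_peaks, resistance_site_ids, hgrs) {
  res <- all_peaks$id %in% resistance_site_ids
  if (!any(res) || all(res)) stop("empty resistance stratum")
  hit <- all_peaks$id %in%
    unique(intersect_peaks(all_peaks,
                           peak_set(hgrs$chrom, hgrs$start, hgrs$end,
                                    id = hgrs$id))$id_a)
  a <- sum(res & hit); b <- sum(res & !hit)
  c_ <- sum(!res & hit); d <- sum(!res & !hit)
  ft <- fisher_exact(a, b, c_, d)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("resistance", "other"), c("hgr", "no_hgr")))
  list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p)
}

#' LD r-squared between two dosage vectors
#'
#' Squared Pearson correlation of additive genotype dosages (composite LD);
#' pairs with a missing value are dropped.
#'
#' @param g1,g2 numeric dosage vectors (0/1/2, NA allowed).
#' @return r-squared, or NA when either vector has zero variance.
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 3L) stop("need >= 3 non-missing pairs")
  if (var(g1[ok]) == 0 || var(g2[ok]) == 0) return(NA_real_)
  cor(g1[ok], g2[ok])^2
}

#' Per-variant phenotype (or expression) association
#'
#' Ordinary least squares of the response on additive dosage, one variant
#' at a time; monomorphic variants return NA.
#'
#' @param dosages variants x samples matrix (0/1/2).
#' @param response named numeric vector over samples (phenotype or
#'   log-expression).
#' @return data.frame: variant, beta, p, q.
#' @export
variant_phenotype_association <- function(dosages, response) {
  response <- response[colnames(dosages)]
  if (length(response) < 8L) stop("need n >= 8 samples")
  rows <- lapply(rownames(dosages), function(v) {
    g <- dosages[v, ]
    ok <- !is.na(g) & !is.na(response)
    if (sum(ok) < 8L || var(g[ok]) == 0) {
      return(data.frame(variant = v, beta = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    fit <- summary(lm(response[ok] ~ g[ok]))$coefficients
    data.frame(variant = v, beta = fit[2L, 1L], p = fit[2L, 4L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Allele-specific PWM score difference
#'
#' Best PWM score (both strands, whole window) of the alt-substituted
#' sequence minus that of the reference sequence; negative values mean the
#' alternative allele weakens the best motif match in the window.
#'
#' @param sequence reference DNA sequence of the window (e.g. an HGR).
#' @param offset 1-based position of the variant within `sequence`.
#' @param ref,alt single reference/alternative bases.
#' @param pwm log-odds matrix (default [gre_pwm()]).
#' @return list: `delta` (alt - ref, bits), `ref_score`, `alt_score`.
#' @export
allele_delta_score <- function(sequence, offset, ref, alt, pwm = gre_pwm()) {
  seq_up <- toupper(sequence)
  if (substr(seq_up, offset, offset) != toupper(ref)) {
    stop("reference allele does not match the sequence at the given offset")
  }
  alt_seq <- seq_up
  substr(alt_seq, offset, offset) <- toupper(alt)
  rs <- scan_pwm(seq_up, pwm, threshold_frac = 0)$score
  as_ <- scan_pwm(alt_seq, pwm, threshold_frac = 0)$score
  list(delta = as_ - rs, ref_score = rs, alt_score = as_)
}

#' Fine-map resistance-associated variants to HGRs
#'
#' Leads are variants whose phenotype association passes `lead_q_max`;
#' each lead is expanded by proxies with LD r-squared above `r2_min`.
#' Lead or proxy variants whose position falls inside an HGR are retained,
#' and each retained variant gets an allele delta motif score computed over
#' its HGR window.
#'
#' @param variants data.frame: variant, chrom, pos (0-based), ref, alt.
#' @param assoc data.frame from [variant_phenotype_association()].
#' @param dosages variants x samples dosage matrix.
#' @param hgrs HGR peak set.
#' @param hgr_sequences named character vector of HGR sequences (by HGR id).
#' @param pwm log-odds matrix (default [gre_pwm()]).
#' @param r2_min proxy LD threshold (default 0.8).
#' @param lead_q_max lead association threshold (default 0.05).
#' @return data.frame: variant, status (lead/proxy), lead, r2, hgr_id,
#'   delta_score.
#' @export
finemap_to_hgrs <- function(variants, assoc, dosages, hgrs, hgr_sequences,
                            pwm = gre_pwm(), r2_min = 0.8,
                            lead_q_max = 0.05) {
  leads <- assoc$variant[!is.na(assoc$q) & assoc$q < lead_q_max]
  empty <- data.frame(variant = character(), status = character(),
                      lead = character(), r2 = numeric(),
                      hgr_id = character(), delta_score = numeric(),
                      stringsAsFactors = FALSE)
  if (length(leads) == 0L) return(empty)
  cand <- list()
  for (lead in sort(leads)) {
    cand[[lead]] <- data.frame(variant = lead, status = "lead", lead = lead,
                               r2 = 1, stringsAsFactors = FALSE)
    others <- setdiff(rownames(dosages), lead)
    for (v in others) {
      r2 <- tryCatch(ld_r2(dosages[lead, ], dosages[v, ]),
                     error = function(e) NA_real_)
      if (!is.na(r2) && r2 > r2_min && !(v %in% leads)) {
        cand[[lead]] <- rbind(cand[[lead]],
                              data.frame(variant = v, status = "proxy",
                                         lead = lead, r2 = r2,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$variant, -cand$r2), , drop = FALSE]
  cand <- cand[!duplicated(cand$variant), , drop = FALSE]
  vv <- variants[match(cand$variant, variants$variant), , drop = FALSE]
  vp <- peak_set(vv$chrom, vv$pos, vv$pos + 1L, id = vv$variant)
  ov <- intersect_peaks(vp, peak_set(hgrs$chrom, hgrs$start, hgrs$end,
                                     id = hgrs$id))
  if (nrow(ov) == 0L) return(empty)
  cand <- cand[cand$variant %in% ov$id_a, , drop = FALSE]
  cand$hgr_id <- ov$id_b[match(cand$variant, ov$id_a)]
  cand$delta_score <- vapply(seq_len(nrow(cand)), function(i) {
    v <- variants[variants$variant == cand$variant[i], , drop = FALSE]
    h <- hgrs[hgrs$id == cand$hgr_id[i], , drop = FALSE]
    s <- hgr_sequences[[cand$hgr_id[i]]]
    if (is.null(s) || is.na(s)) {
      warning(sprintf("variant %s outside sequence coverage; skipped",
                      v$variant))
      return(NA_real_)
    }
    allele_delta_score(s, v$pos - h$start + 1L, v$ref, v$alt, pwm)$delta
  }, 0)
  rownames(cand) <- NULL
  cand
}

#' Prioritize candidate HGRs through the integrative funnel
#'
#' Funnel: CRISPRi candidate sites (positive mean log2fc, HGR-overlapping)
#' -> genes by regulatory-domain association -> keep pairs whose gene is a
#' GC-responsive DEG -> keep pairs whose gene is in the supplied
#' resistance-gene list. Output is ranked by screen mean log2 fold change,
#' with survivor counts at every stage.
#'
#' @param candidates output of [select_candidate_sites()].
#' @param site_peaks peak set of screen-site intervals.
#' @param genes gene models.
#' @param deg_ids GC-responsive DEG gene ids.
#' @param resistance_genes character vector of resistance-implicated genes.
#' @return list: `table` (hgr_id, site, gene_id, mean_log2fc, ranked),
#'   `stage_counts` (named integer vector).
#' @export
prioritize_hgrs <- function(candidates, site_peaks, genes, deg_ids,
                            resistance_genes) {
  if (length(resistance_genes) == 0L) stop("empty resistance gene list")
  stage <- c(crispri_hgr_candidates = nrow(candidates))
  empty <- data.frame(hgr_id = character(), site = character(),
                      gene_id = character(), mean_log2fc = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) {
    return(list(table = empty,
                stage_counts = c(stage, gene_associated = 0L,
                                 deg_linked = 0L, resistance_listed = 0L)))
  }
  sp <- site_peaks[site_peaks$id %in% candidates$site, , drop = FALSE]
  assoc <- associate_regions_to_genes(sp, genes)
  pairs <- merge(candidates, assoc, by.x = "site", by.y = "region_id")
  stage <- c(stage, gene_associated = length(unique(pairs$site)))
  pairs <- pairs[pairs$gene_id %in% deg_ids, , drop = FALSE]
  stage <- c(stage, deg_linked = length(unique(pairs$site)))
  pairs <- pairs[pairs$gene_id %in% resistance_genes, , drop = FALSE]
  stage <- c(stage, resistance_listed = length(unique(pairs$site)))
  if (nrow(pairs) == 0L) return(list(table = empty, stage_counts = stage))
  out <- pairs[order(-pairs$mean_log2fc, pairs$site, pairs$gene_id),
               c("hgr_id", "site", "gene_id", "mean_log2fc"), drop = FALSE]
  rownames(out) <- NULL
  list(table = out, stage_counts = stage)
}
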