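## End-to-end orchestration of a synthetic study run: simulate -> diff ->
## SE -> HGR -> loops -> STARR -> footprints -> screen -> cohort ->
## prioritize, with a provenance manifest. Stage outputs can be written as
## plain-text files for reproducibility checks.

#' Default pipeline thresholds
#'
#' Every cutoff used across the stages, serialized with each run:
#' chromatin FDR 0.01, DEG FDR 0.01 with fold > 2 (6 h/24 h union),
#' SE fold 2 at >= 2 treated timepoints, loop q 0.01, STARR binomial
#' p 0.001 and count-model FDR 0.05, screen FDR 0.05, resistance FDR 0.1,
#' LD r2 0.8, motif threshold 0.8 of max score, promoter window 2 kb,
#' stitch gap 12.5 kb.
#'
#' @return named list of thresholds.
#' @export
pipeline_thresholds <- function() {
  list(chromatin_q = 0.01, deg_q = 0.01, deg_min_fold = 2, se_fold = 2,
       se_min_timepoints = 2L, loop_q = 0.01, starr_p = 0.001,
       starr_q = 0.05, screen_q = 0.05, resistance_q = 0.1, ld_r2 = 0.8,
       motif_frac = 0.8, promoter_window = 2000L, stitch_gap = 12500L)
}

## per-timepoint two-group contrasts vs 0 h, over a count_matrix
contrast_vs_0h <- function(cm, timepoints = NULL) {
  meta <- cm$samples
  tps <- setdiff(sort(unique(meta$timepoint)), 0)
  if (!is.null(timepoints)) tps <- intersect(tps, timepoints)
  sf <- size_factors(cm$counts)
  grp <- paste0("t", meta$timepoint)
  disp <- estimate_dispersion(cm$counts, sf, groups = grp)
  res <- lapply(tps, function(tp) {
    nb_wald_test(cm$counts, sf, disp, grp, paste0("t", tp), "t0")
  })
  names(res) <- paste0(tps, "h")
  res
}

#' Run the full synthetic pipeline
#'
#' Executes every stage on a simulated study and returns all intermediate
#' and final results plus a manifest (seed, thresholds, per-stage row
#' counts and, when `out_dir` is given, md5 checksums of the written
#' files).
#'
#' @param cfg a [sim_config()] (its seed drives every stage).
#' @param thresholds list from [pipeline_thresholds()].
#' @param out_dir optional directory for plain-text stage outputs.
#' @return list of stage results with elements `manifest`, `study`,
#'   `responsive`, `degs`, `se`, `hgrs`, `loops`, `starr`, `footprints`,
#'   `screen`, `cohort`, `prioritized`.
#' @export
run_gc_pipeline <- function(cfg = sim_config(),
                            thresholds = pipeline_thresholds(),
                            out_dir = NULL) {
  study <- simulate_study(cfg)
  genome <- study$genome

  ## differential chromatin and expression
  atac_res <- contrast_vs_0h(study$counts$atac)
  k27_res <- contrast_vs_0h(study$counts$k27)
  rna_res <- contrast_vs_0h(study$counts$rna, timepoints = c(6, 24))
  resp_atac <- classify_responsive(atac_res, q_max = thresholds$chromatin_q)
  resp_k27 <- classify_responsive(k27_res, q_max = thresholds$chromatin_q)
  degs <- classify_responsive(rna_res, q_max = thresholds$deg_q,
                              min_fold = thresholds$deg_min_fold)
  degs$direction <- ifelse(degs$direction == "enhanced", "up", "down")

  ## super-enhancers: stitch K27 peaks, signal = normalized K27 counts
  k27_sf <- size_factors(study$counts$k27$counts)
  k27_norm <- sweep(study$counts$k27$counts, 2, k27_sf, "/")
  meta <- study$counts$k27$samples
  se_by_tp <- list()
  stitched <- stitch_peaks(study$support$k27[[1L]], thresholds$stitch_gap)
  for (tp in as.character(cfg$timepoints)) {
    cols <- meta$sample[meta$timepoint == as.numeric(tp)]
    peak_sig <- rowMeans(k27_norm[, cols, drop = FALSE])
    sig <- vapply(stitched$constituents, function(ids) {
      sum(peak_sig[ids])
    }, 0)
    se_by_tp[[tp]] <-
      rank_and_cutoff(stitched[, c("chrom", "start", "end", "id")], sig)
  }
  gc_se <- call_gc_responsive_se(se_by_tp, fold_min = thresholds$se_fold,
                                 min_timepoints = thresholds$se_min_timepoints)

  ## HGRs with GRE annotation
  hgrs <- call_hgrs(study$support$gr, study$support$atac, study$support$k27)
  hgr_seq <- setNames(
    unname(genome$sequences[vapply(strsplit(hgrs$constituent_gr, ","),
                                   `[[`, "", 1L)]),
    hgrs$id)
  hgrs <- annotate_gre(hgrs, as.list(hgr_seq), genome$pwm,
                       threshold_frac = thresholds$motif_frac)
  # responsive-direction overlap for the GRE enrichment test
  enh_sites <- resp_k27$feature[resp_k27$direction == "enhanced"]
  enh_peaks <- genome$peaks[genome$peaks$id %in% enh_sites, , drop = FALSE]
  hgr_peaks <- peak_set(hgrs$chrom, hgrs$start, hgrs$end, id = hgrs$id)
  enh_hgr_ids <- if (nrow(enh_peaks) > 0L) {
    unique(intersect_peaks(hgr_peaks, enh_peaks)$id_a)
  } else character(0)
  gre_enrich <- tryCatch(gre_response_enrichment(hgrs, enh_hgr_ids),
                         error = function(e) NULL)

  ## loops
  loops_in <- study$loops$loops
  loops_in <- loops_in[loops_in$q < thresholds$loop_q, , drop = FALSE]
  ann_loops <- annotate_loops(loops_in, genome$genes,
                              promoter_window_bp = thresholds$promoter_window)
  resp_k27_sites <- genome$peaks[genome$peaks$id %in% resp_k27$feature, ,
                                 drop = FALSE]
  resp_k27_sites$direction <-
    resp_k27$direction[match(resp_k27_sites$id, resp_k27$feature)]
  deg_df <- data.frame(gene_id = degs$feature, direction = degs$direction,
                       stringsAsFactors = FALSE)
  linkage <- loop_deg_linkage(ann_loops, deg_df, resp_k27_sites, hgrs)

  ## STARR activity
  rna_ds <- downsample_libraries(study$starr$rna, seed = cfg$seed + 11L)
  bin_calls <- lapply(colnames(rna_ds), function(cond) {
    call_active_binomial(study$starr$dna, rna_ds[, cond],
                         p_max = thresholds$starr_p)
  })
  names(bin_calls) <- colnames(rna_ds)
  active_ids <- lapply(bin_calls, function(d) d$region[d$active])
  cm_calls <- call_active_countmodel(study$starr$rna_reps,
                                     study$starr$input_reps,
                                     q_max = thresholds$starr_q)
  starr_classes <- classify_condition_specificity(
    study$starr$regions, active_ids$h0, active_ids$h6, active_ids$h24)
  resp_atac_ids <- resp_atac$feature
  starr_tests <- starr_enrichment_tests(
    study$starr$regions, starr_classes, resp_atac_ids,
    genome$roles$gre_ids,
    genome$genes[genome$genes$gene_id %in%
                   degs$feature[degs$direction == "up"], , drop = FALSE])

  ## footprints
  fp_diff <- differential_footprint(study$footprints$profiles,
                                    n_perm = 500L, seed = cfg$seed + 13L)
  open_ids <- genome$roles$open_ids
  ap1_test <- ap1_site_depletion_test(
    open_ids, genome$roles$ap1_ids,
    resp_atac$feature[resp_atac$direction == "reduced"])

  ## CRISPRi screen
  sg_enrich <- sgrna_enrichment(study$screen$table,
                                q_max = thresholds$screen_q)
  aggregates <- aggregate_sites_rra(sg_enrich, n_perm = 300L,
                                    seed = cfg$seed + 17L)
  candidates <- select_candidate_sites(aggregates, study$site_peaks, hgrs)

  ## cohort
  coh <- study$cohort
  classes <- stratify_resistance(setNames(coh$samples$phenotype,
                                          coh$samples$sample))
  subtypes <- setNames(coh$samples$subtype, coh$samples$sample)
  res_sites <- resistance_accessibility(coh$accessibility, classes, subtypes,
                                        q_max = thresholds$resistance_q)
  meth <- methylation_concordance(res_sites, genome$peaks, coh$probes,
                                  coh$betas, classes)
  hgr_enrich <- tryCatch(
    hgr_resistance_enrichment(genome$peaks, res_sites$site, hgrs),
    error = function(e) NULL)
  assoc <- variant_phenotype_association(
    coh$dosages, setNames(coh$samples$phenotype, coh$samples$sample))
  finemapped <- finemap_to_hgrs(coh$variants, assoc, coh$dosages, hgrs,
                                as.list(hgr_seq), genome$pwm,
                                r2_min = thresholds$ld_r2)

  ## prioritization funnel
  prio <- prioritize_hgrs(candidates, study$site_peaks, genome$genes,
                          degs$feature, study$resistance_genes)

  result <- list(
    study = study,
    responsive = list(atac = resp_atac, k27 = resp_k27),
    degs = degs, se = gc_se, se_rank = se_by_tp, stitched = stitched,
    hgrs = hgrs, gre_enrich = gre_enrich,
    loops = list(annotated = ann_loops, linkage = linkage),
    starr = list(binomial = bin_calls, countmodel = cm_calls,
                 classes = starr_classes, tests = starr_tests),
    footprints = fp_diff, ap1_test = ap1_test,
    screen = list(sgrna = sg_enrich, aggregates = aggregates,
                  candidates = candidates),
    cohort = list(classes = classes, resistance_sites = res_sites,
                  methylation = meth, hgr_enrichment = hgr_enrich,
                  association = assoc, finemapped = finemapped),
    prioritized = prio)
  result$manifest <- build_manifest(cfg, thresholds, result)
  if (!is.null(out_dir)) {
    result$manifest$files <- write_run(result, out_dir)
  }
  result
}

build_manifest <- function(cfg, thresholds, result) {
  list(seed = cfg$seed,
       thresholds = thresholds,
       n_regions = cfg$n_regions, n_genes = cfg$n_genes,
       stage_rows = c(
         responsive_atac = nrow(result$responsive$atac),
         responsive_k27 = nrow(result$responsive$k27),
         degs = nrow(result$degs),
         gc_responsive_se = nrow(result$se),
         hgrs = nrow(result$hgrs),
         loops = nrow(result$loops$annotated),
         starr_active_gc = sum(result$starr$classes$class %in%
                                 c("GC_specific", "shared")),
         screen_candidates = nrow(result$screen$candidates),
         resistance_sites = nrow(result$cohort$resistance_sites),
         finemapped_variants = nrow(result$cohort$finemapped),
         prioritized_hgrs = length(unique(result$prioritized$table$site))),
       funnel = result$prioritized$stage_counts)
}

write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, name) {
    path <- file.path(out_dir, name)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    wt(result$responsive$atac, "responsive_atac.tsv"),
    wt(result$responsive$k27, "responsive_k27.tsv"),
    wt(result$degs, "degs.tsv"),
    wt(result$se, "gc_responsive_se.tsv"),
    wt(result$hgrs[, setdiff(names(result$hgrs), "constituents")],
       "hgrs.tsv"),
    wt(result$starr$classes, "starr_classes.tsv"),
    wt(result$footprints, "footprint_differential.tsv"),
    wt(result$screen$aggregates, "screen_aggregates.tsv"),
    wt(result$cohort$resistance_sites, "resistance_sites.tsv"),
    wt(result$cohort$finemapped, "finemapped_variants.tsv"),
    wt(result$prioritized$table, "prioritized_hgrs.tsv"))
  md5 <- tools::md5sum(paths)
  names(md5) <- basename(names(md5))
  json_path <- file.path(out_dir, "manifest.json")
  manifest <- result$manifest
  manifest$files <- as.list(md5)
  jsonlite::write_json(manifest, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(md5, setNames(tools::md5sum(json_path), "manifest.json"))
}
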