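## Synthetic study generator. Emits every input the pipeline consumes —
## toy genome, peak sets with per-timepoint assay support, NB count
## matrices, STARR-seq libraries, HiChIP-style loops, footprint insertion
## profiles, a CRISPRi screen and a patient cohort — with planted ground
## truth so each downstream caller can be checked quantitatively.
##
## All randomness is routed through stage-salted seeds, so outputs are
## reproducible per stage and byte-identical per run.

SALTS <- c(genome = 101L, counts = 202L, starr = 303L, screen = 404L,
           cohort = 505L, loops = 606L, footprints = 707L)

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' treatment timepoints 0/2/6/12/24 h with 4 replicates, library depth
#' 1e6 reads (log-normal sd 0.2 across samples), NB overdispersion 0.05,
#' planted responsive effects of log2FC 2, ~6.5 sgRNAs per screen site
#' with 100 non-targeting controls, and STARR activity factor 4.
#'
#' @param seed integer master seed.
#' @param n_regions number of peaks on the toy genome.
#' @param n_genes number of gene models.
#' @param timepoints treatment hours (first must be 0).
#' @param replicates_per_condition replicates per timepoint.
#' @param depth_mean mean reads per sample.
#' @param nb_dispersion NB alpha in Var = mu + alpha mu^2.
#' @param frac_responsive fraction of features with planted effects.
#' @param planted_log2fc planted chromatin/expression effect size.
#' @param frac_se_planted fraction of stitched regions given outlier
#'   H3K27ac signal.
#' @param n_patients cohort size.
#' @param frac_resistant fraction of resistant patients.
#' @param n_variants genotyped variants.
#' @param sgrnas_per_site_mean Poisson mean sgRNAs per screen site.
#' @param n_control_sgrnas non-targeting controls.
#' @param frac_gre fraction of GR peaks bearing a planted GRE.
#' @param activity_factor STARR RNA/DNA activity ratio for planted actives.
#' @param screen_log2fc planted per-sgRNA selection effect.
#' @param meth_concordant_frac fraction of planted methylation probes
#'   anti-correlated with accessibility.
#' @param promoter_fraction fraction of loops that are distal-promoter.
#' @param n_loops loops emitted.
#' @param variant_effect phenotype shift per causal-allele copy.
#' @param frac_starr_active fraction of regions with planted STARR activity.
#' @param starr_dna_coverage mean DNA input reads per 700 bp.
#' @param frac_resistance_sites fraction of peaks planted as
#'   resistance-associated in the cohort.
#' @param frac_screen_planted fraction of screen sites planted as hits.
#' @return validated list with class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_regions = 2000L, n_genes = 500L,
                       timepoints = c(0, 2, 6, 12, 24),
                       replicates_per_condition = 4L, depth_mean = 1e6,
                       nb_dispersion = 0.05, frac_responsive = 0.2,
                       planted_log2fc = 2, frac_se_planted = 0.03,
                       n_patients = 100L, frac_resistant = 0.5,
                       n_variants = 40L, sgrnas_per_site_mean = 6.5,
                       n_control_sgrnas = 100L, frac_gre = 0.55,
                       activity_factor = 4, screen_log2fc = 1,
                       meth_concordant_frac = 0.85,
                       promoter_fraction = 0.35, n_loops = 600L,
                       variant_effect = 1, frac_starr_active = 0.1,
                       starr_dna_coverage = 80,
                       frac_resistance_sites = 0.05,
                       frac_screen_planted = 0.1) {
  cfg <- as.list(environment())
  fracs <- c("frac_responsive", "frac_se_planted", "frac_gre",
             "meth_concordant_frac", "promoter_fraction",
             "frac_starr_active", "frac_resistance_sites",
             "frac_screen_planted")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$activity_factor <= 0) stop("activity_factor must be > 0")
  if (cfg$timepoints[1] != 0) stop("first timepoint must be 0 h")
  counts <- c("n_regions", "n_genes", "n_patients", "n_variants",
              "replicates_per_condition", "n_control_sgrnas", "n_loops")
  for (f in counts) if (cfg[[f]] < 1) stop(f, " must be >= 1")
  if (cfg$depth_mean < 0) stop("depth_mean must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Simulate the toy genome
#'
#' Three 10 Mb chromosomes; `n_regions` disjoint peaks of 200-1000 bp
#' placed in exclusive 6 kb slots; gene models with one TSS each; random
#' DNA with the canonical GRE consensus embedded in the GRE-bearing subset
#' of GR peaks. Also assigns peak roles (GR-bound, GRE, accessible, AP-1)
#' and picks a focal resistance locus: a GRE-bearing GR peak 5-100 kb from
#' its nearest gene, which becomes the planted resistance exemplar.
#'
#' @param cfg a [sim_config()].
#' @return list: `chromosomes`, `genes`, `peaks`, `sequences` (named by
#'   peak id), `pwm`, `roles`.
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed + SALTS["genome"])
  chrom_len <- 1e7
  chroms <- data.frame(chrom = c("chr1", "chr2", "chr3"), length = chrom_len,
                       stringsAsFactors = FALSE)
  slot_bp <- 6000L
  slots_per_chrom <- floor(chrom_len / slot_bp)
  total_slots <- 3L * slots_per_chrom
  if (cfg$n_regions > 0.8 * total_slots) {
    stop("n_regions too large for the toy chromosome length")
  }
  # genes
  g_chrom <- sample(chroms$chrom, cfg$n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(cfg$n_genes)),
    chrom = g_chrom,
    tss = as.integer(round(runif(cfg$n_genes, 5e4, chrom_len - 5e4))),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    biotype = "protein_coding", stringsAsFactors = FALSE)
  # peaks in exclusive slots
  slot_idx <- sort(sample.int(total_slots, cfg$n_regions))
  s_chrom <- chroms$chrom[(slot_idx - 1L) %/% slots_per_chrom + 1L]
  s_off <- ((slot_idx - 1L) %% slots_per_chrom) * slot_bp
  width <- sample(200:1000, cfg$n_regions, replace = TRUE)
  start <- s_off + sample.int(slot_bp - 1001L, cfg$n_regions, replace = TRUE)
  peaks <- peak_set(s_chrom, start, start + width,
                    id = sprintf("peak_%04d", seq_len(cfg$n_regions)))
  # roles
  n <- nrow(peaks)
  gr_ids <- sort(sample(peaks$id, round(0.4 * n)))
  gre_ids <- sort(sample(gr_ids, round(cfg$frac_gre * length(gr_ids))))
  closed_gr <- sort(sample(gr_ids, round(0.25 * length(gr_ids))))
  open_ids <- setdiff(peaks$id, closed_gr)
  ap1_ids <- sort(sample(setdiff(open_ids, gr_ids),
                         round(0.25 * length(setdiff(open_ids, gr_ids)))))
  # sequences with planted GREs
  consensus <- "GGTACAGGATGTTCT"
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), peaks$end[i] - peaks$start[i],
                 replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- peaks$id
  gre_offset <- setNames(rep(NA_integer_, n), peaks$id)
  for (pid in gre_ids) {
    w <- nchar(seqs[[pid]])
    off <- sample.int(w - nchar(consensus) + 1L - 40L, 1L) + 20L
    substr(seqs[[pid]], off, off + nchar(consensus) - 1L) <- consensus
    gre_offset[pid] <- off
  }
  # focal locus: GRE-bearing accessible GR peak 5-100 kb from a gene
  nd <- nearest_tss_distance(peaks, genes)
  cand <- intersect(setdiff(gre_ids, closed_gr), open_ids)
  dist_ok <- nd$id[!is.na(nd$abs_distance) & nd$abs_distance >= 5000 &
                     nd$abs_distance <= 1e5]
  focal_peak <- sort(intersect(cand, dist_ok))[1L]
  if (is.na(focal_peak)) focal_peak <- cand[1L]
  focal_gene <- nd$gene_id[nd$id == focal_peak]
  list(chromosomes = chroms, genes = genes, peaks = peaks,
       sequences = seqs, pwm = gre_pwm(),
       roles = list(gr_ids = gr_ids, gre_ids = gre_ids,
                    closed_gr = closed_gr, open_ids = open_ids,
                    ap1_ids = ap1_ids, gre_offset = gre_offset,
                    nearest = nd, focal_peak = focal_peak,
                    focal_gene = focal_gene))
}

## weighted sample without replacement over ids
sample_weighted <- function(ids, size, favored, weight = 8) {
  if (size <= 0L) return(character(0))
  w <- ifelse(ids %in% favored, weight, 1)
  sort(sample(ids, min(size, length(ids)), prob = w))
}

#' Build the planted response truth
#'
#' Chooses responsive chromatin sites (enhanced preferentially at
#' GRE-bearing GR peaks, reduced preferentially at AP-1 sites), derives
#' up/down DEGs as the nearest genes of enhanced/reduced sites, and keeps
#' the focal locus responsive (enhanced site, upregulated gene).
#'
#' @param cfg a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @return list of planted id sets (used by every generator stage).
#' @export
make_truth <- function(cfg, genome) {
  set.seed(cfg$seed + SALTS["counts"] - 1L)
  r <- genome$roles
  open <- r$open_ids
  n_resp <- round(cfg$frac_responsive * cfg$n_regions)
  n_enh <- round(0.6 * n_resp)
  enh <- sample_weighted(open, n_enh, intersect(r$gre_ids, r$gr_ids))
  if (n_resp > 0 && !(r$focal_peak %in% enh)) {
    enh <- sort(unique(c(enh, r$focal_peak)))
  }
  red <- sample_weighted(setdiff(open, enh), n_resp - n_enh, r$ap1_ids)
  nd <- r$nearest
  near <- setNames(nd$gene_id, nd$id)
  up_genes <- sort(unique(near[enh]))
  down_genes <- sort(unique(setdiff(near[red], up_genes)))
  if (n_resp > 0) up_genes <- sort(unique(c(up_genes, r$focal_gene)))
  planted_se <- sample_weighted(setdiff(open, red),
                                round(cfg$frac_se_planted * cfg$n_regions),
                                character(0))
  list(atac_enhanced = enh, atac_reduced = red,
       k27_enhanced = enh, k27_reduced = red,
       planted_se = planted_se,
       up_genes = up_genes, down_genes = down_genes,
       target_gene = near)
}

## one NB count matrix: features x (timepoint x replicate)
gen_nb_matrix <- function(features, timepoints, reps, depth_mean, alpha,
                          effect_fun) {
  n <- length(features)
  w <- rlnorm(n, 0, 1)
  w <- w / sum(w)
  cols <- list(); cn <- character(0)
  meta <- list()
  for (tp in timepoints) {
    eff <- effect_fun(tp)
    for (rep_i in seq_len(reps)) {
      depth <- if (depth_mean > 0) rlnorm(1, log(depth_mean), 0.2) else 0
      mu <- depth * w * eff
      cnt <- if (depth > 0) rnbinom(n, mu = mu, size = 1 / alpha)
             else rep(0L, n)
      cols[[length(cols) + 1L]] <- cnt
      cn <- c(cn, sprintf("t%g_rep%d", tp, rep_i))
      meta[[length(meta) + 1L]] <- data.frame(
        sample = cn[length(cn)], timepoint = tp, replicate = rep_i,
        condition = if (tp == 0) "untreated" else "treated",
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  dimnames(counts) <- list(features, cn)
  count_matrix(counts, do.call(rbind, meta))
}

#' Simulate NB count matrices for every assay
#'
#' Counts ~ NB(mean = baseline x size factor x fold effect, dispersion =
#' `nb_dispersion`); planted responsive features carry a multiplicative
#' 2^`planted_log2fc` effect (enhanced) or its inverse (reduced) at treated
#' timepoints; nulls have effect 1. RNA uses timepoints 0/6/24 h.
#'
#' @param cfg a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @param truth output of [make_truth()].
#' @return named list of [count_matrix()] objects: atac, k27, gr, rna.
#' @export
simulate_counts <- function(cfg, genome, truth) {
  set.seed(cfg$seed + SALTS["counts"])
  eff <- 2^cfg$planted_log2fc
  chrom_effect <- function(enh, red) {
    function(tp) {
      e <- rep(1, cfg$n_regions)
      if (tp > 0) {
        e[genome$peaks$id %in% enh] <- eff
        e[genome$peaks$id %in% red] <- 1 / eff
      }
      e
    }
  }
  atac <- gen_nb_matrix(genome$peaks$id, cfg$timepoints,
                        cfg$replicates_per_condition, cfg$depth_mean,
                        cfg$nb_dispersion,
                        chrom_effect(truth$atac_enhanced, truth$atac_reduced))
  k27_eff <- chrom_effect(truth$k27_enhanced, truth$k27_reduced)
  k27 <- gen_nb_matrix(genome$peaks$id, cfg$timepoints,
                       cfg$replicates_per_condition, cfg$depth_mean,
                       cfg$nb_dispersion,
                       function(tp) {
                         e <- k27_eff(tp)
                         # planted SEs: outlier acetylation after treatment
                         if (tp > 0) {
                           e[genome$peaks$id %in% truth$planted_se] <- 10
                         }
                         e
                       })
  gr_ids <- genome$roles$gr_ids
  gr <- gen_nb_matrix(gr_ids, cfg$timepoints,
                      cfg$replicates_per_condition, cfg$depth_mean / 4,
                      cfg$nb_dispersion,
                      function(tp) {
                        if (tp > 0) rep(eff, length(gr_ids))
                        else rep(1, length(gr_ids))
                      })
  rna_tps <- intersect(c(0, 6, 24), cfg$timepoints)
  rna <- gen_nb_matrix(genome$genes$gene_id, rna_tps,
                       cfg$replicates_per_condition, cfg$depth_mean,
                       cfg$nb_dispersion,
                       function(tp) {
                         e <- rep(1, cfg$n_genes)
                         if (tp > 0) {
                           e[genome$genes$gene_id %in% truth$up_genes] <- eff
                           e[genome$genes$gene_id %in% truth$down_genes] <-
                             1 / eff
                         }
                         e
                       })
  list(atac = atac, k27 = k27, gr = gr, rna = rna)
}

#' Per-timepoint peak support for HGR calling
#'
#' GR peaks appear at treated timepoints only; ATAC and H3K27ac support
#' covers the accessible universe at every timepoint (GR peaks flagged
#' closed lack ATAC/H3K27ac support and therefore never become HGRs).
#'
#' @param cfg,genome as elsewhere.
#' @return list of named lists `gr`, `atac`, `k27` keyed by timepoint label.
#' @export
simulate_peak_support <- function(cfg, genome) {
  open <- genome$peaks[genome$peaks$id %in% genome$roles$open_ids, ,
                       drop = FALSE]
  grp <- genome$peaks[genome$peaks$id %in% genome$roles$gr_ids, ,
                      drop = FALSE]
  tps <- as.character(cfg$timepoints)
  gr <- atac <- k27 <- setNames(vector("list", length(tps)), tps)
  for (tp in tps) {
    atac[[tp]] <- open
    k27[[tp]] <- open
    gr[[tp]] <- if (as.numeric(tp) > 0) grp else
      peak_set(character(), integer(), integer())
  }
  list(gr = gr, atac = atac, k27 = k27)
}

#' Simulate an ATAC-STARR-seq experiment
#'
#' DNA input counts are Poisson with mean proportional to region length
#' times `starr_dna_coverage`; planted active regions have RNA/DNA
#' proportion ratio `activity_factor`, with GC-specific actives active only
#' at 6/24 h. Regions with zero DNA are excluded from RNA generation.
#' Replicate RNA libraries (4) and pooled-input libraries (3) are emitted
#' for the count-model caller.
#'
#' @param cfg,genome,truth as elsewhere.
#' @return list: `regions` (peak set), `dna`, `rna` (matrix regions x
#'   conditions 0/6/24), `rna_reps`, `input_reps`, `truth` (active ids per
#'   condition and class).
#' @export
simulate_starr <- function(cfg, genome, truth) {
  if (cfg$activity_factor <= 0) stop("activity factor must be > 0")
  set.seed(cfg$seed + SALTS["starr"])
  regions <- genome$peaks[genome$peaks$id %in% genome$roles$open_ids, ,
                          drop = FALSE]
  n <- nrow(regions)
  width <- regions$end - regions$start
  dna <- rpois(n, width / 700 * cfg$starr_dna_coverage)
  names(dna) <- regions$id
  covered <- regions$id[dna > 0]
  n_act <- round(cfg$frac_starr_active * n)
  shared <- sample_weighted(covered, round(0.4 * n_act), character(0))
  gc_spec <- sample_weighted(setdiff(covered, shared), round(0.4 * n_act),
                             genome$roles$gre_ids)
  h0_spec <- sample_weighted(setdiff(covered, c(shared, gc_spec)),
                             n_act - length(shared) - length(gc_spec),
                             character(0))
  active_at <- function(tp) {
    if (tp == 0) c(shared, h0_spec) else c(shared, gc_spec)
  }
  conds <- c(0, 6, 24)
  rna <- matrix(0L, n, length(conds),
                dimnames = list(regions$id, paste0("h", conds)))
  for (j in seq_along(conds)) {
    fac <- ifelse(regions$id %in% active_at(conds[j]),
                  cfg$activity_factor, 1)
    wgt <- dna * fac
    total <- round(rlnorm(1, log(sum(dna) * 2), 0.1))
    rna[, j] <- as.integer(rmultinom(1, total, wgt / sum(wgt)))
  }
  # replicate libraries for the count-model caller (GC condition, 24 h)
  fac24 <- ifelse(regions$id %in% active_at(24), cfg$activity_factor, 1)
  mu_rna <- dna * fac24 / sum(dna * fac24)
  rna_reps <- sapply(1:4, function(i) {
    rpois(n, mu_rna * rlnorm(1, log(sum(dna)), 0.1))
  })
  mu_in <- dna / sum(dna)
  input_reps <- sapply(1:3, function(i) {
    rpois(n, mu_in * rlnorm(1, log(sum(dna)), 0.1))
  })
  dimnames(rna_reps) <- list(regions$id, paste0("rna_", 1:4))
  dimnames(input_reps) <- list(regions$id, paste0("input_", 1:3))
  list(regions = regions, dna = dna, rna = rna, rna_reps = rna_reps,
       input_reps = input_reps,
       truth = list(shared = shared, gc_specific = gc_spec,
                    h0_specific = h0_spec,
                    active_0h = sort(active_at(0)),
                    active_gc = sort(active_at(24))))
}

#' Simulate a CRISPRi tiling screen
#'
#' sgRNAs per site ~ Poisson(`sgrnas_per_site_mean`), minimum 1; planted
#' resistance sites carry a 2^`screen_log2fc` enrichment on every sgRNA in
#' the post-selection arm; controls and null sites follow the null count
#' model. Four replicates per arm at ~500 reads per sgRNA.
#'
#' @param cfg a [sim_config()].
#' @param site_peaks peak set of screened sites (the HGR universe).
#' @param planted_sites ids of planted resistance sites (must be screened).
#' @return list: `table` (long screen table), `truth`.
#' @export
simulate_screen <- function(cfg, site_peaks, planted_sites = character(0)) {
  if (nrow(site_peaks) == 0L) stop("empty screen site universe")
  set.seed(cfg$seed + SALTS["screen"])
  sites <- site_peaks$id
  n_sg <- pmax(1L, rpois(length(sites), cfg$sgrnas_per_site_mean))
  sg_site <- rep(sites, n_sg)
  sg_id <- sprintf("sg_%05d", seq_along(sg_site))
  sg_site <- c(sg_site, rep("control", cfg$n_control_sgrnas))
  sg_id <- c(sg_id, sprintf("ctrl_%03d", seq_len(cfg$n_control_sgrnas)))
  base <- rlnorm(length(sg_id), log(500), 0.3)
  eff <- ifelse(sg_site %in% planted_sites, 2^cfg$screen_log2fc, 1)
  rows <- list()
  for (arm in c("baseline", "selected")) {
    for (rep_i in 1:4) {
      sf <- rlnorm(1, 0, 0.1)
      mu <- base * sf * (if (arm == "selected") eff else 1)
      rows[[length(rows) + 1L]] <- data.frame(
        sgrna = sg_id, site = sg_site, arm = arm, replicate = rep_i,
        count = rnbinom(length(sg_id), mu = mu, size = 1 / cfg$nb_dispersion),
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows),
       truth = list(planted_sites = sort(planted_sites)))
}

#' Simulate the patient cohort
#'
#' Patients carry a molecular subtype, a continuous resistance phenotype
#' (higher = more resistant), peak accessibility counts (planted
#' resistance sites shifted down in resistant patients — 78% occluded, the
#' rest open), methylation betas anti-correlated with accessibility at
#' `meth_concordant_frac` of planted probes, genotype dosages with one
#' causal GRE-disrupting variant inside the focal HGR (plus two LD proxies)
#' that shifts phenotype and the focal gene's expression additively.
#'
#' @param cfg,genome as elsewhere.
#' @param hgr_peak_ids peak ids that are HGRs (resistance sites are drawn
#'   preferentially from these).
#' @return list: `samples`, `accessibility`, `probes`, `betas`,
#'   `variants`, `dosages`, `expression`, `truth`.
#' @export
simulate_cohort <- function(cfg, genome, hgr_peak_ids) {
  if (cfg$frac_resistant <= 0 || cfg$frac_resistant >= 1) {
    stop("frac_resistant must lie in (0, 1)")
  }
  if (cfg$n_patients < 8L) stop("need n_patients >= 8")
  set.seed(cfg$seed + SALTS["cohort"])
  n <- cfg$n_patients
  ids <- sprintf("pt_%03d", seq_len(n))
  subtype <- sample(c("ETV6-RUNX1", "hyperdiploid", "other"), n,
                    replace = TRUE, prob = c(0.35, 0.35, 0.3))
  # genotypes: causal variant inside the focal HGR's GRE + 2 proxies
  focal <- genome$roles$focal_peak
  off <- genome$roles$gre_offset[focal]
  fp <- genome$peaks[genome$peaks$id == focal, , drop = FALSE]
  causal_offset <- off + 11L   # the T of TGTTCT, a consensus base
  causal_pos <- fp$start + causal_offset - 1L
  ref <- substr(genome$sequences[[focal]], causal_offset, causal_offset)
  maf <- runif(cfg$n_variants, 0.1, 0.4)
  dos <- t(sapply(seq_len(cfg$n_variants), function(i) {
    rbinom(n, 2, maf[i])
  }))
  vid <- sprintf("var_%03d", seq_len(cfg$n_variants))
  vid[1L] <- "var_causal"
  dos[1L, ] <- rbinom(n, 2, 0.3)
  for (k in 2:3) {   # proxies of the causal variant
    flip <- runif(n) < 0.05
    dos[k, ] <- ifelse(flip, rbinom(n, 2, 0.3), dos[1L, ])
  }
  rownames(dos) <- vid; colnames(dos) <- ids
  v_chrom <- sample(genome$chromosomes$chrom, cfg$n_variants, replace = TRUE)
  v_pos <- as.integer(round(runif(cfg$n_variants, 1e4, 1e7 - 1e4)))
  variants <- data.frame(variant = vid, chrom = v_chrom, pos = v_pos,
                         ref = sample(c("A", "C", "G", "T"), cfg$n_variants,
                                      replace = TRUE),
                         alt = "A", stringsAsFactors = FALSE)
  variants$chrom[1L] <- fp$chrom
  variants$pos[1L] <- causal_pos
  variants$ref[1L] <- ref
  variants$alt[1L] <- if (ref == "A") "C" else "A"
  variants$alt[-1L] <- ifelse(variants$ref[-1L] == "A", "C", "A")
  # phenotype: noise + additive causal effect
  phenotype <- rnorm(n, 0, 1) + cfg$variant_effect * dos["var_causal", ]
  names(phenotype) <- ids
  resistant <- phenotype > quantile(phenotype, 1 - cfg$frac_resistant)
  classes <- setNames(ifelse(resistant, "resistant", "sensitive"), ids)
  # planted resistance sites: preferentially HGRs, focal always in
  n_res <- max(1L, round(cfg$frac_resistance_sites * cfg$n_regions))
  res_sites <- sample_weighted(genome$roles$open_ids, n_res, hgr_peak_ids,
                               weight = 4)
  res_sites <- sort(unique(c(res_sites, focal)))
  occluded <- sample(res_sites, round(0.78 * length(res_sites)))
  if (!(focal %in% occluded)) occluded <- sort(c(occluded, focal))
  open_dir <- setdiff(res_sites, occluded)
  # a fifth of planted sites shift only within ETV6-RUNX1 patients
  intra_only <- sample(res_sites, round(0.2 * length(res_sites)))
  intra_only <- setdiff(intra_only, focal)
  eff <- 2^cfg$planted_log2fc
  w <- rlnorm(cfg$n_regions, 0, 1); w <- w / sum(w)
  acc <- sapply(seq_len(n), function(j) {
    depth <- rlnorm(1, log(cfg$depth_mean), 0.2)
    e <- rep(1, cfg$n_regions)
    if (resistant[j]) {
      full <- setdiff(res_sites, intra_only)
      scope <- if (subtype[j] == "ETV6-RUNX1") res_sites else full
      e[genome$peaks$id %in% intersect(occluded, scope)] <- 1 / eff
      e[genome$peaks$id %in% intersect(open_dir, scope)] <- eff
    }
    rnbinom(cfg$n_regions, mu = depth * w * e, size = 1 / cfg$nb_dispersion)
  })
  dimnames(acc) <- list(genome$peaks$id, ids)
  # methylation probes at planted sites (plus background probes)
  probe_rows <- list()
  for (s in res_sites) {
    p <- genome$peaks[genome$peaks$id == s, , drop = FALSE]
    npr <- sample(1:3, 1L)
    pos <- sort(sample(seq(p$start + 5L, p$end - 5L), npr))
    probe_rows[[s]] <- data.frame(
      probe = sprintf("cg_%s_%d", s, seq_len(npr)),
      chrom = p$chrom, pos = pos, site = s, stringsAsFactors = FALSE)
  }
  probes <- do.call(rbind, probe_rows)
  bg_n <- 200L
  bg <- data.frame(probe = sprintf("cg_bg_%03d", seq_len(bg_n)),
                   chrom = sample(genome$chromosomes$chrom, bg_n,
                                  replace = TRUE),
                   pos = as.integer(round(runif(bg_n, 1e4, 1e7 - 1e4))),
                   site = NA_character_, stringsAsFactors = FALSE)
  probes <- rbind(probes, bg)
  concord <- runif(nrow(probes)) < cfg$meth_concordant_frac
  betas <- t(sapply(seq_len(nrow(probes)), function(i) {
    s <- probes$site[i]
    base_b <- runif(1, 0.2, 0.4)
    if (is.na(s)) return(pmin(pmax(rnorm(n, base_b, 0.05), 0), 1))
    # occluded in resistant -> methylation UP in resistant when concordant;
    # the open/discordant combinations take the opposite shift
    meth_up <- (s %in% occluded) == concord[i]
    shift <- ifelse(resistant, if (meth_up) 0.3 else -0.1, 0)
    pmin(pmax(rnorm(n, base_b + shift, 0.02), 0), 1)
  }))
  dimnames(betas) <- list(probes$probe, ids)
  # expression: focal gene is an eQTL target of the causal variant
  expr <- t(sapply(genome$genes$gene_id, function(g) {
    base_e <- rlnorm(1, log(100), 0.3)
    mu <- rep(base_e, n)
    if (g == genome$roles$focal_gene) {
      mu <- base_e * 2^(-0.7 * dos["var_causal", ])
    }
    rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
  }))
  dimnames(expr) <- list(genome$genes$gene_id, ids)
  samples <- data.frame(sample = ids, subtype = subtype,
                        phenotype = phenotype, class = classes,
                        stringsAsFactors = FALSE)
  list(samples = samples, accessibility = acc,
       probes = probes[, c("probe", "chrom", "pos")], betas = betas,
       variants = variants, dosages = dos, expression = expr,
       truth = list(resistance_sites = res_sites, occluded = sort(occluded),
                    open_in_resistant = sort(open_dir),
                    intra_only = sort(intra_only),
                    causal_variant = "var_causal",
                    proxies = vid[2:3],
                    target_gene = genome$roles$focal_gene))
}

#' Simulate HiChIP-style loops
#'
#' Planted regulatory loops join enhanced responsive peaks to their target
#' upregulated genes' promoters (and reduced peaks to downregulated
#' genes); background loops fill the promoter-loop count up to
#' `promoter_fraction` of `n_loops`, with the remainder distal-distal.
#' All q-values pass the q < 0.01 filter; self-loops are never emitted.
#'
#' @param cfg,genome,truth as elsewhere.
#' @return list: `loops` (data.frame chrA..q + loop_id), `truth` (planted
#'   peak-gene pairs).
#' @export
simulate_loops <- function(cfg, genome, truth) {
  set.seed(cfg$seed + SALTS["loops"])
  genes <- genome$genes
  peaks <- genome$peaks
  tss_anchor <- function(gids) {
    g <- genes[match(gids, genes$gene_id), , drop = FALSE]
    data.frame(chrB = g$chrom, startB = pmax(g$tss - 1000L, 0L),
               endB = g$tss + 1000L, stringsAsFactors = FALSE)
  }
  peak_anchor <- function(pids) {
    p <- peaks[match(pids, peaks$id), , drop = FALSE]
    data.frame(chrA = p$chrom, startA = p$start, endA = p$end,
               stringsAsFactors = FALSE)
  }
  planted_peaks <- c(truth$k27_enhanced, truth$k27_reduced)
  planted_genes <- unname(truth$target_gene[planted_peaks])
  keep <- planted_genes %in% c(truth$up_genes, truth$down_genes)
  planted_peaks <- planted_peaks[keep]
  planted_genes <- planted_genes[keep]
  cap <- round(0.8 * cfg$promoter_fraction * cfg$n_loops)
  if (length(planted_peaks) > cap) {
    pick <- sort(sample(seq_along(planted_peaks), cap))
    planted_peaks <- planted_peaks[pick]
    planted_genes <- planted_genes[pick]
  }
  planted <- cbind(peak_anchor(planted_peaks), tss_anchor(planted_genes))
  n_prom_bg <- max(0L, round(cfg$promoter_fraction * cfg$n_loops) -
                     nrow(planted))
  bg_peaks <- sample(peaks$id, n_prom_bg, replace = TRUE)
  bg_genes <- sample(genes$gene_id, n_prom_bg, replace = TRUE)
  bg_prom <- cbind(peak_anchor(bg_peaks), tss_anchor(bg_genes))
  n_dd <- cfg$n_loops - nrow(planted) - n_prom_bg
  dd_a <- sample(peaks$id, n_dd, replace = TRUE)
  dd_b <- sample(peaks$id, n_dd, replace = TRUE)
  same <- dd_a == dd_b
  while (any(same)) {   # never emit self-loops
    dd_b[same] <- sample(peaks$id, sum(same), replace = TRUE)
    same <- dd_a == dd_b
  }
  pb <- peak_anchor(dd_b)
  names(pb) <- c("chrB", "startB", "endB")
  dd <- cbind(peak_anchor(dd_a), pb)
  loops <- rbind(planted, bg_prom, dd)
  loops$q <- runif(nrow(loops), 0, 0.009)
  loops$loop_id <- sprintf("loop_%04d", seq_len(nrow(loops)))
  rownames(loops) <- NULL
  list(loops = loops,
       truth = list(planted_pairs = data.frame(peak = planted_peaks,
                                               gene = planted_genes,
                                               stringsAsFactors = FALSE)))
}

#' Simulate TF footprint insertion profiles
#'
#' Eight TFs, 150 motif sites each, insertion counts over a +/-100 bp
#' window. The GR motif (NR3C1) gains footprint depth after treatment;
#' the AP-1 family (JUN/FOS/FOSB) loses it; the rest are null.
#'
#' @param cfg a [sim_config()].
#' @param n_sites sites per TF (default 150).
#' @return list: `profiles` (per TF: matrices `a` = 0 h, `b` = 24 h),
#'   `truth` (planted direction per TF).
#' @export
simulate_footprints <- function(cfg, n_sites = 150L) {
  set.seed(cfg$seed + SALTS["footprints"])
  tfs <- c("NR3C1", "JUN", "FOS", "FOSB", "ETS1", "RUNX1", "GATA3", "SP1")
  dir <- c(NR3C1 = "gain", JUN = "loss", FOS = "loss", FOSB = "loss",
           ETS1 = "none", RUNX1 = "none", GATA3 = "none", SP1 = "none")
  w <- 201L; center <- 101L; core_hw <- 7L
  core_idx <- (center - core_hw):(center + core_hw)
  make_mat <- function(core_factor) {
    lam <- matrix(10, n_sites, w)
    lam[, core_idx] <- 10 * core_factor
    matrix(rpois(n_sites * w, lam), n_sites, w)
  }
  profiles <- lapply(tfs, function(tf) {
    fa <- switch(dir[[tf]], gain = 0.8, loss = 0.45, none = 0.6)
    fb <- switch(dir[[tf]], gain = 0.45, loss = 1.0, none = 0.6)
    list(a = make_mat(fa), b = make_mat(fb))
  })
  names(profiles) <- tfs
  list(profiles = profiles, truth = list(direction = dir))
}

#' Write a simulated study to standard file formats
#'
#' Emits the generator's outputs as plain-text files: peaks as BED6, peak
#' sequences as FASTA, gene models and count matrices as TSV (counts with
#' a sample-metadata sidecar), loops as a 7-column TSV, the cohort's
#' variants+genotypes as a minimal VCF 4.2 (CHROM/POS/ID/REF/ALT + GT;
#' positions converted to 1-based), and the ground truth as JSON.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(peaks = file.path(dir, "peaks.bed"))
  write_bed(study$genome$peaks, paths["peaks"])
  paths["sequences"] <- file.path(dir, "peak_sequences.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(study$genome$sequences), paths["sequences"])
  paths["genes"] <- file.path(dir, "genes.tsv")
  write.table(study$genome$genes, paths["genes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (assay in names(study$counts)) {
    cm <- study$counts[[assay]]
    paths[paste0("counts_", assay)] <-
      file.path(dir, sprintf("counts_%s.tsv", assay))
    write.table(data.frame(feature = rownames(cm$counts), cm$counts,
                           check.names = FALSE),
                paths[paste0("counts_", assay)], sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths[paste0("samples_", assay)] <-
      file.path(dir, sprintf("samples_%s.tsv", assay))
    write.table(cm$samples, paths[paste0("samples_", assay)], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  paths["loops"] <- file.path(dir, "loops.tsv")
  write.table(study$loops$loops[, c("chrA", "startA", "endA", "chrB",
                                    "startB", "endB", "q")],
              paths["loops"], sep = "\t", quote = FALSE, row.names = FALSE)
  # minimal VCF 4.2: fixed columns + GT, coordinates 1-based at this boundary
  v <- study$cohort$variants
  dos <- study$cohort$dosages
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow(dos),
               dimnames = dimnames(dos))
  paths["vcf"] <- file.path(dir, "genotypes.vcf")
  con <- file(paths["vcf"], "w")
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                      "Description=\"Genotype\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(dos)),
                     collapse = "\t")), con)
  body <- cbind(v$chrom, v$pos + 1L, v$variant, v$ref, v$alt, ".", "PASS",
                ".", "GT", gt[v$variant, , drop = FALSE])
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  close(con)
  paths["truth"] <- file.path(dir, "ground_truth.json")
  truth_all <- c(study$truth,
                 list(starr = study$starr$truth,
                      screen = study$screen$truth,
                      cohort = study$cohort$truth,
                      footprints = as.list(study$footprints$truth$direction),
                      resistance_genes = study$resistance_genes,
                      focal_peak = study$genome$roles$focal_peak,
                      focal_gene = study$genome$roles$focal_gene))
  jsonlite::write_json(truth_all, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Simulate the complete study
#'
#' Runs every generator with coherent planted truth: the focal locus is a
#' GRE-bearing HGR with enhanced chromatin response, an upregulated
#' nearest gene on the resistance-gene list, a planted CRISPRi hit, a
#' planted occluded resistance site and a causal GRE-disrupting variant —
#' so the full prioritization funnel has a known survivor.
#'
#' @param cfg a [sim_config()].
#' @return list of all stage inputs plus a `truth` list.
#' @export
simulate_study <- function(cfg) {
  genome <- simulate_genome(cfg)
  truth <- make_truth(cfg, genome)
  counts <- simulate_counts(cfg, genome, truth)
  support <- simulate_peak_support(cfg, genome)
  starr <- simulate_starr(cfg, genome, truth)
  # screen universe: accessible GR peaks (the HGR universe)
  hgr_univ_ids <- setdiff(genome$roles$gr_ids, genome$roles$closed_gr)
  site_peaks <- genome$peaks[genome$peaks$id %in% hgr_univ_ids, ,
                             drop = FALSE]
  cohort <- simulate_cohort(cfg, genome, hgr_univ_ids)
  planted_screen <- intersect(cohort$truth$resistance_sites, hgr_univ_ids)
  n_pl <- max(1L, round(cfg$frac_screen_planted * nrow(site_peaks)))
  if (length(planted_screen) > n_pl) {
    keep <- sort(sample(setdiff(planted_screen, genome$roles$focal_peak),
                        n_pl - 1L))
    planted_screen <- c(keep, genome$roles$focal_peak)
  }
  screen <- simulate_screen(cfg, site_peaks, planted_screen)
  loops <- simulate_loops(cfg, genome, truth)
  footprints <- simulate_footprints(cfg)
  resistance_genes <- sort(unique(c(
    genome$roles$focal_gene,
    sample(truth$up_genes, min(10L, length(truth$up_genes))),
    sample(genome$genes$gene_id, 15L))))
  list(cfg = cfg, genome = genome, truth = truth, counts = counts,
       support = support, starr = starr, screen = screen, cohort = cohort,
       loops = loops, footprints = footprints,
       resistance_genes = resistance_genes,
       site_peaks = site_peaks)
}
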