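#' Pipeline configuration
#'
#' Collects every stage threshold of the full analysis. Either `ped`/`map`
#' paths or an in-memory [genotype_matrix()] serve as input.
#'
#' @param ped,map input PLINK text paths (ignored when `genotypes` given).
#' @param genotypes optional in-memory [genotype_matrix()].
#' @param out_dir output directory for stage artifacts.
#' @param qc a [qc_thresholds()].
#' @param top_k,high_threshold,n_keep purity-screening parameters.
#' @param roh a [roh_params()].
#' @param family_threshold kinship threshold for family assignment.
#' @param family_exclude ids excluded (e.g. outlier bulls) before clustering.
#' @param shi_base Shannon-index log base (`"e"` or `"2"`).
#' @param compute_ne run the LD-based Ne estimate in the diversity stage?
#' @param write_genotypes write the filtered/selected PED/MAP filesets?
#' @param seed integer seed for any stochastic step (Ne pair subsampling).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(ped = NULL, map = NULL, genotypes = NULL,
                            out_dir = "herdpurity_out",
                            qc = qc_thresholds(), top_k = 100L,
                            high_threshold = 0.80, n_keep = 60L,
                            roh = roh_params(), family_threshold = 0.1,
                            family_exclude = character(0),
                            shi_base = "e", compute_ne = TRUE,
                            write_genotypes = TRUE, seed = 1L) {
  if (is.null(genotypes) && (is.null(ped) || is.null(map))) {
    stop("provide ped+map paths or an in-memory genotype matrix")
  }
  stopifnot(inherits(qc, "qc_thresholds"), inherits(roh, "roh_params"),
            top_k >= 1, n_keep >= 1, high_threshold > 0, high_threshold < 1,
            family_threshold >= 0)
  structure(list(ped = ped, map = map, genotypes = genotypes,
                 out_dir = out_dir, qc = qc, top_k = as.integer(top_k),
                 high_threshold = high_threshold, n_keep = as.integer(n_keep),
                 roh = roh, family_threshold = family_threshold,
                 family_exclude = family_exclude, shi_base = shi_base,
                 compute_ne = isTRUE(compute_ne),
                 write_genotypes = isTRUE(write_genotypes),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat key-value document; keys mirror the [pipeline_config()] arguments,
#' with QC thresholds under `qc:` and ROH parameters under `roh:`.
#'
#' @param path YAML file path.
#' @param overrides named list of values taking precedence over file keys.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  args <- raw
  args$qc <- if (is.null(raw$qc)) qc_thresholds() else
    do.call(qc_thresholds, raw$qc)
  args$roh <- if (is.null(raw$roh)) roh_params() else
    do.call(roh_params, raw$roh)
  do.call(pipeline_config, args)
}

pipeline_log <- function(stage, ..., log_con = NULL) {
  msg <- paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", stage, ": ", ...)
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
}

#' Run the full conserved-herd analysis pipeline
#'
#' Executes the stages in the order a conservation-genomics workup follows:
#' 1. quality control of the full herd; 2. purity screening (PCA loading x
#' concordance panel, individual ranking, top-`n_keep` selection) on the
#' QC-filtered genotypes; 3. re-application of QC to the **raw** genotypes
#' of the selected individuals (sample-dependent filters are recomputed, so
#' the two QC reports differ everywhere except the total and the
#' sample-independent sex-chromosome count); 4. diversity statistics with
#' inbreeding F and (optionally) LD-based Ne; 5. IBS and G matrices;
#' 6. ROH detection and F_ROH; 7. NJ clustering of bulls and
#' kinship-threshold family assignment. All artifacts are written under
#' `cfg$out_dir` with a JSON manifest and a run log.
#'
#' @param cfg a [pipeline_config()].
#' @return An object of class `herd_report`: `qc_all`, `screening`,
#'   `qc_selected`, `diversity`, `ibs`, `grm`, `roh`, `roh_summary`,
#'   `family`, `bull_tree`, `selected_ids`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(cfg$out_dir, "run.log"), open = "wt")
  on.exit(close(log_con))
  lg <- function(stage, ...) pipeline_log(stage, ..., log_con = log_con)
  out <- function(name) file.path(cfg$out_dir, name)
  manifest <- list()
  set.seed(cfg$seed)

  raw <- cfg$genotypes %||% read_ped_map(cfg$ped, cfg$map)
  lg("input", n_samples(raw), " individuals x ", n_markers(raw), " markers")

  # Stage 1: QC on the full herd.
  qc1 <- apply_qc(raw, cfg$qc)
  render_qc_table(qc1$report, out("qc_all.tsv"))
  manifest$qc_all <- out("qc_all.tsv")
  lg("qc", "retained ", qc1$report$retained_markers, " of ",
     qc1$report$total_markers, " markers")

  # Stage 2: purity screening on the filtered matrix.
  scr <- screen_purity(qc1$genotypes, top_k = cfg$top_k,
                       high_threshold = cfg$high_threshold,
                       n_keep = cfg$n_keep)
  panel_tab <- scr$panel
  panel_tab$pc1_contribution <-
    scr$pca$pc1_contribution[panel_tab$marker_id]
  utils::write.table(panel_tab, out("panel.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scr$ranking, out("ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$screening <- c(out("panel.tsv"), out("ranking.tsv"))
  lg("screen", "panel ", nrow(scr$panel), " loci; selected ",
     length(scr$selected_ids), " individuals")

  # Stage 3: re-QC the raw genotypes of the selected individuals.
  raw_sel <- raw[scr$selected_ids, ]
  qc2 <- apply_qc(raw_sel, cfg$qc)
  render_qc_table(qc2$report, out("qc_selected.tsv"))
  manifest$qc_selected <- out("qc_selected.tsv")
  gm <- qc2$genotypes
  if (cfg$write_genotypes) {
    write_ped_map(gm, out("selected.ped"), out("selected.map"))
    manifest$genotypes <- c(out("selected.ped"), out("selected.map"))
  }
  lg("re-qc", "retained ", qc2$report$retained_markers, " markers for ",
     n_samples(gm), " selected individuals")

  # Stage 4: diversity.
  div <- diversity_summary(gm, shi_base = cfg$shi_base,
                           compute_ne = cfg$compute_ne)
  stats_df <- locus_stats(gm, shi_base = cfg$shi_base)
  utils::write.table(stats_df, out("locus_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chrom = names(div$shi_by_chrom),
               mean_shi = as.numeric(div$shi_by_chrom)),
    out("shi_by_chrom.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$diversity <- c(out("locus_stats.tsv"), out("shi_by_chrom.tsv"))
  lg("diversity", sprintf("Ho %.3f He %.3f PIC %.3f",
                          div$means["ho", "mean"], div$means["he", "mean"],
                          div$means["pic", "mean"]))

  # Stage 5: relatedness.
  ibs <- ibs_distance(gm)
  G <- grm(gm)
  write_square_matrix(ibs, out("ibs.tsv"))
  write_square_matrix(G, out("grm.tsv"))
  manifest$relatedness <- c(out("ibs.tsv"), out("grm.tsv"))
  lg("relatedness", "IBS and G matrices over ", n_samples(gm),
     " individuals")

  # Stage 6: ROH.
  segs <- detect_roh(gm, cfg$roh)
  rs <- roh_summaries(segs, gm, n_autosomes = cfg$qc$n_autosomes)
  utils::write.table(segs, out("roh_segments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rs$per_individual, out("f_roh.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$roh <- c(out("roh_segments.tsv"), out("f_roh.tsv"))
  lg("roh", nrow(segs), " segments; mean F_ROH ",
     sprintf("%.4f", rs$f_roh_mean))

  # Stage 7: family structure.
  bulls <- gm$samples$iid[gm$samples$sex == "male"]
  bulls <- setdiff(bulls, cfg$family_exclude)
  tree <- NULL
  if (length(bulls) >= 2L) {
    tree <- suppressWarnings(nj_tree(ibs[bulls, bulls]))
    writeLines(to_newick(tree), out("bulls_nj.nwk"))
    manifest$tree <- out("bulls_nj.nwk")
  }
  fam <- assign_families(G, gm$samples, threshold = cfg$family_threshold,
                         exclude_ids = cfg$family_exclude)
  render_family_table(fam, out("families.tsv"))
  manifest$family <- out("families.tsv")
  lg("family", length(fam$families), " families; ",
     length(fam$other_cows), " cows unassigned")

  manifest$log <- file.path(cfg$out_dir, "run.log")
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  structure(list(
    qc_all = qc1$report, screening = scr, qc_selected = qc2$report,
    genotypes = gm, diversity = div, ibs = ibs, grm = G,
    roh = segs, roh_summary = rs, family = fam, bull_tree = tree,
    selected_ids = scr$selected_ids,
    manifest = c(manifest, manifest_path = out("manifest.json"))
  ), class = "herd_report")
}

#' @export
print.herd_report <- function(x, ...) {
  cat("herd_report\n")
  cat("  QC (all): retained", x$qc_all$retained_markers, "of",
      x$qc_all$total_markers, "markers\n")
  cat("  selected:", length(x$selected_ids), "individuals; panel",
      nrow(x$screening$panel), "loci\n")
  cat("  QC (selected): retained", x$qc_selected$retained_markers,
      "markers\n")
  cat(sprintf("  Ho %.3f | He %.3f | PIC %.3f | mean F_ROH %.4f\n",
              x$diversity$means["ho", "mean"],
              x$diversity$means["he", "mean"],
              x$diversity$means["pic", "mean"], x$roh_summary$f_roh_mean))
  cat("  families:", length(x$family$families), "| other cows:",
      length(x$family$other_cows), "\n")
  invisible(x)
}
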