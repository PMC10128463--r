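#' Validated configuration for an end-to-end pipeline run
#'
#' Bundles the input paths and every stage parameter, validated up front so
#' a run fails before any compute when a parameter is out of range. The
#' effective configuration is echoed to `provenance.json` in the output
#' directory, which suffices to rerun any stage.
#'
#' @param sample_sheet Path to the cohort sample sheet CSV.
#' @param out_dir Output directory for stage artifacts.
#' @param gene_gff,repeat_gff Optional annotation paths; when both are
#'   present the profile and nearest-element stages run.
#' @param target_bed Optional capture-target BED (enables the per-region
#'   coverage stage).
#' @param floor_matrix Coverage floor of the main common-site matrix
#'   (default 5: the clock/PCA matrix).
#' @param floor_bins Coverage floor of the chromosome-bin track (default 3).
#' @param floor_ks Coverage floor of the pooled KS comparison (default 10).
#' @param bin_size Chromosome bin width in bp (default 500000).
#' @param flank_bp,body_bins,flank_bin_bp Metagene profile geometry.
#' @param max_lag Neighbor-autocorrelation maximum lag (default 20).
#' @param top_n Number of age-associated sites to select (default 4500).
#' @param merge_gap_bp,pad_bp Capture-region collapse parameters.
#' @param remove_var PCA low-variance filter fraction (default 0.1).
#' @param alpha,l1_ratio Elastic-net hyperparameters (defaults 0.00283693
#'   and 0.5).
#' @param top_variable Number of top-variable sites (default 500).
#' @param cluster_k Site-cluster count (default 5).
#' @param seed Seed recorded in the provenance (the pipeline itself is
#'   deterministic given its inputs).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(sample_sheet, out_dir,
                            gene_gff = NULL, repeat_gff = NULL,
                            target_bed = NULL,
                            floor_matrix = 5, floor_bins = 3, floor_ks = 10,
                            bin_size = 500000,
                            flank_bp = 2000, body_bins = 10,
                            flank_bin_bp = 200,
                            max_lag = 20, top_n = 4500,
                            merge_gap_bp = 200, pad_bp = 60,
                            remove_var = 0.1,
                            alpha = 0.00283693, l1_ratio = 0.5,
                            top_variable = 500, cluster_k = 5,
                            seed = 1) {
  chk <- function(ok, msg) if (!ok) stop_validation("pipeline_config: ", msg)
  chk(is.character(sample_sheet) && length(sample_sheet) == 1L,
      "sample_sheet must be a single path")
  chk(all(c(floor_matrix, floor_bins, floor_ks) >= 1),
      "coverage floors must be >= 1")
  chk(bin_size >= 1000, "bin_size must be >= 1000 bp")
  chk(flank_bp > 0 && body_bins >= 1 && flank_bin_bp > 0 &&
        flank_bp %% flank_bin_bp == 0,
      "flank_bp must be a positive multiple of flank_bin_bp")
  chk(max_lag >= 1, "max_lag must be >= 1")
  chk(top_n >= 1, "top_n must be >= 1")
  chk(merge_gap_bp >= 0 && pad_bp >= 0,
      "merge_gap_bp and pad_bp must be non-negative")
  chk(remove_var >= 0 && remove_var < 1, "remove_var must lie in [0, 1)")
  chk(alpha >= 0 && l1_ratio >= 0 && l1_ratio <= 1,
      "alpha must be >= 0 and l1_ratio in [0, 1]")
  chk(top_variable >= 1 && cluster_k >= 1,
      "top_variable and cluster_k must be >= 1")
  structure(list(sample_sheet = sample_sheet, out_dir = out_dir,
                 gene_gff = gene_gff, repeat_gff = repeat_gff,
                 target_bed = target_bed,
                 floor_matrix = floor_matrix, floor_bins = floor_bins,
                 floor_ks = floor_ks, bin_size = bin_size,
                 flank_bp = flank_bp, body_bins = body_bins,
                 flank_bin_bp = flank_bin_bp, max_lag = max_lag,
                 top_n = top_n, merge_gap_bp = merge_gap_bp,
                 pad_bp = pad_bp, remove_var = remove_var,
                 alpha = alpha, l1_ratio = l1_ratio,
                 top_variable = top_variable, cluster_k = cluster_k,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run every pipeline stage on a configuration
#'
#' Stages run in dependency order: sample sheet and matrix construction;
#' methylome descriptors (context means, level histogram, chromosome bins,
#' pooled-group KS comparisons, neighbor autocorrelation); metagene and
#' repeat profiles plus nearest-element annotation when annotation files
#' are configured; per-region coverage when a target BED is configured;
#' age-association selection and capture-region BED; the LOOCV elastic-net
#' clock; PCA, sample clustering and top-variable-site clustering. Every
#' artifact is a deterministic function of the inputs and parameters; the
#' effective configuration is written to `provenance.json`.
#'
#' @param config A [pipeline_config()].
#' @param overwrite Re-run even when the output directory already holds a
#'   provenance file (default `TRUE`; with `FALSE` an existing completed
#'   run is returned untouched).
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, overwrite = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  prov_path <- file.path(out, "provenance.json")
  if (!overwrite && file.exists(prov_path)) {
    prov <- jsonlite::read_json(prov_path)
    if (isTRUE(prov$complete)) {
      message("run_pipeline: existing completed run found; skipping")
      return(invisible(unlist(prov$artifacts)))
    }
  }
  if (!file.exists(config$sample_sheet)) {
    stop_input("sample sheet not found: ", config$sample_sheet)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  artifacts <- character()
  add <- function(name, path) artifacts[[name]] <<- path
  stage <- "sample_sheet"
  res <- tryCatch({
    sheet <- read_sample_sheet(config$sample_sheet)
    records <- lapply(sheet$cgmap_path, read_cgmap)
    names(records) <- sheet$sample_id

    stage <- "matrix"
    mat <- build_common_matrix(records, config$floor_matrix)
    add("matrix", write_methyl_matrix(mat, file.path(out, "matrix.tsv")))

    stage <- "methylome_stats"
    cm <- t(vapply(records, context_means, numeric(4)))
    cm_df <- data.frame(sample_id = rownames(cm), cm, check.names = FALSE)
    utils::write.table(cm_df, file.path(out, "context_means.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add("context_means", file.path(out, "context_means.tsv"))

    hist <- level_histogram(as.vector(mat$levels))
    utils::write.table(
      data.frame(bin_start = hist$breaks[-length(hist$breaks)],
                 bin_end = hist$breaks[-1], density = hist$density),
      file.path(out, "level_histogram.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    add("level_histogram", file.path(out, "level_histogram.tsv"))

    by_group <- split(seq_len(nrow(sheet)), sheet$group)
    pooled <- lapply(by_group, function(i) pool_group(records[i]))
    bins <- do.call(rbind, lapply(names(pooled), function(g) {
      b <- chromosome_bins(pooled[[g]], config$bin_size, config$floor_bins)
      b$group <- g
      b
    }))
    utils::write.table(bins, file.path(out, "chromosome_bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add("chromosome_bins", file.path(out, "chromosome_bins.tsv"))

    mat10 <- build_common_matrix(records, config$floor_ks)
    pooled10 <- lapply(by_group, function(i) {
      p <- pool_group(records[i])
      key <- site_key(p$chrom, p$pos)
      p$level[match(rownames(mat10$levels), key)]
    })
    pairs <- utils::combn(names(pooled10), 2)
    ks <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                     D = NA_real_, p_value = NA_real_)
    for (i in seq_len(ncol(pairs))) {
      res_ks <- ks_compare(pooled10[[pairs[1, i]]], pooled10[[pairs[2, i]]])
      ks$D[i] <- res_ks$D
      ks$p_value[i] <- res_ks$p_value
    }
    utils::write.table(ks, file.path(out, "ks_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add("ks_groups", file.path(out, "ks_groups.tsv"))

    ac <- do.call(rbind, lapply(sheet$sample_id, function(id) {
      a <- neighbor_autocorrelation(records[[id]], config$max_lag)
      a$sample_id <- id
      a
    }))
    utils::write.table(ac, file.path(out, "autocorrelation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add("autocorrelation", file.path(out, "autocorrelation.tsv"))

    elements <- NULL
    if (!is.null(config$gene_gff) && !is.null(config$repeat_gff)) {
      stage <- "profiles"
      genes <- read_elements(config$gene_gff, "gene")
      reps <- read_elements(config$repeat_gff, "repeat")
      elements <- rbind(genes, reps)
      pooled_all <- pool_group(records)
      write_profile(metagene_profile(pooled_all, genes, config$flank_bp,
                                     config$body_bins, config$flank_bin_bp),
                    file.path(out, "metagene_genes.tsv"), "all_samples")
      add("metagene_genes", file.path(out, "metagene_genes.tsv"))
      write_profile(metagene_profile(pooled_all, reps, config$flank_bp,
                                     config$body_bins, config$flank_bin_bp,
                                     min_element_length = 1000),
                    file.path(out, "metagene_repeats.tsv"), "all_samples")
      add("metagene_repeats", file.path(out, "metagene_repeats.tsv"))
    }

    if (!is.null(config$target_bed)) {
      stage <- "region_coverage"
      targets <- read_bed(config$target_bed)
      rc <- region_mean_coverage(records, targets)
      utils::write.table(rc$coverage, file.path(out, "region_coverage.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      add("region_coverage", file.path(out, "region_coverage.tsv"))
    }

    stage <- "age_association"
    assoc <- site_age_stats(mat, sheet$age_years, sheet$group)
    assoc <- rank_and_select(assoc, min(config$top_n, sum(!assoc$zero_variance)))
    utils::write.table(assoc, file.path(out, "age_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add("age_association", file.path(out, "age_association.tsv"))
    sel <- assoc[assoc$selected, , drop = FALSE]
    regions <- collapse_to_regions(sel, config$merge_gap_bp, config$pad_bp)
    add("selected_regions", write_bed(regions,
                                      file.path(out, "selected_regions.bed")))
    if (!is.null(elements)) {
      ann <- annotate_nearest_element(sel, elements)
      utils::write.table(ann$annotation,
                         file.path(out, "nearest_elements.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      add("nearest_elements", file.path(out, "nearest_elements.tsv"))
    }

    stage <- "clock"
    ev <- loocv_clock(mat, sheet$age_years, config$alpha, config$l1_ratio)
    utils::write.table(ev$predictions, file.path(out, "clock_predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add("clock_predictions", file.path(out, "clock_predictions.tsv"))
    utils::write.table(ev$feature_union, file.path(out, "clock_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add("clock_features", file.path(out, "clock_features.tsv"))
    jsonlite::write_json(list(r2 = ev$r2, r2_cod = ev$r2_cod, mae = ev$mae,
                              alpha = config$alpha,
                              l1_ratio = config$l1_ratio,
                              n_feature_union = nrow(ev$feature_union)),
                         file.path(out, "clock_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    add("clock_metrics", file.path(out, "clock_metrics.json"))

    stage <- "cohort_structure"
    pca <- methyl_pca(mat, config$remove_var)
    scores <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                         check.names = FALSE)
    utils::write.table(scores, file.path(out, "pca_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add("pca_scores", file.path(out, "pca_scores.tsv"))
    r2 <- pc_age_correlation(pca, sheet$age_years)
    utils::write.table(data.frame(component = names(r2), r2_age = r2),
                       file.path(out, "pc_age_r2.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add("pc_age_r2", file.path(out, "pc_age_r2.tsv"))
    scc <- sample_correlation_cluster(mat)
    add("sample_dendrogram", write_newick(scc$hclust,
                                          file.path(out, "samples.nwk")))
    tv <- top_variable_sites(mat, min(config$top_variable, nrow(mat$sites)))
    sc <- site_cluster(tv, min(config$cluster_k, nrow(tv$sites)),
                       ages = sheet$age_years)
    utils::write.table(cbind(tv$sites, cluster = sc$labels),
                       file.path(out, "site_clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add("site_clusters", file.path(out, "site_clusters.tsv"))
    TRUE
  }, error = function(e) {
    jsonlite::write_json(list(complete = FALSE, failed_stage = stage,
                              error = conditionMessage(e)),
                         prov_path, auto_unbox = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  prov <- c(list(complete = TRUE, artifacts = as.list(artifacts)),
            unclass(config))
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(artifacts)
}
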