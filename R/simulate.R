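#' Configuration for a synthetic bisulfite cohort
#'
#' Defines the data-generating conditions of a synthetic methylome cohort:
#' a 3-ages x 3-replicates design (1, 5 and 9 years) by default; a
#' bimodal baseline level distribution with 70% of CpG sites above 80%
#' methylation and ~3% essentially unmethylated; a small fraction of
#' planted drift sites whose level changes linearly with age (majority
#' decreasing, the classic global loss of methylation with age, minority
#' increasing); AR(1) spatial correlation of the per-sample noise along
#' each chromosome, stronger in younger groups; negative-binomial read
#' coverage (mean 12, the scale of a 9-15x whole-genome run); and
#' near-zero non-CpG methylation. Planted slopes (0.08-0.14 per year)
#' represent the strong age-associated positions a capture panel targets:
#' clearly detectable above the binomial sampling noise of ~12x coverage.
#'
#' @param ages Numeric ages, one per sample.
#' @param groups Age-group labels, one per sample.
#' @param strains Strain labels (recycled).
#' @param n_chromosomes,chrom_length Genome layout.
#' @param n_cg_sites,n_noncg_sites Site counts across the genome.
#' @param p_high,p_low Mixture masses of the high (> 0.8) and low (< 0.05)
#'   baseline components; the remainder is spread over (0.05, 0.8).
#' @param fraction_drift Fraction of CpG sites with planted age drift.
#' @param slope_range Magnitude range of drift slopes (level units / year).
#' @param prob_positive_slope Probability a drift slope is positive.
#' @param drift_pair_fraction Fraction of drift sites placed as close CpG
#'   pairs (both members within `drift_pair_gap` bp, drifting coherently
#'   with one shared slope), emulating age-DMRs that span neighboring
#'   CpGs; the remainder are isolated sites. Default 0.5, so ~0.75 capture
#'   regions per selected site after interval merging.
#' @param drift_pair_gap Maximum genomic gap within a drift pair (bp).
#' @param rho_by_group Named AR(1) autocorrelation of the noise field per
#'   group (young > mid > old by default).
#' @param noise_sd Standard deviation of the AR(1) noise field added to the
#'   latent level (level units).
#' @param coverage_mean,coverage_size Negative-binomial coverage parameters
#'   (`mu`, `size`); draws are floored at 1 read.
#' @param noncg_level_shape Beta shape parameters of non-CpG levels
#'   (default mean 0.005).
#' @param levels_mode `"bimodal"` (default) or `"ar1"`: in `"ar1"` mode the
#'   latent level is a constant `ar1_mean` plus an AR(1) field of sd
#'   `ar1_sd`, giving an exactly geometric autocorrelation profile.
#' @param ar1_mean,ar1_sd Latent mean and field sd for `"ar1"` mode.
#' @param promoter_hypomethylation Plant a hypomethylated window around
#'   gene TSSs when an annotation is supplied to [simulate_cohort()].
#' @param promoter_window,promoter_level_range TSS window (bp each side)
#'   and baseline range of the planted promoter dip.
#' @param seed Integer seed; identical configurations and seeds give
#'   byte-identical outputs.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(ages = rep(c(1, 5, 9), each = 3),
                       groups = rep(c("Young", "Mid", "Old"), each = 3),
                       strains = "synthetic",
                       n_chromosomes = 3, chrom_length = 1500000,
                       n_cg_sites = 5000, n_noncg_sites = 2000,
                       p_high = 0.70, p_low = 0.03,
                       fraction_drift = 0.04,
                       slope_range = c(0.08, 0.14),
                       prob_positive_slope = 0.16,
                       drift_pair_fraction = 0.5,
                       drift_pair_gap = 200,
                       rho_by_group = NULL,
                       noise_sd = 0.03,
                       coverage_mean = 12, coverage_size = 20,
                       noncg_level_shape = c(1, 199),
                       levels_mode = c("bimodal", "ar1"),
                       ar1_mean = 0.6, ar1_sd = 0.1,
                       promoter_hypomethylation = FALSE,
                       promoter_window = 1000,
                       promoter_level_range = c(0.1, 0.25),
                       seed = 1) {
  levels_mode <- match.arg(levels_mode)
  n <- length(ages)
  if (length(groups) != n) stop_validation("one group label per sample")
  if (any(ages <= 0)) stop_validation("ages must be positive")
  if (p_high + p_low > 1 || p_high < 0 || p_low < 0) {
    stop_validation("baseline mixture masses must be fractions summing <= 1")
  }
  if (fraction_drift < 0 || fraction_drift > 1) {
    stop_validation("fraction_drift must lie in [0, 1]")
  }
  if (drift_pair_fraction < 0 || drift_pair_fraction > 1) {
    stop_validation("drift_pair_fraction must lie in [0, 1]")
  }
  if (n_cg_sites + n_noncg_sites > n_chromosomes * (chrom_length - 2)) {
    stop_validation("more sites requested than genome positions available")
  }
  if (is.null(rho_by_group)) {
    ug <- unique(groups)
    rho_by_group <- stats::setNames(
      seq(0.7, 0.3, length.out = length(ug)), ug)
  }
  if (!all(groups %in% names(rho_by_group))) {
    stop_validation("rho_by_group must name every group")
  }
  structure(list(
    ages = ages, groups = groups,
    sample_ids = paste0(groups, "_", stats::ave(seq_len(n), groups,
                                                FUN = seq_along)),
    strains = rep_len(strains, n),
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    n_cg_sites = n_cg_sites, n_noncg_sites = n_noncg_sites,
    p_high = p_high, p_low = p_low,
    fraction_drift = fraction_drift, slope_range = slope_range,
    prob_positive_slope = prob_positive_slope,
    drift_pair_fraction = drift_pair_fraction,
    drift_pair_gap = drift_pair_gap,
    rho_by_group = rho_by_group, noise_sd = noise_sd,
    coverage_mean = coverage_mean, coverage_size = coverage_size,
    noncg_level_shape = noncg_level_shape,
    levels_mode = levels_mode, ar1_mean = ar1_mean, ar1_sd = ar1_sd,
    promoter_hypomethylation = promoter_hypomethylation,
    promoter_window = promoter_window,
    promoter_level_range = promoter_level_range,
    seed = as.integer(seed)), class = "sim_config")
}

#' Targeted-bisulfite-style cohort preset
#'
#' Sixteen samples over nine distinct ages between 2.3 and 10.9 years,
#' very high capture coverage (negative-binomial mean 300) on a smaller
#' site panel — the targeted-sequencing counterpart of the default
#' whole-genome preset.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_tbseq <- function(...) {
  ages <- c(2.3, 2.3, 3.6, 3.6, 4.2, 4.2, 4.6, 4.6,
            6.9, 6.9, 7.9, 7.9, 8.5, 8.5, 8.7, 10.9)
  groups <- ifelse(ages < 5, "Young", ifelse(ages <= 9, "Mature", "Old"))
  defaults <- list(ages = ages, groups = groups,
                   n_cg_sites = 2000, n_noncg_sites = 500,
                   coverage_mean = 300, coverage_size = 10,
                   rho_by_group = c(Young = 0.6, Mature = 0.45, Old = 0.3))
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

ar1_field <- function(n, rho, sd) {
  if (n == 0L) return(numeric())
  e <- numeric(n)
  e[1L] <- stats::rnorm(1L, 0, sd)
  if (n > 1L) {
    innov <- stats::rnorm(n - 1L, 0, sd * sqrt(1 - rho^2))
    for (t in 2:n) e[t] <- rho * e[t - 1L] + innov[t - 1L]
  }
  e
}

#' Simulate a CGmap cohort with ground truth
#'
#' Emits one CGmap file per sample, a sample sheet CSV, and a JSON truth
#' file. Per site and sample the latent level is
#' `clamp(baseline + slope * age + AR(1) noise, 0, 1)`; the observed
#' methylated count is `Binomial(coverage, latent)` with negative-binomial
#' coverage. Everything is reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if absent).
#' @param annotation Optional [simulate_annotation()] result; with
#'   `config$promoter_hypomethylation`, CpG baselines within
#'   `promoter_window` of a gene TSS are lowered into
#'   `promoter_level_range` (and never carry drift), planting the
#'   promoter dip of a metagene profile.
#' @return List with `sample_sheet` (absolute `cgmap_path`s), `truth`
#'   (list: `sites` data frame with per-site baseline/slope/drift,
#'   `ages`, `rho_by_group`), `sheet_path`, `truth_path`, `dir`.
#' @export
simulate_cohort <- function(config, dir, annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$fraction_drift * config$n_cg_sites > config$n_cg_sites) {
    stop_validation("more drift sites than CpG sites")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  n_sites <- config$n_cg_sites + config$n_noncg_sites
  per_chrom <- diff(round(seq(0, n_sites, length.out =
                                config$n_chromosomes + 1L)))
  chrom <- rep(chroms, per_chrom)
  pos <- unlist(lapply(per_chrom, function(m)
    sort(sample.int(config$chrom_length - 2L, m) + 1L)), use.names = FALSE)
  is_cg <- rep(FALSE, n_sites)
  is_cg[sample.int(n_sites, config$n_cg_sites)] <- TRUE

  # --- CpG baselines, drift, strand base --------------------------------
  ncg <- config$n_cg_sites
  if (config$levels_mode == "bimodal") {
    comp <- sample(c("high", "mid", "low"), ncg, replace = TRUE,
                   prob = c(config$p_high,
                            1 - config$p_high - config$p_low, config$p_low))
    baseline <- numeric(ncg)
    baseline[comp == "high"] <- 1 - 0.2 * stats::rbeta(sum(comp == "high"),
                                                       1.2, 4)
    baseline[comp == "mid"] <- 0.05 + 0.75 * stats::rbeta(sum(comp == "mid"),
                                                          2, 2)
    baseline[comp == "low"] <- 0.05 * stats::rbeta(sum(comp == "low"), 1, 3)
  } else {
    baseline <- rep(config$ar1_mean, ncg)
  }
  drift <- rep(FALSE, ncg)
  n_drift <- round(config$fraction_drift * ncg)
  promoter_site <- rep(FALSE, ncg)
  cg_chrom <- chrom[is_cg]; cg_pos <- pos[is_cg]
  if (!is.null(annotation) && config$promoter_hypomethylation &&
      nrow(annotation$genes)) {
    g <- annotation$genes
    tss <- ifelse(g$strand == "-", g$end - 1L, g$start)
    for (i in seq_len(nrow(g))) {
      hit <- cg_chrom == g$chrom[i] &
        abs((cg_pos - 1L) - tss[i]) <= config$promoter_window
      promoter_site <- promoter_site | hit
    }
    baseline[promoter_site] <- stats::runif(sum(promoter_site),
                                            config$promoter_level_range[1L],
                                            config$promoter_level_range[2L])
  }
  if (n_drift > sum(!promoter_site)) {
    stop_validation("more drift sites requested than eligible CpG sites")
  }
  slope <- numeric(ncg)
  if (n_drift > 0) {
    # a fraction of drift sites come as close CpG pairs sharing one slope
    # (age-DMRs span neighboring CpGs); the rest are isolated sites
    n_pairs <- floor(config$drift_pair_fraction * n_drift / 2)
    left <- which(cg_chrom[-1L] == cg_chrom[-ncg] &
                    (cg_pos[-1L] - cg_pos[-ncg]) <= config$drift_pair_gap &
                    !promoter_site[-1L] & !promoter_site[-ncg])
    chosen <- integer(0)
    if (n_pairs > 0 && length(left)) {
      used <- rep(FALSE, ncg)
      for (i in sample(left)) {
        if (length(chosen) >= n_pairs) break
        if (!used[i] && !used[i + 1L]) {
          chosen <- c(chosen, i)
          used[i] <- used[i + 1L] <- TRUE
        }
      }
    }
    drift[c(chosen, chosen + 1L)] <- TRUE
    n_single <- n_drift - 2L * length(chosen)
    eligible <- which(!promoter_site & !drift)
    singles <- if (n_single > 0) sample(eligible, n_single) else integer(0)
    drift[singles] <- TRUE
    draw_slope <- function(m) {
      sgn <- ifelse(stats::runif(m) < config$prob_positive_slope, 1, -1)
      sgn * stats::runif(m, config$slope_range[1L], config$slope_range[2L])
    }
    pair_slopes <- draw_slope(length(chosen))
    slope[chosen] <- slope[chosen + 1L] <- pair_slopes
    slope[singles] <- draw_slope(length(singles))
  }
  # drift sites get baselines with room to move in their direction
  if (config$levels_mode == "bimodal" && any(drift)) {
    neg <- drift & slope < 0
    pos_d <- drift & slope > 0
    baseline[neg] <- stats::runif(sum(neg), 0.75, 0.95)
    baseline[pos_d] <- stats::runif(sum(pos_d), 0.05, 0.30)
  }
  base_allele <- sample(c("C", "G"), ncg, replace = TRUE)

  # --- non-CpG sites ----------------------------------------------------
  nh <- config$n_noncg_sites
  noncg_level <- stats::rbeta(nh, config$noncg_level_shape[1L],
                              config$noncg_level_shape[2L])
  noncg_dinuc <- sample(c("CA", "CC", "CT"), nh, replace = TRUE)
  noncg_context <- sample(c("CHG", "CHH"), nh, replace = TRUE,
                          prob = c(0.3, 0.7))

  sd_field <- if (config$levels_mode == "ar1") config$ar1_sd else
    config$noise_sd
  cg_idx_by_chrom <- split(seq_len(ncg), cg_chrom)

  sheet <- data.frame(sample_id = config$sample_ids,
                      age_years = config$ages, group = config$groups,
                      strain = config$strains,
                      cgmap_path = paste0(config$sample_ids, ".cgmap"),
                      stringsAsFactors = FALSE)
  for (s in seq_len(nrow(sheet))) {
    rho <- config$rho_by_group[[config$groups[s]]]
    noise <- numeric(ncg)
    for (ch in names(cg_idx_by_chrom)) {
      idx <- cg_idx_by_chrom[[ch]]
      noise[idx] <- ar1_field(length(idx), rho, sd_field)
    }
    latent <- pmin(1, pmax(0, baseline + slope * config$ages[s] + noise))
    cov_cg <- pmax(1L, stats::rnbinom(ncg, size = config$coverage_size,
                                      mu = config$coverage_mean))
    meth_cg <- stats::rbinom(ncg, cov_cg, latent)
    cov_h <- pmax(1L, stats::rnbinom(nh, size = config$coverage_size,
                                     mu = config$coverage_mean))
    meth_h <- stats::rbinom(nh, cov_h, noncg_level)

    rec <- data.frame(chrom = chrom, base = "C", pos = pos,
                      context = "CHH", dinucleotide = "CT",
                      level = 0, meth_count = 0L, total_count = 1L,
                      stringsAsFactors = FALSE)
    rec$base[is_cg] <- base_allele
    rec$context[is_cg] <- "CG"
    rec$dinucleotide[is_cg] <- "CG"
    rec$meth_count[is_cg] <- meth_cg
    rec$total_count[is_cg] <- cov_cg
    rec$context[!is_cg] <- noncg_context
    rec$dinucleotide[!is_cg] <- noncg_dinuc
    rec$meth_count[!is_cg] <- meth_h
    rec$total_count[!is_cg] <- cov_h
    rec$level <- rec$meth_count / rec$total_count
    write_cgmap(rec, file.path(dir, sheet$cgmap_path[s]))
  }
  sheet_path <- file.path(dir, "sample_sheet.csv")
  utils::write.csv(sheet, sheet_path, row.names = FALSE, quote = FALSE)

  truth <- list(sites = data.frame(chrom = cg_chrom, pos = cg_pos,
                                   baseline = baseline, slope = slope,
                                   drift = drift,
                                   promoter = promoter_site,
                                   stringsAsFactors = FALSE),
                ages = stats::setNames(config$ages, config$sample_ids),
                rho_by_group = as.list(config$rho_by_group),
                levels_mode = config$levels_mode,
                seed = config$seed)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  sheet$cgmap_path <- file.path(normalizePath(dir), sheet$cgmap_path)
  list(sample_sheet = sheet, truth = truth, sheet_path = sheet_path,
       truth_path = truth_path, dir = dir)
}

#' Simulate gene/repeat annotation and capture targets
#'
#' Genes are placed at least 1 kb apart with lengths 1-5 kb (written as
#' GFF3 `gene` features, each with an `mRNA` child so child filtering is
#' exercised); repeats are 0.3-3 kb with a guaranteed > 1 kb subset;
#' capture targets are a BED of windows around random positions. Elements
#' never exceed chromosome bounds.
#'
#' @param config A [sim_config()] (genome layout and seed).
#' @param dir Output directory.
#' @param n_genes,n_repeats,n_targets Element counts (upper bounds for
#'   genes, which also respect the spacing rule).
#' @return List with `genes`, `repeats`, `targets` element data frames and
#'   `gene_gff`, `repeat_gff`, `target_bed` file paths.
#' @export
simulate_annotation <- function(config, dir, n_genes = 40, n_repeats = 60,
                                n_targets = 30) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed + 1000L)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  len <- config$chrom_length

  genes <- list()
  if (n_genes > 0) {
    per <- diff(round(seq(0, n_genes, length.out =
                            config$n_chromosomes + 1L)))
    for (ci in seq_along(chroms)) {
      x <- 3000
      made <- 0L
      while (made < per[ci]) {
        glen <- round(stats::runif(1, 1000, 5000))
        if (x + glen >= len - 2000) break
        made <- made + 1L
        genes[[length(genes) + 1L]] <- data.frame(
          chrom = chroms[ci], start = as.integer(x),
          end = as.integer(x + glen),
          strand = sample(c("+", "-"), 1L),
          kind = "gene",
          name = paste0("gene_", chroms[ci], "_", made),
          stringsAsFactors = FALSE)
        x <- x + glen + 1000 + round(stats::runif(1, 0, len / per[ci]))
      }
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), kind = character(), name = character(),
               stringsAsFactors = FALSE)

  rep_len_bp <- round(stats::runif(n_repeats, 300, 3000))
  if (n_repeats >= 4) {  # guarantee a > 1 kb subset
    rep_len_bp[seq_len(ceiling(n_repeats / 3))] <-
      round(stats::runif(ceiling(n_repeats / 3), 1200, 3000))
  }
  rep_chrom <- sample(chroms, n_repeats, replace = TRUE)
  rep_start <- vapply(rep_len_bp, function(l)
    round(stats::runif(1, 0, len - l - 1)), numeric(1))
  repeats <- data.frame(chrom = rep_chrom, start = as.integer(rep_start),
                        end = as.integer(rep_start + rep_len_bp),
                        strand = "*", kind = "repeat",
                        name = paste0("repeat_", seq_len(n_repeats)),
                        stringsAsFactors = FALSE)
  repeats <- repeats[genomic_order(repeats$chrom, repeats$start), ,
                     drop = FALSE]

  t_chrom <- sample(chroms, n_targets, replace = TRUE)
  t_start <- round(stats::runif(n_targets, 0, len - 500))
  targets <- data.frame(chrom = t_chrom, start = as.integer(t_start),
                        end = as.integer(t_start + round(stats::runif(
                          n_targets, 120, 400))),
                        strand = "*", kind = "target_region",
                        name = paste0("target_", seq_len(n_targets)),
                        stringsAsFactors = FALSE)
  targets <- targets[genomic_order(targets$chrom, targets$start), ,
                     drop = FALSE]

  gene_gff <- file.path(dir, "genes.gff3")
  write_gff3_genes(genes, gene_gff)
  repeat_gff <- file.path(dir, "repeats.gff")
  write_gff_repeats(repeats, repeat_gff)
  target_bed <- file.path(dir, "targets.bed")
  write_bed(targets, target_bed)
  list(genes = genes, repeats = repeats, targets = targets,
       gene_gff = gene_gff, repeat_gff = repeat_gff,
       target_bed = target_bed)
}

write_gff3_genes <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(c(
      paste(g$chrom, "synthetic", "gene", g$start + 1L, g$end, ".",
            g$strand, ".", paste0("ID=", g$name), sep = "\t"),
      paste(g$chrom, "synthetic", "mRNA", g$start + 1L, g$end, ".",
            g$strand, ".", paste0("ID=", g$name, ".t1;Parent=", g$name),
            sep = "\t")), con)
  }
  invisible(path)
}

write_gff_repeats <- function(repeats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(repeats)) {
    writeLines(paste(repeats$chrom, "RepeatMasker", "dispersed_repeat",
                     repeats$start + 1L, repeats$end, ".", ".", ".",
                     paste0("ID=", repeats$name), sep = "\t"), con)
  }
  invisible(path)
}
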