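#' Per-site age-association statistics
#'
#' For every site of a methylation matrix: the Pearson correlation of its
#' levels with numeric age (two-sided t-based p-value) and the one-way
#' ANOVA F statistic across age-group labels. Computation is vectorized
#' over sites; the formulas are the ones `cor.test()` and `anova(lm())`
#' evaluate. Sites with zero variance across samples have no defined
#' correlation: they are returned with `NA` statistics, flagged
#' `zero_variance`, and excluded from ranking (a message reports how many).
#'
#' @param mat A `methyl_matrix` (no missing cells).
#' @param ages Numeric age in years, one per sample (not constant).
#' @param groups Age-group labels, one per sample (>= 2 distinct).
#' @return A data frame with one row per site: `chrom`, `pos`, `pearson_r`,
#'   `pearson_p`, `anova_F`, `anova_p`, `adj_p_pearson`, `adj_p_anova`
#'   (Benjamini-Hochberg), `zero_variance`.
#' @export
site_age_stats <- function(mat, ages, groups) {
  x <- mat$levels
  n <- ncol(x)
  if (n < 3L) stop_input("need at least 3 samples")
  if (length(ages) != n || length(groups) != n) {
    stop_input("ages and groups must have one entry per sample")
  }
  if (stats::var(ages) == 0) stop_input("ages are constant")
  groups <- as.factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop_input("need at least 2 groups for ANOVA")

  xm <- rowMeans(x)
  xc <- x - xm
  ss_tot <- rowSums(xc^2)
  zero_var <- ss_tot <= 0
  a <- ages - mean(ages)
  r <- as.vector(xc %*% a) / sqrt(ss_tot * sum(a^2))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pearson_p <- 2 * stats::pt(-abs(tstat), df = n - 2)

  ng <- as.vector(table(groups))
  gm <- t(rowsum(t(x), groups) / ng)  # sites x groups of group means
  ssb <- rowSums(sweep((gm - xm)^2, 2, ng, `*`))
  ssw <- pmax(ss_tot - ssb, 0)
  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  anova_p <- stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)

  r[zero_var] <- pearson_p[zero_var] <- NA_real_
  Fstat[zero_var] <- anova_p[zero_var] <- NA_real_
  if (any(zero_var)) {
    message(sum(zero_var), " zero-variance site(s) excluded from ranking")
  }
  out <- data.frame(chrom = mat$sites$chrom, pos = mat$sites$pos,
                    pearson_r = r, pearson_p = pearson_p,
                    anova_F = Fstat, anova_p = anova_p,
                    stringsAsFactors = FALSE)
  out$adj_p_pearson <- adjust_pvalues(out$pearson_p)
  out$adj_p_anova <- adjust_pvalues(out$anova_p)
  out$zero_variance <- zero_var
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, as implemented by [stats::p.adjust()]. `NA` p-values stay
#' `NA` and do not enter the adjustment.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param method Adjustment method (default `"BH"`).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  stats::p.adjust(p, method = method)
}

#' Rank sites by the two adjusted p-values and flag the top N
#'
#' Each site gets a rank by `adj_p_pearson` and a rank by `adj_p_anova`
#' (ascending; within equal adjusted p, smaller raw p first, then genomic
#' order, so each rank list is a deterministic permutation).
#' `combined_rank` is the sum of the two ranks (a site best on both
#' criteria scores 2); the `top_n` sites with the smallest rank-sum are
#' flagged `selected`, ties broken by smaller `adj_p_pearson` then genomic
#' order. The rank-sum treats the two criteria symmetrically.
#'
#' @param results Data frame from [site_age_stats()].
#' @param top_n Number of sites to select (default 4500).
#' @return `results` with added `rank_pearson`, `rank_anova`,
#'   `combined_rank`, `selected`. Zero-variance (`NA`) sites are never
#'   selected and carry `NA` ranks.
#' @export
rank_and_select <- function(results, top_n = 4500) {
  usable <- which(!is.na(results$adj_p_pearson) & !is.na(results$adj_p_anova))
  n_use <- length(usable)
  if (top_n > n_use) {
    warning("top_n = ", top_n, " exceeds the ", n_use,
            " rankable sites; selecting all", call. = FALSE)
    top_n <- n_use
  }
  rank_of <- function(adj, raw) {
    o <- order(adj[usable], raw[usable], results$chrom[usable],
               results$pos[usable], method = "radix")
    rk <- integer(n_use)
    rk[o] <- seq_len(n_use)
    rk
  }
  rank_p <- rank_of(results$adj_p_pearson, results$pearson_p)
  rank_a <- rank_of(results$adj_p_anova, results$anova_p)
  rank_sum <- rank_p + rank_a
  o <- order(rank_sum, results$adj_p_pearson[usable], results$chrom[usable],
             results$pos[usable], method = "radix")

  results$rank_pearson <- results$rank_anova <- NA_integer_
  results$combined_rank <- NA_integer_
  results$rank_pearson[usable] <- rank_p
  results$rank_anova[usable] <- rank_a
  results$combined_rank[usable] <- rank_sum
  results$selected <- FALSE
  results$selected[usable[o[seq_len(top_n)]]] <- TRUE
  results
}

#' Collapse selected sites into capture regions
#'
#' Sites closer than `merge_gap_bp` are merged into one interval, each
#' interval is padded by `pad_bp` on both sides, and overlaps created by
#' the padding are re-merged, so the result is a non-overlapping region set
#' ready for probe design (BED export via [write_bed()]). Idempotent under
#' re-collapse.
#'
#' @param sites Data frame with `chrom`, `pos` (1-based site positions) and
#'   optionally `pearson_r` for the direction summary.
#' @param merge_gap_bp Maximum distance between neighboring site positions
#'   to merge (default 200).
#' @param pad_bp Padding added to each side of a merged region (default 60).
#' @return A data frame `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `n_sites`, `frac_positive` (fraction of member sites with
#'   `pearson_r > 0`; `NA` when `pearson_r` is absent).
#' @export
collapse_to_regions <- function(sites, merge_gap_bp = 200, pad_bp = 60) {
  if (!nrow(sites)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      n_sites = integer(), frac_positive = numeric(),
                      stringsAsFactors = FALSE))
  }
  ord <- genomic_order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  p0 <- sites$pos - 1
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(pmax(1L, p0 + 1L - pad_bp),
                                                p0 + 1L + pad_bp))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max(0L, merge_gap_bp - 2L * pad_bp))
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(p0 + 1L, p0 + 1L)),
    merged)
  s <- S4Vectors::subjectHits(hits)
  n_sites <- tabulate(s, nbins = length(merged))
  frac_pos <- rep(NA_real_, length(merged))
  if ("pearson_r" %in% names(sites)) {
    pos_counts <- rowsum(as.numeric(sites$pearson_r[S4Vectors::queryHits(hits)] > 0), s)
    frac_pos[as.integer(rownames(pos_counts))] <-
      pos_counts[, 1L] / n_sites[as.integer(rownames(pos_counts))]
  }
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                    start = pmax(0L, GenomicRanges::start(merged) - 1L),
                    end = GenomicRanges::end(merged),
                    stringsAsFactors = FALSE)
  out$name <- paste0("region_", seq_len(nrow(out)))
  out$n_sites <- n_sites
  out$frac_positive <- frac_pos
  out[genomic_order(out$chrom, out$start), , drop = FALSE]
}

#' Nearest gene/repeat element for each site
#'
#' Distance is 0 when the site lies inside an element; otherwise the bp gap
#' between the site and the element's nearest contained base. *All*
#' equidistant nearest elements are reported (the `-t all` semantics of
#' interval tools), so a site can contribute several rows.
#'
#' @param sites Data frame with `chrom`, `pos` (1-based).
#' @param elements Combined gene + repeat element data frame.
#' @return A list with `annotation` (data frame `chrom`, `pos`,
#'   `element_name`, `element_kind`, `distance`) and `kind_summary`
#'   (fraction of sites whose nearest element set contains each kind;
#'   a site tied between kinds counts once per kind). Sites on chromosomes
#'   without elements are absent from `annotation` and counted in
#'   `n_unannotated`.
#' @export
annotate_nearest_element <- function(sites, elements) {
  validate_elements(elements)
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  el_gr <- GenomicRanges::GRanges(elements$chrom,
                                  IRanges::IRanges(elements$start + 1L,
                                                   elements$end))
  # distanceToNearest picks one nearest element; a second, windowed overlap
  # pass recovers every element at the same gap so ALL ties are reported,
  # including ties on opposite sides of the site
  dtn <- GenomicRanges::distanceToNearest(site_gr, el_gr,
                                          ignore.strand = TRUE)
  best <- rep(NA_integer_, nrow(sites))
  best[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance
  window <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(pmax(1L, sites$pos - ifelse(is.na(best), 0L, best) - 1L),
                     sites$pos + ifelse(is.na(best), 0L, best) + 1L))
  hits <- GenomicRanges::findOverlaps(window, el_gr)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(site_gr[q], el_gr[s], ignore.strand = TRUE)
  keep <- !is.na(best[q]) & d == best[q]
  q <- q[keep]; s <- s[keep]; d <- d[keep]
  # GRanges gap distance -> bp to the nearest contained base (0 if inside)
  dist_bp <- ifelse(d == 0 &
                      IRanges::overlapsAny(site_gr[q], el_gr[s]), 0L, d + 1L)
  annotation <- data.frame(chrom = sites$chrom[q], pos = sites$pos[q],
                           element_name = elements$name[s],
                           element_kind = elements$kind[s],
                           distance = as.integer(dist_bp),
                           stringsAsFactors = FALSE)
  n_unannotated <- nrow(sites) - length(unique(q))
  if (n_unannotated > 0) {
    message(n_unannotated, " site(s) on chromosomes without elements were ",
            "left unannotated")
  }
  per_kind <- unique(annotation[, c("chrom", "pos", "element_kind")])
  tab <- table(per_kind$element_kind)
  kind_summary <- data.frame(element_kind = names(tab),
                             n_sites = as.integer(tab),
                             fraction = as.integer(tab) / length(unique(q)),
                             stringsAsFactors = FALSE)
  list(annotation = annotation, kind_summary = kind_summary,
       n_unannotated = n_unannotated)
}
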