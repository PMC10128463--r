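#' Mean methylation percentage per dinucleotide context
#'
#' The unweighted mean of per-site methylation levels, expressed in
#' percent, for each of the CpG, CpA, CpC and CpT dinucleotide contexts —
#' the classic per-sample summary row of a bisulfite methylome (vertebrate
#' CpG methylation is high, CpH methylation near zero). Means are
#' unweighted site means, not read-weighted means.
#'
#' @param records Methylation records of one sample (or a pooled group).
#' @param coverage_floor Minimum `total_count` for a site to contribute
#'   (default 1).
#' @return Named numeric vector `c(CpG=, CpA=, CpC=, CpT=)` in percent;
#'   `NA` for contexts absent from the input.
#' @export
context_means <- function(records, coverage_floor = 1) {
  records <- validate_records(records)
  records <- records[records$total_count >= coverage_floor, , drop = FALSE]
  labs <- c(CG = "CpG", CA = "CpA", CC = "CpC", CT = "CpT")
  out <- stats::setNames(rep(NA_real_, 4L), labs)
  for (d in names(labs)) {
    lv <- records$level[records$dinucleotide == d]
    if (length(lv)) out[labs[[d]]] <- 100 * mean(lv)
  }
  out
}

#' Histogram of methylation levels with headline fractions
#'
#' Bins values in `[0, 1]` into `n_bins` equal bins (proportions summing to
#' one) and reports the fractions the field quotes for a methylome: the
#' share of sites above 80% methylation, below 5%, and the exact-0 /
#' exact-1 point masses.
#'
#' @param values Numeric methylation levels in `[0, 1]`.
#' @param n_bins Number of equal-width bins (default 20).
#' @return A list with `breaks`, `density` (proportions, sum 1),
#'   `frac_above_080`, `frac_below_005`, `mass_at_0`, `mass_at_1`, `n`.
#' @export
level_histogram <- function(values, n_bins = 20) {
  values <- values[!is.na(values)]
  if (!length(values)) stop_input("level_histogram needs at least one value")
  if (any(values < 0 | values > 1)) {
    stop_validation("methylation levels must lie in [0, 1]")
  }
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  list(breaks = breaks,
       density = counts / length(values),
       frac_above_080 = mean(values > 0.80),
       frac_below_005 = mean(values < 0.05),
       mass_at_0 = mean(values == 0),
       mass_at_1 = mean(values == 1),
       n = length(values))
}

#' Chromosome-binned mean methylation track
#'
#' Mean CpG methylation level in fixed-width genomic bins (default 500 kb),
#' the coarse "methylation landscape" view of a genome. Bins tile each
#' chromosome without overlap; bins with no qualifying site carry
#' `mean_level = NA` and `n_sites = 0`.
#'
#' @param records Methylation records (typically a pooled age group).
#' @param bin_size Bin width in bp (default 500000).
#' @param coverage_floor Minimum `total_count` per site (default 3).
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   absent each chromosome is tiled up to its last observed site.
#' @return A data frame `chrom`, `bin_start` (0-based), `bin_end`,
#'   `mean_level`, `n_sites`.
#' @export
chromosome_bins <- function(records, bin_size = 500000, coverage_floor = 3,
                            chrom_lengths = NULL) {
  records <- validate_records(records)
  r <- records[records$context == "CG" &
                 records$total_count >= coverage_floor, , drop = FALSE]
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else
    sort(unique(r$chrom))
  out <- list()
  for (ch in chroms) {
    ri <- r[r$chrom == ch, , drop = FALSE]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      if (nrow(ri)) max(ri$pos) else 0
    n_bins <- max(1L, as.integer(ceiling(len / bin_size)))
    bin <- pmin(as.integer((ri$pos - 1) %/% bin_size) + 1L, n_bins)
    sums <- rowsum(ri$level, bin)
    cnt <- tabulate(bin, nbins = n_bins)
    mean_level <- rep(NA_real_, n_bins)
    mean_level[as.integer(rownames(sums))] <- sums[, 1L] /
      cnt[as.integer(rownames(sums))]
    out[[ch]] <- data.frame(chrom = ch,
                            bin_start = (seq_len(n_bins) - 1L) * bin_size,
                            bin_end = pmin(seq_len(n_bins) * bin_size,
                                           if (len > 0) len else bin_size),
                            mean_level = mean_level, n_sites = cnt,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Export a binned track as bedGraph
#' @param bins Output of [chromosome_bins()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(bins, path) {
  keep <- !is.na(bins$mean_level)
  utils::write.table(bins[keep, c("chrom", "bin_start", "bin_end",
                                  "mean_level")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Two-sample Kolmogorov-Smirnov comparison of methylation levels
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic two-sample KS distribution, appropriate at the site
#' counts of pooled methylomes. Symmetric in its arguments.
#'
#' @param a,b Numeric vectors of per-site levels (length >= 2 each).
#' @return List with `D` and `p_value`.
#' @export
ks_compare <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop_input("ks_compare needs at least 2 values per group")
  }
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p_value = res$p.value)
}

#' Autocorrelation of methylation across neighboring CpG sites
#'
#' For each lag k = 1..`max_lag`, the Pearson correlation between the level
#' of the i-th CpG and the (i+k)-th CpG in genomic order — the k-th
#' *closest* CpG, not a fixed bp distance. Pairs never span chromosomes;
#' correlations are pooled over all chromosomes. Lags with fewer than 3
#' pairs, or zero variance in either member, report `NA`.
#'
#' @param records CG-context methylation records of one sample.
#' @param max_lag Largest neighbor rank (default 20).
#' @return Data frame `lag`, `correlation`, `n_pairs`.
#' @export
neighbor_autocorrelation <- function(records, max_lag = 20) {
  records <- validate_records(records)
  r <- records[records$context == "CG", , drop = FALSE]
  r <- r[genomic_order(r$chrom, r$pos), , drop = FALSE]
  by_chrom <- split(r$level, r$chrom)
  out <- data.frame(lag = seq_len(max_lag), correlation = NA_real_,
                    n_pairs = 0L)
  for (k in seq_len(max_lag)) {
    x <- unlist(lapply(by_chrom, function(v)
      if (length(v) > k) v[seq_len(length(v) - k)] else numeric()),
      use.names = FALSE)
    y <- unlist(lapply(by_chrom, function(v)
      if (length(v) > k) v[(k + 1L):length(v)] else numeric()),
      use.names = FALSE)
    out$n_pairs[k] <- length(x)
    if (length(x) >= 3L && stats::sd(x) > 0 && stats::sd(y) > 0) {
      out$correlation[k] <- stats::cor(x, y)
    }
  }
  out
}
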