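#' Metagene / repeat-body methylation profile
#'
#' Aggregates per-site CpG methylation over a set of elements (genes or
#' repeats) into a fixed-length profile: fixed-width upstream flank bins, a
#' body scaled into `body_bins` fractional bins (strand-aware, 5' to 3'),
#' and fixed-width downstream flank bins. A site falling in several
#' (overlapping) elements contributes one observation per element. Flanks
#' are genomic and are not masked against neighboring elements. Elements
#' without strand are profiled as `+` strand.
#'
#' @param records CG-context methylation records (one sample or a pooled
#'   group).
#' @param elements Element data frame (see [read_elements()]).
#' @param flank_bp Flank width in bp on each side (default 2000).
#' @param body_bins Number of scaled body bins (default 10: deciles).
#' @param flank_bin_bp Width of each flank bin in bp (default 200;
#'   `flank_bp` must be a multiple).
#' @param min_element_length Elements shorter than this are excluded
#'   (use 1000 for repeat-body profiles restricted to repeats > 1 kb).
#' @return A data frame with one row per bin: `zone`
#'   (`upstream`/`body`/`downstream`), `bin` (1-based within zone, 5' to
#'   3'), `bin_label`, `mean_level`, `n_observations`.
#' @export
metagene_profile <- function(records, elements, flank_bp = 2000,
                             body_bins = 10, flank_bin_bp = 200,
                             min_element_length = 0) {
  records <- validate_records(records)
  validate_elements(elements)
  if (flank_bp %% flank_bin_bp != 0) {
    stop_input("flank_bp must be a multiple of flank_bin_bp")
  }
  n_flank <- flank_bp %/% flank_bin_bp
  el <- elements[elements$end - elements$start >= max(1, min_element_length), ,
                 drop = FALSE]
  r <- records[records$context == "CG", , drop = FALSE]
  total_bins <- 2L * n_flank + body_bins
  template <- data.frame(
    zone = rep(c("upstream", "body", "downstream"),
               c(n_flank, body_bins, n_flank)),
    bin = c(seq_len(n_flank), seq_len(body_bins), seq_len(n_flank)),
    stringsAsFactors = FALSE)
  template$bin_label <- with(template, ifelse(
    zone == "upstream", paste0("U", bin - n_flank - 1L),
    ifelse(zone == "body", paste0("B", bin), paste0("D", bin))))
  template$mean_level <- NA_real_
  template$n_observations <- 0L
  if (!nrow(el) || !nrow(r)) return(template)

  site_gr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$pos, r$pos))
  el_gr <- GenomicRanges::GRanges(
    el$chrom,
    IRanges::IRanges(pmax(1L, el$start + 1L - flank_bp), el$end + flank_bp))
  hits <- GenomicRanges::findOverlaps(site_gr, el_gr)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (!length(q)) return(template)

  p0 <- r$pos[q] - 1            # site, 0-based
  start <- el$start[s]
  end <- el$end[s]
  len <- end - start
  minus <- el$strand[s] == "-"
  # distance from the element 5' end, in element orientation
  d <- ifelse(minus, (end - 1) - p0, p0 - start)
  zone_idx <- integer(length(d))  # global bin index 1..total_bins
  up <- d < 0
  body <- d >= 0 & d < len
  down <- d >= len
  # upstream: d in [-flank_bp, -1]; bin n_flank is adjacent to the 5' end
  ubin <- n_flank - (((-d[up]) - 1) %/% flank_bin_bp)
  zone_idx[up] <- ubin
  frac <- (d[body] + 0.5) / len[body]
  zone_idx[body] <- n_flank + pmin(body_bins, floor(frac * body_bins) + 1L)
  dbin <- ((d[down] - len[down]) %/% flank_bin_bp) + 1L
  zone_idx[down] <- n_flank + body_bins + pmin(dbin, n_flank)
  keep <- zone_idx >= 1L & zone_idx <= total_bins
  zone_idx <- zone_idx[keep]
  lv <- r$level[q][keep]
  sums <- rowsum(lv, zone_idx)
  cnt <- tabulate(zone_idx, nbins = total_bins)
  template$n_observations <- cnt
  idx <- as.integer(rownames(sums))
  template$mean_level[idx] <- sums[, 1L] / cnt[idx]
  template
}

#' Write a profile to TSV
#' @param profile Output of [metagene_profile()].
#' @param path Output path.
#' @param label Optional sample/group label column.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, label = NULL) {
  if (!is.null(label)) profile$sample_or_group <- label
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
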