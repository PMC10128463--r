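#' Build a common-site methylation matrix across samples
#'
#' A site enters the matrix only if its read coverage passes the coverage
#' floor in *every* sample ("common sites"); cell values are the per-sample
#' methylation levels. An any-k-of-n relaxation is available through
#' `min_samples` (cells that fail the floor are then reported as `NA`), but
#' the all-samples rule is the default and is what every downstream stage
#' assumes.
#'
#' @param samples Either a sample sheet `data.frame` (see
#'   [read_sample_sheet()]), whose `cgmap_path` files are read, or a named
#'   list of methylation-record data frames (names are the sample ids).
#' @param coverage_floor Minimum `total_count` (default 5). With
#'   `strict = TRUE` the rule becomes `total_count > coverage_floor`,
#'   matching a "more than N reads" reading.
#' @param context Context classes to keep (default `"CG"`).
#' @param min_samples Minimum number of samples in which a site must pass
#'   the floor (default: all samples).
#' @param strict Use strictly-greater-than instead of at-least.
#' @return A `methyl_matrix`: a list with `sites` (data frame `chrom`,
#'   `pos`, `context`, sorted by chromosome and position), `samples`,
#'   `levels` (sites x samples numeric matrix), `coverage_floor`,
#'   `context_filter`, `strict`.
#' @export
build_common_matrix <- function(samples, coverage_floor = 5, context = "CG",
                                min_samples = NULL, strict = FALSE) {
  records <- as_records_list(samples)
  if (length(records) < 2L) stop_input("need at least 2 samples")
  if (coverage_floor < 1) stop_input("coverage_floor must be >= 1")
  ids <- names(records)
  records <- lapply(records, function(r) {
    r <- validate_records(r)
    r[r$context %in% context, , drop = FALSE]
  })
  pass <- function(r) if (strict) r$total_count > coverage_floor else
    r$total_count >= coverage_floor
  keys <- lapply(records, function(r) site_key(r$chrom, r$pos))
  passing <- mapply(function(r, k) k[pass(r)], records, keys,
                    SIMPLIFY = FALSE)
  min_samples <- min_samples %||% length(records)
  if (min_samples >= length(records)) {
    common <- Reduce(intersect, passing)
  } else {
    tab <- table(unlist(lapply(passing, unique)))
    common <- names(tab)[tab >= min_samples]
  }
  if (!length(common)) {
    warning("no sites pass coverage_floor = ", coverage_floor,
            " in the required number of samples; returning an empty matrix",
            call. = FALSE)
  }
  # site table from the first sample that carries each common site
  all_sites <- do.call(rbind, lapply(records, function(r)
    data.frame(chrom = r$chrom, pos = r$pos, context = r$context,
               stringsAsFactors = FALSE)))
  all_keys <- site_key(all_sites$chrom, all_sites$pos)
  sites <- all_sites[match(common, all_keys), , drop = FALSE]
  ord <- genomic_order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  skey <- site_key(sites$chrom, sites$pos)
  levels <- matrix(NA_real_, nrow = nrow(sites), ncol = length(records),
                   dimnames = list(skey, ids))
  for (i in seq_along(records)) {
    r <- records[[i]]
    ok <- if (min_samples >= length(records)) pass(r) else r$total_count >= 1
    idx <- match(skey, keys[[i]][ok])
    levels[, i] <- (r$meth_count[ok] / r$total_count[ok])[idx]
  }
  new_methyl_matrix(sites, ids, levels, coverage_floor, context, strict)
}

new_methyl_matrix <- function(sites, samples, levels, coverage_floor,
                              context, strict = FALSE) {
  structure(list(sites = sites, samples = samples, levels = levels,
                 coverage_floor = coverage_floor, context_filter = context,
                 strict = strict),
            class = "methyl_matrix")
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat("methylation matrix: ", nrow(x$sites), " sites x ", length(x$samples),
      " samples\n", sep = "")
  cat("  contexts: ", paste(x$context_filter, collapse = ","),
      "; coverage floor: ", if (x$strict) "> " else ">= ", x$coverage_floor,
      " in all samples\n", sep = "")
  if (nrow(x$sites)) {
    cat("  mean level: ", round(mean(x$levels, na.rm = TRUE), 4), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
dim.methyl_matrix <- function(x) dim(x$levels)

#' Subset a methylation matrix by site row indices
#' @param mat A `methyl_matrix`.
#' @param i Integer or logical row (site) index.
#' @return A `methyl_matrix` restricted to the chosen sites.
#' @export
subset_sites <- function(mat, i) {
  new_methyl_matrix(mat$sites[i, , drop = FALSE], mat$samples,
                    mat$levels[i, , drop = FALSE], mat$coverage_floor,
                    mat$context_filter, mat$strict)
}

as_records_list <- function(samples) {
  if (is.data.frame(samples)) {
    recs <- lapply(samples$cgmap_path, read_cgmap)
    names(recs) <- samples$sample_id
    recs
  } else if (is.list(samples)) {
    if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
      stop_input("record lists must be named by sample id")
    }
    samples
  } else {
    stop_input("samples must be a sample sheet data frame or a named list ",
               "of record data frames")
  }
}

#' Pool methylation records of one group by summing counts
#'
#' Per site, methylated and total counts are summed across the group
#' members and the level recomputed from the pooled counts — the count
#' equivalent of merging the group's alignments and re-calling methylation.
#' Pooling on counts (not on averaged levels) weights each read equally.
#'
#' @param records_list Named list of record data frames (one per sample).
#' @return One records data frame with pooled counts, sorted by chromosome
#'   and position.
#' @export
pool_group <- function(records_list) {
  if (!length(records_list)) stop_input("need at least 1 sample to pool")
  records_list <- lapply(records_list, validate_records)
  all <- do.call(rbind, records_list)
  key <- site_key(all$chrom, all$pos)
  meth <- rowsum(all$meth_count, key, reorder = FALSE)
  tot <- rowsum(all$total_count, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- all[first, , drop = FALSE]
  idx <- match(key[first], rownames(meth))
  out$meth_count <- as.integer(meth[idx, 1L])
  out$total_count <- as.integer(tot[idx, 1L])
  out$level <- out$meth_count / out$total_count
  out <- out[genomic_order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean read coverage per target region and sample
#'
#' For every region, the mean `total_count` over the CG-context sites that
#' fall inside `[start, end)`; regions containing no sites report `NA`. A
#' cohort-level on-target summary (fraction of reads falling inside any
#' region) is attached as the `on_target` element.
#'
#' @param records_by_sample Named list of record data frames.
#' @param regions Element data frame (e.g. from [read_bed()]).
#' @return A list with `coverage` (data frame: `chrom`, `start`, `end`,
#'   `name`, one column per sample) and `on_target` (data frame: `sample`,
#'   `fraction_reads_on_target`).
#' @export
region_mean_coverage <- function(records_by_sample, regions) {
  validate_elements(regions)
  reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L,
                                                    regions$end))
  cov <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, name = regions$name,
                    stringsAsFactors = FALSE)
  on_target <- data.frame(sample = names(records_by_sample),
                          fraction_reads_on_target = NA_real_,
                          stringsAsFactors = FALSE)
  for (i in seq_along(records_by_sample)) {
    r <- records_by_sample[[i]]
    r <- r[r$context == "CG", , drop = FALSE]
    means <- rep(NA_real_, nrow(regions))
    if (nrow(r)) {
      site_gr <- GenomicRanges::GRanges(r$chrom,
                                        IRanges::IRanges(r$pos, r$pos))
      hits <- GenomicRanges::findOverlaps(site_gr, reg_gr)
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      if (length(s)) {
        sums <- rowsum(r$total_count[q], s)
        cnt <- rowsum(rep(1L, length(s)), s)
        means[as.integer(rownames(sums))] <- sums[, 1L] / cnt[, 1L]
      }
      on_target$fraction_reads_on_target[i] <-
        sum(r$total_count[unique(q)]) / sum(r$total_count)
    }
    cov[[names(records_by_sample)[i]]] <- means
  }
  list(coverage = cov, on_target = on_target)
}

#' Write / read a methylation matrix as TSV
#'
#' Columns `chrom`, `pos`, `context`, then one column per sample. The
#' coverage floor and context filter travel in a `#` header line so the
#' round trip is exact.
#'
#' @param mat A `methyl_matrix`.
#' @param path Output path.
#' @return `write_methyl_matrix()`: `path` invisibly;
#'   `read_methyl_matrix()`: a `methyl_matrix`.
#' @export
write_methyl_matrix <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# coverage_floor=", mat$coverage_floor,
                    " context=", paste(mat$context_filter, collapse = ","),
                    " strict=", mat$strict), con)
  df <- cbind(mat$sites,
              as.data.frame(mat$levels, optional = TRUE))
  utils::write.table(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_methyl_matrix
#' @export
read_methyl_matrix <- function(path) {
  if (!file.exists(path)) stop_input("matrix file not found: ", path)
  header <- readLines(path, n = 1L)
  floor <- 1
  ctx <- "CG"
  strict <- FALSE
  if (startsWith(header, "#")) {
    get <- function(k) sub(paste0(".*", k, "=([^ ]+).*"), "\\1", header)
    floor <- as.numeric(get("coverage_floor"))
    ctx <- strsplit(get("context"), ",")[[1L]]
    strict <- as.logical(get("strict"))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  sites <- df[, c("chrom", "pos", "context")]
  sample_cols <- setdiff(names(df), c("chrom", "pos", "context"))
  levels <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(levels) <- site_key(sites$chrom, sites$pos)
  new_methyl_matrix(sites, sample_cols, levels, floor, ctx, strict)
}
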