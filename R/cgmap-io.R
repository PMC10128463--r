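#' Read a CGmap file of per-cytosine methylation calls
#'
#' CGmap is the 8-column tab-separated format emitted by bisulfite
#' methylation callers (BSBolt, CGmapTools): chromosome, reference base on
#' the reported strand (`C` or `G`), 1-based position, three-letter context
#' (`CG`, `CHG`, `CHH`), two-letter dinucleotide (`CA`, `CC`, `CT`, `CG`),
#' methylation level, methylated read count, total read count. Cytosines on
#' the reverse strand are reported as `base = "G"` at their own position;
#' symmetric CpG dyads are *not* merged across strands (see
#' [merge_cpg_strands()] for the optional merge).
#'
#' @param path Path to a CGmap file (plain text, tab-separated).
#' @return A `data.frame` with columns `chrom`, `base`, `pos`, `context`,
#'   `dinucleotide`, `level`, `meth_count`, `total_count`, in file order.
#' @details Printed levels in CGmap files are rounded; a level further than
#'   0.005 from `meth_count / total_count` triggers a warning naming the
#'   offending lines. Structural problems (wrong column count, non-numeric
#'   counts, counts violating `0 <= meth_count <= total_count`,
#'   `total_count >= 1`) are errors naming the first offending line.
#' @seealso [write_cgmap()], [read_sample_sheet()]
#' @export
read_cgmap <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_input("CGmap file not found: ", path)
  }
  if (file.size(path) == 0L) return(empty_records())
  fields <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(fields) == 0L) return(empty_records())
  bad <- which(fields != 8L)
  if (length(bad)) {
    stop_input("CGmap parse error: line ", bad[1L], " of ", path,
               " has ", fields[bad[1L]], " columns (expected 8)")
  }
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "base", "pos", "context",
                                        "dinucleotide", "level",
                                        "meth_count", "total_count"),
                          colClasses = c("character", "character", "character",
                                         "character", "character", "character",
                                         "character", "character"))
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      stop_input("CGmap parse error: non-numeric ", what, " at line ",
                 which(is.na(v))[1L], " of ", path)
    }
    v
  }
  df$pos <- num(df$pos, "position")
  df$level <- num(df$level, "level")
  df$meth_count <- as.integer(num(df$meth_count, "methylated count"))
  df$total_count <- as.integer(num(df$total_count, "total count"))
  bad <- which(df$total_count < 1L | df$meth_count < 0L |
                 df$meth_count > df$total_count | df$pos < 1)
  if (length(bad)) {
    stop_input("CGmap parse error: invalid counts/position at line ", bad[1L],
               " of ", path)
  }
  off <- which(abs(df$level - df$meth_count / df$total_count) > 0.005)
  if (length(off)) {
    warning("CGmap level differs from meth_count/total_count by > 0.005 at ",
            length(off), " line(s), first at line ", off[1L], " of ", path,
            call. = FALSE)
  }
  df
}

empty_records <- function() {
  data.frame(chrom = character(), base = character(), pos = numeric(),
             context = character(), dinucleotide = character(),
             level = numeric(), meth_count = integer(),
             total_count = integer(), stringsAsFactors = FALSE)
}

#' Validate a methylation-record data frame
#'
#' @param records A data frame as returned by [read_cgmap()].
#' @param recompute_level Replace `level` by `meth_count / total_count`.
#' @return The validated (possibly level-recomputed) data frame, invisibly
#'   usable in pipelines.
#' @export
validate_records <- function(records, recompute_level = FALSE) {
  needed <- c("chrom", "base", "pos", "context", "dinucleotide",
              "level", "meth_count", "total_count")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop_validation("records are missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  if (nrow(records)) {
    bad <- which(records$total_count < 1L | records$meth_count < 0L |
                   records$meth_count > records$total_count)
    if (length(bad)) {
      stop_validation("record ", bad[1L], " violates 0 <= meth_count <= ",
                      "total_count, total_count >= 1")
    }
    bad <- which((records$context == "CG") != (records$dinucleotide == "CG"))
    if (length(bad)) {
      stop_validation("record ", bad[1L],
                      ": context CG must coincide with dinucleotide CG")
    }
    if (any(records$pos < 1)) {
      stop_validation("record positions must be 1-based (pos >= 1)")
    }
  }
  if (recompute_level) records$level <- records$meth_count / records$total_count
  records
}

#' Write methylation records as a CGmap file
#'
#' The level column is recomputed as `meth_count / total_count` and printed
#' with four decimals, so `read_cgmap(write_cgmap(x))` is the identity on
#' positions and counts.
#'
#' @param records Data frame of methylation records (see [read_cgmap()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cgmap <- function(records, path) {
  records <- validate_records(records, recompute_level = TRUE)
  lines <- sprintf("%s\t%s\t%d\t%s\t%s\t%.4f\t%d\t%d",
                   records$chrom, records$base, as.integer(records$pos),
                   records$context, records$dinucleotide, records$level,
                   records$meth_count, records$total_count)
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort sample sheet
#'
#' A CSV with columns `sample_id`, `age_years`, `group`, `strain`,
#' `cgmap_path`. Relative `cgmap_path` entries are resolved against the
#' sample sheet's own directory.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame`, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_input("sample sheet not found: ", path)
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "age_years", "group", "strain", "cgmap_path")
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols)) {
    stop_input("sample sheet is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop_validation("sample_id values must be unique within a cohort")
  }
  if (any(!is.finite(sheet$age_years)) || any(sheet$age_years <= 0)) {
    stop_validation("age_years must be positive")
  }
  rel <- !file.exists(sheet$cgmap_path) &
    file.exists(file.path(dirname(path), sheet$cgmap_path))
  sheet$cgmap_path[rel] <- file.path(dirname(path), sheet$cgmap_path[rel])
  sheet
}

#' Merge symmetric CpG dyads across strands
#'
#' Optionally combines the forward-strand cytosine (base `C` at position p)
#' with its reverse-strand partner (base `G` at position p+1) into a single
#' record at the forward position, summing counts. Off by default in every
#' pipeline stage: site counts elsewhere in the package are per reported
#' position.
#'
#' @param records Methylation records (CG context rows are merged; other
#'   contexts pass through unchanged).
#' @return A records data frame with merged CpG dyads.
#' @export
merge_cpg_strands <- function(records) {
  records <- validate_records(records)
  cg <- records[records$context == "CG", , drop = FALSE]
  rest <- records[records$context != "CG", , drop = FALSE]
  if (!nrow(cg)) return(records)
  # anchor G-strand records at the forward-strand C position (pos - 1)
  anchor <- ifelse(cg$base == "G", cg$pos - 1, cg$pos)
  key <- site_key(cg$chrom, anchor)
  meth <- rowsum(cg$meth_count, key)
  tot <- rowsum(cg$total_count, key)
  first <- !duplicated(key)
  out <- data.frame(chrom = cg$chrom[first], base = "C",
                    pos = anchor[first], context = "CG",
                    dinucleotide = "CG",
                    level = NA_real_,
                    meth_count = as.integer(meth[match(key[first], rownames(meth)), 1L]),
                    total_count = as.integer(tot[match(key[first], rownames(tot)), 1L]),
                    stringsAsFactors = FALSE)
  out$level <- out$meth_count / out$total_count
  out <- rbind(out, rest)
  out[genomic_order(out$chrom, out$pos), , drop = FALSE]
}
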