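#' Read genomic elements from a GFF/GFF3 annotation
#'
#' Coordinates are converted from the GFF 1-based closed convention to the
#' package-internal 0-based half-open convention (`start = gff_start - 1`,
#' `end = gff_end`). For `source_kind = "gene"` only top-level `gene`
#' features are kept (mRNA/exon/CDS children are dropped); for
#' `source_kind = "repeat"` every feature row is kept, as in RepeatMasker
#' GFF output where each row is one repeat instance.
#'
#' @param path Path to a GFF3 (genes) or GFF (repeats) file.
#' @param source_kind `"gene"` or `"repeat"`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   (`+`, `-`, or `*` when unknown), `kind`, `name`, sorted by
#'   chromosome and start.
#' @export
read_elements <- function(path, source_kind = c("gene", "repeat")) {
  source_kind <- match.arg(source_kind)
  if (!file.exists(path)) stop_input("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff")
  if (source_kind == "gene" && length(gr)) {
    type <- as.character(gr$type)
    if (any(type == "gene")) gr <- gr[type == "gene"]
  }
  elements_from_granges(gr, source_kind)
}

elements_from_granges <- function(gr, kind) {
  n <- length(gr)
  name <- rep(NA_character_, n)
  meta <- S4Vectors::mcols(gr)
  for (col in c("ID", "Name", "name", "gene_id", "Target")) {
    if (col %in% names(meta)) {
      cand <- as.character(meta[[col]])
      name[is.na(name) & !is.na(cand)] <- cand[is.na(name) & !is.na(cand)]
    }
  }
  if (anyNA(name)) name[is.na(name)] <- paste0(kind, "_", which(is.na(name)))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    kind = rep_len(kind, n), name = name,
                    stringsAsFactors = FALSE)
  validate_elements(out)
  out[genomic_order(out$chrom, out$start), , drop = FALSE]
}

validate_elements <- function(elements) {
  needed <- c("chrom", "start", "end", "strand", "kind", "name")
  missing_cols <- setdiff(needed, names(elements))
  if (length(missing_cols)) {
    stop_validation("elements are missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  if (nrow(elements)) {
    bad <- which(elements$start < 0 | elements$start >= elements$end)
    if (length(bad)) {
      stop_validation("element ", bad[1L],
                      " violates 0 <= start < end (0-based half-open)")
    }
  }
  invisible(elements)
}

#' Read / write BED interval files
#'
#' BED is 0-based half-open already, so no coordinate shift is applied.
#' `write_bed()` emits BED4 (`chrom`, `start`, `end`, `name`).
#'
#' @param path Path to a BED3+ file.
#' @param kind Element kind to record (default `"target_region"`).
#' @return `read_bed()`: a `data.frame` of elements (see [read_elements()]);
#'   `write_bed()`: `path`, invisibly.
#' @export
read_bed <- function(path, kind = "target_region") {
  if (!file.exists(path)) stop_input("BED file not found: ", path)
  nonempty <- any(nzchar(trimws(readLines(path, warn = FALSE))))
  if (!nonempty) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), kind = character(),
                      name = character(), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    kind = kind,
                    name = if (!is.null(gr$name)) as.character(gr$name) else
                      paste0(kind, "_", seq_along(gr)),
                    stringsAsFactors = FALSE)
  if (anyNA(out$name)) {
    out$name[is.na(out$name)] <- paste0(kind, "_", which(is.na(out$name)))
  }
  validate_elements(out)
  out[genomic_order(out$chrom, out$start), , drop = FALSE]
}

#' @rdname read_bed
#' @param elements Element data frame with columns `chrom`, `start`, `end`
#'   and optionally `name`.
#' @export
write_bed <- function(elements, path) {
  if (nrow(elements)) {
    bad <- which(elements$start >= elements$end | elements$start < 0)
    if (length(bad)) {
      stop_validation("element ", bad[1L], " has start >= end; refusing to ",
                      "write invalid BED")
    }
  }
  name <- elements$name %||% paste0("region_", seq_len(nrow(elements)))
  out <- data.frame(elements$chrom, as.integer(elements$start),
                    as.integer(elements$end), name)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
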