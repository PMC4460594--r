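#' Read a chromosome-sizes table
#'
#' Parses a UCSC-style two-column TSV (chromosome name, length in bp) into a
#' genome table. File order is preserved and defines the chromosome sort order
#' used for all outputs.
#'
#' @param path Path to a two-column tab-separated file.
#' @return A tibble with columns `chrom` (character) and `length` (integer bp).
#' @examples
#' tf <- tempfile()
#' writeLines(c("chr1\t248956422", "chr2\t242193529"), tf)
#' read_genome_table(tf)
#' @export
read_genome_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- readr::read_tsv(path, col_names = c("chrom", "length"),
                         col_types = "cd", progress = FALSE)
  if (nrow(tab) == 0L) abort("Genome table is empty.")
  if (anyNA(tab$length) || any(tab$length != floor(tab$length))) {
    abort("Genome table lengths must be integers.")
  }
  if (any(duplicated(tab$chrom))) {
    abort(sprintf("Duplicated chromosome name in genome table: %s",
                  tab$chrom[duplicated(tab$chrom)][1]))
  }
  if (any(tab$length <= 0)) {
    abort(sprintf("Non-positive length for chromosome %s",
                  tab$chrom[tab$length <= 0][1]))
  }
  mutate(tab, length = as.integer(.data$length))
}

#' Read aligned reads from BED or BAM
#'
#' Loads one track of aligned, deduplicated single-end reads. BED input is
#' taken as 0-based half-open; BAM coordinates are converted to the same
#' convention on read (only primary mapped alignments are kept). No
#' deduplication is performed: the input contract is that duplicates were
#' removed upstream. When a genome table is supplied, reads on chromosomes
#' absent from it are dropped and their count reported.
#'
#' @param path Path to the alignment file.
#' @param format `"bed"` (3+ columns; column 6, when present, is the strand)
#'   or `"bam"`.
#' @param genome Optional genome table from [read_genome_table()]; reads on
#'   unlisted chromosomes are dropped with a message.
#' @return A tibble of reads with columns `chrom`, `start`, `end` (0-based
#'   half-open, integers) and `strand`.
#' @export
read_alignments <- function(path, format = c("bed", "bam"), genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  reads <- if (format == "bed") read_bed_reads(path) else read_bam_reads(path)
  if (nrow(reads) == 0L) {
    warn(sprintf("No reads in %s", path))
  }
  if (!is.null(genome)) {
    keep <- reads$chrom %in% genome$chrom
    n_drop <- sum(!keep)
    if (n_drop > 0L) {
      inform(sprintf(
        "Dropped %d read(s) on chromosomes absent from the genome table.",
        n_drop))
      reads <- reads[keep, , drop = FALSE]
    }
  }
  if (any(reads$start < 0L) || any(reads$start >= reads$end)) {
    abort("Invalid read coordinates: require 0 <= start < end.")
  }
  reads
}

read_bed_reads <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), strand = character()))
  }
  if (ncol(raw) < 3L) abort(sprintf("BED file %s has fewer than 3 columns.", path))
  start <- suppressWarnings(as.integer(raw[[2]]))
  end <- suppressWarnings(as.integer(raw[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    abort(sprintf("Unparseable BED record at line %d of %s", bad[1], path))
  }
  strand <- if (ncol(raw) >= 6L) raw[[6]] else rep("+", nrow(raw))
  strand[is.na(strand) | !(strand %in% c("+", "-"))] <- "+"
  tibble(chrom = raw[[1]], start = start, end = end, strand = strand)
}

read_bam_reads <- function(path) {
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("rname", "pos", "qwidth", "strand"))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(res$pos)
  tibble(
    chrom = as.character(res$rname[keep]),
    start = as.integer(res$pos[keep] - 1L),
    end = as.integer(res$pos[keep] - 1L + res$qwidth[keep]),
    strand = ifelse(as.character(res$strand[keep]) == "-", "-", "+")
  )
}

#' Write peak calls as BED6
#'
#' Writes peaks in BED6 dialect: `chrom, start, end, name, score, strand`,
#' with `strand = "."` and the raw region score printed with 4 decimal places
#' (not clamped to the BED 0-1000 score convention; the statistic is
#' preserved as-is). Output formatting is deterministic: the same input
#' always yields a byte-identical file.
#'
#' @param peaks A tibble with columns `chrom`, `start`, `end`, `name`,
#'   `score`, sorted by (`chrom`, `start`); sorting is the caller's
#'   responsibility and unsorted input is an error.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_peaks_bed <- function(peaks, path) {
  required <- c("chrom", "start", "end", "name", "score")
  if (!all(required %in% names(peaks))) {
    abort(sprintf("`peaks` must have columns: %s",
                  paste(required, collapse = ", ")))
  }
  if (nrow(peaks) > 0L) {
    if (any(!is.finite(peaks$score))) abort("Peak scores must be finite.")
    if (any(peaks$start >= peaks$end)) abort("Peaks must satisfy start < end.")
    blocks <- rle(peaks$chrom)$values
    unsorted_chrom <- anyDuplicated(blocks) > 0L
    unsorted_start <- any(unlist(
      tapply(peaks$start, factor(peaks$chrom, levels = unique(peaks$chrom)),
             function(s) diff(s) < 0L)))
    if (unsorted_chrom || isTRUE(unsorted_start)) {
      abort("`peaks` must be sorted by (chrom, start) before writing.")
    }
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%.4f\t.",
                   peaks$chrom, peaks$start, peaks$end, peaks$name, peaks$score)
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSS table from BED6
#'
#' Reads transcription start sites from a BED6 file where the name column
#' carries the gene identifier. The TSS position is the strand-appropriate
#' end of the interval: the `start` coordinate for `+`-strand entries and
#' `end - 1` for `-`-strand entries (for the common 1-bp BED intervals both
#' coincide).
#'
#' @param path Path to a BED6 file of TSS positions.
#' @return A tibble with columns `gene_id`, `chrom`, `tss` (0-based bp) and
#'   `strand`.
#' @export
read_tss_bed <- function(path) {
  reads <- read_bed_reads(path)
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) > 0L && ncol(raw) < 4L) {
    abort(sprintf("TSS BED %s needs a name column (BED4+).", path))
  }
  gene_id <- if (nrow(raw) > 0L) raw[[4]] else character()
  tibble(
    gene_id = gene_id,
    chrom = reads$chrom,
    tss = ifelse(reads$strand == "-", reads$end - 1L, reads$start),
    strand = reads$strand
  )
}
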