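#' Assign peaks to promoters
#'
#' Returns the genes whose promoter window — the closed interval
#' `[tss - window, tss + window]`, strand-ignored — intersects at least one
#' peak. This is the standard peak-to-gene assignment used to compare target
#' predictions across platforms.
#'
#' @param peaks A peak tibble (`chrom`, `start`, `end`, 0-based half-open).
#' @param tss A TSS table from [read_tss_bed()] or with columns `gene_id`,
#'   `chrom`, `tss`.
#' @param window Half-width of the promoter window in bp (default 2000).
#' @return A sorted character vector of unique gene ids.
#' @export
assign_to_promoters <- function(peaks, tss, window = 2000L) {
  if (nrow(peaks) == 0L || nrow(tss) == 0L) return(character())
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  win_gr <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(start = pmax(tss$tss - window, 0L) + 1L,
                                end = tss$tss + window + 1L))
  hits <- GenomicRanges::findOverlaps(win_gr, peak_gr)
  sort(unique(tss$gene_id[unique(S4Vectors::queryHits(hits))]))
}

#' Jaccard similarity between two gene sets
#'
#' The ratio of intersection to union sizes, the reproducibility measure used
#' to compare target-promoter predictions between replicate experiments.
#' Defined as 0 when both sets are empty.
#'
#' @param set_a,set_b Vectors of gene ids (duplicates ignored).
#' @return A fraction in \[0, 1\].
#' @examples
#' jaccard_index(c("g1", "g2", "g3"), c("g2", "g3", "g4"))  # 0.5
#' @export
jaccard_index <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Precision and recall against truth peaks
#'
#' For simulated data with a known truth set: a truth peak is *recovered*
#' when some called peak intersects it after expanding the truth interval by
#' `slack` bp on both sides; a called peak is *correct* when it intersects
#' some slack-expanded truth peak. Recall is the recovered fraction of truth
#' peaks, precision the correct fraction of calls. With no calls and no
#' truth, precision is 1 by convention; otherwise empty denominators give 0.
#'
#' @param peaks Called peaks (`chrom`, `start`, `end`).
#' @param truth Truth peaks (`chrom`, `start`, `end`), e.g. from
#'   [simulate_tracks()].
#' @param slack Non-negative expansion in bp applied to truth intervals.
#' @return A one-row tibble: `precision`, `recall`, `n_called`, `n_truth`,
#'   `n_recovered`, `n_correct`.
#' @export
match_to_truth <- function(peaks, truth, slack = 0L) {
  stopifnot(slack >= 0L)
  n_called <- nrow(peaks)
  n_truth <- nrow(truth)
  if (n_called == 0L || n_truth == 0L) {
    precision <- if (n_called == 0L && n_truth == 0L) 1 else 0
    return(tibble(precision = precision, recall = 0,
                  n_called = n_called, n_truth = n_truth,
                  n_recovered = 0L, n_correct = 0L))
  }
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  truth_gr <- GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(start = pmax(truth$start - slack, 0L) + 1L,
                                  end = truth$end + slack))
  hits <- GenomicRanges::findOverlaps(truth_gr, peak_gr)
  n_recovered <- length(unique(S4Vectors::queryHits(hits)))
  n_correct <- length(unique(S4Vectors::subjectHits(hits)))
  tibble(precision = n_correct / n_called, recall = n_recovered / n_truth,
         n_called = n_called, n_truth = n_truth,
         n_recovered = n_recovered, n_correct = n_correct)
}
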