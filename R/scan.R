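#' Count reads in overlapping fixed-length segments
#'
#' Scans each chromosome in overlapping windows ("segments") of length `L`
#' starting at offsets `0, step, 2 * step, ...` while the full window fits on
#' the chromosome. A read is assigned to a segment when its leftmost mapped
#' coordinate lies inside the window; no strand shifting or fragment
#' extension is applied. Every segment is emitted, including empty ones —
#' they populate the null distribution.
#'
#' For each segment the IP read count is the *magnitude* `m`, the control
#' count is `mbar`, and their sum the *amplitude* `a = m + mbar`.
#'
#' @param ip,control Equal-sized read tibbles (see [normalize_tracks()]).
#' @param genome Genome table from [read_genome_table()].
#' @param config A [dip_config()].
#' @return A tibble with columns `chrom`, `start`, `m`, `mbar`, `a`, one row
#'   per segment, ordered by genome-table chromosome order then `start`.
#' @export
scan_segments <- function(ip, control, genome, config = dip_config()) {
  stopifnot(inherits(config, "dip_config"))
  L <- config$L
  step <- config$step
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    chrom <- genome$chrom[i]
    C <- genome$length[i]
    if (C < L) {
      inform(sprintf("Chromosome %s (%d bp) is shorter than L = %d; skipped.",
                     chrom, C, L))
      return(tibble(chrom = character(), start = integer(),
                    m = integer(), mbar = integer(), a = integer()))
    }
    n_seg <- (C - L) %/% step + 1L
    starts <- (seq_len(n_seg) - 1L) * step
    m <- window_counts(ip$start[ip$chrom == chrom], n_seg, L, step)
    mbar <- window_counts(control$start[control$chrom == chrom], n_seg, L, step)
    tibble(chrom = chrom, start = starts, m = m, mbar = mbar, a = m + mbar)
  })
}

# Rolling window counts via per-step bins: window i (1-based) covers bins
# i .. i + L/step - 1, so a cumulative sum over bin counts gives all windows
# in O(n). Positions beyond the last window's end never contribute.
window_counts <- function(pos, n_seg, L, step) {
  w <- L %/% step
  n_bins <- n_seg + w - 1L
  if (length(pos) == 0L) return(integer(n_seg))
  bin <- pos %/% step + 1L
  bin <- bin[bin >= 1L & bin <= n_bins]
  counts <- tabulate(bin, nbins = n_bins)
  cs <- c(0L, cumsum(counts))
  as.integer(cs[seq_len(n_seg) + w] - cs[seq_len(n_seg)])
}
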