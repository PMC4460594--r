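#' Merge significant segments into candidate regions
#'
#' On each chromosome, consecutive significant segments whose spans
#' (`[start, start + L)`) are separated by a gap smaller than `delta` are
#' joined transitively into one candidate region; overlapping or touching
#' spans always merge. A region runs from the first merged segment's start to
#' the last one's end. IP and control totals are then *recounted* from the
#' raw reads over the merged interval — summing overlapping windows would
#' count each read up to `L/step` times.
#'
#' @param significant Significant segments from [flag_significant()], sorted
#'   by (`chrom`, `start`).
#' @param ip,control The (normalized) read tracks used for the scan.
#' @param config A [dip_config()].
#' @return A tibble with columns `chrom`, `start`, `end`, `m_total`,
#'   `mbar_total`, `n_segments` (number of merged significant segments).
#' @export
merge_significant <- function(significant, ip, control, config = dip_config()) {
  stopifnot(inherits(config, "dip_config"))
  L <- config$L
  delta <- config$delta
  if (nrow(significant) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  m_total = integer(), mbar_total = integer(),
                  n_segments = integer()))
  }
  purrr::map_dfr(split_in_order(significant), function(seg) {
    if (is.unsorted(seg$start)) {
      abort("Significant segments must be sorted by (chrom, start).")
    }
    gap <- seg$start[-1L] - (seg$start[-nrow(seg)] + L)
    grp <- cumsum(c(TRUE, gap >= delta))
    this_chrom <- seg$chrom[1]
    start <- as.integer(tapply(seg$start, grp, min))
    end <- as.integer(tapply(seg$start, grp, max)) + L
    m_total <- count_in_intervals(ip$start[ip$chrom == this_chrom], start, end)
    mbar_total <- count_in_intervals(control$start[control$chrom == this_chrom],
                                     start, end)
    tibble(chrom = this_chrom, start = start, end = end,
           m_total = m_total, mbar_total = mbar_total,
           n_segments = as.integer(tabulate(grp)))
  })
}

split_in_order <- function(df) {
  split(df, factor(df$chrom, levels = unique(df$chrom)))
}

# reads with leftmost coordinate in [start, end), vectorized over intervals
count_in_intervals <- function(pos, start, end) {
  pos <- sort(pos)
  lo <- findInterval(start - 0.5, pos)
  hi <- findInterval(end - 0.5, pos)
  as.integer(hi - lo)
}

#' Filter candidate regions on length and control fraction
#'
#' Keeps regions that are at least `k` bp long and whose control-read
#' fraction `mbar_total / (m_total + mbar_total)` is below the FDR cutoff
#' `phi` — a region-level significance check mirroring the segment-level
#' FDR. Regions with no reads at all are dropped.
#'
#' @param regions Candidate regions from [merge_significant()].
#' @param config A [dip_config()].
#' @return The surviving subset of `regions`.
#' @export
filter_regions <- function(regions, config = dip_config()) {
  stopifnot(inherits(config, "dip_config"))
  if (nrow(regions) == 0L) return(regions)
  total <- regions$m_total + regions$mbar_total
  keep <- (regions$end - regions$start) >= config$k &
    total > 0L &
    regions$mbar_total / pmax(total, 1L) < config$phi
  regions[keep, , drop = FALSE]
}

#' Score regions with the divergence statistic
#'
#' Scores each region as the sum, over all scanned segments fully contained
#' in it, of `a * ln(m / mbar)`. The statistic equals the difference of
#' unnormalized Kullback-Leibler divergences between the IP and control count
#' profiles, `D_KL(m || mbar) - D_KL(mbar || m)`: large positive scores mean
#' the control profile carries far less information than the IP profile, i.e.
#' consistent IP enrichment across the region. Long enriched regions
#' accumulate evidence from more segments and are deliberately rewarded with
#' higher scores.
#'
#' Segments where either count is zero would make the logarithm undefined;
#' for those segments only, the pseudocount is added to both numerator and
#' denominator. Empty segments (`a = 0`) contribute zero.
#'
#' @param regions Regions from [merge_significant()] / [filter_regions()].
#' @param segments The full scanned-segment table the regions were derived
#'   from (all segments, not only significant ones).
#' @param config A [dip_config()].
#' @return `regions` with a `score` column appended.
#' @export
score_regions <- function(regions, segments, config = dip_config()) {
  stopifnot(inherits(config, "dip_config"))
  if (nrow(regions) == 0L) {
    return(mutate(regions, score = numeric(0)))
  }
  L <- config$L
  contrib <- segment_score_contrib(segments, config)
  scores <- numeric(nrow(regions))
  for (chrom in unique(regions$chrom)) {
    seg_idx <- which(segments$chrom == chrom)
    reg_idx <- which(regions$chrom == chrom)
    s_start <- segments$start[seg_idx]
    cs <- c(0, cumsum(contrib[seg_idx]))
    # contained segments: start >= region start and start + L <= region end
    lo <- findInterval(regions$start[reg_idx] - 0.5, s_start)
    hi <- findInterval(regions$end[reg_idx] - L + 0.5 - 1e-9, s_start)
    none <- hi <= lo
    if (any(none)) {
      warn(sprintf("%d region(s) contain no scanned segment; scored 0.",
                   sum(none)))
    }
    scores[reg_idx] <- ifelse(none, 0, cs[pmax(hi, lo) + 1L] - cs[lo + 1L])
  }
  mutate(regions, score = scores)
}

# per-segment score contribution a * ln(m / mbar), with the pseudocount
# applied to both counts only where one of them is zero
segment_score_contrib <- function(segments, config) {
  m <- segments$m
  mbar <- segments$mbar
  c0 <- config$pseudocount
  needs_pc <- m == 0L | mbar == 0L
  ratio <- ifelse(needs_pc, (m + c0) / (mbar + c0), m / mbar)
  contrib <- segments$a * log(ratio)
  contrib[segments$a == 0L] <- 0
  contrib
}

#' Re-centre regions to a fixed output length
#'
#' Replaces each region by a fixed-length interval centred at the region
#' midpoint (rounded down), clipped at the chromosome boundaries. A common
#' post-processing step when comparing callers whose native region lengths
#' differ.
#'
#' @param regions Scored regions (with `chrom`, `start`, `end`, `score`).
#' @param length Target length in bp.
#' @param genome Genome table, used for boundary clipping.
#' @return A peak tibble with columns `chrom`, `start`, `end`, `name`,
#'   `score`.
#' @export
standardize_region_length <- function(regions, length = 800L, genome) {
  stopifnot(length > 0L)
  half <- as.integer(length) %/% 2L
  chrom_len <- genome$length[match(regions$chrom, genome$chrom)]
  center <- (regions$start + regions$end) %/% 2L
  start <- pmax(center - half, 0L)
  end <- pmin(center + (as.integer(length) - half), chrom_len)
  tibble(chrom = regions$chrom,
         start = as.integer(start),
         end = as.integer(end),
         name = sprintf("peak_%d", seq_len(nrow(regions))),
         score = if ("score" %in% names(regions)) regions$score
                 else rep(0, nrow(regions)))
}
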