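#' Call peaks from IP and control read tracks
#'
#' Runs the full caller: library-size normalization by resampling, the
#' overlapping-segment scan, the empirical `N(a, m)` null table, the
#' per-amplitude magnitude thresholds at FDR `phi`, segment flagging, gap
#' merging, the length and control-fraction region filters, divergence
#' scoring and (optionally) re-centring to a fixed output length. The result
#' is fully deterministic given the seed in `config`.
#'
#' @param ip,control Read tibbles from [read_alignments()] or
#'   [simulate_tracks()].
#' @param genome Genome table from [read_genome_table()].
#' @param config A [dip_config()].
#' @return An object of class `dip_result`, a list with elements:
#'   \describe{
#'     \item{peaks}{tibble of peak calls (`chrom`, `start`, `end`, `name`,
#'       `score`), sorted by genome-table chromosome order then start.}
#'     \item{regions}{the scored merged regions before length
#'       standardization.}
#'     \item{thresholds}{the `dip_thresholds` table.}
#'     \item{null}{the `dip_null` table.}
#'     \item{n_segments, n_significant}{scan bookkeeping.}
#'     \item{config, genome}{the inputs that shaped the run.}
#'   }
#' @examples
#' sim <- simulate_tracks(sim_config(
#'   genome_length = 50000, n_reads_ip = 4000, n_reads_control = 4000,
#'   peaks = data.frame(center = 25000, width = 400, fold = 10), seed = 1))
#' res <- call_peaks(sim$ip, sim$control, sim$genome)
#' tidy(res)
#' @export
call_peaks <- function(ip, control, genome, config = dip_config()) {
  stopifnot(inherits(config, "dip_config"))
  norm <- normalize_tracks(ip, control, seed = config$seed)
  segments <- scan_segments(norm$ip, norm$control, genome, config)
  null <- build_null_table(segments)
  thresholds <- compute_min_magnitude(null, config$phi)
  significant <- flag_significant(segments, thresholds)
  regions <- merge_significant(significant, norm$ip, norm$control, config)
  regions <- filter_regions(regions, config)
  regions <- score_regions(regions, segments, config)
  regions <- arrange(regions,
                     factor(.data$chrom, levels = genome$chrom),
                     .data$start, .data$end)
  peaks <- if (is.null(config$standard_length)) {
    tibble(chrom = regions$chrom, start = regions$start, end = regions$end,
           name = sprintf("peak_%d", seq_len(nrow(regions))),
           score = regions$score)
  } else {
    standardize_region_length(regions, config$standard_length, genome)
  }
  structure(
    list(peaks = peaks, regions = regions, thresholds = thresholds,
         null = null, n_segments = nrow(segments),
         n_significant = nrow(significant), config = config, genome = genome),
    class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat("<dip_result>\n")
  cat(sprintf("  %d segments scanned, %d flagged significant (phi = %g)\n",
              x$n_segments, x$n_significant, x$config$phi))
  cat(sprintf("  %d peak(s) called\n", nrow(x$peaks)))
  if (nrow(x$peaks) > 0L) {
    print(utils::head(x$peaks, 5))
    if (nrow(x$peaks) > 5L) cat(sprintf("  ... and %d more\n", nrow(x$peaks) - 5L))
  }
  invisible(x)
}

#' @describeIn call_peaks One row per peak call.
#' @param x,object A `dip_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dip_result <- function(x, ...) {
  x$peaks
}

#' @describeIn call_peaks One-row run summary: segment and peak counts,
#'   flagged fraction and the parameters that shaped them.
#' @exportS3Method generics::glance
glance.dip_result <- function(x, ...) {
  tibble(
    n_segments = x$n_segments,
    n_significant = x$n_significant,
    frac_significant = x$n_significant / x$n_segments,
    n_peaks = nrow(x$peaks),
    phi = x$config$phi,
    L = x$config$L,
    delta = x$config$delta,
    k = x$config$k
  )
}

#' @describeIn call_peaks Peak score vs genomic position, one panel per
#'   chromosome, with the number of calls in the title.
#' @exportS3Method ggplot2::autoplot
autoplot.dip_result <- function(object, ...) {
  peaks <- object$peaks
  ggplot2::ggplot(peaks,
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$score)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = .data$score)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "region score",
                  title = sprintf("%d peak call(s)", nrow(peaks))) +
    ggplot2::theme_minimal()
}
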