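#' Simulation parameters
#'
#' Describes a synthetic single-chromosome ChIP-seq experiment: a shared
#' non-uniform background intensity (the same for IP and control, standing in
#' for mappability and accessibility bias) plus IP-only enrichment peaks of
#' configurable width and fold.
#'
#' The defaults describe the benchmark conditions used throughout the
#' package's tests: a 1 Mb chromosome with 1e5 single-end 50 bp reads per
#' track, background intensity piecewise-constant over 1 kb bins with
#' log-normal bin weights of log-scale standard deviation 0.5 (kilobase-scale
#' accessibility variation of roughly two- to three-fold across the
#' chromosome).
#'
#' @param genome_length Chromosome length in bp.
#' @param chrom_name Chromosome name used in all outputs.
#' @param n_reads_ip,n_reads_control Exact read counts per track.
#' @param read_length Read length in bp (single-end).
#' @param background_bins Number of equal-width piecewise-constant background
#'   bins.
#' @param background_log_sd Standard deviation of the natural-log bin
#'   weights; 0 gives a uniform background.
#' @param peaks A data frame with columns `center`, `width` (bp) and `fold`
#'   (enrichment multiplier, >= 1) — one row per spiked peak; may be empty.
#' @param seed Integer seed; the full simulation is deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, chrom_name = "chrS",
                       n_reads_ip = 1e5, n_reads_control = 1e5,
                       read_length = 50L, background_bins = 1000L,
                       background_log_sd = 0.5,
                       peaks = data.frame(center = numeric(),
                                          width = numeric(),
                                          fold = numeric()),
                       seed = 1L) {
  genome_length <- as.integer(genome_length)
  peaks <- as_tibble(peaks)
  stopifnot(genome_length > 0L, n_reads_ip > 0, n_reads_control > 0,
            read_length > 0, background_bins > 0, background_log_sd >= 0,
            all(c("center", "width", "fold") %in% names(peaks)) ||
              nrow(peaks) == 0L)
  if (nrow(peaks) > 0L) {
    if (any(peaks$fold < 1)) abort("Peak fold must be >= 1.")
    if (any(peaks$width <= 0)) abort("Peak width must be positive.")
    pstart <- peaks$center - peaks$width %/% 2
    pend <- pstart + peaks$width
    if (any(pstart < 0 | pend > genome_length)) {
      abort("Every peak interval must lie within the genome.")
    }
  }
  structure(
    list(genome_length = genome_length, chrom_name = chrom_name,
         n_reads_ip = as.integer(n_reads_ip),
         n_reads_control = as.integer(n_reads_control),
         read_length = as.integer(read_length),
         background_bins = as.integer(background_bins),
         background_log_sd = background_log_sd,
         peaks = peaks, seed = as.integer(seed)),
    class = "sim_config")
}

#' Shared background intensity table
#'
#' Draws the piecewise-constant background intensity: one log-normal weight
#' per bin (log-mean 0, log-sd `background_log_sd`), normalized to sum to 1.
#' The identical table drives both IP and control read placement, so the
#' bias cancels in the IP-vs-control comparison — exactly the role of shared
#' technical bias in real data.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `bin`, `start`, `end`, `weight`
#'   (weights sum to 1).
#' @export
build_background_intensity <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nb <- config$background_bins
  z <- withr::with_seed(config$seed, stats::rnorm(nb, 0, config$background_log_sd))
  w <- exp(z)
  edges <- round(seq(0, config$genome_length, length.out = nb + 1L))
  tibble(bin = seq_len(nb),
         start = as.integer(edges[-length(edges)]),
         end = as.integer(edges[-1L]),
         weight = w / sum(w))
}

#' Simulate IP and control read tracks with spiked peaks
#'
#' Control read leftmost positions are drawn from the background intensity
#' alone; IP positions from the background with each peak interval's
#' intensity multiplied by its fold and the whole track renormalized.
#' Within the chosen piecewise-constant interval, leftmost positions are
#' uniform; read ends are clipped at the chromosome boundary. Both tracks
#' have exactly the requested number of reads.
#'
#' @param config A [sim_config()].
#' @return A list with elements `ip` and `control` (read tibbles), `truth`
#'   (tibble `chrom`, `start`, `end`, `fold`, one row per spiked peak) and
#'   `genome` (a one-row genome table).
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$genome_length
  rl <- config$read_length
  bg <- build_background_intensity(config)
  # refine the bin partition at peak edges so peak intervals are exact
  pstart <- as.integer(config$peaks$center - config$peaks$width %/% 2)
  pend <- as.integer(pstart + config$peaks$width)
  cuts <- sort(unique(c(bg$start, bg$end, pstart, pend)))
  lo <- cuts[-length(cuts)]
  hi <- cuts[-1L]
  width <- hi - lo
  dens <- bg$weight[findInterval(lo, bg$start)] /
    pmax(bg$end - bg$start, 1L)[findInterval(lo, bg$start)]
  w_ctl <- dens * width
  boost <- rep(1, length(lo))
  if (length(pstart) > 0L) {
    for (i in seq_along(pstart)) {
      inside <- lo >= pstart[i] & hi <= pend[i]
      boost[inside] <- boost[inside] * config$peaks$fold[i]
    }
  }
  w_ip <- w_ctl * boost
  draw <- function(n, w) {
    iv <- sample.int(length(w), n, replace = TRUE, prob = w)
    pos <- lo[iv] + floor(stats::runif(n) * width[iv])
    as.integer(pmin(pos, G - 1L))
  }
  withr::with_seed(config$seed, {
    stats::rnorm(config$background_bins)  # consume the background draw
    ip_pos <- draw(config$n_reads_ip, w_ip)
    ctl_pos <- draw(config$n_reads_control, w_ctl)
  })
  mk_reads <- function(pos) {
    tibble(chrom = config$chrom_name, start = pos,
           end = pmin(pos + rl, G), strand = "+")
  }
  truth <- tibble(chrom = rep(config$chrom_name, length(pstart)),
                  start = pstart, end = pend,
                  fold = config$peaks$fold)
  list(ip = mk_reads(ip_pos), control = mk_reads(ctl_pos), truth = truth,
       genome = tibble(chrom = config$chrom_name, length = G))
}

#' Write a simulated experiment to disk
#'
#' Writes `ip.bed`, `control.bed`, `truth.bed` and `genome.tsv` into a
#' directory. Deterministic: re-running with the same simulation yields
#' byte-identical files.
#'
#' @param sim Result of [simulate_tracks()].
#' @param out_dir Output directory; created if missing.
#' @return Invisibly, the four file paths.
#' @export
write_simulation <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory %s", out_dir))
  }
  write_reads_bed <- function(reads, path) {
    writeLines(sprintf("%s\t%d\t%d\t.\t0\t%s",
                       reads$chrom, reads$start, reads$end, reads$strand),
               path)
  }
  paths <- file.path(out_dir, c("ip.bed", "control.bed", "truth.bed",
                                "genome.tsv"))
  write_reads_bed(sim$ip, paths[1])
  write_reads_bed(sim$control, paths[2])
  writeLines(sprintf("%s\t%d\t%d\tpeak_%d\t%g\t.",
                     sim$truth$chrom, sim$truth$start, sim$truth$end,
                     seq_len(nrow(sim$truth)), sim$truth$fold),
             paths[3])
  writeLines(sprintf("%s\t%d", sim$genome$chrom, sim$genome$length), paths[4])
  invisible(paths)
}
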