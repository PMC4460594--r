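# Shared fixture builders and independent oracles.

make_reads <- function(starts, chrom = "chr1", read_length = 50L,
                       strand = "+") {
  tibble::tibble(chrom = chrom, start = as.integer(starts),
                 end = as.integer(starts) + as.integer(read_length),
                 strand = strand)
}

make_genome <- function(lengths, chroms = paste0("chr", seq_along(lengths))) {
  tibble::tibble(chrom = chroms, length = as.integer(lengths))
}

# Independent brute-force oracle for the magnitude threshold: for each
# amplitude, scan every candidate magnitude m in 0..a+1 and take the first
# whose upper-tail fraction is within phi; then apply the monotone max-rule
# over a dense amplitude index with inheritance at unobserved amplitudes.
oracle_thresholds <- function(null_tbl, phi) {
  amps <- sort(unique(null_tbl$a))
  raw <- vapply(amps, function(a0) {
    sub <- null_tbl[null_tbl$a == a0, ]
    tot <- sum(sub$n)
    for (mm in 0:(a0 + 1L)) {
      if (sum(sub$n[sub$m >= mm]) / tot <= phi) return(as.integer(mm))
    }
    stop("unreachable")
  }, integer(1))
  a_max <- max(amps)
  enforced <- integer(a_max + 1L)
  run <- 1L
  for (a0 in 0:a_max) {
    i <- match(a0, amps)
    if (!is.na(i)) run <- max(run, raw[i])
    enforced[a0 + 1L] <- run
  }
  list(raw = tibble::tibble(a = amps, m_min_raw = raw), enforced = enforced)
}

# Random sparse null table: amplitudes <= a_max, a random subset of
# magnitudes per amplitude, counts up to n_max.
random_null_table <- function(a_max = 30L, n_max = 1e4L) {
  amps <- sort(sample.int(a_max + 1L, sample(2:8, 1)) - 1L)
  purrr::map_dfr(amps, function(a0) {
    ms <- sort(sample.int(a0 + 1L, sample.int(min(a0 + 1L, 6L), 1)) - 1L)
    tibble::tibble(a = a0, m = ms, n = sample.int(n_max, length(ms)))
  })
}

# turn a (a, m, n) tibble into the dip_null class the package builds
as_null <- function(tbl) {
  structure(dplyr::arrange(tbl, a, m),
            class = c("dip_null", class(tbl)),
            n_segments = sum(tbl$n))
}

# Deterministic read landscape with a known calling outcome:
# - uniform background: 1 read per 25 bp on both tracks (4 per 100 bp segment)
# - 130 "hot" balanced windows (40 extra reads per track each) that populate
#   the high-amplitude classes of the null without being IP-enriched
# - one IP-only cluster at [50000, 50400) with 80 extra IP reads per 100 bp
# - one control-only cluster of the same shape at [80000, 80400), so both
#   tracks have identical sizes and normalization is an exact no-op
# Every grid-aligned count is exact, so the flagged set, merged region and
# filter outcome are derivable by hand (see test-pipeline.R).
deterministic_landscape <- function() {
  G <- 100000L
  uniform <- seq(0L, G - 25L, by = 25L)
  quarter_block <- function(anchor, per_quarter) {
    unlist(lapply(anchor, function(h) {
      rep(h + c(0L, 25L, 50L, 75L), each = per_quarter) +
        seq_len(per_quarter) - 1L
    }))
  }
  hot <- seq(1000L, by = 300L, length.out = 130L)
  hot_extra <- quarter_block(hot, 10L)          # 40 per window per track
  cluster <- function(at) {
    unlist(lapply(seq(at, at + 375L, by = 25L),
                  function(q) q + 0:19))        # 20 extra per 25 bp
  }
  ip <- make_reads(c(uniform, hot_extra, cluster(50000L)))
  control <- make_reads(c(uniform, hot_extra, cluster(80000L)))
  list(ip = ip, control = control, genome = make_genome(G, "chr1"),
       cluster = c(50000L, 50400L))
}
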