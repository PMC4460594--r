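small_cfg <- function(...) {
  sim_config(genome_length = 50000, n_reads_ip = 2000, n_reads_control = 2000,
             background_bins = 50, ...)
}

test_that("background intensity is normalized, deterministic, and flat at sd 0", {
  cfg <- small_cfg(background_log_sd = 0, seed = 3)
  bg <- build_background_intensity(cfg)
  expect_equal(nrow(bg), 50L)
  expect_equal(bg$weight, rep(1 / 50, 50))
  expect_equal(sum(bg$weight), 1)

  cfg2 <- small_cfg(background_log_sd = 0.5, seed = 3)
  expect_identical(build_background_intensity(cfg2),
                   build_background_intensity(cfg2))
  expect_equal(sum(build_background_intensity(cfg2)$weight), 1)
  expect_false(isTRUE(all.equal(build_background_intensity(cfg2)$weight,
                                rep(1 / 50, 50))))
})

test_that("simulated tracks have exact sizes and valid coordinates", {
  cfg <- small_cfg(background_log_sd = 0.5, seed = 11,
                   peaks = data.frame(center = 25000, width = 400, fold = 8))
  sim <- simulate_tracks(cfg)
  expect_equal(nrow(sim$ip), 2000L)
  expect_equal(nrow(sim$control), 2000L)
  expect_true(all(sim$ip$start >= 0 & sim$ip$start < 50000))
  expect_true(all(sim$ip$end <= 50000))
  expect_true(all(sim$ip$end > sim$ip$start))
  expect_equal(sim$truth$start, 24800L)
  expect_equal(sim$truth$end, 25200L)
  expect_equal(sim$genome$length, 50000L)
})

test_that("zero peaks means identical generative law; truth is empty", {
  cfg <- small_cfg(background_log_sd = 0.4, seed = 21)
  sim <- simulate_tracks(cfg)
  expect_equal(nrow(sim$truth), 0L)
  # under no peaks, IP and control bin fractions agree with the intensity
  # table (chi-square goodness of fit, alpha = 0.01)
  bg <- build_background_intensity(cfg)
  big <- sim_config(genome_length = 50000, n_reads_ip = 1e5,
                    n_reads_control = 1e5, background_bins = 50,
                    background_log_sd = 0.4, seed = 21)
  sim_big <- simulate_tracks(big)
  for (track in list(sim_big$ip, sim_big$control)) {
    obs <- tabulate(findInterval(track$start, bg$start), nbins = 50)
    p <- suppressWarnings(chisq.test(obs, p = bg$weight)$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("fold = 1 peaks reduce to the null; enrichment grows with fold", {
  base <- small_cfg(background_log_sd = 0, seed = 5)
  ratios <- vapply(c(1, 2, 5, 10), function(f) {
    cfg <- small_cfg(background_log_sd = 0, seed = 5,
                     peaks = data.frame(center = 25000, width = 2000,
                                        fold = f))
    sim <- simulate_tracks(cfg)
    inside <- function(r) sum(r$start >= 24000 & r$start < 26000)
    (inside(sim$ip) + 1) / (inside(sim$control) + 1)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_equal(ratios[1], 1, tolerance = 0.3)

  # a fold-1 peak leaves the IP law identical to the background draw
  cfg1 <- small_cfg(background_log_sd = 0, seed = 5,
                    peaks = data.frame(center = 25000, width = 2000, fold = 1))
  expect_equal(nrow(simulate_tracks(cfg1)$truth), 1L)
})

test_that("peaks outside the genome are rejected", {
  expect_error(small_cfg(peaks = data.frame(center = 49950, width = 400,
                                            fold = 5)),
               "within the genome")
  expect_error(small_cfg(peaks = data.frame(center = 100, width = 400,
                                            fold = 0.5)),
               "fold")
})

test_that("written simulations round-trip and are byte-identical across runs", {
  cfg <- small_cfg(background_log_sd = 0.5, seed = 13,
                   peaks = data.frame(center = c(10000, 30000), width = 400,
                                      fold = 10))
  sim <- simulate_tracks(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(sim, d1)
  write_simulation(simulate_tracks(cfg), d2)
  for (f in c("ip.bed", "control.bed", "truth.bed", "genome.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_length(readLines(file.path(d1, "truth.bed")), 2L)

  genome <- read_genome_table(file.path(d1, "genome.tsv"))
  ip_back <- read_alignments(file.path(d1, "ip.bed"), "bed", genome)
  expect_equal(sort(ip_back$start), sort(sim$ip$start))
  expect_equal(nrow(ip_back), nrow(sim$ip))
})
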