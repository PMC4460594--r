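#' Build the empirical (amplitude, magnitude) null table
#'
#' Tallies the scanned segments into the sparse table `N(a, m)`: the number of
#' genome segments with amplitude `a` and magnitude `m`. This empirical joint
#' distribution is the nonparametric null against which segments are judged —
#' a segment is compared only with other segments carrying the same total
#' read support.
#'
#' @param segments Segment tibble from [scan_segments()] (one genome-wide
#'   scan; must be non-empty).
#' @return A tibble of class `dip_null` with columns `a`, `m`, `n`
#'   (all counts positive), carrying the total number of scanned segments as
#'   attribute `n_segments`.
#' @export
build_null_table <- function(segments) {
  if (nrow(segments) == 0L) {
    abort("Cannot build a null table from zero segments.")
  }
  tab <- segments |>
    count(.data$a, .data$m, name = "n") |>
    arrange(.data$a, .data$m)
  structure(tab, class = c("dip_null", class(tab)),
            n_segments = nrow(segments))
}

#' Per-amplitude totals of a null table
#'
#' @param null A `dip_null` table.
#' @return A tibble with columns `a` and `total` (segments at that amplitude).
#' @export
null_totals <- function(null) {
  null |>
    as_tibble() |>
    group_by(.data$a) |>
    summarise(total = sum(.data$n), .groups = "drop")
}

#' Minimum significant magnitude per amplitude
#'
#' For each amplitude `a`, computes the upper-tail fraction
#' `U(a, m) = sum over m' >= m of N(a, m') / total(a)` and takes the raw
#' threshold `m_min(a)` as the smallest magnitude with `U(a, m) <= phi`
#' (`U(a, a + 1) = 0`, so a threshold always exists; `m_min = a + 1` encodes
#' "no magnitude at this amplitude is significant"). The threshold is then
#' forced to be non-decreasing in amplitude by sweeping upward with
#' `m_min(a) <- max(m_min(a), m_min(a - 1))`; amplitudes not observed in the
#' table inherit the previous amplitude's value.
#'
#' @param null A `dip_null` table from [build_null_table()].
#' @param phi FDR cutoff in (0, 1).
#' @return A tibble of class `dip_thresholds` with one row per amplitude
#'   `0 .. max(a)`: columns `a`, `total` (0 for unobserved amplitudes),
#'   `m_min_raw` (NA when unobserved) and `m_min` (monotone-enforced).
#'   The cutoff is carried as attribute `phi`.
#' @export
compute_min_magnitude <- function(null, phi = 0.1) {
  if (!(is.numeric(phi) && length(phi) == 1L && phi > 0 && phi < 1)) {
    abort("`phi` must be a single fraction in (0, 1).")
  }
  if (nrow(null) == 0L) abort("Empty null table.")
  raw <- null |>
    as_tibble() |>
    group_by(.data$a) |>
    summarise(total = sum(.data$n),
              m_min_raw = raw_m_min(.data$m, .data$n, phi),
              .groups = "drop")
  a_max <- max(raw$a)
  dense <- left_join(tibble(a = 0:a_max), raw, by = "a")
  dense$total[is.na(dense$total)] <- 0L
  # monotone sweep; unobserved amplitudes inherit the running maximum
  # (raw thresholds are always >= 1, so 1 is a neutral starting value)
  m_min <- dense$m_min_raw
  run <- 1L
  for (i in seq_along(m_min)) {
    run <- max(run, m_min[i], na.rm = TRUE)
    m_min[i] <- run
  }
  dense$m_min <- as.integer(m_min)
  structure(dense, class = c("dip_thresholds", class(dense)), phi = phi)
}

# Smallest m with upper-tail fraction <= phi, for one amplitude's sparse
# counts. Tail mass at m equals the suffix sum over observed magnitudes >= m;
# the first suffix sum within budget pins the threshold just above the
# previous observed magnitude.
raw_m_min <- function(m, n, phi) {
  ord <- order(m)
  m <- m[ord]
  n <- n[ord]
  suffix <- rev(cumsum(rev(n)))
  j <- which(suffix / sum(n) <= phi)
  if (length(j) == 0L) {
    m[length(m)] + 1L   # even the top magnitude exceeds the budget
  } else {
    j <- j[1]
    if (j == 1L) m[1] else m[j - 1L] + 1L
  }
}

#' Keep segments at or above the magnitude threshold
#'
#' Flags the segments whose IP magnitude reaches the minimum significant
#' magnitude for their amplitude, `m >= m_min(a)`.
#'
#' @param segments Segment tibble from [scan_segments()].
#' @param thresholds A `dip_thresholds` table built from these segments'
#'   null table; a segment amplitude missing from the table is an error
#'   (it cannot happen when the table comes from the same scan).
#' @return The significant subset of `segments`, original order preserved.
#' @export
flag_significant <- function(segments, thresholds) {
  if (nrow(segments) == 0L) return(segments)
  lookup <- thresholds$m_min
  if (any(segments$a > max(thresholds$a))) {
    abort("Segment amplitude missing from the threshold table.")
  }
  mmin <- lookup[segments$a + 1L]
  segments[segments$m >= mmin, , drop = FALSE]
}

#' Write a threshold table as TSV
#'
#' Dumps the per-amplitude thresholds (raw and monotone-enforced) with
#' columns `amplitude`, `m_min_raw`, `m_min_enforced`.
#'
#' @param thresholds A `dip_thresholds` table.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_thresholds_tsv <- function(thresholds, path) {
  out <- tibble(amplitude = thresholds$a,
                m_min_raw = thresholds$m_min_raw,
                m_min_enforced = thresholds$m_min)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @exportS3Method generics::tidy
tidy.dip_thresholds <- function(x, ...) {
  tibble(a = x$a, total = x$total, m_min_raw = x$m_min_raw, m_min = x$m_min)
}

#' Threshold-curve plot
#'
#' Plots the minimum significant magnitude as a function of amplitude, before
#' and after monotone enforcement, mirroring the diagnostic curve used to
#' pick operating points on real data.
#'
#' @param object A `dip_thresholds` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dip_thresholds <- function(object, ...) {
  df <- tidy(object)
  long <- bind_rows(
    tibble(a = df$a, m_min = df$m_min_raw, curve = "raw"),
    tibble(a = df$a, m_min = df$m_min, curve = "enforced"))
  ggplot2::ggplot(long[!is.na(long$m_min), ],
                  ggplot2::aes(x = .data$a, y = .data$m_min,
                               colour = .data$curve)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "amplitude a (IP + control reads)",
                  y = expression(m[min]),
                  colour = NULL,
                  title = sprintf("Minimum significant magnitude (phi = %g)",
                                  attr(object, "phi"))) +
    ggplot2::theme_minimal()
}
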