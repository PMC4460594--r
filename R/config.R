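#' Peak-calling parameters
#'
#' Bundles the tunable parameters of the caller. Defaults are the values used
#' throughout the method's development: segments of `L = 100` bp scanned at a
#' quarter-length offset (75% overlap between consecutive segments), FDR cutoff
#' `phi = 0.1`, merge gap `delta = 1000` bp and minimum region length
#' `k = 150` bp.
#'
#' @param L Segment length in bp; an approximate lower bound on the
#'   immunoprecipitated fragment length.
#' @param step Scan offset in bp between consecutive segment starts. Must
#'   divide `L` so that the overlap fraction is exact; the default `L/4` gives
#'   75% overlap.
#' @param delta Merge gap in bp: significant segments whose spans are closer
#'   than `delta` are joined into one candidate region.
#' @param k Minimum length in bp a merged region must reach to be reported.
#' @param phi False discovery rate cutoff, a fraction in (0, 1). Used both for
#'   the per-amplitude magnitude threshold and for the region-level
#'   control-read-fraction filter.
#' @param seed Integer seed driving the resampling step of track
#'   normalization.
#' @param pseudocount Positive value added to both counts inside the logarithm
#'   of the region score, only for segments where the IP or the control count
#'   is zero (the score is otherwise undefined there).
#' @param standard_length Optional fixed output length in bp: each reported
#'   region is re-centred to this length (the default 800 bp eases comparison
#'   across callers). Use `NULL` to report merged regions at their native
#'   length.
#'
#' @return An object of class `dip_config`: a validated named list.
#' @examples
#' dip_config()
#' dip_config(phi = 0.05, standard_length = NULL)
#' @export
dip_config <- function(L = 100L, step = L %/% 4L, delta = 1000L, k = 150L,
                       phi = 0.1, seed = 1L, pseudocount = 0.5,
                       standard_length = 800L) {
  L <- as.integer(L)
  step <- as.integer(step)
  delta <- as.integer(delta)
  k <- as.integer(k)
  seed <- as.integer(seed)
  if (!is.null(standard_length)) standard_length <- as.integer(standard_length)
  if (L <= 0L) abort("`L` must be positive.")
  if (step <= 0L || L %% step != 0L) {
    abort("`step` must be positive and divide `L` exactly.")
  }
  if (!(is.numeric(phi) && length(phi) == 1L && phi > 0 && phi < 1)) {
    abort("`phi` must be a single fraction in (0, 1).")
  }
  if (k <= 0L) abort("`k` must be positive.")
  if (delta < 0L) abort("`delta` must be non-negative.")
  if (!(is.numeric(pseudocount) && pseudocount > 0)) {
    abort("`pseudocount` must be positive.")
  }
  if (!is.null(standard_length) && standard_length <= 0L) {
    abort("`standard_length` must be positive or NULL.")
  }
  structure(
    list(L = L, step = step, delta = delta, k = k, phi = phi, seed = seed,
         pseudocount = pseudocount, standard_length = standard_length),
    class = "dip_config"
  )
}

#' @export
print.dip_config <- function(x, ...) {
  cat("<dip_config>\n")
  cat(sprintf("  segment length L: %d bp, step: %d bp (%.0f%% overlap)\n",
              x$L, x$step, 100 * (1 - x$step / x$L)))
  cat(sprintf("  FDR phi: %g, merge gap delta: %d bp, min region length k: %d bp\n",
              x$phi, x$delta, x$k))
  cat(sprintf("  seed: %d, pseudocount: %g, standard length: %s\n",
              x$seed, x$pseudocount,
              if (is.null(x$standard_length)) "off"
              else paste0(x$standard_length, " bp")))
  invisible(x)
}
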