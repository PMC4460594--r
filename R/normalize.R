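#' Equalize IP and control library sizes
#'
#' The significance model compares IP and control read counts segment by
#' segment, so the two tracks must carry the same number of reads. The
#' smaller track is grown to the size of the larger one by resampling its own
#' reads with replacement; the larger track is returned untouched. The draw is
#' reproducible given the seed.
#'
#' @param ip,control Read tibbles as returned by [read_alignments()]. Both
#'   must be non-empty: the method is defined only with a matched control.
#' @param seed Integer seed for the resampling draw.
#' @return A list with elements `ip` and `control`, equal-sized read tibbles.
#' @examples
#' ip <- tibble::tibble(chrom = "chr1", start = 0:9, end = 50:59, strand = "+")
#' ctl <- ip[1:6, ]
#' norm <- normalize_tracks(ip, ctl, seed = 7)
#' nrow(norm$control)  # 10
#' @export
normalize_tracks <- function(ip, control, seed = 1L) {
  if (nrow(ip) == 0L || nrow(control) == 0L) {
    abort(paste("Both an IP and a control track are required:",
                "the method's null model is built from the matched control."))
  }
  n_ip <- nrow(ip)
  n_ctl <- nrow(control)
  if (n_ip == n_ctl) return(list(ip = ip, control = control))
  n_max <- max(n_ip, n_ctl)
  grow <- function(reads, extra) {
    idx <- withr::with_seed(seed, sample.int(nrow(reads), extra, replace = TRUE))
    bind_rows(reads, reads[idx, , drop = FALSE])
  }
  if (n_ip < n_max) {
    list(ip = grow(ip, n_max - n_ip), control = control)
  } else {
    list(ip = ip, control = grow(control, n_max - n_ctl))
  }
}
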