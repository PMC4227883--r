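# Cortical depth profile of staining intensity (e.g. myelin basic
# protein), rescaled to a fixed number of bins from the pial surface to
# the subcortical white matter and normalized to a white-matter reference.

#' Normalize an intensity profile along cortical depth
#'
#' Resamples a raw intensity trace spanning the cortex (ordered from pia
#' to white matter) down to `n_bins` bins (100 by default) by averaging
#' the raw samples falling in each bin, then divides every bin by the
#' intensity of the designated white-matter reference bin, so the
#' reference bin equals 1.0.
#'
#' @param intensity Numeric vector of raw intensities, pia first; must
#'   contain at least `n_bins` samples.
#' @param wm_bin_index Index of the reference bin (default: the deepest
#'   bin, `n_bins`).
#' @param n_bins Number of output bins.
#' @return Data frame (class `depth_profile`) with `bin` (1 = pia) and
#'   normalized `intensity`.
#' @examples
#' prof <- normalize_depth_profile(seq(0, 10, length.out = 200))
#' tail(prof)  # deepest bin is exactly 1
#' @export
normalize_depth_profile <- function(intensity, wm_bin_index = n_bins,
                                    n_bins = 100L) {
  n_bins <- chk_count(n_bins, "n_bins", 1L)
  if (!is.numeric(intensity) || anyNA(intensity))
    stop("`intensity` must be numeric with no missing values",
         call. = FALSE)
  n <- length(intensity)
  if (n < n_bins)
    stop("need at least ", n_bins, " raw samples, got ", n, call. = FALSE)
  wm_bin_index <- chk_count(wm_bin_index, "wm_bin_index", 1L)
  if (wm_bin_index > n_bins)
    stop("`wm_bin_index` must be <= `n_bins`", call. = FALSE)
  bin <- ceiling(seq_len(n) * n_bins / n)
  means <- as.numeric(tapply(intensity, bin, mean))
  ref <- means[wm_bin_index]
  if (!is.finite(ref) || ref <= 0)
    stop("reference (white matter) bin intensity must be positive",
         call. = FALSE)
  out <- data.frame(bin = seq_len(n_bins), intensity = means / ref)
  class(out) <- c("depth_profile", "data.frame")
  out
}
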