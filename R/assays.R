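# Dye-leakage assay normalization.

#' Normalize liposome dye-leakage fluorescence
#'
#' Rescales a sample fluorescence onto the assay's anchor scale: detergent
#' (Triton X-100) lysis defines 100% leakage and buffer-only defines 0%, so
#' percent = 100 (F_sample - F_buffer) / (F_triton - F_buffer).
#' Values outside [0, 100] (quenching or scatter artifacts) are returned
#' unchanged but flagged via `in_range`.
#'
#' @param fluorescence_sample sample fluorescence (arbitrary units).
#' @param fluorescence_buffer buffer-only (0%) anchor on the same scale.
#' @param fluorescence_triton detergent-lysis (100%) anchor on the same
#'   scale; must differ from the buffer anchor.
#' @return list with `percent` and `in_range` (vectorized over samples).
#' @export
normalize_leakage <- function(fluorescence_sample, fluorescence_buffer,
                              fluorescence_triton) {
  if (fluorescence_triton == fluorescence_buffer) {
    stop("degenerate normalization: Triton and buffer anchors are equal")
  }
  pct <- 100 * (fluorescence_sample - fluorescence_buffer) /
    (fluorescence_triton - fluorescence_buffer)
  list(percent = pct, in_range = pct >= 0 & pct <= 100)
}
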