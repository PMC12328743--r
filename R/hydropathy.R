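# Hydrophobicity and amphipathicity analysis: hydrophobic fraction,
# sliding-window Kyte-Doolittle hydropathy, transmembrane-span calling,
# and the Eisenberg hydrophobic moment.

#' Hydrophobic residue fraction of a peptide
#'
#' Percentage of residues belonging to a hydrophobic classification set.
#' No universal classification exists; the default set
#' \{A, F, G, I, L, M, V, W\} is the package's documented convention and is
#' always configurable.
#'
#' @param peptide a [peptide_record()] or sequence string.
#' @param hydrophobic_set character vector of one-letter codes, a non-empty
#'   subset of the 20 standard residues.
#' @return list with `count`, `length`, `percent` (unrounded) and
#'   `percent_rounded` (nearest integer).
#' @export
hydrophobic_fraction <- function(peptide,
                                 hydrophobic_set = HYDROPHOBIC_SET_DEFAULT) {
  if (is.character(peptide)) peptide <- peptide_record(peptide)
  stopifnot(length(hydrophobic_set) >= 1L,
            all(hydrophobic_set %in% names(RESIDUE_MONO_MASS)))
  n <- length(peptide$residues)
  k <- sum(peptide$residues %in% hydrophobic_set)
  pct <- 100 * k / n
  list(count = k, length = n, percent = pct,
       percent_rounded = round(pct))
}

#' Sliding-window hydropathy profile
#'
#' Mean Kyte-Doolittle hydropathy over a sliding window of odd length. Score
#' positions index the window centers: score j covers residues
#' j .. j + window - 1 and its center residue is j + (window - 1) / 2.
#'
#' @param peptide a [peptide_record()] or sequence string.
#' @param window odd window length in residues (default 19, the classical
#'   transmembrane-helix span).
#' @param scale named numeric vector of per-residue hydropathy values.
#' @return object of class `hydropathy_profile`: list with `scores` (length
#'   `n - window + 1`), `centers` (1-based residue index of each window
#'   center), `window`, `scale_name`.
#' @export
hydropathy_profile <- function(peptide, window = 19,
                               scale = KYTE_DOOLITTLE) {
  if (is.character(peptide)) peptide <- peptide_record(peptide)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be a positive odd integer")
  n <- length(peptide$residues)
  if (window > n) stop("window exceeds sequence length")
  h <- unname(scale[peptide$residues])
  cs <- cumsum(c(0, h))
  scores <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  half <- (window - 1L) %/% 2L
  structure(
    list(scores = scores,
         centers = seq.int(1L + half, n - half),
         window = window,
         scale_name = "Kyte-Doolittle"),
    class = "hydropathy_profile"
  )
}

#' Longest hydrophobic span above a threshold
#'
#' Finds the longest contiguous run of window centers whose hydropathy score
#' meets the threshold, and expands it to the full extent of the contributing
#' windows. Run-length ties are broken toward the N-terminal run.
#'
#' @param profile a [hydropathy_profile()].
#' @param threshold score threshold (default 1.6, the classical
#'   transmembrane-helix call on the Kyte-Doolittle scale).
#' @return `NULL` if no center passes; otherwise list with `start`, `end`
#'   (1-based residue interval of the expanded span), `center_start`,
#'   `center_end`, and `max_score`.
#' @export
max_hydrophobic_span <- function(profile, threshold = 1.6) {
  stopifnot(inherits(profile, "hydropathy_profile"))
  pass <- profile$scores >= threshold
  if (!any(pass)) return(NULL)
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]  # which.max takes the first => N-terminal tie-break
  i0 <- starts[best]; i1 <- ends[best]
  half <- (profile$window - 1L) %/% 2L
  list(start = profile$centers[i0] - half,
       end = profile$centers[i1] + half,
       center_start = profile$centers[i0],
       center_end = profile$centers[i1],
       max_score = max(profile$scores[i0:i1]))
}

#' Eisenberg hydrophobic moment
#'
#' mu_H = | sum_k h_k exp(i k delta) | / N for a residue segment, where delta
#' is the angular periodicity of the secondary structure (100 degrees per
#' residue for an alpha helix, 180 for a beta strand) and h_k the
#' Kyte-Doolittle hydropathy. Large mu_H indicates amphipathic segregation of
#' hydrophobic and hydrophilic faces.
#'
#' @param segment sequence string or character vector of residues.
#' @param periodicity_deg angular periodicity in degrees (default 100).
#' @param scale named numeric hydropathy scale.
#' @return mu_H, dimensionless.
#' @export
hydrophobic_moment <- function(segment, periodicity_deg = 100,
                               scale = KYTE_DOOLITTLE) {
  if (length(segment) == 1L && nchar(segment) > 1L) {
    segment <- strsplit(toupper(segment), "")[[1]]
  }
  if (length(segment) < 2L) stop("segment must have at least 2 residues")
  h <- unname(scale[segment])
  if (anyNA(h)) stop("segment contains residues outside the hydropathy scale")
  delta <- periodicity_deg * pi / 180
  k <- seq_along(h)
  Mod(sum(h * exp(1i * k * delta))) / length(h)
}
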