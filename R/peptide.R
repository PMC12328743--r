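# Peptide records, monoisotopic mass arithmetic, and electrospray
# charge-state deconvolution.

#' Construct a peptide record
#'
#' A `peptide_record` holds a mature peptide sequence in one-letter code
#' together with any intrachain disulfide bonds. It is the object consumed by
#' all mass and hydrophobicity operations.
#'
#' @param sequence character scalar of one-letter amino-acid codes (the 20
#'   standard residues; lower case is accepted and normalized to upper case).
#' @param id text label for the record.
#' @param disulfide_pairs list of length-2 integer vectors giving 1-based
#'   residue positions of disulfide-bonded cysteine pairs, or `NULL`.
#' @return an object of class `peptide_record` with elements `id`, `sequence`
#'   (single upper-case string), `residues` (character vector) and
#'   `disulfide_pairs`.
#' @examples
#' p <- peptide_record("ACDEFGC", disulfide_pairs = list(c(2, 7)))
#' monoisotopic_mass(p)
#' @export
peptide_record <- function(sequence, id = "peptide", disulfide_pairs = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  seq_up <- toupper(gsub("[ \t\r\n]", "", sequence))
  residues <- strsplit(seq_up, "")[[1]]
  bad <- which(!(residues %in% names(RESIDUE_MONO_MASS)))
  if (length(bad) > 0) {
    stop(sprintf("unknown residue code '%s' at position %d", residues[bad[1]], bad[1]))
  }
  if (!is.null(disulfide_pairs)) {
    if (!is.list(disulfide_pairs)) disulfide_pairs <- list(disulfide_pairs)
    for (pr in disulfide_pairs) {
      if (length(pr) != 2L || any(pr < 1) || any(pr > length(residues))) {
        stop("disulfide pair positions must be two in-range residue indices")
      }
      if (pr[1] == pr[2]) stop("disulfide pair positions must be distinct")
      if (any(residues[pr] != "C")) {
        stop(sprintf("disulfide pair %d:%d does not reference two cysteines", pr[1], pr[2]))
      }
    }
  }
  structure(
    list(id = id, sequence = seq_up, residues = residues,
         disulfide_pairs = disulfide_pairs),
    class = "peptide_record"
  )
}

#' @export
print.peptide_record <- function(x, ...) {
  cat(sprintf("<peptide_record> %s: %d residues", x$id, length(x$residues)))
  if (length(x$disulfide_pairs)) {
    cat(sprintf(", %d disulfide bond(s)", length(x$disulfide_pairs)))
  }
  cat("\n  ", x$sequence, "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a peptide
#'
#' Sum of standard residue monoisotopic masses plus one water for the chain
#' termini, minus two hydrogen atoms per disulfide bond (each S-S bond removes
#' one hydrogen from each cysteine thiol).
#'
#' @param peptide a [peptide_record()] (a bare sequence string is coerced).
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(peptide) {
  if (is.character(peptide)) peptide <- peptide_record(peptide)
  stopifnot(inherits(peptide, "peptide_record"))
  sum(RESIDUE_MONO_MASS[peptide$residues]) + MASS_WATER -
    2 * MASS_H_ATOM * length(peptide$disulfide_pairs)
}

#' Report a mass in kilodaltons at one-decimal rounding
#'
#' Half-up rounding (so 5.85 reports as 5.9), the convention used for
#' headline peptide masses.
#'
#' @param mass_da mass in Da.
#' @return mass in kDa rounded to one decimal.
#' @export
mass_kda <- function(mass_da) {
  floor(mass_da / 100 + 0.5) / 10
}

#' Predict an electrospray charge-state ladder
#'
#' Inverse of [deconvolute()]: for a neutral mass M and positive charges i,
#' the singly protonated species appear at m/z = (M + i * m_p) / i.
#'
#' @param mass neutral monoisotopic mass in Da.
#' @param charges vector of positive integer charge states.
#' @param proton_mass proton mass in Da; the default is the rounded constant
#'   used in the deconvolution protocol (`PROTON_MASS["physical"]` gives the
#'   CODATA value).
#' @return an object of class `charge_peaks`: data frame with columns
#'   `charge` and `mz`.
#' @export
predict_charge_ladder <- function(mass, charges = 3:6,
                                  proton_mass = PROTON_MASS[["paper"]]) {
  stopifnot(is.numeric(mass), length(mass) == 1L, mass > 0,
            length(charges) >= 1L)
  charges <- as.integer(charges)
  if (any(charges <= 0)) stop("charges must be positive integers")
  if (anyDuplicated(charges)) stop("charges must be unique")
  charge_peaks(charges, (mass + charges * proton_mass) / charges)
}

#' Construct a charge-state peak set
#'
#' @param charge positive integer charge states (unique).
#' @param mz mass-to-charge values in Th (> 0).
#' @return object of class `charge_peaks` (a data frame).
#' @export
charge_peaks <- function(charge, mz) {
  charge <- as.integer(charge)
  stopifnot(length(charge) == length(mz), length(charge) >= 1L)
  if (any(charge <= 0)) stop("charges must be positive")
  if (anyDuplicated(charge)) stop("duplicate charge states")
  if (any(mz <= 0)) stop("m/z values must be positive")
  structure(data.frame(charge = charge, mz = as.numeric(mz)),
            class = c("charge_peaks", "data.frame"))
}

#' Deconvolute a charge-state peak set to a neutral mass
#'
#' Each peak at m/z with charge i implies a neutral mass
#' M_i = (m/z - m_p) * i. The reported mass is the arithmetic mean over
#' charge states and the spread is the sample standard deviation
#' (divisor n - 1). A single-peak input yields `sd = NA` with
#' `sd_defined = FALSE`.
#'
#' @param peaks a `charge_peaks` object (or data frame with columns `charge`,
#'   `mz`).
#' @param proton_mass proton mass in Da (see [predict_charge_ladder()]).
#' @return object of class `deconvolution_result`: list with
#'   `per_charge_masses`, `charges_used`, `mean_mass`, `sd`, `sd_defined`.
#' @export
deconvolute <- function(peaks, proton_mass = PROTON_MASS[["paper"]]) {
  if (!inherits(peaks, "charge_peaks")) {
    stopifnot(is.data.frame(peaks), all(c("charge", "mz") %in% names(peaks)))
    peaks <- charge_peaks(peaks$charge, peaks$mz)
  }
  if (nrow(peaks) == 0L) stop("no peaks to deconvolute")
  m_i <- (peaks$mz - proton_mass) * peaks$charge
  n <- length(m_i)
  structure(
    list(per_charge_masses = m_i,
         charges_used = peaks$charge,
         mean_mass = mean(m_i),
         sd = if (n > 1) stats::sd(m_i) else NA_real_,
         sd_defined = n > 1),
    class = "deconvolution_result"
  )
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("<deconvolution_result> M = %.4f Da", x$mean_mass))
  if (x$sd_defined) cat(sprintf(" ± %.4f (sd, n = %d)", x$sd,
                                length(x$per_charge_masses)))
  cat("\n  charges:", paste0("+", x$charges_used, collapse = " "), "\n")
  invisible(x)
}
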