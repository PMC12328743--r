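# Shared fixtures and small oracles used across the test files.

# Mature 52-residue TMcin-G1905 peptide with its Cys25-Cys50 disulfide.
tmcin_sequence <- "AWFVVLLAAILVFATAIFAGLTIWCVVNQHGKFTGNWNWHIKGVSLDVECKR"
tmcin_peptide <- function() {
  peptide_record(tmcin_sequence, id = "TMcin-G1905",
                 disulfide_pairs = list(c(25, 50)))
}

# Greedy matching of detected to true event times within a tolerance;
# returns the number of true positives.
match_event_times <- function(detected, truth, tol_s = 0.002) {
  used <- logical(length(detected))
  tp <- 0L
  for (tt in truth) {
    if (length(detected) == 0) break
    d <- abs(detected - tt)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol_s) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}

# Random peptide sequence over the 20 standard residues.
random_sequence <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(porescribe:::RESIDUE_MONO_MASS), n, replace = TRUE),
        collapse = "")
}
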