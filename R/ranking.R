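# Confidence-score ranking of multimer pore models over a stoichiometry
# scan. The package consumes metric tables (ipTM, pTM, mean pLDDT per
# stoichiometry); it never runs the structure predictor.

#' Construct a multimer metrics table
#'
#' @param df data frame with columns `n` (stoichiometry, unique within a
#'   round), `iptm` and `ptm` in [0, 1], `mean_plddt` in [0, 100], and
#'   optionally `round` (label, default "round1").
#' @return the validated data frame with class `multimer_metrics`.
#' @export
multimer_metrics <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("n", "iptm", "ptm", "mean_plddt") %in% names(df)))
  if (!"round" %in% names(df)) df$round <- "round1"
  if (nrow(df) == 0L) stop("metrics table is empty")
  for (r in split(df, df$round)) {
    if (anyDuplicated(r$n)) stop("stoichiometry n must be unique within a round")
  }
  if (any(df$iptm < 0 | df$iptm > 1) || any(df$ptm < 0 | df$ptm > 1)) {
    stop("ipTM and pTM must lie in [0, 1]")
  }
  if (any(df$mean_plddt < 0 | df$mean_plddt > 100)) {
    stop("mean pLDDT must lie in [0, 100]")
  }
  class(df) <- c("multimer_metrics", "data.frame")
  df
}

#' Overall model confidence score
#'
#' Weighted average 0.8 ipTM + 0.2 pTM, the standard multimer model
#' confidence combining interface-weighted and global predicted TM-scores.
#'
#' @param iptm interface predicted TM-score in [0, 1].
#' @param ptm global predicted TM-score in [0, 1].
#' @return confidence score in [0, 1].
#' @export
confidence_score <- function(iptm, ptm) {
  if (any(iptm < 0 | iptm > 1) || any(ptm < 0 | ptm > 1)) {
    stop("ipTM and pTM must lie in [0, 1]")
  }
  0.8 * iptm + 0.2 * ptm
}

#' pLDDT confidence band
#'
#' Band labels over [0, 100]: "low" for pLDDT <= 50, "moderate" for
#' (50, 70], "confident" for the open interval (70, 90) (strict bounds, so
#' exactly 70 is moderate and exactly 90 is very-high), and "very-high" for
#' pLDDT >= 90. The (70, 90) window is the conventional "confident" range;
#' the outer cutpoints follow predictor-community convention.
#'
#' @param plddt pLDDT value(s) in [0, 100].
#' @return character vector of band labels.
#' @export
plddt_band <- function(plddt) {
  if (any(plddt < 0 | plddt > 100)) stop("pLDDT must lie in [0, 100]")
  out <- character(length(plddt))
  out[plddt <= 50] <- "low"
  out[plddt > 50 & plddt <= 70] <- "moderate"
  out[plddt > 70 & plddt < 90] <- "confident"
  out[plddt >= 90] <- "very-high"
  out
}

#' Rank multimer models by confidence score
#'
#' Orders a metrics table by descending confidence score, breaking ties
#' toward the lower stoichiometry (parsimony).
#'
#' @param table a [multimer_metrics()] table (or coercible data frame).
#' @return list with `ranked` (the table with a `score` column, in rank
#'   order) and `best_n` (stoichiometry of the top model).
#' @export
rank_models <- function(table) {
  if (!inherits(table, "multimer_metrics")) table <- multimer_metrics(table)
  if (nrow(table) == 0L) stop("cannot rank an empty table")
  table$score <- confidence_score(table$iptm, table$ptm)
  ord <- order(-table$score, table$n)
  ranked <- table[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  list(ranked = ranked, best_n = ranked$n[1])
}

#' Two-round stoichiometry scan selection
#'
#' Reproduces the two-round model-selection logic: a broad first-round scan
#' selects a best stoichiometry, a second (template-seeded) round rescans a
#' range around it; the final model is the round-2 best, and a score
#' improvement flag records whether the second round's best score exceeds
#' the first round's.
#'
#' @param round1 first-round [multimer_metrics()] table.
#' @param round2 second-round table.
#' @param declared_range2 optional integer range the second round was
#'   declared to cover; a warning is issued if round2 contains
#'   stoichiometries outside it.
#' @return list with `round1_best`, `round1_best_score`, `final_best`,
#'   `final_best_score`, `improvement` (logical),
#'   `round2_covers_round1_best` (logical), `range_warning` (character or
#'   NULL).
#' @export
two_round_selection <- function(round1, round2, declared_range2 = NULL) {
  r1 <- rank_models(round1)
  r2 <- rank_models(round2)
  range_warning <- NULL
  if (!is.null(declared_range2)) {
    outside <- setdiff(r2$ranked$n, declared_range2)
    if (length(outside) > 0) {
      range_warning <- sprintf(
        "round-2 stoichiometries outside declared range: %s",
        paste(outside, collapse = ", "))
      warning(range_warning)
    }
  }
  list(round1_best = r1$best_n,
       round1_best_score = r1$ranked$score[1],
       final_best = r2$best_n,
       final_best_score = r2$ranked$score[1],
       improvement = r2$ranked$score[1] > r1$ranked$score[1],
       round2_covers_round1_best = r1$best_n %in% r2$ranked$n,
       range_warning = range_warning)
}
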