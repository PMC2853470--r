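#' @title Candidate scoring
#' @description
#' A candidate's raw weight is a weighted peak count over the peaks its
#' fragments explain: heavier, more intense peaks are more characteristic,
#' so each explained peak contributes `intensity^m * mz^n` with `m = 0.6`,
#' `n = 3`. The raw weights are scaled by their maximum into `[0, 1]`; the
#' arithmetic mean of the cumulative bond dissociation energies of each
#' candidate's explained fragments is scaled by twice its maximum into
#' `[0, 0.5]` and subtracted — the higher the BDE, the less likely the
#' fragment. The final score therefore lies in `[-0.5, 1]`.
#' @name scoring-model
NULL

#' Scoring parameters
#' @param m intensity exponent (default 0.6).
#' @param n mass exponent (default 3).
#' @return a list of class `fr_score_params`.
#' @export
score_params <- function(m = 0.6, n = 3) {
  structure(list(m = m, n = n), class = "fr_score_params")
}

#' Weight of an explained peak
#'
#' `intensity^m * mz^n`; a candidate's raw weight is the sum over its
#' explained peaks.
#'
#' @param mz,intensity peak coordinates.
#' @param params an [score_params()].
#' @return numeric weight(s).
#' @export
peak_weight <- function(mz, intensity, params = score_params()) {
  intensity^params$m * mz^params$n
}

#' Normalized candidate scores from raw weights and BDE means
#'
#' `S_i = w_i / max(w) - e_i / (2 max(e))`. Candidates with no matches
#' enter with `w_i = 0` and a zero BDE term; if all weights are zero every
#' score is 0; if all BDE means are zero the BDE term vanishes.
#'
#' @param raw a data frame with columns `w` (raw weight, >= 0) and `e`
#'   (mean cumulative BDE of explained fragments; use 0 for no matches).
#' @return the input tibble with a `score` column added.
#' @export
candidate_scores <- function(raw) {
  stopifnot(is.data.frame(raw), all(c("w", "e") %in% names(raw)))
  if (nrow(raw) == 0) stop("no candidates to score", call. = FALSE)
  max_w <- max(raw$w)
  max_e <- max(raw$e)
  w_term <- if (max_w > 0) raw$w / max_w else rep(0, nrow(raw))
  e_term <- if (max_e > 0) raw$e / (2 * max_e) else rep(0, nrow(raw))
  e_term[raw$w == 0] <- 0
  out <- tibble::as_tibble(raw)
  out$score <- w_term - e_term
  out
}

#' Fragment, match and score every candidate in a library
#'
#' The end-to-end in-silico identification step: each candidate is
#' fragmented and matched against the spectrum, raw weights and BDE means
#' are computed, scores are normalized, and candidates are ranked
#' (worst-case tied ranks) with tied-rank structure clustering at the
#' given Tanimoto threshold.
#'
#' @param library a candidate library ([load_library()] /
#'   [as_candidate_library()]) or a list of `fr_mol`.
#' @param spec an `fr_spectrum`.
#' @param config an [fragmenter_config()].
#' @param params an [match_params()].
#' @param sparams an [score_params()].
#' @param rules neutral-loss rules or `NULL`.
#' @param bde_table BDE table.
#' @param cluster_threshold Tanimoto similarity at or above which tied
#'   candidates collapse into one cluster (default 0.95).
#' @return a tibble of class `fr_result`, one row per candidate, sorted by
#'   score descending: `id`, `name`, `formula`, `mass`, `n_peaks_explained`,
#'   `n_fragments`, `n_matched_fragments`, `w`, `e`, `score`, `rank`
#'   (worst-case), `cluster`, `cluster_rank`. The per-candidate match
#'   tables are in `attr(, "matches")`.
#' @export
rank_candidates <- function(library, spec,
                            config = fragmenter_config(),
                            params = match_params(),
                            sparams = score_params(),
                            rules = default_rules(),
                            bde_table = default_bde_table(),
                            cluster_threshold = 0.95) {
  mols <- .library_mols(library)
  if (!length(mols)) stop("empty candidate library", call. = FALSE)
  res <- lapply(mols, function(m) {
    fragment_and_match(m, spec, config, params, rules, bde_table)
  })
  raw <- tibble::tibble(
    id = vapply(mols, function(m) m$id %||% NA_character_, character(1)),
    name = vapply(mols, function(m) m$name %||% NA_character_, character(1)),
    formula = vapply(mols, function(m)
      formula_string(formula_of(m)), character(1)),
    mass = vapply(mols, function(m) monoisotopic_mass(formula_of(m)),
                  numeric(1)),
    n_peaks_explained = vapply(res, function(r) r$n_explained, integer(1)),
    n_fragments = vapply(res, function(r) r$n_fragments, integer(1)),
    n_matched_fragments = vapply(res, function(r) r$n_matched_fragments,
                                 integer(1)),
    w = vapply(res, function(r) {
      if (nrow(r$matches) == 0) return(0)
      sum(peak_weight(r$matches$peak_mz, r$matches$intensity, sparams))
    }, numeric(1)),
    e = vapply(res, function(r) {
      if (nrow(r$matches) == 0) return(0)
      # mean cumulative BDE over the distinct explained fragments
      mean(r$matches$bde[!duplicated(paste(r$matches$source,
                                           r$matches$formula,
                                           r$matches$frag_mass))])
    }, numeric(1))
  )
  scored <- candidate_scores(raw)
  scored$rank <- vapply(scored$score, function(s)
    sum(scored$score > s) + sum(scored$score == s), integer(1))
  # fingerprints only matter inside tied-score groups
  fps <- vector("list", length(mols))
  tied <- scored$score %in% scored$score[duplicated(scored$score)]
  fps[tied] <- lapply(mols[tied], fingerprint)
  cl <- cluster_tied(scored$score, fps, threshold = cluster_threshold)
  scored$cluster <- cl
  cluster_scores <- tapply(scored$score, cl, function(s) s[1])
  scored$cluster_rank <- vapply(scored$score, function(s) {
    sum(cluster_scores > s) + sum(cluster_scores == s)
  }, integer(1))
  ord <- order(-scored$score, scored$id)
  scored <- scored[ord, ]
  attr(scored, "matches") <- stats::setNames(
    lapply(res, function(r) r$matches), raw$id)[ord]
  attr(scored, "spectrum") <- spec
  class(scored) <- c("fr_result", class(scored))
  scored
}
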