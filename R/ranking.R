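#' @title Ranks, tied-rank clustering and evaluation statistics
#' @description
#' Ranks are reported most pessimistically: a candidate's worst-case rank
#' counts every candidate scoring at least as high, itself included — if
#' the correct solution shares the single highest score with nine others,
#' its rank is 10. Within each group of identical scores, structures with
#' pairwise Tanimoto similarity at or above a threshold (default 0.95)
#' collapse into one cluster, and the worst-case rank over clusters is the
#' cluster rank. The positive predictive value of a run is the fraction of
#' generated fragments that explain a measured peak.
#' @name ranking-model
NULL

#' Worst-case (most pessimistic tied) rank
#'
#' @param scores numeric vector of candidate scores.
#' @param target index (or id within `ids`) of the correct candidate.
#' @param ids optional character ids parallel to `scores`.
#' @return integer rank: number of candidates with a score `>=` the
#'   target's (target included).
#' @examples
#' worst_case_rank(c(rep(1, 10), rep(0, 5)), target = 1)  # 10
#' @export
worst_case_rank <- function(scores, target, ids = NULL) {
  if (!is.null(ids)) {
    target <- match(target, ids)
  }
  if (is.na(target) || target < 1 || target > length(scores)) {
    stop("target candidate not present in the score list", call. = FALSE)
  }
  s <- scores[target]
  sum(scores > s) + sum(scores == s)
}

#' Cluster candidates with tied scores by fingerprint similarity
#'
#' Within each identical-score group, candidates whose pairwise Tanimoto
#' similarity meets the threshold are collapsed into one cluster by
#' single linkage (transitive closure; `linkage = "complete"` requires
#' every pair in a cluster to meet the threshold). Candidates with
#' different scores are never merged.
#'
#' @param scores numeric scores.
#' @param fingerprints list of fingerprints parallel to `scores`.
#' @param threshold similarity threshold in (0, 1] (default 0.95).
#' @param linkage `"single"` (default) or `"complete"`.
#' @return integer cluster ids (1 = best-scoring cluster; ids ordered by
#'   decreasing score, then within-group discovery order).
#' @export
cluster_tied <- function(scores, fingerprints, threshold = 0.95,
                         linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(threshold > 0, threshold <= 1,
            length(scores) == length(fingerprints))
  n <- length(scores)
  cluster <- integer(n)
  next_id <- 0L
  for (s in sort(unique(scores), decreasing = TRUE)) {
    idx <- which(scores == s)
    k <- length(idx)
    if (k == 1) {
      next_id <- next_id + 1L
      cluster[idx] <- next_id
      next
    }
    sim <- matrix(1, k, k)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        sim[i, j] <- sim[j, i] <-
          tanimoto(fingerprints[[idx[i]]], fingerprints[[idx[j]]])
      }
    }
    if (linkage == "single") {
      g <- igraph::graph_from_adjacency_matrix(sim >= threshold,
                                               mode = "undirected",
                                               diag = FALSE)
      memb <- igraph::components(g)$membership
    } else {
      d <- stats::as.dist(1 - sim)
      hc <- stats::hclust(d, method = "complete")
      memb <- stats::cutree(hc, h = 1 - threshold)
    }
    cluster[idx] <- next_id + as.integer(memb)
    next_id <- next_id + max(memb)
  }
  cluster
}

#' Worst-case rank over tied-score clusters
#'
#' Clusters inherit the (tied) score of their members; the target's cluster
#' rank counts the clusters scoring at least as high as its own.
#'
#' @param scores numeric scores.
#' @param clusters integer cluster assignment ([cluster_tied()]).
#' @param target index (or id within `ids`) of the correct candidate.
#' @param ids optional character ids parallel to `scores`.
#' @return integer cluster rank; never larger than the worst-case rank.
#' @export
cluster_rank <- function(scores, clusters, target, ids = NULL) {
  if (!is.null(ids)) target <- match(target, ids)
  if (is.na(target) || target < 1 || target > length(scores)) {
    stop("target candidate not present in the score list", call. = FALSE)
  }
  cl_score <- tapply(scores, clusters, function(s) s[1])
  s <- scores[target]
  as.integer(sum(cl_score > s) + sum(cl_score == s))
}

#' Positive predictive value of a fragmentation run
#'
#' Fraction of generated in-silico fragments that explain a measured peak;
#' 0 when no fragments were generated.
#'
#' @param matched number of fragments matching a peak.
#' @param total number of fragments generated.
#' @return `matched / total` in `[0, 1]`.
#' @export
ppv <- function(matched, total) {
  stopifnot(all(total >= matched), all(matched >= 0))
  ifelse(total == 0, 0, matched / total)
}

#' Summary statistics of a rank list
#'
#' @param ranks numeric vector of ranks (nonempty).
#' @return one-row tibble: `mean`, `median`, `q75` (75% quantile, linear
#'   interpolation, `stats::quantile` type 7), `sd` (`NA` for a single
#'   rank).
#' @export
rank_summary <- function(ranks) {
  stopifnot(length(ranks) >= 1)
  tibble::tibble(
    mean = mean(ranks),
    median = stats::median(ranks),
    q75 = unname(stats::quantile(ranks, 0.75, type = 7)),
    sd = stats::sd(ranks)
  )
}
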