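# BLOSUM62-based fragment distance and k-nearest-neighbour scores: the
# evolutionary-similarity features. The KNN score of a query site is the
# fraction of positive-labeled fragments among its k nearest labeled
# neighbors under the normalized-substitution-matrix distance.

#' Configure the KNN score schedule
#'
#' Each fraction `f` yields one score with `k = max(minimum_k,
#' round_half_up(f * N))` where `N` is the reference-set size; the default
#' schedule (0.025%, 0.05%, 0.1%, 0.2%, 0.4% of the reference) produces the
#' five KNN features.
#'
#' @param k_fractions Strictly increasing fractions in `(0, 1)`.
#' @param minimum_k Lower bound on every `k` (default 1).
#' @return A `knn_config` object.
#' @export
knn_config <- function(k_fractions = c(0.00025, 0.0005, 0.001, 0.002, 0.004),
                       minimum_k = 1L) {
  if (!is.numeric(k_fractions) || !length(k_fractions) ||
      any(k_fractions <= 0) || any(k_fractions >= 1) ||
      is.unsorted(k_fractions, strictly = TRUE))
    .stopf("`k_fractions` must be strictly increasing fractions in (0, 1)")
  structure(list(k_fractions = k_fractions,
                 minimum_k = .assert_scalar_count(minimum_k, "minimum_k")),
            class = "knn_config")
}

# k values for a reference of size n
knn_k_values <- function(config, n) {
  pmax(config$minimum_k, round_half_up(config$k_fractions * n))
}

#' Distance between two aligned fragments
#'
#' `D(S1, S2) = 1 - (1/L) * sum_i Sim(S1[i], S2[i])` where `Sim` is the
#' min-max normalized substitution similarity
#' (see [normalize_substitution_matrix()]). Positions where either sequence
#' carries the pad symbol contribute similarity 0. The distance is symmetric
#' and lies in `[0, 1]`.
#'
#' @param s1,s2 Residue strings of equal length.
#' @param sim A `substitution_similarity` (default: normalized BLOSUM62).
#' @return A distance in `[0, 1]`.
#' @export
fragment_distance <- function(s1, s2, sim = normalize_substitution_matrix()) {
  if (nchar(s1) != nchar(s2)) .stopf("sequences differ in length")
  c1 <- .aa_codes(strsplit(s1, "", fixed = TRUE)[[1L]])
  c2 <- .aa_codes(strsplit(s2, "", fixed = TRUE)[[1L]])
  if (any(is.na(c1)) || any(is.na(c2))) .stopf("illegal residue character")
  1 - mean(sim$sim[cbind(c1, c2)])
}

# All pairwise distances between query and reference code matrices.
# Returns an n_query x n_ref matrix; O(L) passes of vectorized lookup.
.distance_matrix <- function(qcodes, rcodes, sim) {
  L <- ncol(qcodes)
  stopifnot(ncol(rcodes) == L)
  acc <- matrix(0, nrow(qcodes), nrow(rcodes))
  S <- sim$sim
  for (l in seq_len(L)) {
    acc <- acc + S[qcodes[, l], rcodes[, l], drop = FALSE]
  }
  1 - acc / L
}

# Core scorer. qcodes/rcodes: integer code matrices over identical masked
# offsets; qkey/rkey: "(protein_id)\r(position)" identity keys used for
# self-exclusion; rpos: logical, reference fragment labeled positive.
# Reference must already be in deterministic (protein_id, position) order;
# ties in distance are broken by that order. Distances are quantized at 1e-9
# before ranking: true distances sit on a lattice no finer than 1/(15 L), so
# quantization only collapses floating-point summation noise and makes exact
# ties break by reference order regardless of evaluation order.
# Returns n_query x length(ks).
.knn_scores_block <- function(qcodes, qkey, rcodes, rkey, rpos, ks, sim) {
  D <- round(.distance_matrix(qcodes, rcodes, sim), 9L)
  kmax <- max(ks)
  out <- matrix(NA_real_, nrow(qcodes), length(ks))
  for (i in seq_len(nrow(qcodes))) {
    keep <- if (is.null(qkey)) rep(TRUE, length(rkey)) else rkey != qkey[i]
    n_avail <- sum(keep)
    if (kmax > n_avail)
      .stopf("k = %d exceeds reference size %d after self-exclusion",
             kmax, n_avail)
    d <- D[i, keep]
    ord <- order(d, seq_along(d))[seq_len(kmax)]
    cum_pos <- cumsum(rpos[keep][ord])
    out[i, ] <- cum_pos[ks] / ks
  }
  out
}

# normalize a query argument to list(fragment, key)
.query_parts <- function(query) {
  if (is.character(query) && length(query) == 1L)
    return(list(fragment = query, key = NULL))
  q <- as.list(query)
  key <- if (!is.null(q$protein_id) && !is.null(q$position))
    paste0(q$protein_id, "\r", q$position) else NULL
  list(fragment = q$fragment[[1L]], key = key)
}

# sort a corpus-like data frame into the deterministic reference order
.ref_order <- function(ref) order(ref$protein_id, ref$position)

#' KNN score of a query fragment against a labeled reference
#'
#' The reference fragments are sorted by distance to the query (ties broken
#' by `(protein_id, position)` order); any reference fragment sharing the
#' query's `(protein_id, position)` identity is excluded as a self-match.
#' The score is the fraction of positives among the `k` nearest remaining
#' neighbors: above 0.5 the local sequence neighborhood looks like known
#' acetylation sites, below 0.5 like background lysines.
#'
#' @param query A fragment string, or a one-row corpus / list with fields
#'   `fragment`, `protein_id`, `position` (the latter two enable
#'   self-exclusion).
#' @param reference A labeled `fragment_corpus`.
#' @param k Number of neighbors.
#' @param sim A `substitution_similarity`.
#' @return A fraction in `[0, 1]`.
#' @export
knn_score <- function(query, reference, k,
                      sim = normalize_substitution_matrix()) {
  k <- .assert_scalar_count(k, "k")
  qp <- .query_parts(query)
  ord <- .ref_order(reference)
  ref <- as.data.frame(reference)[ord, , drop = FALSE]
  rcodes <- .code_matrix(ref$fragment)
  qcodes <- .code_matrix(qp$fragment)
  .knn_scores_block(qcodes, if (is.null(qp$key)) NULL else qp$key,
                    rcodes, paste0(ref$protein_id, "\r", ref$position),
                    ref$label == "positive", k, sim)[1L, 1L]
}

#' The five-score KNN feature vector of a query fragment
#'
#' One [knn_score()] per fraction of the schedule in `config`, in schedule
#' order.
#'
#' @inheritParams knn_score
#' @param config A [knn_config()].
#' @return Numeric vector, one score per configured fraction.
#' @export
knn_feature_vector <- function(query, reference, config = knn_config(),
                               sim = normalize_substitution_matrix()) {
  if (nrow(reference) == 0L) .stopf("reference corpus is empty")
  ks <- knn_k_values(config, nrow(reference))
  qp <- .query_parts(query)
  ord <- .ref_order(reference)
  ref <- as.data.frame(reference)[ord, , drop = FALSE]
  scores <- .knn_scores_block(.code_matrix(qp$fragment),
                              if (is.null(qp$key)) NULL else qp$key,
                              .code_matrix(ref$fragment),
                              paste0(ref$protein_id, "\r", ref$position),
                              ref$label == "positive", ks, sim)[1L, ]
  stats::setNames(scores, sprintf("KNN[%g%%]", 100 * config$k_fractions))
}
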