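# shared fixtures and independent oracles for the test suite

# build a corpus from raw fragment strings (one synthetic protein per
# fragment so every (protein_id, position) key is unique)
make_corpus <- function(fragments, labels, window = window_spec()) {
  fragment_corpus(data.frame(
    protein_id = sprintf("tp%04d", seq_along(fragments)),
    position = rep(window$upstream + 1L, length(fragments)),
    label = labels,
    fragment = fragments,
    stringsAsFactors = FALSE), window = window)
}

# random lysine-centered fragments over the plain alphabet
random_fragments <- function(n, window = window_spec()) {
  L <- window_length(window)
  vapply(seq_len(n), function(i) {
    ch <- sample(AA_ALPHABET, L, replace = TRUE)
    ch[window$upstream + 1L] <- "K"
    paste(ch, collapse = "")
  }, character(1))
}

# ---- independent oracles (deliberately naive implementations) ----

# entropy / information gain via explicit P log2 P sums over the
# symbol-by-class contingency table
oracle_ig <- function(fragments, labels, offset, window = window_spec()) {
  chars <- t(vapply(strsplit(fragments, ""), identity,
                    character(window_length(window))))
  col <- chars[, offset + window$upstream + 1L]
  plogp <- function(p) if (p == 0) 0 else p * log2(p)
  classes <- sort(unique(labels))
  h_x <- -sum(vapply(classes,
                     function(cl) plogp(mean(labels == cl)), numeric(1)))
  h_cond <- 0
  for (y in unique(col)) {
    in_y <- col == y
    p_y <- mean(in_y)
    h_y <- -sum(vapply(classes, function(cl) {
      plogp(sum(labels[in_y] == cl) / sum(in_y))
    }, numeric(1)))
    h_cond <- h_cond + p_y * h_y
  }
  list(h_x = h_x, h_cond = h_cond, ig = h_x - h_cond)
}

# KNN score by full sort of all pairwise distances computed one at a time;
# accepts a vector of k values and returns one score per k
oracle_knn <- function(query_frag, query_key, ref, k,
                       sim = normalize_substitution_matrix()) {
  d <- round(vapply(ref$fragment,
                    function(f) fragment_distance(query_frag, f, sim),
                    numeric(1)), 9)
  keep <- paste(ref$protein_id, ref$position) != query_key
  ord <- order(d[keep], ref$protein_id[keep], ref$position[keep])
  lab <- ref$label[keep][ord]
  vapply(k, function(kk) mean(lab[seq_len(kk)] == "positive"), numeric(1))
}

# confusion metrics via indicator-vector statistics: accuracy as a mean,
# sensitivity/specificity as conditional means, MCC as the Pearson (phi)
# correlation of the truth and prediction indicators
oracle_metrics <- function(tp, fn, tn, fp) {
  truth <- rep(c(1, 1, 0, 0), c(tp, fn, tn, fp))
  pred <- rep(c(1, 0, 0, 1), c(tp, fn, tn, fp))
  mcc <- suppressWarnings(cor(truth, pred))
  if (is.na(mcc)) mcc <- 0
  c(acc = 100 * mean(truth == pred),
    sn = 100 * mean(pred[truth == 1]),
    sp = 100 * mean(1 - pred[truth == 0]),
    mcc = 100 * mcc)
}

# tiny fast configuration used wherever a CV run is exercised structurally
fast_svm <- function() svm_config(cost = 1, gamma = 0.05)
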