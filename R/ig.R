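# Position analysis: per-offset information gain on the class variable,
# position masks (computed or preset), and composition/enrichment summaries
# of the window around the site.

.entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy of the class labels
#'
#' Shannon entropy, in bits, of the positive/negative class distribution:
#' `H(X) = -sum_i P(x_i) log2 P(x_i)` with `0 log 0 = 0`. Balanced labels
#' give 1 bit.
#'
#' @param labels Character/factor vector of class labels.
#' @return Entropy in bits.
#' @export
class_entropy <- function(labels) {
  if (!length(labels)) .stopf("need at least one label")
  .entropy_bits(as.vector(table(labels)) / length(labels))
}

#' Conditional class entropy given the residue at one window offset
#'
#' `H(X | Y_c) = sum_j P(y_j) * H(X | Y_c = y_j)` where `Y_c` is the residue
#' observed at offset `c` (20 amino acids plus the pad symbol, which is
#' treated as an observable 21st value) and probabilities are
#' maximum-likelihood estimates from the counts. `laplace` adds the given
#' pseudocount to every (symbol, class) cell before estimating.
#'
#' @param fragments A `fragment_corpus`, or a character vector of equal-length
#'   fragments (then supply `labels` and `window`).
#' @param offset Signed window offset.
#' @param labels Class labels (taken from the corpus when omitted).
#' @param window A [window_spec()] (taken from the corpus when omitted).
#' @param laplace Pseudocount (default 0 = unsmoothed).
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(fragments, offset, labels = NULL,
                                window = NULL, laplace = 0) {
  if (inherits(fragments, "fragment_corpus")) {
    if (is.null(labels)) labels <- fragments$label
    if (is.null(window)) window <- attr(fragments, "window")
    fragments <- fragments$fragment
  }
  if (is.null(window)) .stopf("`window` required for bare fragment vectors")
  offs <- window_offsets(window)
  if (!(offset %in% offs)) .stopf("offset %d outside window", offset)
  codes <- .code_matrix(fragments)[, match(offset, offs)]
  .cond_entropy_from_counts(table(factor(codes, levels = 1:.PAD_CODE),
                                  labels), laplace)
}

# H(X|Y) from a symbol x class contingency table
.cond_entropy_from_counts <- function(tab, laplace = 0) {
  tab <- unclass(tab) + laplace
  n <- sum(tab)
  rs <- rowSums(tab)
  keep <- rs > 0
  sum(vapply(which(keep), function(j) {
    (rs[j] / n) * .entropy_bits(tab[j, ] / rs[j])
  }, numeric(1)))
}

#' Per-offset information gain profile
#'
#' For every window offset `c`, the information gain
#' `IG(c) = H(X) - H(X | Y_c)`: the reduction in class entropy obtained by
#' observing the residue at that offset. Offsets whose residue distribution
#' is more class-discriminating score higher; the center (always lysine)
#' scores exactly 0.
#'
#' @inheritParams conditional_entropy
#' @return An `ig_profile`: a data frame with columns `offset`,
#'   `h_conditional` and `ig`, carrying the class entropy and the per-offset
#'   symbol-by-class counts as attributes.
#' @export
compute_ig_profile <- function(fragments, labels = NULL, window = NULL,
                               laplace = 0) {
  if (inherits(fragments, "fragment_corpus")) {
    if (is.null(labels)) labels <- fragments$label
    if (is.null(window)) window <- attr(fragments, "window")
    fragments <- fragments$fragment
  }
  if (is.null(window)) .stopf("`window` required for bare fragment vectors")
  if (length(unique(labels)) < 2L)
    .stopf("information gain needs both classes present")
  offs <- window_offsets(window)
  codes <- .code_matrix(fragments, offs)
  H <- class_entropy(labels)
  lab <- factor(labels)
  counts <- lapply(seq_along(offs), function(j) {
    table(symbol = factor(c(AA_ALPHABET, PAD_SYMBOL)[codes[, j]],
                          levels = c(AA_ALPHABET, PAD_SYMBOL)),
          class = lab)
  })
  h_cond <- vapply(counts, function(tab) {
    .cond_entropy_from_counts(tab, laplace)
  }, numeric(1))
  ig <- H - h_cond
  ig[offs == 0L] <- 0
  structure(data.frame(offset = offs, h_conditional = h_cond, ig = ig),
            class_entropy = H, counts = stats::setNames(counts, offs),
            n = length(fragments),
            class = c("ig_profile", "data.frame"))
}

#' Position masks: ordered sets of informative window offsets
#'
#' A mask is a strictly increasing set of signed nonzero offsets within the
#' window; the center lysine (offset 0) is never part of the encoded
#' positions.
#'
#' @param offsets Sorted signed integer offsets, excluding 0.
#' @param name Mask name used in reports.
#' @return A `position_mask` (integer vector with a `name` attribute).
#' @export
position_mask <- function(offsets, name = "custom") {
  offsets <- as.integer(offsets)
  if (anyDuplicated(offsets)) .stopf("mask offsets must be unique")
  if (0L %in% offsets) .stopf("mask offsets never include the center (0)")
  structure(sort(offsets), mask_name = name, class = "position_mask")
}

#' @export
print.position_mask <- function(x, ...) {
  cat(sprintf("<position_mask> %s (%d offsets): %s\n", attr(x, "mask_name"),
              length(x), paste(sprintf("%+d", unclass(x)), collapse = ", ")))
  invisible(x)
}

#' Select the most informative offsets from an IG profile
#'
#' Picks the `size` nonzero offsets with the largest information gain; ties
#' are broken by smaller absolute offset, then by the upstream (negative)
#' offset first. The result is returned sorted by offset.
#'
#' @param profile An `ig_profile` from [compute_ig_profile()].
#' @param size Number of offsets to keep.
#' @return A `position_mask` named `IG<size>`.
#' @export
select_positions <- function(profile, size) {
  cand <- profile[profile$offset != 0L, , drop = FALSE]
  size <- .assert_scalar_count(size, "size")
  if (size > nrow(cand))
    .stopf("size %d exceeds the %d scored offsets", size, nrow(cand))
  ord <- order(-cand$ig, abs(cand$offset), cand$offset)
  position_mask(cand$offset[ord[seq_len(size)]], name = sprintf("IG%d", size))
}

# preset IG window offset lists (position-specific) for the 21-mer window
.ig_presets <- list(
  IG9  = c(-8:-1, 1L),
  IG11 = c(-8:-1, 1L, 4L, 6L),
  IG13 = c(-8:-1, 1L, 3L, 4L, 6L, 7L),
  IG15 = c(-8:-1, 1L, 3L, 4L, 5L, 6L, 7L, 9L),
  IG17 = c(-8:-1, 1:9)
)

#' Preset position masks
#'
#' Named masks for the 21-mer window: the position-specific IG windows
#' (`IG9`, `IG11`, `IG13`, `IG15`, `IG17`) and the symmetric contiguous
#' general windows (`general9` ... `general21`,
#' `generalW = {-(W-1)/2 .. +(W-1)/2} \ {0}`).
#'
#' @param name Mask name.
#' @return A `position_mask`.
#' @export
preset_mask <- function(name) {
  general <- paste0("general", seq(9L, 21L, 2L))
  valid <- c(names(.ig_presets), general)
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    .stopf("unknown mask '%s'; valid names: %s",
           as.character(name)[1L], paste(valid, collapse = ", "))
  if (name %in% names(.ig_presets))
    return(position_mask(.ig_presets[[name]], name = name))
  half <- (as.integer(sub("general", "", name)) - 1L) %/% 2L
  position_mask(setdiff(-half:half, 0L), name = name)
}

#' Apply a position mask to fragments
#'
#' Extracts the residues at the masked offsets, in ascending offset order.
#' The center lysine is never among the encoded positions.
#'
#' @param fragments Fragment string(s) or a `fragment_corpus`.
#' @param mask A `position_mask`.
#' @param window The [window_spec()] (taken from the corpus when omitted).
#' @return Character vector of masked residue strings.
#' @export
apply_mask <- function(fragments, mask, window = NULL) {
  if (inherits(fragments, "fragment_corpus")) {
    if (is.null(window)) window <- attr(fragments, "window")
    fragments <- fragments$fragment
  }
  if (is.null(window)) .stopf("`window` required for bare fragment vectors")
  offs <- window_offsets(window)
  if (!all(mask %in% offs))
    .stopf("mask offset(s) outside the window: %s",
           paste(setdiff(mask, offs), collapse = ", "))
  cols <- match(as.integer(mask), offs)
  vapply(strsplit(fragments, "", fixed = TRUE),
         function(ch) paste(ch[cols], collapse = ""), character(1))
}

# two-proportion z-test without continuity correction (the construction used
# for per-position residue enrichment between two fragment sets)
.two_prop_test <- function(x1, n1, x2, n2) {
  if ((x1 + x2) == 0L || (x1 + x2) == (n1 + n2))
    return(list(statistic = 0, p_value = 1))
  # sparse cells are routine here; the z-test is the defined construction
  ht <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                                          correct = FALSE))
  z <- sign(x1 / n1 - x2 / n2) * sqrt(unname(ht$statistic))
  list(statistic = z, p_value = ht$p.value)
}

#' Residue composition of positive and negative fragments
#'
#' Per-class residue frequencies over all non-pad window positions (summing
#' to 1 within each class), with a two-proportion test of each residue's
#' overall frequency between the classes.
#'
#' @param corpus A labeled `fragment_corpus` with both classes present.
#' @return A data frame with one row per residue: `freq_positive`,
#'   `freq_negative`, `statistic` (signed z), `p_value`.
#' @export
composition_frequencies <- function(corpus) {
  lab <- corpus$label
  if (length(unique(lab)) < 2L) .stopf("both classes must be present")
  codes <- .code_matrix(corpus$fragment)
  count_class <- function(which_lab) {
    cc <- codes[lab == which_lab, , drop = FALSE]
    tab <- tabulate(cc[cc <= .N_AA], nbins = .N_AA)
    stats::setNames(tab, AA_ALPHABET)
  }
  np <- count_class("positive")
  nn <- count_class("negative")
  res <- data.frame(residue = AA_ALPHABET,
                    freq_positive = np / sum(np),
                    freq_negative = nn / sum(nn))
  tests <- lapply(seq_len(.N_AA), function(i) {
    .two_prop_test(np[i], sum(np), nn[i], sum(nn))
  })
  res$statistic <- vapply(tests, `[[`, numeric(1), "statistic")
  res$p_value <- vapply(tests, `[[`, numeric(1), "p_value")
  rownames(res) <- NULL
  res
}

#' Position-wise residue enrichment between classes
#'
#' For every (offset, residue) pair, a two-proportion z-test compares the
#' occurrence frequency of the residue at that offset between positive and
#' negative fragments. Pairs with `p <= alpha` are called `enriched` (more
#' frequent around acetylation sites) or `depleted`. No multiple-testing
#' correction is applied; the total number of tests is recorded in the
#' `n_tests` attribute so readers can judge the fixed threshold.
#'
#' @param corpus A labeled `fragment_corpus`.
#' @param alpha Significance threshold (default `1e-4`).
#' @return Data frame with columns `offset`, `residue`, `freq_positive`,
#'   `freq_negative`, `statistic`, `p_value`, `call`.
#' @export
positionwise_enrichment <- function(corpus, alpha = 1e-4) {
  lab <- corpus$label
  if (length(unique(lab)) < 2L) .stopf("both classes must be present")
  window <- attr(corpus, "window")
  offs <- setdiff(window_offsets(window), 0L)
  codes <- .code_matrix(corpus$fragment, window_offsets(window))
  is_pos <- lab == "positive"
  n1 <- sum(is_pos); n2 <- sum(!is_pos)
  rows <- list()
  for (off in offs) {
    col <- codes[, match(off, window_offsets(window))]
    for (r in seq_len(.N_AA)) {
      x1 <- sum(col[is_pos] == r)
      x2 <- sum(col[!is_pos] == r)
      ht <- .two_prop_test(x1, n1, x2, n2)
      rows[[length(rows) + 1L]] <- data.frame(
        offset = off, residue = AA_ALPHABET[r],
        freq_positive = x1 / n1, freq_negative = x2 / n2,
        statistic = ht$statistic, p_value = ht$p_value)
    }
  }
  out <- do.call(rbind, rows)
  out$call <- "none"
  hit <- alpha > 0 & out$p_value <= alpha
  out$call[hit & out$statistic > 0] <- "enriched"
  out$call[hit & out$statistic < 0] <- "depleted"
  structure(out, n_tests = nrow(out), alpha = alpha)
}

#' Export an IG profile as TSV and a mask as JSON
#'
#' @param profile An `ig_profile`.
#' @param path Output path.
#' @export
write_ig_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile)[c("offset", "ig")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ig_profile
#' @param mask A `position_mask`.
#' @export
write_mask_json <- function(mask, path) {
  jsonlite::write_json(stats::setNames(list(as.integer(mask)),
                                       attr(mask, "mask_name")),
                       path, auto_unbox = FALSE)
  invisible(path)
}
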