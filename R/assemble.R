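# Feature assembly: [BE | KNN | AASA] blocks over mask-selected positions,
# with a recorded layout, plus the property-screening harness.

# stratified fold assignment (uses the current RNG stream)
.stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds)
      .stopf("class '%s' has %d fragments, fewer than %d folds",
             cl, length(idx), folds)
    assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

# default mask: every window offset except the center
.full_mask <- function(window) {
  position_mask(setdiff(window_offsets(window), 0L),
                name = sprintf("general%d", window_length(window)))
}

#' Assemble the feature matrix for a fragment corpus
#'
#' Concatenates, per fragment, any subset of the three feature blocks
#' computed over the mask-selected window positions:
#' \describe{
#'   \item{BE}{one-hot binary encoding, `20 * L` columns;}
#'   \item{KNN}{the similarity scores against the labeled `reference`
#'     corpus, one per configured fraction (5 by default);}
#'   \item{AASA}{the physicochemical property encoding, `L` columns.}
#' }
#' `L` is the mask size. Reference fragments sharing a query's
#' `(protein_id, position)` identity are excluded from that query's KNN
#' neighbors, so a corpus can safely be encoded against itself.
#'
#' @param corpus A `fragment_corpus` to encode.
#' @param reference Labeled `fragment_corpus` serving as the KNN reference
#'   (default: `corpus` itself). Required whenever `"KNN"` is among `blocks`.
#' @param mask A `position_mask` (default: all offsets except the center).
#' @param blocks Subset of `c("BE", "KNN", "AASA")`.
#' @param sim A `substitution_similarity` for the KNN distance.
#' @param index A `property_index` for the AASA block.
#' @param config A [knn_config()].
#' @param property_scaling `"minmax"` or `"none"` for the AASA block.
#' @return Numeric matrix with one row per fragment and a `layout` attribute
#'   (data frame of block name, start and end column).
#' @export
assemble_features <- function(corpus, reference = corpus, mask = NULL,
                              blocks = c("BE", "KNN", "AASA"),
                              sim = normalize_substitution_matrix(),
                              index = aasa_index(),
                              config = knn_config(),
                              property_scaling = c("minmax", "none")) {
  blocks <- match.arg(blocks, c("BE", "KNN", "AASA"), several.ok = TRUE)
  property_scaling <- match.arg(property_scaling)
  window <- attr(corpus, "window")
  if (is.null(mask)) mask <- .full_mask(window)
  offs <- window_offsets(window)
  if (!all(mask %in% offs)) .stopf("mask offsets outside the corpus window")
  cols <- match(as.integer(mask), offs)
  codes <- .code_matrix(corpus$fragment)[, cols, drop = FALSE]
  L <- length(mask)
  off_lab <- sprintf("%+d", as.integer(mask))

  parts <- list(); layout <- list()
  add_block <- function(name, m, cn) {
    colnames(m) <- cn
    start <- sum(vapply(parts, ncol, integer(1))) + 1L
    parts[[length(parts) + 1L]] <<- m
    layout[[length(layout) + 1L]] <<-
      data.frame(block = name, start = start, end = start + ncol(m) - 1L)
  }

  if ("BE" %in% blocks) {
    add_block("BE", .binary_encode_codes(codes),
              as.vector(t(outer(off_lab, AA_ALPHABET,
                                function(o, a) sprintf("BE[%s][%s]", o, a)))))
  }
  if ("KNN" %in% blocks) {
    if (is.null(reference) || nrow(reference) == 0L)
      .stopf("KNN block needs a non-empty labeled reference corpus")
    ord <- .ref_order(reference)
    ref <- as.data.frame(reference)[ord, , drop = FALSE]
    rcodes <- .code_matrix(ref$fragment)[, cols, drop = FALSE]
    ks <- knn_k_values(config, nrow(ref))
    scores <- .knn_scores_block(codes,
                                paste0(corpus$protein_id, "\r", corpus$position),
                                rcodes,
                                paste0(ref$protein_id, "\r", ref$position),
                                ref$label == "positive", ks, sim)
    add_block("KNN", scores, sprintf("KNN[%g%%]", 100 * config$k_fractions))
  }
  if ("AASA" %in% blocks) {
    vals <- .property_lookup(index, property_scaling)
    aasa <- matrix(vals[codes], nrow(codes), L)
    add_block("AASA", aasa, sprintf("AASA[%s]", off_lab))
  }
  out <- do.call(cbind, parts)
  structure(out, layout = do.call(rbind, layout), mask = mask)
}

#' Rank physicochemical property indices by cross-validated accuracy
#'
#' Encodes the corpus with each candidate index alone (property block only)
#' and measures stratified k-fold cross-validation accuracy of an RBF-kernel
#' SVM at its default parameters; indices whose single-property encoding
#' separates the classes best rank first. This is the screening harness used
#' to pick one property (average accessible surface area by default) out of
#' a large index collection.
#'
#' @param indices List of `property_index` objects (e.g. from
#'   [read_aaindex()]).
#' @param corpus Labeled, balanced `fragment_corpus`.
#' @param mask Optional `position_mask` (default: all offsets except center).
#' @param folds Cross-validation folds (default 5).
#' @param seed Integer seed for the fold split.
#' @param property_scaling Passed to [assemble_features()].
#' @return Data frame `(index, description, accuracy)` sorted by decreasing
#'   accuracy, ties broken by index name.
#' @export
screen_property_indices <- function(indices, corpus, mask = NULL, folds = 5L,
                                    seed = NULL,
                                    property_scaling = c("minmax", "none")) {
  property_scaling <- match.arg(property_scaling)
  if (!length(indices)) .stopf("need at least one property index")
  nm <- vapply(indices, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    .stopf("duplicate index names: %s",
           paste(unique(nm[duplicated(nm)]), collapse = ", "))
  folds <- .assert_scalar_count(folds, "folds")
  y <- factor(corpus$label, levels = c("negative", "positive"))
  fold_of <- with_seed(seed, .stratified_folds(corpus$label, folds))
  acc <- vapply(indices, function(idx) {
    x <- assemble_features(corpus, reference = NULL, mask = mask,
                           blocks = "AASA", index = idx,
                           property_scaling = property_scaling)
    correct <- 0L
    for (f in seq_len(folds)) {
      te <- fold_of == f
      fit <- e1071::svm(x[!te, , drop = FALSE], y[!te], kernel = "radial",
                        scale = FALSE)
      correct <- correct + sum(predict(fit, x[te, , drop = FALSE]) == y[te])
    }
    correct / length(y)
  }, numeric(1))
  out <- data.frame(index = nm,
                    description = vapply(indices, `[[`, character(1),
                                         "description"),
                    accuracy = acc)
  out <- out[order(-out$accuracy, out$index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
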