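# Fragment corpus construction: FASTA + site annotations -> lysine-centered
# windows, redundancy reduction, balanced negative sets, protein-level holdout.

#' Define a lysine-centered extraction window
#'
#' A window covers `upstream` residues on the N-terminal side and `downstream`
#' residues on the C-terminal side of a candidate lysine, for a total length
#' of `upstream + downstream + 1`. Positions internally carry signed offsets
#' `-upstream .. +downstream`, with 0 at the site itself. Offsets that run
#' past a protein terminus are filled with `pad`.
#'
#' @param upstream,downstream Non-negative integer flank sizes (default 10
#'   each, giving the 21-mer window used throughout).
#' @param pad Single padding character, not in [AA_ALPHABET] (default
#'   [PAD_SYMBOL]).
#' @return A `window_spec` object.
#' @export
window_spec <- function(upstream = 10L, downstream = 10L, pad = PAD_SYMBOL) {
  if (!is.numeric(upstream) || upstream < 0 || upstream != floor(upstream) ||
      !is.numeric(downstream) || downstream < 0 || downstream != floor(downstream))
    .stopf("`upstream` and `downstream` must be non-negative integers")
  if (!is.character(pad) || nchar(pad) != 1L || pad %in% AA_ALPHABET)
    .stopf("`pad` must be a single character outside the amino-acid alphabet")
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 pad = pad),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> -%d..+%d (length %d), pad '%s'\n",
              x$upstream, x$downstream, window_length(x), x$pad))
  invisible(x)
}

#' @rdname window_spec
#' @param window A `window_spec`.
#' @export
window_length <- function(window) window$upstream + window$downstream + 1L

#' @rdname window_spec
#' @export
window_offsets <- function(window) seq.int(-window$upstream, window$downstream)

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the 20-letter amino-acid
#' alphabet plus `'X'` (unknown residue, tolerated on input but never allowed
#' at a site center).
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` and `sequence`, one row per entry.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) .stopf("malformed FASTA in %s: %s",
                                             path, conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    .stopf("duplicate FASTA ids: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  ok_chars <- c(AA_ALPHABET, PAD_SYMBOL)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) .stopf("empty sequence for id '%s'", ids[i])
    chars <- unique(strsplit(seqs[i], "", fixed = TRUE)[[1L]])
    bad <- setdiff(chars, ok_chars)
    if (length(bad))
      .stopf("illegal character(s) %s in sequence '%s'",
             paste(sQuote(bad), collapse = ", "), ids[i])
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Read and validate site annotations
#'
#' Reads a tab-separated file with header columns `protein_id`, `position`
#' and optionally `label` (`positive`/`negative`; missing labels default to
#' `positive`). Every annotation is checked against the protein sequences:
#' the position must be in range and the residue there must be lysine.
#'
#' @param path Path to the TSV file.
#' @param proteins Data frame from [read_fasta()].
#' @return A data frame with columns `protein_id`, `position`, `label`.
#' @export
read_site_annotations <- function(path, proteins) {
  if (!file.exists(path)) .stopf("annotation file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position")
  if (!all(need %in% names(tab)))
    .stopf("annotation file must have columns %s", paste(need, collapse = ", "))
  if (is.null(tab$label)) tab$label <- "positive"
  validate_annotations(tab[c("protein_id", "position", "label")], proteins)
}

#' @rdname read_site_annotations
#' @param annotations Data frame with columns `protein_id`, `position` and
#'   optionally `label`.
#' @export
validate_annotations <- function(annotations, proteins) {
  ann <- as.data.frame(annotations)
  if (is.null(ann$label)) ann$label <- "positive"
  if (!all(ann$label %in% c("positive", "negative")))
    .stopf("labels must be 'positive' or 'negative'")
  ann$position <- as.integer(ann$position)
  unknown <- setdiff(ann$protein_id, proteins$id)
  if (length(unknown))
    .stopf("unknown protein id(s) in annotations: %s",
           paste(unknown, collapse = ", "))
  seqs <- stats::setNames(proteins$sequence, proteins$id)
  len <- nchar(seqs[ann$protein_id])
  bad_range <- which(is.na(ann$position) | ann$position < 1L | ann$position > len)
  if (length(bad_range))
    .stopf("annotation position out of range (rows %s)",
           paste(bad_range, collapse = ", "))
  res <- substr(seqs[ann$protein_id], ann$position, ann$position)
  bad_res <- which(res != "K")
  if (length(bad_res))
    .stopf("annotated residue is not lysine (rows %s: %s)",
           paste(bad_res, collapse = ", "),
           paste(unique(res[bad_res]), collapse = ", "))
  key <- paste(ann$protein_id, ann$position)
  if (anyDuplicated(key))
    .stopf("duplicate (protein_id, position) annotations: %s",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  rownames(ann) <- NULL
  ann
}

#' Extract one lysine-centered window
#'
#' @param sequence A protein sequence string.
#' @param position 1-based position of the lysine in `sequence`.
#' @param window A [window_spec()].
#' @return The window as a string of length `window_length(window)`;
#'   offsets beyond either terminus carry the pad symbol.
#' @export
extract_fragment <- function(sequence, position, window = window_spec()) {
  n <- nchar(sequence)
  position <- as.integer(position)
  if (position < 1L || position > n) .stopf("position %d out of range", position)
  if (substr(sequence, position, position) != "K")
    .stopf("residue at position %d is '%s', not 'K'",
           position, substr(sequence, position, position))
  from <- position - window$upstream
  to <- position + window$downstream
  core <- substr(sequence, max(1L, from), min(n, to))
  lead <- strrep(window$pad, max(0L, 1L - from))
  trail <- strrep(window$pad, max(0L, to - n))
  paste0(lead, core, trail)
}

#' Build a fragment corpus from proteins and validated annotations
#'
#' @inheritParams extract_fragment
#' @param proteins Data frame from [read_fasta()].
#' @param annotations Validated annotation data frame
#'   (see [read_site_annotations()]).
#' @param provenance Optional free-text metadata carried on the corpus.
#' @return A `fragment_corpus`: a data frame with columns `protein_id`,
#'   `position`, `label`, `fragment`, carrying the window spec as an
#'   attribute.
#' @export
extract_fragments <- function(proteins, annotations, window = window_spec(),
                              provenance = character()) {
  ann <- validate_annotations(annotations, proteins)
  seqs <- stats::setNames(proteins$sequence, proteins$id)
  frags <- vapply(seq_len(nrow(ann)), function(i) {
    extract_fragment(seqs[[ann$protein_id[i]]], ann$position[i], window)
  }, character(1))
  fragment_corpus(data.frame(protein_id = ann$protein_id,
                             position = ann$position,
                             label = ann$label,
                             fragment = frags,
                             stringsAsFactors = FALSE),
                  window = window, provenance = provenance)
}

#' Construct (or re-validate) a fragment corpus
#'
#' @param fragments Data frame with columns `protein_id`, `position`, `label`
#'   and `fragment`.
#' @param window The shared [window_spec()].
#' @param provenance Optional free-text metadata.
#' @export
fragment_corpus <- function(fragments, window = window_spec(),
                            provenance = character()) {
  df <- as.data.frame(fragments, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label", "fragment")
  if (!all(need %in% names(df)))
    .stopf("corpus needs columns %s", paste(need, collapse = ", "))
  df <- df[need]
  df$position <- as.integer(df$position)
  L <- window_length(window)
  if (nrow(df) > 0L) {
    if (!all(nchar(df$fragment) == L))
      .stopf("all fragments must have window length %d", L)
    center <- substr(df$fragment, window$upstream + 1L, window$upstream + 1L)
    if (!all(center == "K")) .stopf("fragment center (offset 0) must be 'K'")
    if (!all(df$label %in% c("positive", "negative")))
      .stopf("labels must be 'positive' or 'negative'")
    key <- paste(df$protein_id, df$position)
    if (anyDuplicated(key))
      .stopf("duplicate (protein_id, position) fragments: %s",
             paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  rownames(df) <- NULL
  structure(df, window = window, provenance = provenance,
            class = c("fragment_corpus", "data.frame"))
}

#' @export
print.fragment_corpus <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("<fragment_corpus> %d fragments (%d positive, %d negative), window -%d..+%d\n",
              nrow(x), sum(x$label == "positive"), sum(x$label == "negative"),
              w$upstream, w$downstream))
  invisible(x)
}

#' @rdname fragment_corpus
#' @param x A `fragment_corpus`.
#' @export
corpus_window <- function(x) attr(x, "window")

#' @rdname fragment_corpus
#' @param i Row index (logical or integer) selecting fragments.
#' @export
corpus_subset <- function(x, i) {
  fragment_corpus(as.data.frame(x)[i, , drop = FALSE],
                  window = attr(x, "window"),
                  provenance = attr(x, "provenance"))
}

#' Enumerate candidate negative sites
#'
#' Every lysine position that is not an annotated (positive) site, in every
#' protein, labeled `negative`.
#'
#' @param proteins Data frame from [read_fasta()].
#' @param positives Data frame of positive annotations
#'   (`protein_id`, `position`).
#' @return Annotation data frame with `label = "negative"`.
#' @export
enumerate_negative_sites <- function(proteins, positives) {
  pos_key <- paste(positives$protein_id, positives$position)
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    kpos <- which(strsplit(proteins$sequence[i], "", fixed = TRUE)[[1L]] == "K")
    if (!length(kpos)) return(NULL)
    data.frame(protein_id = proteins$id[i], position = kpos,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(protein_id = character(), position = integer(),
                      label = character(), stringsAsFactors = FALSE))
  out <- out[!(paste(out$protein_id, out$position) %in% pos_key), , drop = FALSE]
  out$label <- rep("negative", nrow(out))
  rownames(out) <- NULL
  out
}

#' Positional identity between two aligned fragments
#'
#' The fraction of window offsets at which the two fragments carry the same
#' symbol (pad matches pad), i.e. ungapped identity over the fixed-length
#' aligned windows.
#'
#' @param a,b Fragment strings of equal length.
#' @return A fraction in `[0, 1]`.
#' @export
fragment_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) .stopf("fragments differ in window length")
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(ca == cb)
}

#' Remove redundant fragments by pairwise identity
#'
#' Greedy keep-first scan in deterministic `(protein_id, position)` order:
#' a fragment is discarded iff its positional identity with an
#' already-retained fragment strictly exceeds `threshold`.
#'
#' @param corpus A `fragment_corpus`.
#' @param threshold Identity above which the later fragment is dropped
#'   (default 0.30).
#' @return The reduced `fragment_corpus`, in scan order.
#' @export
reduce_redundancy <- function(corpus, threshold = 0.30) {
  if (nrow(corpus) == 0L) return(corpus)
  ord <- order(corpus$protein_id, corpus$position)
  df <- as.data.frame(corpus)[ord, , drop = FALSE]
  m <- .code_matrix(df$fragment)
  L <- ncol(m)
  keep <- logical(nrow(df))
  kept_rows <- matrix(integer(0), nrow = 0L, ncol = L)
  for (i in seq_len(nrow(df))) {
    if (nrow(kept_rows) == 0L) {
      ident <- numeric(0)
    } else {
      ident <- rowSums(kept_rows == matrix(m[i, ], nrow(kept_rows), L,
                                           byrow = TRUE)) / L
    }
    if (!length(ident) || max(ident) <= threshold) {
      keep[i] <- TRUE
      kept_rows <- rbind(kept_rows, m[i, ])
    }
  }
  fragment_corpus(df[keep, , drop = FALSE], window = attr(corpus, "window"),
                  provenance = attr(corpus, "provenance"))
}

#' Draw balanced negative training sets
#'
#' Each set is a simple random sample, without replacement within the set, of
#' `n_positive` negative fragments; the sets are drawn independently of each
#' other (they may overlap across sets), mirroring repeated balanced
#' subsampling of the much larger negative pool.
#'
#' @param negatives A `fragment_corpus` of negative fragments.
#' @param n_positive Target size of each set (the positive-set size).
#' @param n_sets Number of sets (default 5).
#' @param seed Integer seed for reproducibility.
#' @return A list of `n_sets` fragment corpora, each with `n_positive` rows.
#' @export
sample_balanced_negative_sets <- function(negatives, n_positive, n_sets = 5L,
                                          seed = NULL) {
  n_positive <- .assert_scalar_count(n_positive, "n_positive")
  n_sets <- .assert_scalar_count(n_sets, "n_sets")
  if (nrow(negatives) < n_positive)
    .stopf("need at least %d negatives, have %d", n_positive, nrow(negatives))
  with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      corpus_subset(negatives, sort(sample.int(nrow(negatives), n_positive)))
    })
  })
}

#' Protein-level train/holdout split
#'
#' Randomly assigns a fraction of proteins to an independent holdout, so that
#' no protein contributes fragments to both sides.
#'
#' @param proteins Data frame from [read_fasta()].
#' @param fraction Fraction of proteins held out, in `(0, 1)` (default 0.10).
#' @param seed Integer seed.
#' @return A list with elements `training` and `holdout`, both protein data
#'   frames.
#' @export
hold_out_proteins <- function(proteins, fraction = 0.10, seed = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    .stopf("`fraction` must lie strictly between 0 and 1")
  n <- nrow(proteins)
  n_hold <- max(1L, round_half_up(fraction * n))
  idx <- with_seed(seed, sort(sample.int(n, n_hold)))
  list(training = proteins[-idx, , drop = FALSE],
       holdout = proteins[idx, , drop = FALSE])
}

#' Write / read a fragment corpus as TSV
#'
#' The on-disk dialect is `protein_id<TAB>position<TAB>label<TAB>fragment`
#' with a header row; pads appear as the window's pad symbol.
#'
#' @param corpus A `fragment_corpus`.
#' @param path Output (or input) path.
#' @export
write_corpus <- function(corpus, path) {
  utils::write.table(as.data.frame(corpus), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corpus
#' @param window The [window_spec()] the file was written with.
#' @export
read_corpus <- function(path, window = window_spec()) {
  if (!file.exists(path)) .stopf("corpus file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(protein_id = "character",
                                         fragment = "character"))
  fragment_corpus(df, window = window,
                  provenance = sprintf("read from %s", path))
}
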