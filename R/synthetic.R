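# Synthetic corpora with planted positional motifs. The defaults emulate the
# qualitative signal around real acetylation sites: lysine enriched across
# the upstream flank and arginine immediately downstream, i.e. informative
# offsets -8..-1 and +1 over a uniform residue background, with negatives as
# pure background. Ground truth travels with the corpus so position-recovery
# and end-to-end accuracy are directly checkable.

#' Specify a planted positional motif
#'
#' At each informative offset a positive fragment carries the enriched
#' residue with probability exactly `p_enrich`, and otherwise draws from the
#' background distribution restricted to the remaining residues; everywhere
#' else (and everywhere in negatives) residues are plain background draws.
#' Setting `p_enrich` equal to the background frequency of the enriched
#' residue therefore makes the two classes exactly exchangeable (the null
#' construction). Offset 0 is always lysine in both classes and cannot be
#' informative.
#'
#' @param informative_offsets Signed nonzero offsets carrying signal
#'   (default `-8..-1` and `+1`).
#' @param enriched_residues One residue per informative offset (default
#'   `"K"` upstream, `"R"` at `+1`).
#' @param p_enrich Enrichment probability in `(0, 1]` (default 0.35, against
#'   a uniform background frequency of 0.05).
#' @param background Named probability vector over (a subset of) the 20
#'   amino acids; default uniform over all 20.
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(informative_offsets = c(-8:-1, 1L),
                       enriched_residues = c(rep("K", 8L), "R"),
                       p_enrich = 0.35,
                       background = NULL) {
  if (length(enriched_residues) != length(informative_offsets))
    .stopf("need one enriched residue per informative offset")
  if (0L %in% informative_offsets)
    .stopf("offset 0 is always 'K' and cannot be informative")
  if (!all(enriched_residues %in% AA_ALPHABET))
    .stopf("enriched residues must be amino acids")
  if (!is.numeric(p_enrich) || p_enrich <= 0 || p_enrich > 1)
    .stopf("`p_enrich` must lie in (0, 1]")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), AA_ALPHABET)
  } else {
    if (is.null(names(background)) ||
        !all(names(background) %in% AA_ALPHABET) ||
        any(background < 0) || sum(background) <= 0)
      .stopf("`background` must be non-negative, named by amino acids")
    bg <- stats::setNames(rep(0, 20L), AA_ALPHABET)
    bg[names(background)] <- background / sum(background)
    background <- bg
  }
  structure(list(informative_offsets = as.integer(informative_offsets),
                 enriched_residues = enriched_residues,
                 p_enrich = p_enrich, background = background),
            class = "motif_spec")
}

#' Specify a synthetic dataset
#'
#' @param n_positive,n_negative Fragment counts per class (defaults 2000).
#' @param window A [window_spec()].
#' @param motif A [motif_spec()].
#' @param fragments_per_protein How many fragments are concatenated into one
#'   protein when emitting FASTA (default 5).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_positive = 2000L, n_negative = 2000L,
                           window = window_spec(), motif = motif_spec(),
                           fragments_per_protein = 5L) {
  if (!all(motif$informative_offsets %in% window_offsets(window)))
    .stopf("motif offsets must lie within the window")
  structure(list(n_positive = .assert_scalar_count(n_positive, "n_positive"),
                 n_negative = .assert_scalar_count(n_negative, "n_negative"),
                 window = window, motif = motif,
                 fragments_per_protein =
                   .assert_scalar_count(fragments_per_protein,
                                        "fragments_per_protein")),
            class = "synthetic_spec")
}

#' Generate a labeled fragment corpus with planted signal
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @return A `fragment_corpus` (positives first) whose `ground_truth`
#'   attribute records the motif.
#' @export
generate_fragments <- function(spec, seed = NULL) {
  window <- spec$window
  L <- window_length(window)
  offs <- window_offsets(window)
  np <- spec$n_positive; nn <- spec$n_negative
  n <- np + nn
  motif <- spec$motif
  with_seed(seed, {
    codes <- matrix(sample.int(20L, n * L, replace = TRUE,
                               prob = motif$background), n, L)
    codes[, match(0L, offs)] <- match("K", AA_ALPHABET)
    for (j in seq_along(motif$informative_offsets)) {
      col <- match(motif$informative_offsets[j], offs)
      e <- match(motif$enriched_residues[j], AA_ALPHABET)
      hit <- stats::runif(np) < motif$p_enrich
      codes[which(hit), col] <- e
      # misses occur with probability exactly 1 - p_enrich, so they must
      # never carry the enriched residue: redraw from the background
      # restricted to the other residues
      redraw <- which(!hit & codes[seq_len(np), col] == e)
      if (length(redraw)) {
        rest <- motif$background
        rest[e] <- 0
        if (sum(rest) <= 0)
          .stopf("background puts all mass on the enriched residue '%s'",
                 motif$enriched_residues[j])
        codes[redraw, col] <- sample.int(20L, length(redraw), replace = TRUE,
                                         prob = rest)
      }
    }
    frags <- apply(codes, 1L, function(cc) paste(AA_ALPHABET[cc],
                                                 collapse = ""))
    fpp <- spec$fragments_per_protein
    prot <- sprintf("SYNP%05d", ceiling(seq_len(n) / fpp))
    pos_in_prot <- ((seq_len(n) - 1L) %% fpp) * L + window$upstream + 1L
    corpus <- fragment_corpus(
      data.frame(protein_id = prot, position = pos_in_prot,
                 label = rep(c("positive", "negative"), c(np, nn)),
                 fragment = frags, stringsAsFactors = FALSE),
      window = window,
      provenance = sprintf("synthetic (seed %s)",
                           if (is.null(seed)) "NULL" else seed))
    attr(corpus, "ground_truth") <- motif
    corpus
  })
}

#' Emit a synthetic corpus as FASTA plus a site-annotation TSV
#'
#' Fragments are concatenated, `fragments_per_protein` at a time, into
#' synthetic proteins; every generated site is annotated with its label.
#' Reading the emitted files back through [read_fasta()],
#' [read_site_annotations()] and [extract_fragments()] reproduces the
#' generated corpus exactly.
#'
#' @inheritParams generate_fragments
#' @param fasta,annotations Optional output paths; when given, the FASTA and
#'   TSV files are written there.
#' @return List with elements `proteins` (data frame `id`, `sequence`),
#'   `annotations` (data frame `protein_id`, `position`, `label`) and
#'   `corpus` (the generated `fragment_corpus`).
#' @export
generate_annotated_proteins <- function(spec, seed = NULL, fasta = NULL,
                                        annotations = NULL) {
  corpus <- generate_fragments(spec, seed = seed)
  seqs <- vapply(split(corpus$fragment, corpus$protein_id),
                 paste, character(1), collapse = "")
  proteins <- data.frame(id = names(seqs), sequence = unname(seqs),
                         stringsAsFactors = FALSE)
  proteins <- proteins[order(proteins$id), , drop = FALSE]
  rownames(proteins) <- NULL
  ann <- data.frame(protein_id = corpus$protein_id,
                    position = corpus$position,
                    label = corpus$label, stringsAsFactors = FALSE)
  if (!is.null(fasta)) {
    set <- Biostrings::BStringSet(stats::setNames(proteins$sequence,
                                                  proteins$id))
    Biostrings::writeXStringSet(set, fasta)
  }
  if (!is.null(annotations)) {
    utils::write.table(ann, annotations, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(proteins = proteins, annotations = ann, corpus = corpus)
}
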