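# Feature encoders: one-hot binary encoding, physicochemical property
# encoding (AAindex), and the normalized substitution-similarity matrix that
# underlies the KNN distance.

#' Min-max normalize a substitution matrix into a unit-interval similarity
#'
#' `Sim = (M - min(M)) / (max(M) - min(M))`, applied globally over all
#' entries. For [blosum62] the range is -4..11, so e.g.
#' `Sim(W, W) = 15/15 = 1` and `Sim(A, A) = 8/15`. Any comparison involving
#' the pad symbol has similarity 0, so terminal padding never attracts
#' neighbors.
#'
#' @param M Symmetric 20 x 20 substitution matrix with `AA_ALPHABET`
#'   dimnames (default [blosum62]).
#' @return A `substitution_similarity` object holding the raw matrix and a
#'   21 x 21 similarity matrix (row/column 21 is the pad symbol, all zeros).
#' @export
normalize_substitution_matrix <- function(M = blosum62) {
  if (!is.matrix(M) || nrow(M) != 20L || ncol(M) != 20L)
    .stopf("`M` must be a 20 x 20 matrix over the amino-acid alphabet")
  if (!isTRUE(all.equal(M[AA_ALPHABET, AA_ALPHABET],
                        t(M[AA_ALPHABET, AA_ALPHABET]))))
    .stopf("substitution matrix must be symmetric")
  M <- M[AA_ALPHABET, AA_ALPHABET]
  rng <- range(M)
  sim <- (M - rng[1L]) / (rng[2L] - rng[1L])
  full <- matrix(0, .PAD_CODE, .PAD_CODE,
                 dimnames = list(c(AA_ALPHABET, PAD_SYMBOL),
                                 c(AA_ALPHABET, PAD_SYMBOL)))
  full[1:20, 1:20] <- sim
  structure(list(raw = M, sim = full, min = rng[1L], max = rng[2L]),
            class = "substitution_similarity")
}

#' @export
print.substitution_similarity <- function(x, ...) {
  cat(sprintf("<substitution_similarity> raw range [%d, %d], Sim in [0, 1]\n",
              x$min, x$max))
  invisible(x)
}

#' One-hot (binary) encoding of a residue sequence
#'
#' Each position becomes a 20-slot indicator block in `ACDEFGHIKLMNPQRSTVWY`
#' order: `A -> 1 0 0 ...`, `C -> 0 1 0 ...`, and so on; the pad symbol
#' encodes as all zeros. A sequence of length `L` yields a vector of length
#' `20 * L`.
#'
#' @param residues A residue string, or a character vector of single
#'   residues.
#' @return Numeric 0/1 vector of length `20 * L`.
#' @export
binary_encode <- function(residues) {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "", fixed = TRUE)[[1L]]
  codes <- .aa_codes(residues)
  if (any(is.na(codes)))
    .stopf("illegal residue character(s): %s",
           paste(unique(residues[is.na(codes)]), collapse = ", "))
  drop(.binary_encode_codes(matrix(codes, nrow = 1L)))
}

# vectorized one-hot over an n x L code matrix -> n x (20 L)
.binary_encode_codes <- function(codes) {
  n <- nrow(codes); L <- ncol(codes)
  out <- matrix(0, n, 20L * L)
  for (j in seq_len(L)) {
    cj <- codes[, j]
    nonpad <- which(cj <= .N_AA)
    out[cbind(nonpad, (j - 1L) * 20L + cj[nonpad])] <- 1
  }
  out
}

#' Parse an AAindex1 flat file
#'
#' Reads one or more amino-acid index entries in the AAindex1 flat-file
#' format (records separated by `//`; the ten `A/L R/K ...` value pairs on
#' the two lines following the `I` header). `NA` values are replaced by 0.
#'
#' @param path Path to an AAindex1-format file.
#' @return A named list of `property_index` objects, keyed by accession.
#' @export
read_aaindex <- function(path) {
  if (!file.exists(path)) .stopf("AAindex file not found: %s", path)
  lines <- readLines(path)
  recs <- split(lines, cumsum(c(TRUE, head(lines, -1L) == "//")))
  # column order of the I block in AAindex1
  top <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  bottom <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  out <- list()
  for (rec in recs) {
    rec <- rec[rec != "//"]
    if (!length(rec) || !any(startsWith(rec, "H "))) next
    acc <- trimws(sub("^H ", "", rec[startsWith(rec, "H ")][1L]))
    desc_line <- rec[startsWith(rec, "D ")]
    desc <- if (length(desc_line)) trimws(sub("^D ", "", desc_line[1L])) else ""
    i_at <- which(startsWith(rec, "I "))
    idx <- tryCatch({
      if (!length(i_at) || i_at[1L] + 2L > length(rec))
        stop("missing I block")
      vals <- suppressWarnings(
        as.numeric(unlist(strsplit(trimws(rec[i_at[1L] + c(1L, 2L)]),
                                   "[[:space:]]+"))))
      if (length(vals) != 20L) stop("I block does not hold 20 values")
      vals[is.na(vals)] <- 0
      property_index(acc, stats::setNames(vals, c(top, bottom)),
                     description = desc)
    }, error = function(e) {
      warning(sprintf("skipping AAindex entry '%s': %s",
                      acc, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(idx)) {
      if (acc %in% names(out)) .stopf("duplicate AAindex accession '%s'", acc)
      out[[acc]] <- idx
    }
  }
  if (!length(out)) .stopf("no parseable AAindex entries in %s", path)
  out
}

#' Construct a physicochemical property index
#'
#' @param name Index name (e.g. an AAindex accession).
#' @param values Named numeric vector mapping each of the 20 amino acids to a
#'   property value; `NA`s are replaced by 0.
#' @param description Optional free-text description.
#' @return A `property_index` object.
#' @export
property_index <- function(name, values, description = "") {
  if (!setequal(names(values), AA_ALPHABET))
    .stopf("`values` must be named by exactly the 20 amino acids")
  values <- values[AA_ALPHABET]
  values[is.na(values)] <- 0
  structure(list(name = name, values = values, description = description),
            class = "property_index")
}

#' @export
print.property_index <- function(x, ...) {
  cat(sprintf("<property_index> %s%s\n", x$name,
              if (nzchar(x$description)) paste0(": ", x$description) else ""))
  print(round(x$values, 3))
  invisible(x)
}

#' The bundled average accessible surface area index
#'
#' Loads the average accessible surface area (AASA) per-residue index
#' (AAindex accession JANJ780101, attributed to Janin et al.) shipped with
#' the package in AAindex1 flat-file format.
#'
#' @return A `property_index`.
#' @export
aasa_index <- function() {
  path <- system.file("extdata", "JANJ780101.aaindex1", package = "lysace",
                      mustWork = TRUE)
  read_aaindex(path)[[1L]]
}

#' Encode a residue sequence with a property index
#'
#' Position-wise substitution of the per-residue property value. With
#' `scaling = "minmax"` (the default) the 20 index values are affinely
#' rescaled so they span `[0, 1]`, keeping the block commensurate with the
#' 0/1 one-hot block; the pad symbol always maps to 0.
#'
#' @param residues Residue string or character vector.
#' @param index A `property_index` (default the bundled AASA index).
#' @param scaling `"minmax"` or `"none"`.
#' @return Numeric vector of length `L`.
#' @export
property_encode <- function(residues, index = aasa_index(),
                            scaling = c("minmax", "none")) {
  scaling <- match.arg(scaling)
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "", fixed = TRUE)[[1L]]
  codes <- .aa_codes(residues)
  if (any(is.na(codes)))
    .stopf("illegal residue character(s): %s",
           paste(unique(residues[is.na(codes)]), collapse = ", "))
  vals <- .property_lookup(index, scaling)
  unname(vals[codes])
}

# 21-slot lookup (20 aa + pad=0), optionally min-max scaled over the 20 values
.property_lookup <- function(index, scaling) {
  v <- index$values
  if (scaling == "minmax") {
    rng <- range(v)
    v <- if (rng[1L] == rng[2L]) rep(0, 20L) else (v - rng[1L]) / (rng[2L] - rng[1L])
  }
  c(unname(v), 0)
}
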