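# fragment extraction, annotation validation, redundancy reduction and
# sampling of the corpus-construction layer

test_that("FASTA reading normalizes case and validates the alphabet", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "mkka", ">p2 some description", "MKKAY"), path)
  prot <- read_fasta(path)
  expect_equal(prot$id, c("p1", "p2"))
  expect_equal(prot$sequence, c("MKKA", "MKKAY"))

  writeLines(c(">p1", "MK1A"), path)
  expect_error(read_fasta(path), "illegal character")

  writeLines(c(">p1", "MKKA", ">p1", "MAKA"), path)
  expect_error(read_fasta(path), "duplicate")
})

test_that("site annotations are validated against the sequences", {
  prot <- data.frame(id = "p1", sequence = "MKKA")
  ok <- validate_annotations(data.frame(protein_id = "p1", position = 2), prot)
  expect_equal(ok$label, "positive")
  expect_error(validate_annotations(
    data.frame(protein_id = "p1", position = 1), prot), "not lysine")
  expect_error(validate_annotations(
    data.frame(protein_id = "p1", position = 9), prot), "out of range")
  expect_error(validate_annotations(
    data.frame(protein_id = "p9", position = 2), prot), "unknown protein")
  expect_error(validate_annotations(
    data.frame(protein_id = c("p1", "p1"), position = c(2, 2)), prot),
    "duplicate")
})

test_that("window extraction pads past either terminus", {
  w <- window_spec(10, 10)
  # site in the middle of a length-12 protein: pads on both sides
  frag <- extract_fragment("AACDKFGHILLM", 5, w)
  expect_equal(nchar(frag), 21)
  expect_equal(frag, "XXXXXXAACDKFGHILLMXXX")
  # exact fit: no pads
  s21 <- paste(c(rep("A", 10), "K", rep("C", 10)), collapse = "")
  expect_equal(extract_fragment(s21, 11, w), s21)
  # site at position 1: upstream all pads
  frag1 <- extract_fragment("KAAAA", 1, w)
  expect_equal(substr(frag1, 1, 10), strrep("X", 10))
  expect_error(extract_fragment("MKKA", 1, w), "not 'K'")
})

test_that("negative-site enumeration is the complement of the positives", {
  prot <- data.frame(id = c("p1", "p2", "p3"),
                     sequence = c("MKKA", "MAAA", "KKK"))
  pos <- data.frame(protein_id = c("p1", "p3", "p3", "p3"),
                    position = c(2, 1, 2, 3))
  neg <- enumerate_negative_sites(prot, pos)
  expect_equal(neg$protein_id, "p1")
  expect_equal(neg$position, 3L)
  expect_true(all(neg$label == "negative"))
  # positives and negatives partition the lysine positions
  all_k <- enumerate_negative_sites(prot, pos[0, ])
  expect_equal(nrow(all_k), nrow(neg) + nrow(pos))
})

test_that("fragment identity counts matching offsets", {
  expect_equal(fragment_identity("AAKAA", "AAKAA"), 1)
  expect_equal(fragment_identity("AAKAA", "CCKCC"), 1 / 5)
  expect_equal(fragment_identity("XXKAA", "XXKCC"), 3 / 5)  # pad matches pad
  expect_error(fragment_identity("AK", "AKA"), "length")
})

test_that("redundancy reduction is a deterministic greedy keep-first scan", {
  w <- window_spec(2, 1)
  # identity(A,B) = 0.5 > 0.3 so B is dropped; C is dissimilar to A and kept
  corp <- fragment_corpus(data.frame(
    protein_id = c("p1", "p2", "p3"), position = 3L,
    label = "positive",
    fragment = c("AAKA", "CAKC", "DEKF")), window = w)
  red <- reduce_redundancy(corp, threshold = 0.3)
  expect_equal(red$protein_id, c("p1", "p3"))

  # duplicates collapse to one
  dup <- make_corpus(rep("AAAAAAAAAAKAAAAAAAAAA", 2),
                     c("positive", "positive"))
  expect_equal(nrow(reduce_redundancy(dup)), 1)

  # empty input passes through
  expect_equal(nrow(reduce_redundancy(corpus_subset(dup, FALSE))), 0)

  # property: no retained pair exceeds the threshold; boundary is kept
  set.seed(11)
  frags <- random_fragments(120)
  corp <- make_corpus(frags, rep("positive", length(frags)))
  red <- reduce_redundancy(corp, threshold = 0.3)
  ids <- red$fragment
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      expect_lte(fragment_identity(ids[i], ids[j]), 0.3)
    }
  }
})

test_that("balanced negative sets have the positive-set size and reproduce under a seed", {
  set.seed(2)
  neg <- make_corpus(random_fragments(400), rep("negative", 400))
  sets <- sample_balanced_negative_sets(neg, n_positive = 100, n_sets = 5,
                                        seed = 99)
  expect_length(sets, 5)
  expect_true(all(vapply(sets, nrow, integer(1)) == 100))
  # no duplicates within a set
  for (s in sets) expect_false(anyDuplicated(paste(s$protein_id, s$position)) > 0)
  sets2 <- sample_balanced_negative_sets(neg, 100, n_sets = 5, seed = 99)
  expect_identical(lapply(sets, as.data.frame), lapply(sets2, as.data.frame))
  expect_error(sample_balanced_negative_sets(neg, 401), "at least")
})

test_that("protein holdout splits at the protein level and reproduces", {
  prot <- data.frame(id = sprintf("p%03d", 1:100),
                     sequence = rep("AAKAA", 100))
  sp <- hold_out_proteins(prot, fraction = 0.10, seed = 5)
  expect_equal(nrow(sp$holdout), 10)
  expect_length(intersect(sp$training$id, sp$holdout$id), 0)
  sp2 <- hold_out_proteins(prot, fraction = 0.10, seed = 5)
  expect_identical(sp, sp2)
  expect_error(hold_out_proteins(prot, fraction = 0), "between 0 and 1")
  expect_error(hold_out_proteins(prot, fraction = 1), "between 0 and 1")
})

test_that("corpus TSV round-trips", {
  set.seed(3)
  corp <- make_corpus(random_fragments(10),
                      rep(c("positive", "negative"), 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(corp, path)
  back <- read_corpus(path)
  expect_equal(as.data.frame(back), as.data.frame(corp), ignore_attr = TRUE)
})
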