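# information gain, position masks, composition and enrichment analysis

test_that("class entropy hits the analytic values", {
  expect_equal(class_entropy(rep(c("positive", "negative"), 50)), 1)
  expect_equal(class_entropy(rep("positive", 10)), 0)
  expect_equal(class_entropy(rep(c("positive", "negative"), c(75, 25))),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_error(class_entropy(character(0)), "at least one")
})

test_that("conditional entropy reproduces the hand-computed contingency case", {
  w <- window_spec(1, 0)
  corp <- make_corpus(c("KK", "KK", "AK", "KK"),
                      c("positive", "positive", "negative", "negative"), w)
  # Y at offset -1: K in 3 fragments (2 pos, 1 neg), A in 1 (neg)
  h <- conditional_entropy(corp, offset = -1)
  expect_equal(h, 0.75 * (-(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3)))
  expect_equal(class_entropy(corp$label) - h, 0.3112781, tolerance = 1e-6)

  # a constant offset gives H(X|Y) = H(X); offset 0 is constant 'K'
  expect_equal(conditional_entropy(corp, 0), class_entropy(corp$label))
  expect_error(conditional_entropy(corp, 5), "outside")
})

test_that("the IG profile matches the explicit entropy oracle", {
  set.seed(13)
  w <- window_spec(4, 4)
  n <- 80
  corp <- make_corpus(random_fragments(n, w),
                      sample(c("positive", "negative"), n, TRUE), w)
  prof <- compute_ig_profile(corp)
  expect_equal(prof$offset, -4:4)
  for (off in setdiff(-4:4, 0)) {
    o <- oracle_ig(corp$fragment, corp$label, off, w)
    expect_equal(prof$ig[prof$offset == off], o$ig, tolerance = 1e-12)
    expect_equal(prof$h_conditional[prof$offset == off], o$h_cond,
                 tolerance = 1e-12)
  }
  expect_equal(attr(prof, "class_entropy"),
               oracle_ig(corp$fragment, corp$label, 1, w)$h_x)
  # invariants: 0 <= IG <= H(X); center reported as 0
  expect_true(all(prof$ig >= -1e-12))
  expect_true(all(prof$ig <= attr(prof, "class_entropy") + 1e-12))
  expect_equal(prof$ig[prof$offset == 0], 0)
  expect_error(compute_ig_profile(make_corpus(random_fragments(4, w),
                                              rep("positive", 4), w)),
               "both classes")
})

test_that("pads count as an observable symbol near the termini", {
  w <- window_spec(2, 2)
  # positives all terminal (padded), negatives all internal: the pad itself
  # is perfectly class-informative at offset -2
  corp <- make_corpus(c("XXKAA", "XXKCC", "AAKAA", "CCKCC"),
                      c("positive", "positive", "negative", "negative"), w)
  prof <- compute_ig_profile(corp)
  expect_equal(prof$ig[prof$offset == -2], 1)
})

test_that("select_positions ranks by IG with deterministic tie-breaks", {
  w <- window_spec(2, 2)
  prof <- structure(data.frame(offset = c(-2, -1, 0, 1, 2),
                               h_conditional = NA,
                               ig = c(0.3, 0.5, 0, 0.4, 0.1)),
                    class = c("ig_profile", "data.frame"))
  expect_equal(as.integer(select_positions(prof, 2)), c(-1, 1))
  expect_equal(as.integer(select_positions(prof, 4)), c(-2, -1, 1, 2))
  # ties: smaller |offset| first, then upstream before downstream
  prof$ig <- c(0.2, 0.2, 0, 0.2, 0.2)
  expect_equal(as.integer(select_positions(prof, 2)), c(-1, 1))
  expect_equal(as.integer(select_positions(prof, 3)), c(-2, -1, 1))
  expect_error(select_positions(prof, 5), "exceeds")
})

test_that("preset masks list the published offsets exactly", {
  expect_equal(as.integer(preset_mask("IG9")), c(-8:-1, 1))
  expect_equal(as.integer(preset_mask("IG11")), sort(c(-8:-1, 1, 4, 6)))
  expect_equal(as.integer(preset_mask("IG13")),
               sort(c(-8, -7, -6, -5, -4, -3, -2, -1, 1, 3, 4, 6, 7)))
  expect_equal(as.integer(preset_mask("IG15")),
               sort(c(-8:-1, 1, 3, 4, 5, 6, 7, 9)))
  expect_equal(as.integer(preset_mask("IG17")), sort(c(-8:-1, 1:9)))
  for (sz in c(9, 11, 13, 15, 17)) {
    expect_length(preset_mask(sprintf("IG%d", sz)), sz)
  }
  expect_equal(as.integer(preset_mask("general15")), setdiff(-7:7, 0))
  expect_equal(as.integer(preset_mask("general21")), setdiff(-10:10, 0))
  expect_error(preset_mask("IG12"), "valid names")
})

test_that("apply_mask keeps masked offsets in ascending order, center dropped", {
  w <- window_spec(10, 10)
  frag <- paste0("ACDEFGHILM", "K", "NPQRSTVWYA")
  expect_equal(nchar(apply_mask(frag, preset_mask("IG13"), w)), 13)
  expect_equal(nchar(apply_mask(frag, preset_mask("general21"), w)), 20)
  expect_false(grepl("K", apply_mask(frag, preset_mask("general21"), w),
                     fixed = TRUE))
  expect_equal(apply_mask(frag, position_mask(c(-10, 1)), w),
               paste0(substr(frag, 1, 1), substr(frag, 12, 12)))
  expect_error(apply_mask(frag, position_mask(11), w), "outside")
  expect_error(position_mask(c(0, 1)), "center")
})

test_that("composition frequencies sum to one per class and ignore pads", {
  w <- window_spec(2, 2)
  corp <- make_corpus(c("XXKAA", "AAKRR"), c("positive", "negative"), w)
  tab <- composition_frequencies(corp)
  expect_equal(sum(tab$freq_positive), 1)
  expect_equal(sum(tab$freq_negative), 1)
  # positive class: K,A,A over 3 non-pad residues
  expect_equal(tab$freq_positive[tab$residue == "K"], 1 / 3)
  expect_equal(tab$freq_positive[tab$residue == "A"], 2 / 3)
})

test_that("position-wise enrichment flags the planted residues and only those kinds", {
  spec <- synthetic_spec(n_positive = 400, n_negative = 400)
  corp <- generate_fragments(spec, seed = 17)
  enr <- positionwise_enrichment(corp, alpha = 1e-4)
  k_up <- enr[enr$residue == "K" & enr$offset %in% -8:-1, ]
  expect_true(all(k_up$call == "enriched"))
  r_down <- enr[enr$residue == "R" & enr$offset == 1, ]
  expect_equal(r_down$call, "enriched")
  expect_equal(attr(enr, "n_tests"), 20 * 20)

  # identical class corpora produce no calls; alpha = 0 disables flagging
  w <- window_spec(2, 2)
  same <- make_corpus(c("AAKAA", "CCKCC", "AAKAA", "CCKCC"),
                      c("positive", "positive", "negative", "negative"), w)
  expect_true(all(positionwise_enrichment(same)$call == "none"))
  expect_true(all(positionwise_enrichment(corp, alpha = 0)$call == "none"))
})
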