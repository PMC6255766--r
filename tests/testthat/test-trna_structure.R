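# hand-built cloverleaf with known 7/4/5/5 all-Watson-Crick arms (69 nt):
# GCGCGCG |GGCC|AAAAAAAA|GGCC| GCCGG|AA GAA AA|CCGGC| AAAAA |GGGCC|AAAAAAA|GGCCC| CGCGCGC
hand_cloverleaf <- function() {
  paste0("GCGCGCG", "GGCC", "AAAAAAAA", "GGCC",
         "GCCGG", "AAGAAAA", "CCGGC", "AAAAA",
         "GGGCC", "AAAAAAA", "GGCCC", "CGCGCGC")
}

test_that("base pairs classify as Watson-Crick, wobble or mismatch", {
  expect_identical(pair_class("G", "T"), "wobble")
  expect_identical(pair_class("A", "T"), "watson_crick")
  expect_identical(pair_class(c("G", "A", "C"), c("C", "A", "G")),
                   c("watson_crick", "mismatch", "watson_crick"))
})

test_that("a perfectly complementary fixture folds to its exact arm sizes", {
  s <- hand_cloverleaf()
  f <- fold_cloverleaf(s, anticodon_hint = "GAA")
  expect_true(f$foldable)
  expect_equal(unname(f$arm_lengths), c(7L, 4L, 5L, 5L))
  expect_equal(unname(f$loop_lengths[c("dhu", "anticodon", "variable", "t_arm")]),
               c(8L, 7L, 5L, 7L))
  expect_identical(f$anticodon, "GAA")
  cp <- classify_pairs(f)
  expect_equal(sum(cp$mismatch), 0L)
  expect_equal(sum(cp$watson_crick), 21L)
  expect_identical(flatten_cloverleaf(f), s)
})

test_that("DHU-less tRNAs fold without a DHU arm", {
  set.seed(3)
  b <- mitocomp:::build_trna(62, "GCT", base_probs(0.62), dhu_absent = TRUE)
  f <- fold_cloverleaf(b$seq, anticodon_hint = "GCT")
  expect_true(f$foldable)
  expect_null(f$dhu)
  expect_equal(unname(f$arm_lengths["dhu"]), 0L)
  expect_false(classify_pairs(f)$present[classify_pairs(f)$arm == "dhu"])
})

test_that("sequences without complementary stems are reported unfoldable", {
  set.seed(4)
  rej <- random_dna(70, alphabet = c("A", "C"))  # no WC or wobble pairs exist
  f <- fold_cloverleaf(rej)
  expect_false(f$foldable)
  expect_error(classify_pairs(f), "unfoldable")
  expect_error(flatten_cloverleaf(f), "unfoldable")
  expect_error(fold_cloverleaf(random_dna(40)), "outside supported range")
})

test_that("flattening any generated fold reconstructs the input exactly", {
  gen <- generate_genome(seed = 51L)
  rec <- gen$record
  trnas <- rec$features[rec$features$category == "tRNA", ]
  for (i in seq_len(nrow(trnas))) {
    s <- extract_feature_sequence(rec, trnas$name[i])
    f <- fold_cloverleaf(s, anticodon_hint = trnas$anticodon[i])
    expect_true(f$foldable, info = trnas$name[i])
    expect_identical(flatten_cloverleaf(f), s, info = trnas$name[i])
    expect_identical(f$anticodon, trnas$anticodon[i])
  }
})

test_that("planted wobble and mismatch pairs are recovered by classification", {
  set.seed(5)
  planted <- data.frame(arm = c("acceptor", "t_arm"), index = c(2L, 1L),
                        class = c("wobble", "mismatch"),
                        stringsAsFactors = FALSE)
  b <- mitocomp:::build_trna(72, "TAC", base_probs(0.62), planted = planted)
  f <- fold_cloverleaf(b$seq, anticodon_hint = "TAC",
                       max_mismatch_per_arm = 1L)
  expect_true(f$foldable)
  cp <- classify_pairs(f)
  expect_equal(cp$wobble[cp$arm == "acceptor"], 1L)
  expect_equal(cp$mismatch[cp$arm == "t_arm"], 1L)
})

test_that("replacing a mismatch by a Watson-Crick pair never lowers the score", {
  s <- hand_cloverleaf()
  # break acceptor pair 3 (position 3 pairs with the 3rd-last base)
  s_mm <- s
  substr(s_mm, 3, 3) <- "A"     # A:C mismatch in the acceptor stem
  f_mm <- fold_cloverleaf(s_mm, anticodon_hint = "GAA")
  f_fix <- fold_cloverleaf(s, anticodon_hint = "GAA")
  expect_true(f_mm$foldable)
  expect_equal(sum(classify_pairs(f_mm)$mismatch), 1L)
  expect_gt(f_fix$score, f_mm$score)
})

test_that("identical inputs fold identically (determinism)", {
  set.seed(9)
  b <- mitocomp:::build_trna(74, "TGT", base_probs(0.6))
  f1 <- fold_cloverleaf(b$seq)
  f2 <- fold_cloverleaf(b$seq)
  expect_identical(f1, f2)
})

test_that("cross-species comparison summarises arm variability", {
  set.seed(10)
  probs <- base_probs(0.62)
  one <- mitocomp:::build_trna(72, "TTC", probs)
  same <- replicate(13, fold_cloverleaf(one$seq, anticodon_hint = "TTC"),
                    simplify = FALSE)
  names(same) <- paste0("sp", 1:13)
  cmp <- compare_across_species(same)
  expect_true(cmp$identical_in_all)
  expect_equal(cmp$n_modal_profile, 13L)

  # two structures differing only in variable-loop length
  a <- fold_cloverleaf(mitocomp:::build_trna(70, "TTC", probs)$seq,
                       anticodon_hint = "TTC")
  b2 <- fold_cloverleaf(mitocomp:::build_trna(73, "TTC", probs)$seq,
                        anticodon_hint = "TTC")
  cmp2 <- compare_across_species(list(x = a, y = b2))
  expect_equal(unname(cmp2$arm_ranges[1, ]), unname(cmp2$arm_ranges[2, ]))
  expect_true(diff(cmp2$variable_loop_range) >= 0)

  # mixed tRNA identities are rejected
  other <- fold_cloverleaf(mitocomp:::build_trna(72, "CAT", probs)$seq,
                           anticodon_hint = "CAT")
  expect_error(compare_across_species(list(a = a, b = other)), "mixed")

  # >= 10 pooled non-WC pairs flags the tRNA as highly variable
  planted <- data.frame(arm = "acceptor", index = 2L, class = "wobble",
                        stringsAsFactors = FALSE)
  wob <- lapply(1:10, function(i) {
    fold_cloverleaf(
      mitocomp:::build_trna(72, "TCA", probs, planted = planted)$seq,
      anticodon_hint = "TCA")
  })
  names(wob) <- paste0("sp", 1:10)
  cmp3 <- compare_across_species(wob)
  expect_gte(cmp3$nonwc_total, 10L)
  expect_true(cmp3$flagged)
})
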