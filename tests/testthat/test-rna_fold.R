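test_that("GC content, AMFE and MFEI follow their closed forms", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("AUAU"), 0)
  expect_equal(gc_content("GUAC"), 50)
  expect_error(gc_content(""), "empty")

  expect_equal(amfe(-50, 100), 50)
  expect_equal(amfe(0, 80), 0)
  expect_equal(amfe(-30, 60), 50)

  expect_equal(mfei(-50, 100, 50), 1.00)
  expect_equal(mfei(-35, 100, 50), 0.70)
  expect_error(mfei(-10, 50, 0), "undefined")

  # AMFE is scale-consistent: doubling sequence and energy changes nothing
  expect_equal(amfe(-31.4, 87), amfe(-62.8, 174))
})

test_that("unpairable sequences fold to the open chain at zero energy", {
  f <- fold_mfe("AAAAAAAAAA")
  expect_equal(f$dot_bracket, "..........")
  expect_equal(f$mfe, 0)
  expect_true(all(is.na(f$pair_map)))
})

test_that("a simple stem scores as the hand-summed stack and loop terms", {
  # ..((((........)))) : pairs UA, UA, GC, GC from the outside in;
  # stacks UA/UA, UA/GC, GC/GC plus an 8-nt hairpin loop
  f <- fold_mfe("UUUUGGAACCUGGGCCAA")
  expect_equal(f$dot_bracket, "..((((........))))")
  m <- energy_model()
  hand <- (m$stack["UA", "UA"] + m$stack["UA", "GC"] +
             m$stack["GC", "GC"] + m$hairpin[["8"]]) / 10
  expect_equal(f$mfe, hand)
})

test_that("folding equals exhaustive enumeration and re-scoring is exact", {
  model <- energy_model()
  f <- fold_mfe("GGGAAAACCC", model)
  expect_equal(f$mfe, oracle_fold_mfe("GGGAAAACCC", model))

  set.seed(11)
  for (k in 1:25) {
    s <- random_rna(sample(15:22, 1))
    f <- fold_mfe(s, model)
    expect_equal(f$mfe, oracle_fold_mfe(s, model), info = s)
    expect_equal(structure_energy(s, f$dot_bracket, model), f$mfe, info = s)
  }
  # re-scoring stays exact at precursor scale
  for (k in 1:5) {
    s <- random_rna(sample(80:180, 1))
    f <- fold_mfe(s, model)
    expect_equal(structure_energy(s, f$dot_bracket, model), f$mfe)
  }
})

test_that("planted hairpins have higher MFEI than shuffled sequences", {
  model <- energy_model()
  set.seed(5)
  planted <- vapply(1:8, function(i) {
    pre <- make_precursor(random_dna_str(22), seed = 1000 + i)
    g <- glance(fold_mfe(pre$precursor, model))
    g$mfei
  }, numeric(1))
  shuffled <- vapply(1:8, function(i) {
    pre <- make_precursor(random_dna_str(22), seed = 1000 + i)
    shuf <- paste(sample(strsplit(pre$precursor, "")[[1]]), collapse = "")
    g <- glance(fold_mfe(shuf, model))
    g$mfei
  }, numeric(1))
  expect_gt(mean(planted), mean(shuffled))
})

test_that("hairpin geometry reports arm, pairing and star span", {
  pre <- make_precursor("TGACAGAAGAGAGTGAGCACAT", loop_len = 8,
                        star_mismatches = 0, arm = "5p", seed = 9)
  st <- fold_mfe(pre$precursor)
  feat <- hairpin_features(st, pre$mature_span)
  expect_equal(feat$arm, "5p")
  expect_equal(feat$n_paired, 22L)
  expect_equal(feat$max_asym_bulge, 0L)
  expect_gte(feat$terminal_loop, 3L)
  # star span overlaps the constructed star arm
  expect_lte(pre$star_span[1], feat$star_span[2])
  expect_gte(pre$star_span[2], feat$star_span[1])

  # mature placed across the terminal loop
  loop_mid <- round(mean(pre$loop_span))
  feat_loop <- hairpin_features(st, c(loop_mid - 10L, loop_mid + 10L))
  expect_equal(feat_loop$arm, "loop-spanning")

  # two planted star mismatches surface as two unpaired mature bases
  pre2 <- make_precursor("TGACAGAAGAGAGTGAGCACAT", star_mismatches = 2,
                         arm = "5p", seed = 10)
  feat2 <- hairpin_features(fold_mfe(pre2$precursor), pre2$mature_span)
  expect_equal(feat2$n_unpaired, 2L)

  expect_error(hairpin_features(st, c(0, 5)), "outside")
})

test_that("3p-arm matures are assigned to the 3p arm", {
  pre <- make_precursor("TGACAGAAGAGAGTGAGCACAT", arm = "3p",
                        star_mismatches = 2, seed = 12)
  feat <- hairpin_features(fold_mfe(pre$precursor), pre$mature_span)
  expect_equal(feat$arm, "3p")
})
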