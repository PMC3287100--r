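# Composition, RSCU, representation classes, ENC and the expected-ENC curve.

test_that("count_codons pools and excludes flagged codons", {
  s1 <- coding_sequence("a", "ATGAAA")
  s2 <- coding_sequence("b", "AAATTT")
  cc <- count_codons(list(s1, s2), pool = TRUE)
  expect_equal(unname(cc$counts[c("ATG", "AAA", "TTT")]), c(1, 2, 1))
  expect_equal(cc$n_codons, 4)
  expect_identical(cc$source_ids, c("a", "b"))

  per <- count_codons(list(s1, s2))
  expect_named(per, c("a", "b"))
  expect_equal(per$a$n_codons, 2)
  expect_error(count_codons(list()), "empty input")
})

test_that("stop codons never enter count tables", {
  cc <- count_codons(coding_sequence("a", "ATGAAATAG"))
  expect_equal(cc$n_codons, 2)
  expect_equal(sum(cc$counts[c("TAA", "TAG", "TGA")]), 0)
  expect_warning(direct <- codon_counts(c(AAA = 2, TAA = 1)),
                 "never counted")
  expect_equal(direct$n_codons, 2)
})

test_that("composition matches hand-computed degenerate cases", {
  p <- composition(count_codons(coding_sequence("a", "GCTGCTGCTGCT",
    validation_policy(on_bad_length = "truncate-trailing"))))
  expect_equal(unname(p$overall[c("G", "C", "T", "A")]),
               c(100 / 3, 100 / 3, 100 / 3, 0), tolerance = 1e-12)
  expect_equal(unname(p$third_syn[["T"]]), 100)
  expect_equal(p$gc3, 0)
  expect_equal(p$gc12, 100)  # G and C at positions 1 and 2 of GCT

  # Met-only sequence: no synonymous codon, third-position pool undefined
  p2 <- composition(count_codons(coding_sequence("m", "ATGATGATG")))
  expect_true(all(is.na(p2$third_syn)))
  expect_true(is.na(p2$gc3))
  expect_equal(unname(p2$overall[c("A", "T", "G", "C")]),
               c(100 / 3, 100 / 3, 100 / 3, 0), tolerance = 1e-12)
})

test_that("composition percentages are closed and pool-order invariant", {
  set.seed(21)
  cohort <- simulate_cds(cohort_spec(5, 300, seed = 21),
                         mut = mutation_model_gc(0.7))
  p <- composition(count_codons(cohort, pool = TRUE))
  expect_equal(sum(p$overall), 100, tolerance = 0.01)
  expect_equal(sum(p$third_syn), 100, tolerance = 0.01)
  expect_true(all(c(p$overall, p$third_syn, p$gc12, p$gc3) >= 0))
  expect_true(all(c(p$overall, p$third_syn, p$gc12, p$gc3) <= 100))

  p_rev <- composition(count_codons(rev(cohort), pool = TRUE))
  expect_equal(p_rev$overall, p$overall)
  expect_equal(p_rev$third_syn, p$third_syn)
})

test_that("gc_partition matches hand-computed slot counts", {
  # GCG: G at position 1 and C at position 2, so every pos-1/2 slot is G or C
  gc <- gc_partition(count_codons(coding_sequence("a", "GCGGCGGCG")))
  expect_equal(unname(gc), c(100, 100))
  gc2 <- gc_partition(count_codons(coding_sequence("b", "ATAATAATA")))
  expect_equal(unname(gc2), c(0, 0))
  # equal GCT/GCC: positions 1-2 all G/C, thirds split half T half C
  gc3 <- gc_partition(codon_counts(c(GCT = 5, GCC = 5)))
  expect_equal(unname(gc3), c(100, 50))
  # mixed: GCT + ATA pools G,C,A,T at positions 1-2 -> 50%
  gc4 <- gc_partition(codon_counts(c(GCT = 5, ATA = 5)))
  expect_equal(unname(gc4), c(50, 0))
})

test_that("RSCU matches its definition on worked examples", {
  v <- rscu(codon_counts(c(TTT = 3, TTC = 1)))
  expect_equal(v[["TTT"]], 1.5)
  expect_equal(v[["TTC"]], 0.5)

  # every sense codon once -> all 59 values 1.0
  all_once <- codon_counts(stats::setNames(rep(1, 61),
                                           c(synonymous_codons(),
                                             "ATG", "TGG")))
  v1 <- rscu(all_once)
  expect_equal(unname(as.numeric(v1)), rep(1, 59))
  expect_length(attr(v1, "undefined"), 0)

  # absent family -> undefined, not zero
  v2 <- rscu(codon_counts(c(TTT = 2)))
  expect_true(all(c("TGT", "TGC") %in% attr(v2, "undefined")))
  expect_true(is.na(v2[["TGT"]]))
})

test_that("RSCU family sums equal degeneracy and scaling is a no-op", {
  set.seed(31)
  for (i in 1:50) {
    x <- random_count_table()
    v <- rscu(codon_counts(x))
    for (fam in ORACLE_FAMILIES) {
      s <- sum(v[fam])
      if (!is.na(s)) expect_equal(s, length(fam), tolerance = 1e-9)
    }
    v_scaled <- rscu(codon_counts(x * 7))
    expect_equal(as.numeric(v_scaled), as.numeric(v), tolerance = 1e-12)
  }
})

test_that("RSCU agrees with an independent implementation (seqinr)", {
  skip_if_not_installed("seqinr")
  set.seed(41)
  s <- simulate_cds(cohort_spec(1, 3000, w = 0.6, seed = 41),
                    mut = mutation_model_gc(0.62),
                    sel = selection_model_concentrated())[[1]]
  v <- rscu(count_codons(s))
  coding_part <- substr(s$sequence, 1, nchar(s$sequence) - 3)  # drop stop
  ref <- seqinr::uco(strsplit(tolower(coding_part), "")[[1]], index = "rscu")
  names(ref) <- toupper(names(ref))
  common <- names(v)[!is.na(v)]
  expect_equal(as.numeric(v[common]), unname(ref[common]), tolerance = 1e-9)
})

test_that("representation classes use strict 1.6 / 0.6 thresholds", {
  # Phe 4:1 -> RSCU exactly 1.6 / 0.4
  cls <- classify_representation(rscu(codon_counts(c(TTT = 4, TTC = 1))))
  expect_identical(cls[["TTT"]], "normal")  # boundary is not over
  expect_identical(cls[["TTC"]], "under")
  expect_identical(unname(cls[c("TGT", "TGC")]),
                   c("undefined", "undefined"))

  cls2 <- classify_representation(rscu(codon_counts(c(TTT = 9, TTC = 1))))
  expect_identical(cls2[["TTT"]], "over")  # 1.8 > 1.6

  # published pooled HBV profile: TCT over, ACC under, TCG under by the rule
  cls3 <- classify_representation(hbv_pooled_rscu())
  expect_identical(cls3[["TCT"]], "over")
  expect_identical(unname(cls3[c("ATA", "CCC", "ACC", "GCC", "CGT", "CGG")]),
                   rep("under", 6))
  expect_identical(cls3[["TCG"]], "under")  # 0.58 < 0.6
})

test_that("ENC endpoints: maximal bias gives 20, equal usage caps at 61", {
  cs <- coding_sequence("mono", one_codon_per_family_seq(10))
  res <- enc(count_codons(cs))
  expect_equal(res$enc, 20, tolerance = 1e-12)
  expect_identical(res$imputed_classes, character(0))
  expect_equal(unname(res$families_used), c(9L, 1L, 5L, 3L))

  eq <- codon_counts(stats::setNames(rep(1e4, 59), synonymous_codons()))
  expect_equal(enc(eq)$enc, 61)
})

test_that("ENC matches a hand-computed toy table", {
  # Phe{2,2} F=(4*0.5-1)/3=1/3; Asp{3,1} F=(4*0.625-1)/3=0.5 -> F2=5/12
  # Ile{2,1,1} F=(4*0.375-1)/3=1/6
  # Ala{1,1,1,1} F=(4*0.25-1)/3=0 -> excluded; Gly{4,0,0,0} F=1 -> F4=1
  # Leu{CTG:4} F=1; Ser{3,3} F=(6*0.5-1)/5=0.4; Arg{2,2,2} F=(6/3-1)/5=0.2
  x <- c(TTT = 2, TTC = 2, GAT = 3, GAC = 1, ATT = 2, ATC = 1, ATA = 1,
         GCT = 1, GCC = 1, GCA = 1, GCG = 1, GGT = 4, CTG = 4,
         TCT = 3, TCC = 3, CGT = 2, CGC = 2, CGA = 2)
  f2 <- mean(c(1 / 3, 0.5)); f3 <- 1 / 6; f4 <- 1
  f6 <- mean(c(1, 0.4, 0.2))
  expected <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  res <- enc(codon_counts(x))
  expect_equal(res$enc, expected, tolerance = 1e-12)
  expect_equal(res$enc, oracle_enc(x), tolerance = 1e-12)
  # Ala's F is exactly 0 (all four codons equal at n = 4): unusable, so the
  # 4-fold class keeps only Gly
  expect_equal(unname(res$families_used), c(2L, 1L, 1L, 3L))
})

test_that("missing 3-fold class is imputed; missing 2/4/6 yields NA", {
  # no Ile at all: F3 imputed as mean of F2 and F4
  x <- c(TTT = 3, TTC = 1, GCT = 2, GCC = 2, CTG = 2, CTT = 2,
         GAA = 2, GGT = 4)
  res <- enc(codon_counts(x))
  expect_identical(res$imputed_classes, "3")
  expect_equal(res$f_bar[["3"]], (res$f_bar[["2"]] + res$f_bar[["4"]]) / 2)
  expect_false(is.na(res$enc))

  # GAA alone: Glu has n=2 but the 4-fold and 6-fold classes are empty
  res2 <- enc(codon_counts(c(GAA = 2, TTT = 2)))
  expect_true(is.na(res2$enc))
  expect_equal(unname(res2$families_used), c(2L, 0L, 0L, 0L))
})

test_that("ENC equals the brute-force oracle and stays in [20, 61]", {
  set.seed(51)
  for (i in 1:100) {
    x <- random_count_table(lambda = sample(c(1, 3, 10), 1),
                            drop_family_prob = 0.2)
    got <- enc(codon_counts(x))$enc
    want <- oracle_enc(x)
    if (is.na(want)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, want, tolerance = 1e-9)
      expect_gte(got, 20)
      expect_lte(got, 61)
    }
  }
})

test_that("expected ENC curve has its closed-form values", {
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(1), 32)
  expect_error(expected_enc(1.2), "fraction")
  expect_error(expected_enc(-0.1), "fraction")
})
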