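# Per-term likelihood ratios, composite LR, posttest probability and ranking.
# Expected values are hand-derived from the toy fixtures.

# Hand-specified background over toy_hpo(): A=1, B=0.09, C=0.5, D=0.1, E=0.05.
toy_bg <- function() {
  structure(list(
    freq = c("HP:0000001" = 1.0, "HP:0000002" = 0.09, "HP:0000003" = 0.5,
             "HP:0000004" = 0.1, "HP:0000005" = 0.05),
    n_diseases = 50L), class = "background_frequencies")
}

test_that("observed-term match types and numerators follow the ruleset", {
  hpo <- toy_hpo(); bg <- toy_bg()
  dB <- disease_model("OMIM:000001", c("HP:0000002" = 0.9))   # annotated B
  dD <- disease_model("OMIM:000002", c("HP:0000004" = 0.8))   # annotated D

  x <- term_lr("HP:0000002", TRUE, dB, bg, hpo)               # exact
  expect_equal(x$match_type, "EXACT")
  expect_equal(x$lr, 0.9 / 0.09)                              # 10 by hand

  x <- term_lr("HP:0000004", TRUE, dB, bg, hpo)   # observed D, annotated B
  expect_equal(x$match_type, "QUERY_DESCENDANT_OF_ANNOTATION")
  expect_equal(x$lr, (0.9 * 0.5) / 0.1)                       # 4.5

  x <- term_lr("HP:0000002", TRUE, dD, bg, hpo)   # observed B, annotated D
  expect_equal(x$match_type, "QUERY_ANCESTOR_OF_ANNOTATION")
  expect_equal(x$lr, 0.8 / 0.09)

  x <- term_lr("HP:0000003", TRUE, dD, bg, hpo)   # C unrelated to D
  expect_equal(x$match_type, "NO_MATCH")
  expect_equal(x$lr, 0.01)
})

test_that("best match wins; ties break to the smallest term id", {
  hpo <- toy_hpo(); bg <- toy_bg()
  # observed B: annotated descendant D (num 0.8) beats annotated ancestor A
  # (num 1.0 * 0.5)
  d <- disease_model("OMIM:000003",
                     c("HP:0000004" = 0.8, "HP:0000001" = 1.0))
  x <- term_lr("HP:0000002", TRUE, d, bg, hpo)
  expect_equal(x$match_type, "QUERY_ANCESTOR_OF_ANNOTATION")
  expect_equal(x$matched_term, "HP:0000004")
  # equal numerators from D and E: smallest id D wins
  d2 <- disease_model("OMIM:000004",
                      c("HP:0000004" = 0.8, "HP:0000005" = 0.8))
  x2 <- term_lr("HP:0000002", TRUE, d2, bg, hpo)
  expect_equal(x2$matched_term, "HP:0000004")
})

test_that("excluded-term LRs reward confirmation and punish violation", {
  hpo <- toy_hpo(); bg <- toy_bg()
  dB <- disease_model("OMIM:000001", c("HP:0000002" = 0.9))
  x <- term_lr("HP:0000002", FALSE, dB, bg, hpo)
  expect_equal(x$match_type, "EXCLUDED_VIOLATED")
  expect_equal(x$lr, (1 - 0.9) / (1 - 0.09))                  # by hand
  x <- term_lr("HP:0000003", FALSE, dB, bg, hpo)  # bg 0.5 -> 1/0.5 at cap
  expect_equal(x$match_type, "EXCLUDED_CONFIRMED")
  expect_equal(x$lr, 2.0)
  x <- term_lr("HP:0000005", FALSE, dB, bg, hpo)  # bg 0.05 -> below cap
  expect_equal(x$lr, 1 / 0.95)
})

test_that("term_lr internal consistency: lr = numerator/denominator, positive finite", {
  hpo <- toy_hpo(); bg <- toy_bg()
  d <- disease_model("OMIM:000001",
                     c("HP:0000002" = 0.9, "HP:0000004" = 1.0))
  for (t in hpo$terms) {
    for (obs in c(TRUE, FALSE)) {
      x <- term_lr(t, obs, d, bg, hpo)
      expect_true(x$lr > 0 && is.finite(x$lr))
      expect_equal(x$lr, x$numerator / x$denominator, tolerance = 1e-12)
    }
  }
  expect_error(term_lr("HP:9999999", TRUE, d, bg, hpo), "unknown term")
})

test_that("composite LR is the product of term LRs, order-invariant", {
  hpo <- toy_hpo(); bg <- toy_bg()
  dB <- disease_model("OMIM:000001", c("HP:0000002" = 0.9))
  p1 <- patient_profile("HP:0000002")
  expect_equal(composite_lr(p1, dB, bg, hpo), 10.0)          # product of one
  p2 <- patient_profile(c("HP:0000002", "HP:0000003"))       # 10 * 0.01
  expect_equal(composite_lr(p2, dB, bg, hpo), 0.1, tolerance = 1e-12)
  p2r <- patient_profile(c("HP:0000003", "HP:0000002"))
  expect_equal(composite_lr(p2r, dB, bg, hpo),
               composite_lr(p2, dB, bg, hpo))
  # empty excluded set changes nothing; log accumulation matches the naive
  # product of the per-term breakdown to 1e-9 relative
  bd <- lr_breakdown(p2, dB, bg, hpo)
  expect_equal(composite_lr(p2, dB, bg, hpo), prod(bd$lr),
               tolerance = 1e-9)
  expect_error(composite_lr(patient_profile(character()), dB, bg, hpo),
               "no observed")
})

test_that("posttest probability follows Bayes' rule in odds form", {
  expect_equal(posttest_probability(0.5, 1), 0.5)
  expect_equal(posttest_probability(0, 12), 0)
  expect_equal(posttest_probability(1, 12), 1)
  expect_equal(posttest_probability(0.3, 1), 0.3)
  # direct evaluation of the formula at the uniform pretest of an
  # 8297-disease corpus and a composite LR of 1000
  expect_equal(posttest_probability(1.2053e-4, 1000), 0.1075767416,
               tolerance = 1e-9)
  expect_equal(posttest_probability(1 / 8297, 1000), 1000 / 9296,
               tolerance = 1e-12)
  expect_error(posttest_probability(1.2, 1), "outside")
  expect_error(posttest_probability(0.5, -1), "non-negative")
  # odds-form sweep (restricted to representable odds; near-saturated
  # posttest probabilities cannot express their odds in double precision)
  set.seed(42)
  for (i in 1:200) {
    p <- stats::runif(1, 1e-6, 1 - 1e-6)
    lr <- exp(stats::runif(1, -10, 10))
    post <- posttest_probability(p, lr)
    odds <- (p / (1 - p)) * lr
    expect_equal(post, odds / (1 + odds), tolerance = 1e-9)
    if (odds < 1e6) {
      expect_equal(post / (1 - post), odds, tolerance = 1e-9)
    }
  }
})

test_that("rank_diseases reproduces brute-force posttest values and order", {
  hpo <- toy_hpo()
  corpus <- toy_corpus()
  bg <- background_frequencies(corpus, hpo)
  # patient drawn exactly from disease B's annotations (D and E observed)
  pat <- patient_profile(c("HP:0000004", "HP:0000005"), subject_id = "t")
  res <- rank_diseases(pat, corpus, uniform_pretest(names(corpus)), bg, hpo)
  # brute force: bg counts give A=1, B=2/3, C=1/3, D=1/3, E=1/3;
  # LR(B) = (1/(1/3)) * (0.9/(1/3)) = 8.1
  # LR(A) = (1*0.5/(1/3))^2 = 2.25   (both terms match annotated ancestor B)
  # LR(C) = 0.01^2 = 1e-4            (no related annotation)
  # uniform p = 1/3 so posttest = LR/(2+LR)
  expect_equal(res$disease_id,
               c("OMIM:100002", "OMIM:100001", "OMIM:100003"))
  expect_equal(res$rank, 1:3)
  expect_equal(res$posttest,
               c(8.1 / 10.1, 2.25 / 4.25, 1e-4 / (2 + 1e-4)),
               tolerance = 1e-9)
  expect_equal(res$composite_lr, c(8.1, 2.25, 1e-4), tolerance = 1e-9)
})

test_that("posttest ties are broken deterministically by disease id", {
  hpo <- toy_hpo()
  corpus <- list(
    "OMIM:100010" = disease_model("OMIM:100010", c("HP:0000004" = 1.0)),
    "OMIM:100009" = disease_model("OMIM:100009", c("HP:0000004" = 1.0)),
    "OMIM:100011" = disease_model("OMIM:100011", c("HP:0000003" = 1.0)))
  bg <- background_frequencies(corpus, hpo)
  pat <- patient_profile("HP:0000004")
  res <- rank_diseases(pat, corpus, uniform_pretest(names(corpus)), bg, hpo)
  expect_equal(res$disease_id[1:2], c("OMIM:100009", "OMIM:100010"))
  # competition ranking: the tied pair shares rank 1, third disease rank 3
  expect_equal(competition_rank(res, "OMIM:100009"), 1L)
  expect_equal(competition_rank(res, "OMIM:100010"), 1L)
  expect_equal(competition_rank(res, "OMIM:100011"), 3L)
})

test_that("boosting a group containing the true disease never worsens its rank", {
  hpo <- toy_hpo()
  corpus <- toy_corpus()
  bg <- background_frequencies(corpus, hpo)
  pat <- patient_profile(c("HP:0000004", "HP:0000005"))
  ids <- names(corpus)
  r0 <- rank_diseases(pat, corpus, uniform_pretest(ids), bg, hpo)
  r5 <- rank_diseases(pat, corpus,
                      adjust_pretest(ids, "OMIM:100002", 5), bg, hpo)
  expect_lte(competition_rank(r5, "OMIM:100002"),
             competition_rank(r0, "OMIM:100002"))
  expect_error(
    rank_diseases(pat, corpus, uniform_pretest(ids[1:2]), bg, hpo),
    "does not cover")
})
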