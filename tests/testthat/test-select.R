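test_that("pooled t-statistic matches the textbook formula and handles degeneracy", {
  expect_equal(t_statistic(c(1, 1), c(0, 0)), Inf)
  expect_equal(t_statistic(c(0, 0), c(1, 1)), -Inf)
  expect_equal(t_statistic(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6)), 0)
  set.seed(3)
  for (rep in 1:25) {
    a <- runif(sample(2:6, 1)); b <- runif(sample(2:6, 1))
    expect_equal(t_statistic(a, b), oracle_t(a, b), tolerance = 1e-12)
  }
  # the worked case: oracle recomputation by an independent implementation
  a <- c(0.8, 0.6, 0.7, 0.9); b <- c(0.3, 0.2, 0.4)
  expect_equal(t_statistic(a, b), oracle_t(a, b))
})

test_that("exhaustive permutation p equals brute-force enumeration", {
  set.seed(21)
  for (sizes in list(c(2, 2), c(3, 3))) {
    labels <- rep(c("A", "B"), sizes)
    for (rep in 1:25) {
      x <- round(runif(sum(sizes)), 2)
      p <- permutation_pvalue(x, labels, n_perm = 10000)
      expect_true(attr(p, "exhaustive"))
      expect_equal(attr(p, "n_perm_used"), choose(sum(sizes), sizes[1]))
      expect_equal(as.numeric(p), oracle_perm_p(x, labels == "A"))
    }
  }
})

test_that("degenerate features follow the strict-inequality rule", {
  labels <- rep(c("A", "B"), each = 3)
  # constant feature: all null t equal the observed 0 -> p = 0, flagged
  res <- permutation_test(
    pspnet:::as_signature(paste0("p", 1:6), labels,
                          matrix(0.4, 6, 1, dimnames = list(NULL, "F1"))),
    n_perm = 100)
  expect_equal(res$p_perm, 0)
  expect_true(res$constant)
  # infinite observed t that no permutation reaches -> p = 0
  x <- c(1, 1, 1, 0, 0, 0)
  p <- permutation_pvalue(x, labels, n_perm = 1000)
  expect_equal(as.numeric(p), 0)
})

test_that("matrix-level test equals the per-feature op in exhaustive mode", {
  set.seed(31)
  vals <- matrix(runif(6 * 8), 6, 8,
                 dimnames = list(NULL, sprintf("F%d", 1:8)))
  sig <- pspnet:::as_signature(paste0("p", 1:6), rep(c("A", "B"), each = 3), vals)
  for (alt in c("signed", "two.sided")) for (tie in c("strict", "midp")) {
    res <- permutation_test(sig, n_perm = 1000, alternative = alt, ties = tie)
    per_feat <- vapply(sprintf("F%d", 1:8), function(f)
      as.numeric(permutation_pvalue(sig[[f]], sig$class, n_perm = 1000,
                                    alternative = alt, ties = tie)),
      numeric(1))
    expect_equal(res$p_perm, unname(per_feat))
  }
})

test_that("BH adjustment is the standard step-up with monotonicity", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.07), 0.07)
})

test_that("ranking score reproduces the worked examples exactly", {
  # four patients report A with ratios (1.1, 0.8, 1, 1.2); one reports B at 5
  prof1 <- make_profiles(
    detected = list(m1 = "A", m2 = "A", m3 = "A", m4 = c("A", "B")),
    classes = stats::setNames(rep("mod", 4), paste0("m", 1:4)),
    ratios = list(m1 = c(A = 1.1), m2 = c(A = 0.8), m3 = c(A = 1),
                  m4 = c(A = 1.2, B = 5)))
  r1 <- rank_score(prof1, c("A", "B", "C", "D"))
  expect_equal(r1$s_raw, sum(0.1, 1 / 0.8 - 1, 0, 0.2) + 4)
  expect_equal(r1$s_raw, 4.55)

  # two patients report A (1.1, 1.2), one reports B (5): denominator is the
  # number of unique reported proteins (2), not the feature size (4)
  prof2 <- make_profiles(
    detected = list(m1 = "A", m2 = c("A", "B")),
    classes = stats::setNames(rep("mod", 2), paste0("m", 1:2)),
    ratios = list(m1 = c(A = 1.1), m2 = c(A = 1.2, B = 5)))
  r2 <- rank_score(prof2, c("A", "B", "C", "D"))
  expect_equal(r2$score, (0.1 + 0.2 + 4) / 2)
  expect_equal(r2$score, 2.15)
  expect_equal(r2$n_reported, 2L)

  # nothing reported -> zero
  prof3 <- make_profiles(list(m1 = "Z"), c(m1 = "mod"),
                         ratios = list(m1 = c(Z = 2)))
  expect_equal(rank_score(prof3, c("A", "B", "C", "D"))$score, 0)
})

test_that("ranking score invariances: patient order, ratio symmetry, additivity", {
  prof <- make_profiles(
    detected = list(a = c("A", "B"), b = c("A", "C")),
    classes = c(a = "m", b = "m"),
    ratios = list(a = c(A = 2, B = 0.5), b = c(A = 1.25, C = 3)))
  expect_equal(rank_score(prof, LETTERS[1:4]), rank_score(prof[2:1, ], LETTERS[1:4]))

  # a ratio r and 1/r contribute identically
  prof_r <- make_profiles(list(a = "A"), c(a = "m"), ratios = list(a = c(A = 2)))
  prof_ir <- make_profiles(list(a = "A"), c(a = "m"), ratios = list(a = c(A = 0.5)))
  expect_equal(rank_score(prof_r, "A"), rank_score(prof_ir, "A"))

  # s_raw is additive over disjoint report sets
  s_ab <- rank_score(prof, c("A", "B", "C"))$s_raw
  s_a <- rank_score(prof, "A")$s_raw
  s_b <- rank_score(prof, "B")$s_raw
  s_c <- rank_score(prof, "C")$s_raw
  expect_equal(s_ab, s_a + s_b + s_c)

  expect_error(rank_score(dplyr::mutate(prof, class = c("m", "p")), "A"),
               "single class")
})

test_that("select_features attaches per-class scores and a significance call", {
  sim <- simulate_preset(seed = 17, n_complexes = 30, n_signal_complexes = 5)
  sig <- suppressWarnings(build_signature(sim$profiles, sim$complexes))
  st <- select_features(sig, features = sim$complexes, profiles = sim$profiles,
                        n_perm = 500, seed = 2)
  expect_true(all(c("score_mod", "score_poor", "significant") %in% names(st)))
  expect_true(all(st$score_mod >= 0 & st$score_poor >= 0, na.rm = TRUE))
  expect_true(all(st$p_perm >= 0 & st$p_perm <= 1))
  expect_true(all(st$q_bh >= 0 & st$q_bh <= 1))
  # planted signal features separate the classes strongly
  expect_true(all(st$significant[st$feature_id %in% sim$signal_ids]))
})
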