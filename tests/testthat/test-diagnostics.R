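test_that("pairwise similarity matches hand-evaluated dot products", {
  # three identical one-hot learners: S = 1 on every sample
  onehots <- cube_from_matrices(lapply(1:3, function(i) {
    matrix(c(1, 0, 0, 1), 2, 2)
  }))
  s <- pairwise_similarity(onehots)
  expect_equal(s$similarity_mean, 1)
  expect_equal(s$similarity_se, 0)

  # c0 = c1 = e1, c2 = e2: S = (1 + 0 + 0) / 3
  split <- cube_from_rows(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(pairwise_similarity(split)$similarity_mean, 1 / 3)

  # three uniform vectors over K = 4: each dot product is 1/K
  unif <- cube_from_rows(rep(0.25, 4), rep(0.25, 4), rep(0.25, 4))
  expect_equal(pairwise_similarity(unif)$similarity_mean, 0.25)

  expect_error(pairwise_similarity(cube_from_rows(c(0.5, 0.5))), "two learners")
})

test_that("similarity agrees with the naive pairwise loop and stays in [0, 1]", {
  set.seed(13)
  for (rep in 1:15) {
    cube <- random_cube(sample(2:4, 1), sample(2:50, 1), sample(2:4, 1))
    per <- attr(pairwise_similarity(cube), "per_sample")
    expect_equal(per, oracle_similarity(cube), tolerance = 1e-12)
    expect_true(all(per >= 0 & per <= 1))
  }
})

test_that("similarity is 1 exactly when all learners emit the same one-hot vector", {
  same <- cube_from_rows(c(0, 1, 0), c(0, 1, 0), c(0, 1, 0))
  expect_equal(pairwise_similarity(same)$similarity_mean, 1)
  # identical but not one-hot stays strictly below 1
  soft <- cube_from_rows(c(0.6, 0.4), c(0.6, 0.4))
  expect_lt(pairwise_similarity(soft)$similarity_mean, 1)
})

test_that("similarity is invariant under learner and class permutations", {
  set.seed(17)
  cube <- random_cube(3, 20, 4)
  arr <- unclass(cube)
  s0 <- pairwise_similarity(cube)$similarity_mean
  expect_equal(pairwise_similarity(confidence_cube(arr[c(3, 1, 2), , ]))$similarity_mean, s0)
  expect_equal(pairwise_similarity(confidence_cube(arr[, , c(4, 2, 1, 3)]))$similarity_mean, s0)
})

test_that("agreement patterns histogram the number of wrong learners", {
  perfect <- cube_from_matrices(lapply(1:3, function(i) {
    matrix(rep(c(0.8, 0.2), each = 5), 5, 2)
  }))
  pat <- agreement_patterns(perfect, rep(1, 5))
  expect_equal(pat$pattern, c("RRR", "RRW", "RWW", "WWW"))
  expect_equal(pat$count, c(5, 0, 0, 0))

  # constructed toy with per-sample wrong counts 0, 1, 2, 3
  hi <- c(0.9, 0.1); lo <- c(0.1, 0.9)
  toy <- cube_from_matrices(
    matrix(c(hi, hi, hi, lo), 4, 2, byrow = TRUE),
    matrix(c(hi, hi, lo, lo), 4, 2, byrow = TRUE),
    matrix(c(hi, lo, lo, lo), 4, 2, byrow = TRUE)
  )
  truth <- rep(1, 4)
  pat <- agreement_patterns(toy, truth)
  expect_equal(pat$count, c(1, 1, 1, 1))
  expect_equal(oracle_wrong_counts(toy, truth), 0:3)
})

test_that("pattern counts partition the sample set and match the enumeration oracle", {
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(2:4, 1)
    N <- sample(5:50, 1)
    K <- sample(2:4, 1)
    cube <- random_cube(n, N, K)
    truth <- sample.int(K, N, replace = TRUE)
    pat <- agreement_patterns(cube, truth)
    expect_equal(sum(pat$count), N)
    expect_equal(pat$count, tabulate(oracle_wrong_counts(cube, truth) + 1L, n + 1L))
  }
})

test_that("pattern labels follow the learner count (RR/RW/WW for two learners)", {
  cube <- random_cube(2, 3, 2)
  expect_equal(agreement_patterns(cube, c(1, 1, 2))$pattern, c("RR", "RW", "WW"))
})

test_that("conditional patterns keep only ensemble-correct samples and never exceed unconditional counts", {
  # a sample where all learners are wrong stays out of the conditional histogram
  wrong <- cube_from_rows(c(0.1, 0.9), c(0.2, 0.8), c(0.3, 0.7))
  cond <- conditional_patterns(wrong, 1, "arithmetic")
  expect_equal(sum(cond$count), 0)
  expect_equal(cond$n_conditioned[1], 0)

  # perfect learners: conditional equals unconditional
  perfect <- cube_from_matrices(lapply(1:3, function(i) matrix(rep(c(0.9, 0.1), each = 4), 4, 2)))
  expect_equal(
    conditional_patterns(perfect, rep(1, 4), "geometric")$count,
    agreement_patterns(perfect, rep(1, 4))$count
  )

  set.seed(29)
  for (rep in 1:10) {
    cube <- random_cube(3, 40, 3)
    truth <- sample.int(3, 40, replace = TRUE)
    un <- agreement_patterns(cube, truth)
    for (rule in c("arithmetic", "geometric")) {
      cond <- conditional_patterns(cube, truth, rule)
      expect_true(all(cond$count <= un$count))
    }
  }
})

test_that("an ensemble-rescued RWW sample is counted in the conditional RWW bin", {
  cube <- cube_from_rows(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3), c(0.25, 0.2, 0.55))
  truth <- 1
  # arithmetic combined: (0.35, 0.3333, 0.3167) -> prediction 1, correct
  res <- arithmetic_ensemble(cube)
  expect_equal(res$combined[1, ], c(0.35, 1 / 3, 0.95 / 3), ignore_attr = TRUE)
  expect_equal(res$prediction, 1)
  cond <- conditional_patterns(cube, truth, "arithmetic")
  expect_equal(cond$count[cond$pattern == "RWW"], 1)
})

test_that("identical learners concentrate pattern mass on all-right/all-wrong, and conditional all-wrong is empty", {
  cohort <- generate_cohort(generator_config(n_samples = 400, rho = 1, seed = 19))
  truth <- cohort$labels$true_class
  pat <- agreement_patterns(cohort$cube, truth)
  expect_equal(pat$count[pat$n_wrong %in% c(1, 2)], c(0, 0))
  for (rule in c("arithmetic", "geometric")) {
    cond <- conditional_patterns(cohort$cube, truth, rule)
    expect_equal(cond$count[cond$pattern == "WWW"], 0)
  }
})

test_that("top-1 profile summarizes peakedness per learner", {
  onehot <- matrix(rep(c(1, 0, 0, 0, 0), each = 4), 4, 5)
  unif <- matrix(0.2, 4, 5)
  expect_equal(top1_profile(cube_from_matrices(onehot))$top1_mean, 1)
  expect_equal(top1_profile(cube_from_matrices(unif))$top1_mean, 0.2)
  mixed <- cube_from_matrices(rbind(onehot, unif))
  expect_equal(top1_profile(mixed)$top1_mean, 0.6)
})

test_that("compare_reports tabulates counts, ratios and similarity side by side", {
  cube <- random_cube(3, 10, 3)
  truth <- sample.int(3, 10, replace = TRUE)
  rep_a <- agreement_report(cube, truth)
  cmp_same <- compare_reports(rep_a, rep_a)
  expect_true(all(cmp_same$ratio[!is.na(cmp_same$ratio)] == 1))

  # printed-count fixture: conditional RWW 8 vs 16 gives ratio 2.0
  rep_b <- rep_a
  rep_a$patterns$count <- c(2523L, 100L, 8L, 0L)
  rep_b$patterns$count <- c(2515L, 120L, 16L, 0L)
  cmp <- compare_reports(rep_a, rep_b)
  expect_equal(cmp$ratio[cmp$pattern == "RWW"], 2.0)
  # zero denominator yields NA, not an error
  expect_true(is.na(cmp$ratio[cmp$pattern == "WWW"]))

  rep2 <- agreement_report(random_cube(2, 5, 3), rep(1, 5))
  expect_error(compare_reports(rep_a, rep2), "different numbers of learners")
})

test_that("agreement_report bundles the diagnostics with tidy/glance access", {
  set.seed(3)
  cube <- random_cube(3, 25, 4)
  truth <- sample.int(4, 25, replace = TRUE)
  rep <- agreement_report(cube, truth)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(sum(tidy(rep)$count), 25)
  gl <- glance(rep)
  expect_equal(gl$n_samples, 25)
  expect_equal(gl$similarity_mean, pairwise_similarity(cube)$similarity_mean)
})
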