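test_that("generator_config validates its fields and names the offender", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(rho = 1.2), "rho")
  expect_error(generator_config(rho = -0.1), "rho")
  expect_error(generator_config(temperature = 0), "temperature")
  expect_error(generator_config(signal = -1), "signal")
  expect_error(generator_config(n_classes = 1), "n_classes")
  expect_error(generator_config(class_probs = c(0.5, 0.6)), "class_probs")
  cfg <- generator_config(n_classes = 3, class_probs = c(0.5, 0.3, 0.2))
  expect_equal(cfg$class_probs, c(0.5, 0.3, 0.2))
})

test_that("the same seed reproduces a bit-identical cohort", {
  cfg <- generator_config(n_samples = 200, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(unclass(a$cube), unclass(b$cube))
  expect_identical(a$labels, b$labels)
  c2 <- generate_cohort(generator_config(n_samples = 200, seed = 124))
  expect_false(identical(unclass(a$cube), unclass(c2$cube)))
})

test_that("adding learners does not perturb the labels or earlier learners", {
  small <- generate_cohort(generator_config(n_learners = 3, n_samples = 150, seed = 77))
  big <- generate_cohort(generator_config(n_learners = 5, n_samples = 150, seed = 77))
  expect_identical(small$labels, big$labels)
  expect_equal(unclass(big$cube)[1:3, , ], unclass(small$cube), ignore_attr = TRUE)
})

test_that("generated cubes always sit on the probability simplex", {
  set.seed(1)
  for (rep in 1:8) {
    cfg <- generator_config(
      n_learners = sample(1:4, 1), n_samples = 50,
      n_classes = sample(2:8, 1), signal = runif(1, 0, 4),
      rho = runif(1), temperature = runif(1, 0.2, 5),
      seed = sample.int(1000, 1)
    )
    cohort <- generate_cohort(cfg)
    sums <- apply(unclass(cohort$cube), c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("fully correlated learners are identical and concentrate pattern mass at the extremes", {
  cohort <- generate_cohort(generator_config(rho = 1, n_samples = 300, seed = 9))
  arr <- unclass(cohort$cube)
  expect_equal(arr[1, , ], arr[2, , ], tolerance = 1e-12)
  expect_equal(arr[1, , ], arr[3, , ], tolerance = 1e-12)
  pat <- agreement_patterns(cohort$cube, cohort$labels$true_class)
  expect_equal(sum(pat$count[pat$n_wrong %in% c(1, 2)]), 0)
})

test_that("zero signal gives chance-level single-learner accuracy", {
  cohort <- generate_cohort(generator_config(
    n_samples = 5000, n_classes = 5, signal = 0, seed = 101
  ))
  acc <- mean(learner_predictions(cohort$cube) == cohort$labels$true_class)
  se <- sqrt(0.2 * 0.8 / (3 * 5000))
  expect_lt(abs(acc - 0.2), 3 * se)
})

test_that("class_probs controls the label distribution", {
  cohort <- generate_cohort(generator_config(
    n_samples = 4000, n_classes = 3, class_probs = c(0.7, 0.2, 0.1), seed = 55
  ))
  freq <- tabulate(cohort$labels$true_class, 3) / 4000
  expect_equal(freq, c(0.7, 0.2, 0.1), tolerance = 0.05)
})

test_that("signal calibration hits the target single-learner accuracy", {
  cfg <- generator_config(rho = 0.4, seed = 42)
  cal <- calibrate_signal(0.8, cfg, n_pilot = 2000)
  expect_lt(abs(cal$accuracy - 0.8), 0.01)
  expect_error(calibrate_signal(0.1, cfg), "chance") # 1/K = 0.1 is not above chance
  expect_error(calibrate_signal(1.0, cfg), "chance")
})

test_that("pilot accuracy is nondecreasing along a signal grid", {
  accs <- vapply(seq(0, 4, by = 0.5), function(mu) {
    cohort <- generate_cohort(generator_config(
      n_samples = 1000, signal = mu, rho = 0.3, seed = 7
    ))
    mean(learner_predictions(cohort$cube) == cohort$labels$true_class)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("empirical similarity rises with the correlation knob and top-1 falls with temperature", {
  # With no class signal the correlation knob is the only source of
  # inter-learner alignment, so S must be monotone along the whole grid.
  # With signal > 0 the true-class boost (sqrt(rho) + sqrt(1 - rho)) * mu also
  # moves peakedness, so fixed-mu monotonicity is only guaranteed while the
  # boost is non-decreasing (rho <= 1/2); the matched-accuracy sweep covers
  # the full range.
  rho_grid <- seq(0, 1, by = 0.25)
  for (seed in 1:3) {
    sims0 <- vapply(rho_grid, function(r) {
      cohort <- generate_cohort(generator_config(
        n_samples = 800, rho = r, signal = 0, seed = seed
      ))
      pairwise_similarity(cohort$cube)$similarity_mean
    }, numeric(1))
    expect_equal(cor(rho_grid, sims0, method = "spearman"), 1)

    sims <- vapply(c(0, 0.25, 0.5), function(r) {
      cohort <- generate_cohort(generator_config(n_samples = 800, rho = r, seed = seed))
      pairwise_similarity(cohort$cube)$similarity_mean
    }, numeric(1))
    expect_true(all(diff(sims) > 0))

    tops <- vapply(c(0.5, 1, 2, 4, 8), function(tt) {
      cohort <- generate_cohort(generator_config(
        n_samples = 800, temperature = tt, seed = seed
      ))
      mean(top1_profile(cohort$cube)$top1_mean)
    }, numeric(1))
    expect_true(all(diff(tops) < 0))
  }
})

test_that("ensembling identical learners yields no gain", {
  cohort <- generate_cohort(generator_config(rho = 1, n_samples = 5000, seed = 31))
  truth <- cohort$labels$true_class
  single <- mean(learner_predictions(cohort$cube) == truth)
  for (rule in c("arithmetic", "geometric")) {
    acc <- mean(ensemble_predict(cohort$cube, rule)$prediction == truth)
    expect_lt(abs(acc - single), 1e-3)
  }
})

test_that("uncorrelated learners make conditionally independent errors", {
  rejections <- 0L
  for (seed in 1:10) {
    cohort <- generate_cohort(generator_config(
      n_samples = 5000, rho = 0, signal = 1.5, seed = seed
    ))
    preds <- learner_predictions(cohort$cube)
    ok1 <- preds[, 1] == cohort$labels$true_class
    ok2 <- preds[, 2] == cohort$labels$true_class
    p <- suppressWarnings(stats::chisq.test(table(ok1, ok2))$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})
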