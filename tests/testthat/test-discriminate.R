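test_that("coefficient of variation uses the population convention", {
  expect_equal(coefficient_of_variation(matrix(2, 3, 3)), 0)
  v <- matrix(c(1, 1, 3, 3), 2)
  expect_equal(coefficient_of_variation(v), 0.5)   # population sd 1, mean 2
  expect_equal(coefficient_of_variation(7 * v), coefficient_of_variation(v))
  expect_gt(coefficient_of_variation(v, population = FALSE), 0.5)
  expect_error(coefficient_of_variation(v, matrix(FALSE, 2, 2)), "mask")
})

test_that("mean ratio matches the bruised/sound coefficient ratio", {
  m <- matrix(1.726, 10, 10)
  bruise <- matrix(FALSE, 10, 10); bruise[4:6, 4:6] <- TRUE
  sound <- !bruise
  expect_equal(mean_ratio(m, bruise, sound), 1)
  m[bruise] <- 1.215
  expect_equal(mean_ratio(m, bruise, sound), 1.215 / 1.726)
  expect_equal(round(mean_ratio(m, bruise, sound), 3), 0.704)
  expect_error(mean_ratio(m, bruise, bruise), "disjoint")
  # monotone in severity on rendered fruit scenes
  ratios <- vapply(c(0.25, 0.5, 0.75, 1), function(s) {
    sc <- make_fruit_map(fruit_scene_spec("apple", size = 32, severity = s))
    mean_ratio(sc$map$mu_s_prime, sc$bruise_mask, sc$sound_mask)
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("ROC sweep equals brute-force pair counting", {
  # perfect separation
  r <- roc_curve(c(0.5, 0.6, 0.8, 0.9), c(TRUE, TRUE, FALSE, FALSE),
                 orientation = "lower")
  expect_equal(r$auc, 1)
  # identical distributions: chance
  r2 <- roc_curve(c(1, 2, 3, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                         FALSE), orientation = "lower")
  expect_equal(r2$auc, 0.5)
  # random fixtures incl. ties: AUC == concordance with ties at 1/2
  set.seed(55)
  for (trial in 1:20) {
    n <- sample(6:50, 1)
    scores <- round(runif(n), sample(1:3, 1))   # rounding induces ties
    labels <- runif(n) > 0.5
    if (!any(labels) || all(labels)) next
    r3 <- roc_curve(scores, labels, orientation = "higher")
    pos <- scores[labels]; neg <- scores[!labels]
    oracle <- mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
    expect_equal(r3$auc, oracle, tolerance = 1e-12)
  }
  expect_error(roc_curve(1:4, c(TRUE, TRUE, TRUE, TRUE)), "classes")
})

test_that("Youden selection reproduces printed operating points", {
  expect_equal(youden_index(96, 92), 0.88)
  expect_equal(youden_index(100, 92), 0.92)
  expect_equal(youden_index(1, 1), 1)
  # optimum equals sensitivity + specificity - 1 recomputed from counts
  set.seed(77)
  scores <- c(rnorm(25, 0.68, 0.04), rnorm(25, 0.80, 0.04))
  labels <- rep(c(TRUE, FALSE), each = 25)    # TRUE = severe, lower scores
  roc <- roc_curve(scores, labels, orientation = "lower")
  opt <- youden_optimal_threshold(roc)
  called_severe <- scores < opt$threshold
  sens <- sum(called_severe & labels) / sum(labels)
  spec <- sum(!called_severe & !labels) / sum(!labels)
  expect_equal(opt$youden, sens + spec - 1, tolerance = 1e-12)
  expect_equal(opt$sensitivity, sens)
  expect_equal(opt$specificity, spec)
})

test_that("boundary conventions are strict as stated", {
  expect_equal(classify_bruised(0.117, 0.117), "non-bruised")
  expect_equal(classify_bruised(0.117 + 1e-9, 0.117), "bruised")
  # the 0.117 rule separates synthetic scores spanning it
  cvs <- c(0.09, 0.10, 0.13, 0.15)
  expect_equal(classify_bruised(cvs, 0.117),
               c("non-bruised", "non-bruised", "bruised", "bruised"))
  expect_equal(classify_severity(0.7430, 0.7430), "mild")
  expect_equal(classify_severity(0.70, 0.7430), "severe")
  expect_equal(classify_severity(0.80, 0.7430), "mild")
})

test_that("misclassification arithmetic follows the faults/total convention", {
  tab <- misclassification_rates(c(mild = 1, severe = 2),
                                 c(mild = 25, severe = 25))
  expect_equal(tab$rate, c(0.04, 0.08, 0.06))
  expect_equal(tab$n[3], 50)
  expect_equal(sum(tab$faults[1:2]), tab$faults[3])
})

test_that("the two-step pipeline grades a well-separated cohort", {
  set.seed(97)
  mk_sample <- function(bruised, severity) {
    spec <- fruit_scene_spec("apple", size = 32,
                             bruise_radius_mm = if (bruised) 15 else 0,
                             severity = severity)
    sc <- make_fruit_map(spec)
    mus <- sc$map$mu_s_prime * matrix(exp(rnorm(1024, sd = 0.01)), 32)
    geom <- make_fruit_map(fruit_scene_spec("apple", size = 32,
                                            severity = 0))
    list(mu_s_prime = mus, bruise_mask = geom$bruise_mask,
         sound_mask = geom$sound_mask, valid = NULL,
         truth_bruised = bruised,
         truth_severity = if (!bruised) NA_character_
           else if (severity >= 0.75) "severe" else "mild")
  }
  cohort <- c(lapply(1:8, function(i) mk_sample(FALSE, 0)),
              lapply(1:4, function(i) mk_sample(TRUE, 0.5)),
              lapply(1:4, function(i) mk_sample(TRUE, 1)))
  res <- two_step_pipeline(cohort)
  expect_equal(res$step1_accuracy, 1)
  expect_equal(sum(res$scores$call == "bruised"), 8)
  expect_equal(res$misclassification$faults[3], 0)
  # counts sum to inputs
  expect_equal(nrow(res$scores), 16)
  expect_equal(sum(res$misclassification$n[1:2]), 8)
})
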