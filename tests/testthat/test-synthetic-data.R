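test_that("two-duration counterbalanced schedule has the published shape", {
  d <- design_spec(sprintf("c%02d", 1:10), 60, c("ms50", "ms200"),
                   n_blocks = 8, counterbalance = TRUE, seed = 5)
  s <- make_counterbalanced_design(d)
  expect_equal(nrow(s), 1200)                       # total trials
  expect_equal(as.integer(table(s$block)), rep(150L, 8))  # per-block trials
  # every image exactly once per duration
  expect_equal(anyDuplicated(paste(s$stimulus_id, s$presentation)), 0L)
  # category-duration binding holds within each half and is reversed
  h1 <- unique(s[s$block <= 4, c("true_category", "presentation")])
  h2 <- unique(s[s$block > 4, c("true_category", "presentation")])
  expect_equal(nrow(h1), 10)
  expect_equal(nrow(h2), 10)
  m1 <- setNames(h1$presentation, h1$true_category)
  m2 <- setNames(h2$presentation, h2$true_category)
  expect_true(all(m1[names(m2)] != m2))
})

test_that("single-duration schedule covers each stimulus once in even blocks", {
  d <- design_spec(n_blocks = 6, seed = 3)  # 9 categories x 30 images
  s <- make_counterbalanced_design(d)
  expect_equal(nrow(s), 270)
  expect_equal(as.integer(table(s$block)), rep(45L, 6))
  expect_equal(anyDuplicated(s$stimulus_id), 0L)
})

test_that("schedules are permutations for fuzzed specs", {
  set.seed(42)
  for (rep in 1:15) {
    k <- sample(c(4, 6, 8, 10), 1)
    n_img <- sample(5:40, 1)
    cb <- sample(c(TRUE, FALSE), 1)
    n_blocks <- if (cb) 2 * sample(1:4, 1) else sample(1:7, 1)
    pres <- if (cb) c("ms50", "ms200") else
      sample(c("ms50", "ms200", "self_paced"), sample(1:2, 1))
    d <- design_spec(sprintf("k%02d", 1:k), n_img, pres,
                     n_blocks = n_blocks, counterbalance = cb,
                     seed = rep)
    s <- make_counterbalanced_design(d)
    expect_equal(nrow(s), k * n_img * length(pres))
    expect_equal(anyDuplicated(paste(s$stimulus_id, s$presentation)), 0L)
    expect_lte(diff(range(table(s$block))), 1)
    expect_equal(s$trial_index, seq_len(nrow(s)))
  }
})

test_that("counterbalancing preconditions are enforced", {
  expect_error(design_spec(sprintf("c%d", 1:9), 30, c("ms50", "ms200"),
                           n_blocks = 8, counterbalance = TRUE),
               "even number of categories")
  expect_error(design_spec(sprintf("c%d", 1:10), 30, c("ms50", "ms200"),
                           n_blocks = 7, counterbalance = TRUE),
               "even number of blocks")
  expect_error(design_spec(sprintf("c%d", 1:10), 30, "ms50",
                           n_blocks = 8, counterbalance = TRUE),
               "two presentation conditions")
})

test_that("a perfect-accuracy cohort answers every trial correctly", {
  spec <- cohort_spec(n_participants = 3, n_images_per_category = 5,
                      subgroups = list(list(weight = 1,
                                            accuracy_profile = 1.0)),
                      seed = 8)
  co <- generate_cohort(spec)
  expect_true(all(co$response_category == co$true_category))
  expect_equal(sort(unique(co$session)), c("retest", "test"))
  expect_equal(nrow(co), 3 * 2 * 9 * 5)
})

test_that("cohort generation is a pure function of spec and seed", {
  spec <- cohort_spec(n_participants = 6, n_images_per_category = 4,
                      seed = 123)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  other <- generate_cohort(cohort_spec(n_participants = 6,
                                       n_images_per_category = 4,
                                       seed = 124))
  expect_false(identical(generate_cohort(spec)$response_category,
                         other$response_category))
})

test_that("empirical accuracy converges to the planted profile", {
  spec <- cohort_spec(n_participants = 200, n_images_per_category = 30,
                      subgroups = list(list(weight = 1,
                                            accuracy_profile = 0.8)),
                      session_stability = 1, seed = 31)
  co <- generate_cohort(spec, sessions = "test")
  acc <- compute_accuracy(co)
  per_cat <- tapply(acc$proportion, acc$category, mean)
  tol <- 3 * sqrt(0.8 * 0.2 / (30 * 200))
  expect_true(all(abs(per_cat - 0.8) < tol))
})

test_that("model raters are deterministic and hit their planted accuracy", {
  d <- design_spec(seed = 2)
  perfect <- generate_model_rater("m", 1.0, d, seed = 4)
  expect_true(all(perfect$response_category == perfect$true_category))
  expect_equal(unique(perfect$rater_kind), "model")
  expect_equal(unique(perfect$session), "test")
  expect_equal(nrow(perfect), 270)

  expect_identical(generate_model_rater("m", 0.7, d, seed = 4),
                   generate_model_rater("m", 0.7, d, seed = 4))

  coin <- generate_model_rater("coin", 0.5, d, seed = 10)
  acc <- mean(coin$response_category == coin$true_category)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 270))
})

test_that("structured confusion kernels shape the error distribution", {
  cats <- fixture_categories
  kernel <- matrix(0, 3, 4, dimnames = list(cats, c(cats, "UNKNOWN")))
  kernel["Mug", c("TV", "Helmet", "UNKNOWN")] <- c(0.7, 0.2, 0.1)
  kernel["TV", c("Mug", "Helmet")] <- c(0.5, 0.5)
  kernel["Helmet", c("Mug", "TV")] <- c(0.9, 0.1)
  d <- design_spec(cats, 400, n_blocks = 1, seed = 6)
  m <- generate_model_rater("m", 0.3, d, confusion_kernel = kernel,
                            seed = 9)
  wrong <- m[m$response_category != m$true_category &
               m$true_category == "Mug", ]
  freq <- table(factor(wrong$response_category,
                       levels = c("TV", "Helmet", "UNKNOWN"))) /
    nrow(wrong)
  expect_true(all(abs(freq - c(0.7, 0.2, 0.1)) < 0.09))
  expect_error(
    cohort_spec(categories = cats,
                subgroups = list(list(weight = 1, accuracy_profile = 0.5)),
                confusion_kernel = kernel[, 1:3]),
    "rows must sum to 1")
})

test_that("planted modal scenarios are well-formed", {
  spec <- plant_modal_scenario(50, modal_weight = 0.65,
                               n_variant_subgroups = 4, seed = 1)
  w <- vapply(spec$subgroups, `[[`, numeric(1), "weight")
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w[1], 0.65)
  flat <- spec$subgroups[[1]]$accuracy_profile
  expect_equal(unname(diff(range(flat))), 0)
  # variants differ from flat by more than twice the tolerance
  for (g in spec$subgroups[-1]) {
    gap <- max(abs(g$accuracy_profile - flat))
    expect_gt(gap, 2 * 0.1)
  }
  expect_error(plant_modal_scenario(50, modal_weight = 1.0),
               "strictly in")
  expect_error(plant_modal_scenario(50, modal_weight = 0),
               "strictly in")
})

test_that("retest stability controls whether profiles are redrawn", {
  spec <- cohort_spec(n_participants = 40, n_images_per_category = 3,
                      subgroups = list(list(weight = 1,
                                            accuracy_profile = 0.8)),
                      session_stability = 1, seed = 77)
  gt <- cohort_ground_truth(generate_cohort(spec))
  expect_true(all(gt$stable))
  expect_true(all(vapply(gt$profiles, function(p)
    identical(p$test, p$retest), logical(1))))

  spec0 <- cohort_spec(n_participants = 40, n_images_per_category = 3,
                       subgroups = list(list(weight = 1,
                                             accuracy_profile = 0.8)),
                       session_stability = 0, seed = 77)
  gt0 <- cohort_ground_truth(generate_cohort(spec0))
  expect_false(any(gt0$stable))
  expect_true(all(vapply(gt0$profiles, function(p)
    max(abs(p$test - p$retest)) > 0, logical(1))))
})
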