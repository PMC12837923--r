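test_that("discretisation reproduces hand-worked relations", {
  # all proportions equal: the all-equivalent pattern
  p <- discretise(setNames(rep(25, 9), default_categories()), rep(30, 9))
  expect_equal(p$signature, strrep("=", 36))

  # (30/30, 27/30, 15/30) at tau = 0.1: = then > then >
  p <- discretise(c(a = 30, b = 27, c = 15), c(30, 30, 30))
  expect_equal(p$cells, c("=", ">", ">"))
  expect_equal(p$signature, "=>>")

  # swapping two categories inverts their cell
  q <- discretise(c(c = 15, b = 27, a = 30), c(30, 30, 30))
  expect_equal(q$cells[1], "<")   # c vs b: inverse of the b-vs-c cell
  expect_equal(q$signature, "<<=")

  expect_error(discretise(c(a = 1, b = 0), c(10, 0)), "zero-trial")
})

test_that("signatures are canonical, injective and of length k(k-1)/2", {
  set.seed(91)
  for (k in c(2, 3, 5, 9)) {
    cats <- sprintf("c%d", 1:k)
    p <- discretise(setNames(runif(k), cats), criterion =
                      discretisation_criterion(tolerance = 0.05))
    expect_equal(nchar(p$signature), k * (k - 1) / 2)
  }
  # equality of patterns iff equality of signatures (structural oracle)
  cats <- sprintf("c%d", 1:4)
  for (rep in 1:200) {
    p1 <- discretise(setNames(runif(4), cats))
    p2 <- discretise(setNames(runif(4), cats))
    expect_equal(identical(p1$cells, p2$cells),
                 p1$signature == p2$signature)
  }
  rebuilt <- signature_to_pattern("=>>", c("a", "b", "c"))
  expect_equal(rebuilt$cells, c("=", ">", ">"))
})

test_that("discretisation invariants hold on fuzzed proportion vectors", {
  set.seed(97)
  crit <- discretisation_criterion(tolerance = 0.1)
  crit0 <- discretisation_criterion(tolerance = 0)
  inv <- c("<" = ">", ">" = "<", "=" = "=")
  for (rep in 1:1000) {
    k <- sample(2:9, 1)
    cats <- sprintf("c%d", 1:k)
    p <- setNames(round(runif(k), 3), cats)
    pat <- discretise(p, criterion = crit)
    # antisymmetry: reversing the category order inverts every cell
    rpat <- discretise(rev(p), criterion = crit)
    pairs <- catpattern:::pattern_pairs(k)
    rev_cells <- unname(inv[pat$cells])
    # cell (i,j) of the reversed order is pair (k+1-j, k+1-i)
    idx <- match(paste(k + 1 - pairs[, "col"], k + 1 - pairs[, "row"]),
                 paste(pairs[, "row"], pairs[, "col"]))
    expect_equal(rpat$cells[idx], rev_cells)
    # equal inputs are always equivalent
    i <- sample(k, 1)
    p2 <- p; p2[i] <- p[if (i == 1) k else 1]
    pat2 <- discretise(p2, criterion = crit)
    expect_true(all(pat2$cells[p2[pairs[, 1]] == p2[pairs[, 2]]] == "="))
    # tau = 0 is strict: equivalence iff exact equality
    pat0 <- discretise(p, criterion = crit0)
    expect_equal(pat0$cells == "=",
                 unname(p[pairs[, 1]] == p[pairs[, 2]]))
    # monotone coarsening: raising tau never removes an equivalence
    tau2 <- runif(1, 0.1, 1)
    patw <- discretise(p, criterion =
                         discretisation_criterion(tolerance = tau2))
    expect_true(all(patw$cells[pat$cells == "="] == "="))
  }
  # as tau -> 1 every pattern collapses to all-equivalent
  p <- setNames(c(0, 0.5, 1), c("a", "b", "c"))
  expect_equal(discretise(p, criterion =
                            discretisation_criterion(tolerance = 1))$signature,
               "===")
})

test_that("discretisation depends only on aggregated counts", {
  x <- c(a = 12, b = 20, c = 28)
  n <- c(30, 30, 30)
  direct <- discretise(x, n)
  expect_equal(discretise(x / 30), direct)
  expect_equal(discretise(rev(x), rev(n))$cells,
               c("<" = ">", ">" = "<", "=" = "=")[rev(direct$cells)],
               ignore_attr = TRUE)
})

test_that("confidence-interval overlap mode follows Wilson intervals", {
  crit <- discretisation_criterion("ci_overlap", ci_level = 0.95)
  # wide separation at large n: strict ordering
  p <- discretise(c(a = 290, b = 150), c(300, 300), criterion = crit)
  expect_equal(p$signature, ">")
  # close proportions: intervals overlap, equivalence
  p <- discretise(c(a = 25, b = 24), c(30, 30), criterion = crit)
  expect_equal(p$signature, "=")
  # matches a direct Wilson computation on random pairs
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(10:60, 2, replace = TRUE)
    x <- c(sample(0:n[1], 1), sample(0:n[2], 1))
    ci <- catpattern:::wilson_interval(x, n, 0.95)
    overlap <- ci[1, "low"] <= ci[2, "high"] && ci[2, "low"] <= ci[1, "high"]
    pat <- discretise(c(a = x[1], b = x[2]), n, criterion = crit)
    expect_equal(pat$cells == "=", overlap)
  }
  expect_error(discretise(c(a = 0.5, b = 0.4), criterion = crit),
               "trial counts")
})

test_that("pattern frequencies tally a known multiset and rank by count", {
  cats <- c("a", "b", "c")
  sigs <- c(rep("===", 4), rep("=>>", 3), rep("<<<", 3))
  pats <- lapply(sigs, signature_to_pattern, categories = cats)
  freq <- pattern_frequencies(pats)
  expect_equal(freq$count, c(4L, 3L, 3L))
  expect_equal(freq$signature, c("===", "<<<", "=>>"))  # tie: lexicographic
  expect_equal(sum(freq$count), 10)
  expect_equal(freq$proportion, freq$count / 10)

  single <- pattern_frequencies(pats[1])
  expect_equal(single$proportion, 1.0)

  mixed <- c(pats[1], list(signature_to_pattern("===", c("x", "y", "z"))))
  expect_error(pattern_frequencies(mixed), "alignment error")
})

test_that("modal patterns return all ties in lexicographic order", {
  cats <- c("a", "b", "c")
  pats <- lapply(c("===", "=>>", "===", "=>>"), signature_to_pattern,
                 categories = cats)
  m <- modal_pattern(pats)
  expect_equal(m$signatures, c("===", "=>>"))
  expect_equal(m$proportion, 0.5)
  m1 <- modal_pattern(pats[2])
  expect_equal(m1$signatures, "=>>")
  expect_equal(m1$proportion, 1.0)
})

test_that("session consistency counts identical signatures per participant", {
  cats <- c("a", "b", "c")
  mk <- function(sigs) setNames(lapply(sigs, signature_to_pattern,
                                       categories = cats),
                                sprintf("p%d", seq_along(sigs)))
  te <- mk(c("===", "=>>", "<<<", "===", "=>>"))
  re <- mk(c("===", "=>>", "===", "===", "<<<"))
  res <- session_consistency(te, re)
  expect_equal(res$proportion, 0.6)
  expect_equal(unname(res$indicator),
               c(TRUE, TRUE, FALSE, TRUE, FALSE))

  expect_equal(session_consistency(te, te)$proportion, 1.0)
  disjoint <- mk(c("<<<", "<<<", ">>>", "<<<", ">>>"))
  expect_equal(session_consistency(te, disjoint)$proportion, 0.0)

  res2 <- session_consistency(te[1:3], te)
  expect_setequal(res2$exclusions, c("p4", "p5"))
})

test_that("model patterns are matched to the modal human pattern", {
  cats <- default_categories()
  all_eq <- strrep("=", 36)
  humans <- lapply(c(rep(all_eq, 6), rep(paste0(strrep("=", 28),
                                                strrep(">", 8)), 4)),
                   signature_to_pattern, categories = cats)
  model <- signature_to_pattern(all_eq, cats)
  m <- match_model_to_human(model, humans)
  expect_true(m$exact_match_to_modal)
  expect_equal(m$cell_overlap_with_modal, 1.0)
  expect_equal(m$rank_of_model_signature_among_humans, 1L)

  # differing in exactly 9 of 36 cells: overlap 0.75
  off <- paste0(strrep("=", 27), strrep("<", 9))
  m2 <- match_model_to_human(signature_to_pattern(off, cats), humans)
  expect_false(m2$exact_match_to_modal)
  expect_equal(m2$cell_overlap_with_modal, 0.75)
  expect_true(is.na(m2$rank_of_model_signature_among_humans))

  wrong_order <- signature_to_pattern(all_eq, rev(cats))
  expect_error(match_model_to_human(wrong_order, humans),
               "alignment error")
})

test_that("per-rater patterns from an accuracy table use the shared order", {
  set.seed(23)
  spec <- cohort_spec(n_participants = 4, n_images_per_category = 30,
                      categories = fixture_categories,
                      subgroups = list(list(weight = 1,
                                            accuracy_profile = 0.8)),
                      seed = 5)
  co <- generate_cohort(spec, sessions = "test")
  acc <- compute_accuracy(co)
  pats <- patterns_from_accuracy(acc, categories = fixture_categories)
  expect_length(pats, 4)
  expect_true(all(vapply(pats, function(p)
    identical(p$categories, fixture_categories), logical(1))))
  # matches direct discretisation of the same counts
  sub <- acc[acc$rater_id == names(pats)[1], ]
  m <- match(fixture_categories, sub$category)
  direct <- discretise(setNames(sub$n_correct[m], fixture_categories),
                       sub$n_trials[m])
  expect_equal(pats[[1]], direct)
})
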