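# Shared fixtures: small hand-built response tables and random-table
# generators used across the suite.

fixture_categories <- c("Mug", "TV", "Helmet")

# One trial row with overridable fields.
make_record <- function(rater_id = "r1", session = "test",
                        presentation = "ms50", image_condition = "full",
                        block = 1L, trial_index = 1L,
                        stimulus_id = "Mug_001", true_category = "Mug",
                        response_category = "Mug",
                        response_label = response_category,
                        rater_kind = "human") {
  data.frame(rater_id = rater_id, rater_kind = rater_kind,
             session = session, presentation = presentation,
             image_condition = image_condition, block = block,
             trial_index = trial_index, stimulus_id = stimulus_id,
             true_category = true_category,
             response_label = response_label,
             response_category = response_category,
             stringsAsFactors = FALSE)
}

# A valid single-rater table of n trials over the fixture categories,
# with responses drawn from the current RNG stream.
random_table <- function(n = 30, rater_id = "r1", session = "test",
                         categories = fixture_categories,
                         p_correct = 0.7) {
  truth <- sample(categories, n, replace = TRUE)
  resp <- ifelse(runif(n) < p_correct, truth,
                 sample(categories, n, replace = TRUE))
  data.frame(rater_id = rater_id, rater_kind = "human", session = session,
             presentation = "ms50", image_condition = "full",
             block = rep(seq_len(max(1, n %/% 10)), length.out = n),
             trial_index = seq_len(n),
             stimulus_id = sprintf("stim_%04d", seq_len(n)),
             true_category = truth, response_label = resp,
             response_category = resp, stringsAsFactors = FALSE)
}

# Independent contingency-table computation of kappa ingredients,
# written as an explicit double loop (the brute-force oracle).
oracle_kappa <- function(a, b) {
  labels <- sort(unique(c(a, b)))
  n <- length(a)
  counts <- matrix(0, length(labels), length(labels),
                   dimnames = list(labels, labels))
  for (i in seq_len(n))
    counts[a[i], b[i]] <- counts[a[i], b[i]] + 1
  po <- 0
  for (l in labels) po <- po + counts[l, l] / n
  pe <- 0
  for (l in labels) pe <- pe + sum(counts[l, ]) * sum(counts[, l]) / n^2
  list(po = po, pe = pe, kappa = (po - pe) / (1 - pe))
}

# Independent JZS Bayes-factor oracle: quadrature over the effect-size
# variable delta (noncentral-t likelihood x Cauchy prior), a different
# integration variable from the implementation's g-integral.
oracle_jzs_bf <- function(t, neff, nu, r, width = 40, n_grid = 80001) {
  delta <- seq(-width, width, length.out = n_grid)
  h <- delta[2] - delta[1]
  f <- suppressWarnings(dt(t, df = nu, ncp = delta * sqrt(neff))) *
    dcauchy(delta, 0, r)
  w <- rep(c(2, 4), length.out = n_grid)      # Simpson weights
  w[1] <- w[n_grid] <- 1
  alt <- sum(w * f) * h / 3
  alt / dt(t, df = nu)
}
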