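#' Describe a synthetic cohort
#'
#' A cohort spec is a generative description of a participant pool:
#' latent subgroups with per-category accuracy profiles, a confusion
#' kernel describing where errors go, and a test-retest stability
#' parameter. Each participant is assigned a subgroup by weight; their
#' test-session profile is the subgroup profile, and at retest the
#' profile is kept intact with probability `session_stability` or
#' perturbed by Gaussian jitter on the logit scale otherwise (which keeps
#' accuracies inside (0,1) without truncation).
#'
#' The defaults mirror a large online two-session study: 398 adults, nine
#' object categories with 30 images each, a dominant subgroup (65%) whose
#' accuracy is flat across categories at the cohort's mean level (~86%),
#' and minority subgroups whose profiles dip for particular categories
#' (helmet confusions, difficult plate/vase stimuli, texture-driven
#' observers strong only on easy categories, and generally weak
#' observers), with 60% of participants keeping their profile at retest.
#'
#' @param n_participants Number of participants.
#' @param categories Ordered category labels.
#' @param n_images_per_category Images (trials) per category and session.
#' @param subgroups List of subgroups, each a list with elements `weight`
#'   (nonnegative, weights summing to 1), `accuracy_profile` (per-category
#'   probability of a correct response, length 1 recycled or one value
#'   per category) and optional `note`.
#' @param confusion_kernel Per-category distribution of wrong answers:
#'   a matrix with rows = true categories, columns = response categories
#'   (optionally plus an `UNKNOWN` column), zero diagonal, rows summing
#'   to 1. `NULL` means uniform over the other categories.
#' @param session_stability Probability a participant keeps their exact
#'   accuracy profile at retest.
#' @param profile_jitter SD of the logit-scale perturbation applied to
#'   the profiles of unstable participants at retest.
#' @param second_exposure_boost Accuracy added (probability scale,
#'   clamped to \[0,1\]) when a stimulus is seen for the second time
#'   within a session; models repetition/carryover effects.
#' @param seed Integer master seed; per-participant substreams are
#'   derived from it by stable hashing of the rater id.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 398,
                        categories = default_categories(),
                        n_images_per_category = 30,
                        subgroups = default_subgroups(categories),
                        confusion_kernel = NULL,
                        session_stability = 0.6,
                        profile_jitter = 1.0,
                        second_exposure_boost = 0,
                        seed = 1L) {
  stopifnot(n_participants >= 1, is.character(categories),
            length(categories) >= 2, n_images_per_category >= 1,
            is.list(subgroups), length(subgroups) >= 1,
            session_stability >= 0, session_stability <= 1,
            profile_jitter >= 0)
  k <- length(categories)
  subgroups <- lapply(subgroups, function(g) {
    stopifnot(is.numeric(g$weight), g$weight >= 0)
    p <- g$accuracy_profile
    if (length(p) == 1) p <- rep(p, k)
    if (!is.null(names(p))) p <- p[categories]
    stopifnot(length(p) == k, all(p >= 0), all(p <= 1), !anyNA(p))
    list(weight = g$weight, accuracy_profile = setNames(unname(p), categories),
         note = if (is.null(g$note)) "" else g$note)
  })
  w <- vapply(subgroups, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-12)
    stop("configuration error: subgroup weights must sum to 1 (got ",
         format(sum(w)), ")", call. = FALSE)
  confusion_kernel <- check_confusion_kernel(confusion_kernel, categories)
  structure(list(n_participants = as.integer(n_participants),
                 categories = categories,
                 n_images_per_category = as.integer(n_images_per_category),
                 subgroups = subgroups,
                 confusion_kernel = confusion_kernel,
                 session_stability = session_stability,
                 profile_jitter = profile_jitter,
                 second_exposure_boost = second_exposure_boost,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_subgroups <- function(categories = default_categories()) {
  base <- function(p, ...) {
    pr <- setNames(rep(p, length(categories)), categories)
    over <- c(...)
    pr[names(over)] <- over
    pr
  }
  list(
    list(weight = 0.65, accuracy_profile = base(0.87), note = "flat"),
    list(weight = 0.14,
         accuracy_profile = base(0.88, Helmet = 0.62),
         note = "helmet-weak"),
    list(weight = 0.09,
         accuracy_profile = base(0.88, Plate = 0.60, Vase = 0.72),
         note = "difficult-weak"),
    list(weight = 0.07,
         accuracy_profile = base(0.74, Banana = 0.97, Match = 0.97,
                                 Plunger = 0.97),
         note = "easy-strong"),
    list(weight = 0.05,
         accuracy_profile = base(0.70, Plate = 0.50, Vase = 0.50,
                                 Basket = 0.50, Banana = 0.90, Match = 0.90,
                                 Plunger = 0.90),
         note = "low-graded"))
}

check_confusion_kernel <- function(kernel, categories) {
  k <- length(categories)
  if (is.null(kernel)) {
    kernel <- matrix(1 / (k - 1), k, k,
                     dimnames = list(categories, categories))
    diag(kernel) <- 0
    return(kernel)
  }
  stopifnot(is.matrix(kernel), !is.null(rownames(kernel)),
            !is.null(colnames(kernel)))
  stopifnot(setequal(rownames(kernel), categories),
            all(colnames(kernel) %in% c(categories, UNKNOWN_LABEL)))
  kernel <- kernel[categories, , drop = FALSE]
  for (cat in categories)
    if (cat %in% colnames(kernel) && kernel[cat, cat] != 0)
      stop("confusion kernel must have a zero diagonal", call. = FALSE)
  if (any(abs(rowSums(kernel) - 1) > 1e-12))
    stop("confusion kernel rows must sum to 1", call. = FALSE)
  kernel
}

# Simulate one rater responding to a schedule with a fixed profile.
# Vectorised over trials; draws come from the current RNG stream.
simulate_responses <- function(schedule, profile, kernel, boost = 0) {
  p <- unname(profile[schedule$true_category])
  if (boost != 0) {
    seen_again <- duplicated(paste(schedule$image_condition,
                                   schedule$stimulus_id, sep = "\r"))
    p <- pmin(1, pmax(0, p + boost * seen_again))
  }
  correct <- runif(nrow(schedule)) < p
  resp <- schedule$true_category
  wrong_idx <- which(!correct)
  if (length(wrong_idx)) {
    labels <- colnames(kernel)
    # draw wrong labels category by category (vectorised, deterministic)
    for (cat in rownames(kernel)) {
      idx <- wrong_idx[schedule$true_category[wrong_idx] == cat]
      if (length(idx))
        resp[idx] <- sample(labels, length(idx), replace = TRUE,
                            prob = kernel[cat, ])
    }
  }
  resp
}

#' Generate a synthetic cohort of trial-level responses
#'
#' Simulates every participant through the schedule once per session.
#' Each participant draws a subgroup by weight; per trial the response is
#' correct with probability given by the participant's session profile,
#' otherwise a wrong label (possibly `UNKNOWN`) is drawn from the
#' confusion kernel row of the true category. Trial order is
#' re-randomised per participant and session. The whole table is a pure
#' function of `(spec, design, sessions)`: per-participant substreams are
#' derived from the master seed by stable hashing of the rater id, so the
#' same seed always yields a byte-identical table.
#'
#' Ground truth (subgroup membership and the exact per-session profiles)
#' is attached as attribute `"ground_truth"`; see
#' [cohort_ground_truth()].
#'
#' @param spec A [cohort_spec()].
#' @param design A [design_spec()]; defaults to a single-duration (50 ms)
#'   full-image design over the spec's category grid with blocks of equal
#'   size.
#' @param sessions Sessions to simulate (`"test"`, `"retest"` or both).
#' @return Response data frame (see [response-tables]).
#' @export
generate_cohort <- function(spec, design = NULL,
                            sessions = c("test", "retest")) {
  stopifnot(inherits(spec, "cohort_spec"), all(sessions %in% SESSIONS),
            !anyDuplicated(sessions))
  if (is.null(design))
    design <- design_spec(spec$categories, spec$n_images_per_category,
                          presentations = "ms50", n_blocks = 6,
                          image_condition = "full", seed = spec$seed)
  stopifnot(inherits(design, "design_spec"),
            identical(design$categories, spec$categories))
  weights <- vapply(spec$subgroups, `[[`, numeric(1), "weight")
  n <- spec$n_participants
  ids <- sprintf("sub%04d", seq_len(n))
  membership <- with_seed(spec$seed,
                          sample.int(length(weights), n, replace = TRUE,
                                     prob = weights))
  k <- length(spec$categories)
  parts <- vector("list", n * length(sessions))
  gt_profiles <- vector("list", n)
  stable <- logical(n)
  for (i in seq_len(n)) {
    sub <- spec$subgroups[[membership[i]]]
    prof <- list(test = sub$accuracy_profile)
    pseed <- substream_seed(spec$seed, ids[i])
    # retest profile: kept intact w.p. session_stability, else logit-jittered
    with_seed(pseed, {
      keep <- runif(1) < spec$session_stability
      prof$retest <- if (keep) prof$test else
        setNames(plogis(qlogis(pmin(pmax(prof$test, 1e-9), 1 - 1e-9)) +
                          rnorm(k, 0, spec$profile_jitter)),
                 spec$categories)
      stable[i] <- keep
    })
    gt_profiles[[i]] <- prof
    for (s in seq_along(sessions)) {
      ses <- sessions[s]
      sched_seed <- substream_seed(spec$seed, ids[i],
                                   offset = match(ses, SESSIONS))
      d <- design
      d$seed <- as.integer(sched_seed %% 2147483646 + 1)
      schedule <- make_counterbalanced_design(d)
      resp <- with_seed(substream_seed(spec$seed, ids[i],
                                       offset = 10 + match(ses, SESSIONS)),
                        simulate_responses(schedule, prof[[ses]],
                                           spec$confusion_kernel,
                                           spec$second_exposure_boost))
      parts[[(i - 1) * length(sessions) + s]] <- data.frame(
        rater_id = ids[i], rater_kind = "human", session = ses,
        presentation = schedule$presentation,
        image_condition = schedule$image_condition,
        block = schedule$block, trial_index = schedule$trial_index,
        stimulus_id = schedule$stimulus_id,
        true_category = schedule$true_category,
        response_label = resp, response_category = resp,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, parts)
  rownames(records) <- NULL
  attr(records, "ground_truth") <- list(
    rater_id = ids,
    subgroup = membership,
    subgroup_note = vapply(spec$subgroups, `[[`, character(1),
                           "note")[membership],
    stable = stable,
    profiles = setNames(gt_profiles, ids),
    categories = spec$categories)
  records
}

#' Ground truth attached to a generated cohort
#'
#' @param records A table returned by [generate_cohort()].
#' @return List with per-participant subgroup membership, stability
#'   indicators and exact per-session accuracy profiles.
#' @export
cohort_ground_truth <- function(records) {
  gt <- attr(records, "ground_truth")
  if (is.null(gt))
    stop("no ground truth attached; was this table generated by ",
         "generate_cohort()?", call. = FALSE)
  gt
}

#' Simulate a model rater
#'
#' One deterministic-profile artificial rater answering every scheduled
#' trial once (single session, `rater_kind = "model"`). Stands in for a
#' neural network's response table.
#'
#' @param rater_id Identifier for the rater.
#' @param accuracy_profile Per-category probability of a correct
#'   response (length 1 recycled, or one value per category, optionally
#'   named).
#' @param design A [design_spec()].
#' @param confusion_kernel As in [cohort_spec()]; `NULL` = uniform.
#' @param seed Integer seed.
#' @return Response data frame with one row per scheduled trial.
#' @export
generate_model_rater <- function(rater_id, accuracy_profile, design,
                                 confusion_kernel = NULL, seed = 1L) {
  stopifnot(inherits(design, "design_spec"), is.character(rater_id))
  k <- length(design$categories)
  p <- accuracy_profile
  if (length(p) == 1) p <- rep(p, k)
  if (!is.null(names(p))) p <- p[design$categories]
  stopifnot(length(p) == k, all(p >= 0), all(p <= 1))
  p <- setNames(unname(p), design$categories)
  kernel <- check_confusion_kernel(confusion_kernel, design$categories)
  d <- design
  d$seed <- as.integer(substream_seed(seed, rater_id) %% 2147483646 + 1)
  schedule <- make_counterbalanced_design(d)
  resp <- with_seed(substream_seed(seed, rater_id, offset = 10),
                    simulate_responses(schedule, p, kernel))
  out <- data.frame(
    rater_id = rater_id, rater_kind = "model", session = "test",
    presentation = schedule$presentation,
    image_condition = schedule$image_condition,
    block = schedule$block, trial_index = schedule$trial_index,
    stimulus_id = schedule$stimulus_id,
    true_category = schedule$true_category,
    response_label = resp, response_category = resp,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build a cohort spec with a planted modal pattern
#'
#' Constructs a cohort whose dominant ("modal") subgroup has a perfectly
#' flat accuracy profile — the all-equivalent ordinal pattern — at a
#' chosen weight, with the remaining weight split evenly over variant
#' subgroups. Each variant lowers one category's accuracy by
#' `2.5 * tau`, i.e. well beyond twice the discretisation tolerance, so
#' the variants' ordinal patterns are distinct from the flat pattern and
#' from each other at profile level. Used to verify end-to-end recovery
#' of planted pattern structure.
#'
#' @param n_participants Cohort size.
#' @param modal_weight Weight of the flat-profile subgroup, in (0, 1).
#' @param n_variant_subgroups Number of variant subgroups (each at most
#'   one per category).
#' @param seed Master seed.
#' @param base_accuracy Accuracy level of the flat profile.
#' @param tau Discretisation tolerance the separation is calibrated
#'   against.
#' @param session_stability,profile_jitter Passed to [cohort_spec()].
#' @param categories Category set.
#' @return A [cohort_spec()].
#' @export
plant_modal_scenario <- function(n_participants, modal_weight = 0.65,
                                 n_variant_subgroups = 4, seed = 1L,
                                 base_accuracy = 0.85, tau = 0.1,
                                 session_stability = 0.6,
                                 profile_jitter = 1.0,
                                 categories = default_categories()) {
  if (!is.numeric(modal_weight) || modal_weight <= 0 || modal_weight >= 1)
    stop("configuration error: modal_weight must lie strictly in (0, 1)",
         call. = FALSE)
  stopifnot(n_variant_subgroups >= 1,
            n_variant_subgroups <= length(categories))
  drop <- 2.5 * tau
  stopifnot(base_accuracy - drop >= 0)
  flat <- setNames(rep(base_accuracy, length(categories)), categories)
  variants <- lapply(seq_len(n_variant_subgroups), function(v) {
    p <- flat
    p[categories[v]] <- base_accuracy - drop
    list(weight = (1 - modal_weight) / n_variant_subgroups,
         accuracy_profile = p, note = sprintf("weak-%s", categories[v]))
  })
  cohort_spec(n_participants = n_participants, categories = categories,
              subgroups = c(list(list(weight = modal_weight,
                                      accuracy_profile = flat,
                                      note = "flat")),
                            variants),
              session_stability = session_stability,
              profile_jitter = profile_jitter, seed = seed)
}
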