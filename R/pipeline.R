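#' Configure an end-to-end cohort analysis
#'
#' Bundles the inputs and settings for [run_cohort_analysis()]. Exactly
#' one data source must be given: either trial records already in memory
#' / on disk (`human_records` / `human_path`), or a generator spec
#' (`cohort`). Model raters likewise come from records, paths or
#' per-model accuracy profiles simulated on the same design.
#'
#' @param cohort A [cohort_spec()], or `NULL` when records are supplied.
#' @param design Optional [design_spec()] (defaults to the cohort's
#'   single-duration design).
#' @param human_records,human_path Response table (data frame / CSV
#'   path) as an alternative to generation.
#' @param model_records,model_paths,model_profiles Model raters: a
#'   response table, CSV paths, or a named list of accuracy profiles to
#'   simulate (default: three synthetic tiers — a strong flat
#'   multimodal-style model, a transformer-style model with a mild
#'   helmet dip, and a convolutional-style model strong on easy and weak
#'   on difficult categories).
#' @param categories Category set.
#' @param criterion [discretisation_criterion()] for the pattern stage.
#' @param prior_scale Cauchy prior scale for all Bayes factors.
#' @param ci_level Confidence level for kappa CIs.
#' @param seed Master seed (also used for pair subsampling).
#' @param reliability,agreement,bayes,patterns,carryover Stage toggles.
#' @param agreement_max_raters Cap on the number of humans entering the
#'   pairwise human-human kappa matrix; larger cohorts are subsampled
#'   deterministically by the seed.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(cohort = NULL, design = NULL,
                            human_records = NULL, human_path = NULL,
                            model_records = NULL, model_paths = NULL,
                            model_profiles = default_model_profiles(),
                            categories = default_categories(),
                            criterion = discretisation_criterion(),
                            prior_scale = sqrt(2) / 2,
                            ci_level = 0.95, seed = 1L,
                            reliability = TRUE, agreement = TRUE,
                            bayes = TRUE, patterns = TRUE,
                            carryover = FALSE,
                            agreement_max_raters = 40L) {
  sources <- !vapply(list(cohort, human_records, human_path), is.null,
                     logical(1))
  if (sum(sources) != 1)
    stop("configuration error: supply exactly one of cohort, ",
         "human_records, human_path", call. = FALSE)
  structure(list(cohort = cohort, design = design,
                 human_records = human_records, human_path = human_path,
                 model_records = model_records, model_paths = model_paths,
                 model_profiles = model_profiles, categories = categories,
                 criterion = criterion, prior_scale = prior_scale,
                 ci_level = ci_level, seed = as.integer(seed),
                 reliability = reliability, agreement = agreement,
                 bayes = bayes, patterns = patterns, carryover = carryover,
                 agreement_max_raters = as.integer(agreement_max_raters)),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @export
default_model_profiles <- function(categories = default_categories()) {
  flat <- function(p, ...) {
    pr <- setNames(rep(p, length(categories)), categories)
    over <- c(...)
    pr[names(over)] <- over
    pr
  }
  list(multimodal = flat(0.93),
       transformer = flat(0.92, Helmet = 0.84),
       convnet = flat(0.80, Plate = 0.50, Vase = 0.58, Basket = 0.62,
                      Banana = 0.96, Match = 0.95, Plunger = 0.95))
}

config_human_records <- function(config) {
  if (!is.null(config$human_records)) {
    validate_responses(config$human_records, config$categories)
    config$human_records
  } else if (!is.null(config$human_path)) {
    read_responses(config$human_path, config$categories)
  } else {
    generate_cohort(config$cohort, config$design)
  }
}

config_design <- function(config, human_records) {
  if (!is.null(config$design)) return(config$design)
  if (!is.null(config$cohort))
    return(design_spec(config$cohort$categories,
                       config$cohort$n_images_per_category,
                       presentations = "ms50", n_blocks = 6,
                       image_condition = "full",
                       seed = config$cohort$seed))
  # reconstruct a compatible single-duration design from the data
  n_img <- length(unique(human_records$stimulus_id)) /
    length(unique(human_records$true_category))
  design_spec(config$categories, n_img,
              presentations = unique(human_records$presentation)[1],
              n_blocks = max(human_records$block),
              image_condition = unique(human_records$image_condition)[1],
              seed = config$seed)
}

config_model_records <- function(config, design) {
  if (!is.null(config$model_records)) {
    validate_responses(config$model_records, config$categories)
    return(config$model_records)
  }
  if (!is.null(config$model_paths))
    return(do.call(rbind, lapply(config$model_paths, read_responses,
                                 categories = config$categories)))
  if (is.null(config$model_profiles) || !length(config$model_profiles))
    return(NULL)
  do.call(rbind, lapply(names(config$model_profiles), function(id)
    generate_model_rater(id, config$model_profiles[[id]], design,
                         seed = config$seed)))
}

# Aligned per-rater label vectors (named by stimulus key) for one
# session's records.
rater_label_vectors <- function(records) {
  key <- paste(records$presentation, records$image_condition,
               records$stimulus_id, sep = "\r")
  split_idx <- split(seq_len(nrow(records)), records$rater_id)
  lapply(split_idx, function(ix)
    setNames(records$response_category[ix], key[ix]))
}

#' Run the full cohort analysis
#'
#' Orchestrates the pipeline on one configuration: accuracy tables,
#' test-retest reliability (per-participant kappa with CIs, cohort
#' median), human-human and human-model agreement, per-category
#' Bayes-factor accuracy comparisons, and the ordinal-pattern stage
#' (per-rater signatures, frequency tables, modal pattern, cross-session
#' consistency, model matching). Only test-session human data feed the
#' human-model comparisons; the retest session feeds reliability and
#' pattern consistency alone. A manifest records the seed, package
#' version, criterion and prior scale so a run can be reproduced
#' bit for bit.
#'
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, every stage's report
#'   is written there as plain CSV/JSON and a `manifest.json` is added.
#' @return Object of class `cohort_analysis`: a list with elements
#'   `accuracy`, `reliability`, `agreement`, `bayes`, `patterns`,
#'   `carryover` (stages that were toggled off are `NULL`) and
#'   `manifest`.
#' @export
run_cohort_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name) message(sprintf("[catpattern] %-12s %6.1fs",
                                          name,
                                          proc.time()[["elapsed"]] - t0))
  human <- config_human_records(config)
  design <- config_design(config, human)
  models <- config_model_records(config, design)
  test_h <- human[human$session == "test", , drop = FALSE]
  retest_h <- human[human$session == "retest", , drop = FALSE]
  out <- list()

  stage("accuracy")
  out$accuracy <- compute_accuracy(human, categories = config$categories)
  model_accuracy <- if (!is.null(models))
    compute_accuracy(models, categories = config$categories)

  if (config$carryover) {
    stage("carryover")
    out$carryover <- run_carryover_check(test_h,
                                         prior_scale = config$prior_scale)
  }

  if (config$reliability && nrow(retest_h)) {
    stage("reliability")
    out$reliability <- intra_rater_reliability(test_h, retest_h,
                                               ci_level = config$ci_level)
  }

  if (config$agreement) {
    stage("agreement")
    humans <- rater_label_vectors(test_h)
    picked <- names(humans)
    if (length(humans) > config$agreement_max_raters)
      picked <- with_seed(config$seed + 1,
                          sort(sample(names(humans),
                                      config$agreement_max_raters)))
    hh <- pairwise_agreement_matrix(humans[picked],
                                    ci_level = config$ci_level)
    out$agreement <- list(human_human = hh,
                          human_human_median = median(hh$pairs$kappa),
                          human_human_pooled = pooled_pair_kappa(
                            humans[picked]),
                          raters_used = picked)
    if (!is.null(models)) {
      mv <- rater_label_vectors(models)
      hm_rows <- list()
      for (m in names(mv)) for (h in picked) {
        res <- cohen_kappa(mv[[m]][names(humans[[h]])], humans[[h]],
                           ci_level = config$ci_level)
        hm_rows[[length(hm_rows) + 1L]] <- data.frame(
          rater_a = m, rater_b = h, kappa = res$kappa,
          se = res$standard_error, ci_low = res$ci_low,
          ci_high = res$ci_high, band = res$band, n_items = res$n_items,
          stringsAsFactors = FALSE)
      }
      hm <- do.call(rbind, hm_rows)
      out$agreement$human_model <- hm
      out$agreement$human_model_median <- vapply(
        split(hm$kappa, hm$rater_a), median, numeric(1))
    }
  }

  if (config$bayes && !is.null(models)) {
    stage("bayes")
    test_acc <- compute_accuracy(test_h, categories = config$categories)
    bf_rows <- lapply(unique(models$rater_id), function(m) {
      ma <- model_accuracy[model_accuracy$rater_id == m, , drop = FALSE]
      out <- rbind(
        compare_accuracies(test_acc, ma, scope = "per_category",
                           prior_scale = config$prior_scale),
        compare_accuracies(test_acc, ma, scope = "overall",
                           prior_scale = config$prior_scale))
      cbind(model = m, out, stringsAsFactors = FALSE)
    })
    out$bayes <- do.call(rbind, bf_rows)
  }

  if (config$patterns) {
    stage("patterns")
    test_acc <- compute_accuracy(test_h, categories = config$categories)
    pat_test <- patterns_from_accuracy(test_acc, config$criterion,
                                       config$categories)
    pat <- list(test = pat_test,
                frequencies_test = pattern_frequencies(pat_test),
                modal_test = modal_pattern(pat_test))
    if (nrow(retest_h)) {
      retest_acc <- compute_accuracy(retest_h,
                                     categories = config$categories)
      pat$retest <- patterns_from_accuracy(retest_acc, config$criterion,
                                           config$categories)
      pat$frequencies_retest <- pattern_frequencies(pat$retest)
      pat$modal_retest <- modal_pattern(pat$retest)
      pat$consistency <- session_consistency(pat$test, pat$retest)
    }
    if (!is.null(models)) {
      mpat <- patterns_from_accuracy(model_accuracy, config$criterion,
                                     config$categories)
      pat$model_patterns <- mpat
      pat$model_match <- lapply(mpat, match_model_to_human,
                                human_patterns = pat$test)
    }
    out$patterns <- pat
  }

  out$manifest <- list(
    package = "catpattern",
    version = as.character(packageVersion("catpattern")),
    seed = config$seed,
    categories = config$categories,
    criterion = unclass(config$criterion),
    prior_scale = config$prior_scale,
    ci_level = config$ci_level,
    n_human_raters = length(unique(human$rater_id)),
    n_model_raters = if (is.null(models)) 0L else
      length(unique(models$rater_id)),
    sessions = sort(unique(human$session)),
    stages = c(reliability = config$reliability,
               agreement = config$agreement, bayes = config$bayes,
               patterns = config$patterns, carryover = config$carryover))

  if (!is.null(out_dir)) write_analysis_bundle(out, out_dir)
  stage("done")
  structure(out, class = "cohort_analysis")
}

# Pooled human-human kappa: all aligned pairs' trials concatenated into
# one long pair of sequences.
pooled_pair_kappa <- function(raters) {
  ids <- names(raters)
  stim <- names(raters[[1]])
  a <- list(); b <- list()
  for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
    a[[length(a) + 1L]] <- unname(raters[[i]][stim])
    b[[length(b) + 1L]] <- unname(raters[[j]][stim])
  }
  cohen_kappa(unlist(a), unlist(b))
}

write_analysis_bundle <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name)
    write.csv(x, file.path(out_dir, name), row.names = FALSE)
  wjson <- function(x, name)
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  wcsv(out$accuracy, "accuracy.csv")
  if (!is.null(out$reliability))
    wcsv(out$reliability$table, "reliability.csv")
  if (!is.null(out$agreement)) {
    wcsv(out$agreement$human_human$pairs, "agreement_human_human.csv")
    wcsv(as.data.frame(out$agreement$human_human$kappa),
         "agreement_matrix.csv")
    if (!is.null(out$agreement$human_model))
      wcsv(out$agreement$human_model, "agreement_human_model.csv")
  }
  if (!is.null(out$bayes)) wcsv(out$bayes, "bayes_comparisons.csv")
  if (!is.null(out$patterns)) {
    p <- out$patterns
    sig_tab <- data.frame(
      rater_id = names(p$test),
      session = "test",
      signature = vapply(p$test, pattern_signature, character(1)),
      stringsAsFactors = FALSE)
    if (!is.null(p$retest))
      sig_tab <- rbind(sig_tab, data.frame(
        rater_id = names(p$retest), session = "retest",
        signature = vapply(p$retest, pattern_signature, character(1)),
        stringsAsFactors = FALSE))
    wcsv(sig_tab, "pattern_signatures.csv")
    wcsv(p$frequencies_test, "pattern_frequencies_test.csv")
    if (!is.null(p$frequencies_retest))
      wcsv(p$frequencies_retest, "pattern_frequencies_retest.csv")
    report <- list(
      modal_test = p$modal_test[c("signatures", "proportion")],
      modal_retest = if (!is.null(p$modal_retest))
        p$modal_retest[c("signatures", "proportion")],
      consistency = if (!is.null(p$consistency))
        list(proportion = p$consistency$proportion,
             n = length(p$consistency$indicator),
             exclusions = p$consistency$exclusions),
      model_match = p$model_match)
    wjson(report, "pattern_report.json")
  }
  if (!is.null(out$carryover)) {
    co <- data.frame(
      presentation = names(out$carryover),
      bf10 = vapply(out$carryover, `[[`, numeric(1), "bf10"),
      t = vapply(out$carryover, `[[`, numeric(1), "t_statistic"),
      n = vapply(out$carryover, `[[`, numeric(1), "n1"),
      stringsAsFactors = FALSE)
    wcsv(co, "carryover.csv")
  }
  wjson(out$manifest, "manifest.json")
  invisible(out_dir)
}

#' @export
print.cohort_analysis <- function(x, ...) {
  m <- x$manifest
  cat("Cohort analysis (", m$n_human_raters, " humans, ",
      m$n_model_raters, " models)\n", sep = "")
  if (!is.null(x$reliability))
    cat(sprintf("  intra-rater reliability: median kappa = %.3f (%d ok, %d excluded)\n",
                x$reliability$median_kappa, nrow(x$reliability$table),
                length(x$reliability$exclusions)))
  if (!is.null(x$agreement))
    cat(sprintf("  human-human agreement: median kappa = %.3f (%d raters)\n",
                x$agreement$human_human_median,
                length(x$agreement$raters_used)))
  if (!is.null(x$patterns)) {
    cat(sprintf("  modal pattern (test): %s at %.1f%%\n",
                x$patterns$modal_test$signatures[1],
                100 * x$patterns$modal_test$proportion))
    if (!is.null(x$patterns$consistency))
      cat(sprintf("  session pattern consistency: %.1f%%\n",
                  100 * x$patterns$consistency$proportion))
  }
  invisible(x)
}

#' Bayesian carryover (repetition) check
#'
#' In designs where each stimulus is shown twice to a rater (once per
#' presentation duration), compares every rater's accuracy on first
#' exposures with their accuracy on second exposures, separately per
#' presentation condition, using a paired JZS Bayes-factor t test on the
#' per-rater difference (second minus first). BF10 < 1 supports the
#' absence of a repetition effect.
#'
#' @param records Response data frame in which every stimulus appears
#'   exactly twice per rater.
#' @param prior_scale Cauchy prior scale.
#' @return Named list of [jzs_bf_paired()] results, one per presentation
#'   condition.
#' @export
run_carryover_check <- function(records, prior_scale = sqrt(2) / 2) {
  halves <- split_halves(records)
  if (nrow(halves$second) == 0)
    stop("integrity error: no stimulus was presented twice; ",
         "carryover check needs repeated exposures", call. = FALSE)
  exposure_acc <- function(recs) {
    acc <- aggregate(
      list(correct = as.integer(recs$response_category ==
                                  recs$true_category)),
      by = list(rater_id = recs$rater_id,
                presentation = recs$presentation), FUN = mean)
    acc
  }
  first <- exposure_acc(halves$first)
  second <- exposure_acc(halves$second)
  out <- list()
  for (pres in sort(unique(records$presentation))) {
    f <- first[first$presentation == pres, , drop = FALSE]
    s <- second[second$presentation == pres, , drop = FALSE]
    shared <- intersect(f$rater_id, s$rater_id)
    if (length(shared) < 2) next
    d <- s$correct[match(shared, s$rater_id)] -
      f$correct[match(shared, f$rater_id)]
    out[[pres]] <- jzs_bf_paired(d, prior_scale = prior_scale)
  }
  if (!length(out))
    stop("integrity error: no presentation condition had both first ",
         "and second exposures for at least two raters", call. = FALSE)
  out
}
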