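#' Criterion for calling two category accuracies equivalent
#'
#' Ordinal discretisation reduces a vector of per-category accuracies to
#' pairwise qualitative relations: less than, greater than or
#' approximately equal. The equivalence band can be a fixed threshold on
#' the absolute difference in proportions (`mode = "threshold"`,
#' tolerance tau, default 0.1, i.e. 3 images out of 30) or overlap of
#' the two per-category Wilson score intervals
#' (`mode = "ci_overlap"`). The band is decided before the sign: a pair
#' within tolerance is equivalent even when the difference is nonzero.
#'
#' @param mode `"threshold"` or `"ci_overlap"`.
#' @param tolerance Equality band width tau on the proportion scale
#'   (threshold mode).
#' @param ci_level Confidence level of the Wilson intervals
#'   (ci_overlap mode).
#' @return Object of class `discretisation_criterion`.
#' @export
discretisation_criterion <- function(mode = c("threshold", "ci_overlap"),
                                     tolerance = 0.1, ci_level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(tolerance), tolerance >= 0, tolerance <= 1,
            ci_level > 0, ci_level < 1)
  structure(list(mode = mode, tolerance = tolerance, ci_level = ci_level),
            class = "discretisation_criterion")
}

# Wilson score interval; vectorised over (x, n).
wilson_interval <- function(x, n, level) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  cbind(low = centre - half, high = centre + half)
}

new_ordinal_pattern <- function(categories, cells) {
  k <- length(categories)
  stopifnot(length(cells) == k * (k - 1) / 2,
            all(cells %in% c("<", "=", ">")))
  structure(list(categories = categories, cells = cells,
                 signature = paste(cells, collapse = "")),
            class = "ordinal_pattern")
}

# Index pairs (i, j), i < j, in the row-major order used by signatures.
pattern_pairs <- function(k) {
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
}

#' Discretise per-category accuracies into an ordinal pattern
#'
#' Produces, for every ordered category pair (i, j) with i before j in
#' the configured category order, one of three relations comparing
#' category i's accuracy with category j's: `"="` when the pair falls
#' inside the equivalence band of the criterion, otherwise `">"` or
#' `"<"` by the sign of the difference. The result depends only on the
#' aggregated counts, not on trial order.
#'
#' @param n_correct Per-category correct counts (named or in category
#'   order), or per-category proportions when `n_trials` is `NULL`
#'   (threshold mode only).
#' @param n_trials Per-category trial counts (all positive), or `NULL`.
#' @param criterion A [discretisation_criterion()].
#' @param categories Category order; defaults to `names(n_correct)`.
#' @return Object of class `ordinal_pattern` with fields `categories`,
#'   `cells` (relations in row-major pair order (1,2), (1,3), ...,
#'   (k-1,k)) and `signature` (the cells pasted into a string of length
#'   k(k-1)/2).
#' @export
#' @examples
#' discretise(c(a = 30, b = 27, c = 15), c(30, 30, 30))$signature  # "=>>"
discretise <- function(n_correct, n_trials = NULL,
                       criterion = discretisation_criterion(),
                       categories = NULL) {
  stopifnot(inherits(criterion, "discretisation_criterion"))
  if (is.null(categories)) categories <- names(n_correct)
  if (is.null(categories))
    stop("category order required (name n_correct or pass categories)",
         call. = FALSE)
  k <- length(categories)
  if (k < 2) stop("need at least 2 categories", call. = FALSE)
  if (is.null(n_trials)) {
    if (criterion$mode == "ci_overlap")
      stop("ci_overlap mode needs trial counts", call. = FALSE)
    p <- as.numeric(n_correct)
    stopifnot(length(p) == k, all(p >= 0), all(p <= 1), !anyNA(p))
  } else {
    x <- as.numeric(n_correct)
    n <- as.numeric(n_trials)
    stopifnot(length(x) == k, length(n) == k, !anyNA(x), !anyNA(n))
    if (any(n <= 0))
      stop("domain error: zero-trial category", call. = FALSE)
    stopifnot(all(x >= 0), all(x <= n))
    p <- x / n
  }
  pairs <- pattern_pairs(k)
  i <- pairs[, "row"]; j <- pairs[, "col"]
  if (criterion$mode == "threshold") {
    equiv <- abs(p[i] - p[j]) <= criterion$tolerance
  } else {
    ci <- wilson_interval(x, n, criterion$ci_level)
    equiv <- ci[i, "low"] <= ci[j, "high"] & ci[j, "low"] <= ci[i, "high"]
  }
  cells <- unname(ifelse(equiv, "=", ifelse(p[i] > p[j], ">", "<")))
  new_ordinal_pattern(categories, cells)
}

#' @export
print.ordinal_pattern <- function(x, ...) {
  k <- length(x$categories)
  m <- matrix("", k, k, dimnames = list(x$categories, x$categories))
  pairs <- pattern_pairs(k)
  inv <- c("<" = ">", ">" = "<", "=" = "=")
  for (c_ in seq_len(nrow(pairs))) {
    i <- pairs[c_, "row"]; j <- pairs[c_, "col"]
    m[i, j] <- x$cells[c_]
    m[j, i] <- inv[[x$cells[c_]]]
  }
  diag(m) <- "."
  cat("Ordinal pattern over", k, "categories (signature:", x$signature,
      ")\n")
  print(m, quote = FALSE)
  invisible(x)
}

#' Canonical string signature of an ordinal pattern
#'
#' The k(k-1)/2 relation cells pasted in fixed row-major pair order over
#' the configured category order; two patterns over the same category
#' order are equal iff their signatures are equal.
#'
#' @param pattern An `ordinal_pattern`.
#' @return Character scalar.
#' @export
pattern_signature <- function(pattern) {
  stopifnot(inherits(pattern, "ordinal_pattern"))
  pattern$signature
}

#' Rebuild an ordinal pattern from its signature
#'
#' @param signature Character scalar over the alphabet `<`, `=`, `>`.
#' @param categories Category order the signature refers to.
#' @return An `ordinal_pattern`.
#' @export
signature_to_pattern <- function(signature, categories) {
  new_ordinal_pattern(categories, strsplit(signature, "")[[1]])
}

check_shared_categories <- function(patterns) {
  stopifnot(is.list(patterns), length(patterns) >= 1)
  cats <- patterns[[1]]$categories
  ok <- vapply(patterns, function(p)
    inherits(p, "ordinal_pattern") && identical(p$categories, cats),
    logical(1))
  if (!all(ok))
    stop("alignment error: patterns use different category orders",
         call. = FALSE)
  cats
}

#' Frequency table of ordinal patterns across a cohort
#'
#' Counts identical signatures and ranks them by descending count,
#' breaking ties lexicographically by signature.
#'
#' @param patterns List of `ordinal_pattern` objects sharing one
#'   category order (or a character vector of signatures).
#' @return Data frame with `signature`, `count`, `proportion`; counts
#'   sum to the input size.
#' @export
pattern_frequencies <- function(patterns) {
  sigs <- if (is.character(patterns)) patterns else {
    check_shared_categories(patterns)
    vapply(patterns, pattern_signature, character(1))
  }
  tab <- table(sigs)
  out <- data.frame(signature = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$signature), , drop = FALSE]
  out$proportion <- out$count / length(sigs)
  rownames(out) <- NULL
  out
}

#' Most frequent ordinal pattern(s) in a cohort
#'
#' Returns the top-ranked signature; all tied signatures are returned in
#' lexicographic order.
#'
#' @inheritParams pattern_frequencies
#' @return List with `signatures` (character, ties in lexicographic
#'   order), `patterns` (matching `ordinal_pattern` objects when the
#'   input carried category information) and `proportion` (cohort share
#'   of each modal signature).
#' @export
modal_pattern <- function(patterns) {
  freq <- pattern_frequencies(patterns)
  top <- freq[freq$count == freq$count[1], , drop = FALSE]
  cats <- if (!is.character(patterns)) patterns[[1]]$categories else NULL
  list(signatures = top$signature,
       patterns = if (!is.null(cats))
         lapply(top$signature, signature_to_pattern, categories = cats),
       proportion = top$proportion[1])
}

#' Cross-session consistency of individual ordinal patterns
#'
#' The proportion of participants whose test and retest patterns have
#' identical signatures. Participants missing from one session are
#' reported in `exclusions`, never silently dropped.
#'
#' @param test_patterns,retest_patterns Named lists of `ordinal_pattern`
#'   objects (or named character vectors of signatures), keyed by
#'   participant.
#' @return List with `proportion`, `indicator` (named logical over the
#'   shared participants) and `exclusions`.
#' @export
session_consistency <- function(test_patterns, retest_patterns) {
  sig <- function(x) {
    if (is.character(x)) return(x)
    stopifnot(is.list(x), !is.null(names(x)))
    vapply(x, pattern_signature, character(1))
  }
  st <- sig(test_patterns); sr <- sig(retest_patterns)
  if (is.null(names(st)) || is.null(names(sr)))
    stop("patterns must be named by participant", call. = FALSE)
  shared <- intersect(names(st), names(sr))
  exclusions <- setdiff(union(names(st), names(sr)), shared)
  if (!length(shared))
    stop("no participant present in both sessions", call. = FALSE)
  ind <- setNames(unname(st[shared]) == unname(sr[shared]), shared)
  list(proportion = mean(ind), indicator = ind, exclusions = exclusions)
}

#' Match a model's ordinal pattern against a human cohort
#'
#' Compares a model pattern with the cohort's modal pattern (exact
#' signature match and fraction of identical cells) and locates the
#' model's signature in the cohort frequency table. With tied modal
#' patterns the lexicographically first modal signature is the
#' comparison target.
#'
#' @param model_pattern An `ordinal_pattern`.
#' @param human_patterns List of `ordinal_pattern` objects over the same
#'   category order.
#' @return List with `exact_match_to_modal` (logical),
#'   `cell_overlap_with_modal` (fraction of the k(k-1)/2 cells agreeing
#'   with the modal pattern), `rank_of_model_signature_among_humans`
#'   (row of the frequency table, or `NA` when the model's pattern never
#'   occurs in the cohort) and `modal_signature`.
#' @export
match_model_to_human <- function(model_pattern, human_patterns) {
  stopifnot(inherits(model_pattern, "ordinal_pattern"))
  cats <- check_shared_categories(human_patterns)
  if (!identical(model_pattern$categories, cats))
    stop("alignment error: model pattern uses a different category order",
         call. = FALSE)
  freq <- pattern_frequencies(human_patterns)
  modal_sig <- modal_pattern(human_patterns)$signatures[1]
  modal_cells <- strsplit(modal_sig, "")[[1]]
  overlap <- mean(model_pattern$cells == modal_cells)
  pos <- match(model_pattern$signature, freq$signature)
  list(exact_match_to_modal = model_pattern$signature == modal_sig,
       cell_overlap_with_modal = overlap,
       rank_of_model_signature_among_humans =
         if (is.na(pos)) NA_integer_ else as.integer(pos),
       modal_signature = modal_sig)
}

#' Discretise every rater in an accuracy table
#'
#' Convenience wrapper applying [discretise()] to each rater's
#' per-category counts in one condition cell of an accuracy table.
#'
#' @param accuracy_table Output of [compute_accuracy()] restricted to a
#'   single session/condition cell per rater.
#' @param criterion A [discretisation_criterion()].
#' @param categories Category order.
#' @return Named list of `ordinal_pattern` objects keyed by `rater_id`.
#' @export
patterns_from_accuracy <- function(accuracy_table,
                                   criterion = discretisation_criterion(),
                                   categories = NULL) {
  stopifnot(all(c("rater_id", "category", "n_correct", "n_trials") %in%
                  names(accuracy_table)))
  if (is.null(categories))
    categories <- sort(unique(accuracy_table$category))
  out <- list()
  for (id in unique(accuracy_table$rater_id)) {
    sub <- accuracy_table[accuracy_table$rater_id == id, , drop = FALSE]
    m <- match(categories, sub$category)
    if (anyNA(m))
      stop("alignment error: rater ", dQuote(id), " lacks categories ",
           paste(categories[is.na(m)], collapse = ", "), call. = FALSE)
    out[[id]] <- discretise(setNames(sub$n_correct[m], categories),
                            sub$n_trials[m], criterion = criterion)
  }
  out
}
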