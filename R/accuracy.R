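#' Aggregate trial records into an accuracy table
#'
#' Counts correct responses (a trial is correct when `response_category`
#' equals `true_category`) per grouping cell and category. Counts
#' partition the input exactly: summed `n_trials` over all rows equals the
#' number of input records. When a category set is supplied, categories a
#' rater never saw are reported with `n_trials = 0` and `proportion = NA`
#' rather than dropped.
#'
#' @param records Response data frame (see [response-tables]).
#' @param group_by Character vector of grouping columns in addition to
#'   `category`; defaults to rater, session and both condition columns.
#' @param categories Optional category set used to complete each group
#'   with zero-trial categories.
#' @return Data frame with the grouping columns, `category`, `n_correct`,
#'   `n_trials` and `proportion` (exactly `n_correct / n_trials`).
#' @export
compute_accuracy <- function(records,
                             group_by = c("rater_id", "session",
                                          "presentation", "image_condition"),
                             categories = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("compute_accuracy needs a non-empty response table", call. = FALSE)
  stopifnot(all(group_by %in% names(records)))
  correct <- as.integer(records$response_category == records$true_category)
  keys <- records[group_by]
  keys$category <- records$true_category
  agg <- aggregate(list(n_correct = correct,
                        n_trials = rep(1L, nrow(records))),
                   by = keys, FUN = sum)
  if (!is.null(categories)) {
    # complete each group with unseen categories (n_trials = 0)
    grp <- unique(agg[group_by])
    full <- merge(grp, data.frame(category = categories,
                                  stringsAsFactors = FALSE))
    agg <- merge(full, agg, by = c(group_by, "category"), all.x = TRUE)
    agg$n_correct[is.na(agg$n_correct)] <- 0L
    agg$n_trials[is.na(agg$n_trials)] <- 0L
  }
  agg$proportion <- ifelse(agg$n_trials > 0, agg$n_correct / agg$n_trials,
                           NA_real_)
  ord <- do.call(order, agg[c(group_by, "category")])
  agg <- agg[ord, c(group_by, "category", "n_correct", "n_trials",
                    "proportion")]
  rownames(agg) <- NULL
  agg
}

#' Split repeated stimulus exposures into first and second presentations
#'
#' For each `(rater_id, session, image_condition, stimulus_id)` group the
#' trial with the earlier `trial_index` goes to the first set and the
#' later one to the second; a stimulus seen only once goes to the first
#' set. Three or more exposures of the same stimulus are an integrity
#' error. This is the split behind carryover (repetition) checks in
#' designs where each image is shown twice, once per presentation time.
#'
#' @param records Response data frame.
#' @return List with components `first` and `second`, both response data
#'   frames.
#' @seealso [run_carryover_check()]
#' @export
split_halves <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("split_halves needs a non-empty response table", call. = FALSE)
  key <- paste(records$rater_id, records$session, records$image_condition,
               records$stimulus_id, sep = "\r")
  n_per <- table(key)
  if (any(n_per > 2)) {
    offender <- names(n_per)[which(n_per > 2)[1]]
    stop("integrity error: stimulus presented more than twice for key ",
         dQuote(gsub("\r", "/", offender)), call. = FALSE)
  }
  ord <- order(key, records$trial_index)
  first_of_key <- !duplicated(key[ord])
  idx <- ord[first_of_key]
  list(first = records[sort(idx), , drop = FALSE],
       second = records[sort(ord[!first_of_key]), , drop = FALSE])
}
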