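#' Cohen's kappa for two aligned label sequences
#'
#' Unweighted chance-corrected agreement
#' \deqn{\kappa = (p_o - p_e) / (1 - p_e)}
#' where \eqn{p_o} is the observed proportion of identical labels and
#' \eqn{p_e} the agreement expected from the two raters' marginal label
#' frequencies. The label universe is the union of labels observed in
#' either sequence (with `UNKNOWN` as a first-class category when it
#' occurs). The standard error uses the classical large-sample
#' (Fleiss--Cohen--Everitt) variance for unweighted kappa and the
#' confidence interval is Wald, clamped to \eqn{[-1, 1]}.
#'
#' Degenerate marginals are resolved explicitly: if both raters are
#' constant with the same label (\eqn{p_o = p_e = 1}) kappa is 1; if
#' either rater is constant the result carries a `degenerate` flag.
#'
#' @param responses_a,responses_b Equal-length character vectors of
#'   labels, aligned item by item (same stimulus order).
#' @param ci_level Confidence level (default 0.95).
#' @return Object of class `kappa_result`: a list with `kappa`,
#'   `observed_agreement`, `expected_agreement`, `n_items`,
#'   `standard_error`, `ci_low`, `ci_high`, `ci_level`, `band`
#'   (Landis--Koch, see [kappa_band()]), `degenerate` and `labels`.
#' @references Cohen (1960); Fleiss, Cohen & Everitt (1969) for the
#'   large-sample variance; Landis & Koch (1977) for the bands.
#' @export
#' @examples
#' cohen_kappa(c("a", "a", "b", "b"), c("a", "b", "a", "b"))  # chance: 0
cohen_kappa <- function(responses_a, responses_b, ci_level = 0.95) {
  a <- as.character(responses_a)
  b <- as.character(responses_b)
  if (length(a) != length(b))
    stop("alignment error: sequences differ in length (", length(a),
         " vs ", length(b), ")", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("kappa needs at least 2 aligned items", call. = FALSE)
  if (anyNA(a) || anyNA(b))
    stop("alignment error: missing labels", call. = FALSE)
  labels <- sort(unique(c(a, b)))
  tab <- table(factor(a, levels = labels), factor(b, levels = labels))
  kappa_from_table(tab, ci_level = ci_level)
}

# Core computation from a square contingency table of counts.
kappa_from_table <- function(tab, ci_level = 0.95) {
  n <- sum(tab)
  p <- tab / n
  pi_ <- rowSums(p)   # marginals of rater A
  p_j <- colSums(p)   # marginals of rater B
  po <- sum(diag(p))
  pe <- sum(pi_ * p_j)
  degenerate <- any(pi_ == 1) || any(p_j == 1)
  if (pe >= 1) {               # both raters constant with the same label
    kappa <- 1
    se <- 0
  } else {
    kappa <- (po - pe) / (1 - pe)
    # Fleiss-Cohen-Everitt large-sample variance of unweighted kappa
    k_ <- nrow(p)
    termA <- sum(diag(p) * ((1 - pe) - (p_j + pi_) * (1 - po))^2)
    off <- p * outer(p_j, pi_, "+")^2   # entry (i,j): p_ij (p_.i + p_j.)^2
    termB <- (1 - po)^2 * (sum(off) - sum(diag(off)))
    termC <- (po * pe - 2 * pe + po)^2
    var_k <- (termA + termB - termC) / (n * (1 - pe)^4)
    se <- sqrt(max(var_k, 0))
  }
  z <- qnorm(1 - (1 - ci_level) / 2)
  structure(list(kappa = kappa, observed_agreement = po,
                 expected_agreement = pe, n_items = as.integer(n),
                 standard_error = se,
                 ci_low = max(-1, kappa - z * se),
                 ci_high = min(1, kappa + z * se),
                 ci_level = ci_level, band = kappa_band(kappa),
                 degenerate = degenerate,
                 labels = rownames(tab)),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.4f (%s agreement)\n", x$kappa,
              gsub("_", " ", x$band)))
  cat(sprintf("  p_o = %.4f, p_e = %.4f, n = %d items\n",
              x$observed_agreement, x$expected_agreement, x$n_items))
  cat(sprintf("  SE = %.4f, %d%% CI [%.4f, %.4f]%s\n", x$standard_error,
              round(100 * x$ci_level), x$ci_low, x$ci_high,
              if (x$degenerate) " (degenerate marginals)" else ""))
  invisible(x)
}

#' Landis--Koch qualitative band for a kappa value
#'
#' Values at or below 0 are "no" agreement; then slight (to 0.20), fair
#' (to 0.40), moderate (to 0.60), substantial (to 0.80) and almost
#' perfect (to 1).
#'
#' @param kappa Numeric vector in \eqn{[-1, 1]}.
#' @return Character vector of band labels.
#' @export
#' @examples
#' kappa_band(c(0.79, 0.88, -0.2))
kappa_band <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < -1 - 1e-12) ||
      any(kappa > 1 + 1e-12))
    stop("domain error: kappa must lie in [-1, 1]", call. = FALSE)
  bands <- c("no", "slight", "fair", "moderate", "substantial",
             "almost_perfect")
  bands[findInterval(kappa, c(-Inf, 0, 0.2, 0.4, 0.6, 0.8),
                     left.open = TRUE, rightmost.closed = FALSE)]
}

#' Pairwise kappa matrix over several raters
#'
#' Aligns every rater pair on the shared stimulus set and computes
#' [cohen_kappa()] per pair. All raters must cover the identical stimulus
#' set.
#'
#' @param raters Named list: one character vector of
#'   stimulus-identified labels per rater (all with identical `names()`
#'   in any order), or a named list of equal-length unnamed vectors
#'   already aligned.
#' @param ci_level Confidence level for per-pair CIs.
#' @return Object of class `kappa_matrix`: list with `kappa` (square
#'   symmetric numeric matrix, unit diagonal), `pairs` (long data frame:
#'   `rater_a`, `rater_b`, `kappa`, `se`, `ci_low`, `ci_high`, `band`,
#'   `n_items`) and `results` (list of `kappa_result` keyed
#'   `"a|b"`).
#' @export
pairwise_agreement_matrix <- function(raters, ci_level = 0.95) {
  stopifnot(is.list(raters), length(raters) >= 2, !is.null(names(raters)),
            !anyDuplicated(names(raters)))
  ids <- names(raters)
  stim <- names(raters[[1]])
  aligned <- lapply(raters, function(r) {
    if (is.null(stim) != is.null(names(r)) ||
        (!is.null(stim) && !setequal(names(r), stim)) ||
        (is.null(stim) && length(r) != length(raters[[1]])))
      stop("alignment error: raters cover different stimulus sets",
           call. = FALSE)
    if (is.null(stim)) as.character(r) else as.character(r[stim])
  })
  m <- length(ids)
  kap <- matrix(1, m, m, dimnames = list(ids, ids))
  results <- list()
  rows <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    res <- cohen_kappa(aligned[[i]], aligned[[j]], ci_level = ci_level)
    kap[i, j] <- kap[j, i] <- res$kappa
    results[[paste(ids[i], ids[j], sep = "|")]] <- res
    rows[[length(rows) + 1L]] <- data.frame(
      rater_a = ids[i], rater_b = ids[j], kappa = res$kappa,
      se = res$standard_error, ci_low = res$ci_low, ci_high = res$ci_high,
      band = res$band, n_items = res$n_items, stringsAsFactors = FALSE)
  }
  structure(list(kappa = kap, pairs = do.call(rbind, rows),
                 results = results),
            class = "kappa_matrix")
}

#' @export
print.kappa_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise Cohen's kappa (", nrow(x$kappa), " raters)\n", sep = "")
  print(round(x$kappa, digits))
  invisible(x)
}

# Align one rater's two sessions by stimulus and return the label pair.
align_sessions <- function(test, retest) {
  key <- function(d) paste(d$presentation, d$image_condition, d$stimulus_id,
                           sep = "\r")
  kt <- key(test); kr <- key(retest)
  if (!setequal(kt, kr) || anyDuplicated(kt) || anyDuplicated(kr))
    return(NULL)
  ord <- match(sort(kt), kt)
  list(a = test$response_category[ord],
       b = retest$response_category[match(sort(kt), kr)])
}

#' Test-retest (intra-rater) reliability
#'
#' For every participant present in both sessions, aligns their test and
#' retest responses by stimulus and computes [cohen_kappa()] against
#' themselves; reports the cohort median. Participants missing a session
#' or with mismatched stimulus sets are listed in `exclusions`, never
#' silently dropped.
#'
#' @param test_records,retest_records Response data frames for the two
#'   sessions (may be the same table; it is split on the `session`
#'   column).
#' @param ci_level Confidence level for per-participant CIs.
#' @return List with `results` (named list of `kappa_result`), `table`
#'   (data frame: `rater_id`, `kappa`, `se`, `ci_low`, `ci_high`, `band`,
#'   `n_items`), `median_kappa` and `exclusions` (character vector).
#' @export
intra_rater_reliability <- function(test_records, retest_records = NULL,
                                    ci_level = 0.95) {
  if (is.null(retest_records)) {
    retest_records <- test_records[test_records$session == "retest", ,
                                   drop = FALSE]
    test_records <- test_records[test_records$session == "test", ,
                                 drop = FALSE]
  }
  ids <- sort(unique(c(test_records$rater_id, retest_records$rater_id)))
  results <- list()
  rows <- list()
  exclusions <- character(0)
  for (id in ids) {
    te <- test_records[test_records$rater_id == id, , drop = FALSE]
    re <- retest_records[retest_records$rater_id == id, , drop = FALSE]
    if (nrow(te) == 0 || nrow(re) == 0) {
      exclusions <- c(exclusions, id)
      next
    }
    pair <- align_sessions(te, re)
    if (is.null(pair)) {
      exclusions <- c(exclusions, id)
      next
    }
    res <- cohen_kappa(pair$a, pair$b, ci_level = ci_level)
    results[[id]] <- res
    rows[[length(rows) + 1L]] <- data.frame(
      rater_id = id, kappa = res$kappa, se = res$standard_error,
      ci_low = res$ci_low, ci_high = res$ci_high, band = res$band,
      n_items = res$n_items, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rater_id = character(0), kappa = numeric(0),
               se = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
               band = character(0), n_items = integer(0))
  list(results = results, table = tab,
       median_kappa = if (nrow(tab)) median(tab$kappa) else NA_real_,
       exclusions = exclusions)
}
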