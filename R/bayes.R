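#' @name jzs-bayes-factor
#' @title Default (JZS) Bayes-factor t tests
#'
#' @description
#' Bayes factors for the standard t-test situations under the
#' Jeffreys--Zellner--Siow default prior: the standardised effect size
#' \eqn{\delta} follows a Cauchy(0, r) prior under H1 (equivalently
#' \eqn{\delta | g \sim N(0, g r^2)} with \eqn{g} inverse-chi-squared),
#' and \eqn{\delta = 0} under H0. The Bayes factor depends on the data
#' only through the t statistic, the degrees of freedom and the
#' effective sample size, and is computed by adaptive one-dimensional
#' quadrature of the g-integral on a transformed bounded domain with
#' log-space accumulation, so it is stable for large |t|.
#'
#' The default prior scale is \eqn{r = \sqrt{2}/2 \approx 0.707}, the
#' conventional "medium" default of this test family.
NULL

# log integrand of the JZS g-integral at g = u/(1-u), including the
# Jacobian of the u-transform. neff = effective sample size, nu = df.
jzs_log_integrand <- function(u, t, neff, nu, r) {
  g <- u / (1 - u)
  s <- 1 + neff * r^2 * g
  -0.5 * log(s) - (nu + 1) / 2 * log1p(t^2 / (s * nu)) -
    0.5 * log(2 * pi) - 1.5 * log(g) - 1 / (2 * g) - 2 * log(1 - u)
}

# BF10 from (t, neff, nu, r) by adaptive quadrature in log space.
jzs_bf10 <- function(t, neff, nu, r) {
  stopifnot(is.finite(t), neff > 0, nu >= 1, r > 0)
  # locate the integrand's scale on a coarse grid, then integrate the
  # shifted integrand so exp() cannot overflow/underflow
  grid <- seq(1e-6, 1 - 1e-6, length.out = 201)
  shift <- max(jzs_log_integrand(grid, t, neff, nu, r))
  val <- integrate(function(u)
    exp(jzs_log_integrand(u, t, neff, nu, r) - shift),
    0, 1, rel.tol = 1e-10, abs.tol = 0, subdivisions = 500L)
  log_alt_kernel <- shift + log(val$value)
  log_null_kernel <- -(nu + 1) / 2 * log1p(t^2 / nu)
  lognorm <- lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi)
  list(bf10 = exp(log_alt_kernel - log_null_kernel),
       log_marginal_alt = log_alt_kernel + lognorm,
       log_marginal_null = log_null_kernel + lognorm)
}

new_bf_result <- function(bf, t, n1, n2, r, test) {
  structure(list(bf10 = bf$bf10, bf01 = 1 / bf$bf10, t_statistic = t,
                 n1 = n1, n2 = n2, prior_scale = r,
                 log_marginal_alt = bf$log_marginal_alt,
                 log_marginal_null = bf$log_marginal_null,
                 grade = bf_evidence_label(bf$bf10), test = test),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("JZS Bayes factor (%s test, r = %.3f)\n", x$test,
              x$prior_scale))
  cat(sprintf("  BF10 = %.4g%s  (t = %.3f, n = %s)\n", x$bf10,
              x$grade$marks, x$t_statistic,
              if (is.null(x$n2)) x$n1 else paste(x$n1, x$n2, sep = ", ")))
  cat("  ", x$grade$grade, "\n", sep = "")
  invisible(x)
}

#' Paired / one-sample JZS Bayes-factor t test
#'
#' Tests whether the mean of the supplied differences is zero. The
#' result is invariant to rescaling the data (it depends only on t
#' and n).
#'
#' @param differences Numeric vector of paired differences (or a single
#'   sample tested against zero).
#' @param prior_scale Cauchy prior scale r (default `sqrt(2)/2`).
#' @return Object of class `bf_result` with elements `bf10`, `bf01`,
#'   `t_statistic`, `n1`, `n2` (`NULL` here), `prior_scale`,
#'   `log_marginal_alt`, `log_marginal_null` and `grade`
#'   (see [bf_evidence_label()]).
#' @seealso [jzs_bf_two_sample()], [compare_accuracies()]
#' @export
#' @examples
#' jzs_bf_paired(c(0.1, 0.3, -0.05, 0.2, 0.15, 0.25))
jzs_bf_paired <- function(differences, prior_scale = sqrt(2) / 2) {
  d <- as.numeric(differences)
  if (length(d) < 2)
    stop("domain error: need at least 2 differences", call. = FALSE)
  if (anyNA(d) || any(!is.finite(d)))
    stop("input error: non-finite differences", call. = FALSE)
  n <- length(d)
  s <- sd(d)
  if (s == 0) {
    if (mean(d) != 0)
      stop("domain error: all differences identical and nonzero ",
           "(t statistic undefined)", call. = FALSE)
    t <- 0
  } else t <- mean(d) / (s / sqrt(n))
  bf <- jzs_bf10(t, neff = n, nu = n - 1, r = prior_scale)
  new_bf_result(bf, t, n1 = n, n2 = NULL, r = prior_scale, test = "paired")
}

#' Two-sample JZS Bayes-factor t test
#'
#' Pooled-variance two-sample t with effective sample size
#' \eqn{n_1 n_2 / (n_1 + n_2)} and \eqn{n_1 + n_2 - 2} degrees of
#' freedom; symmetric in the two groups.
#'
#' @param x,y Numeric vectors for the two groups.
#' @inheritParams jzs_bf_paired
#' @return Object of class `bf_result`.
#' @export
jzs_bf_two_sample <- function(x, y, prior_scale = sqrt(2) / 2) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2)
    stop("domain error: both groups need at least 2 observations",
         call. = FALSE)
  if (anyNA(c(x, y)) || any(!is.finite(c(x, y))))
    stop("input error: non-finite values", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  nu <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / nu
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (mean(x) != mean(y))
      stop("domain error: zero pooled variance with unequal means",
           call. = FALSE)
    t <- 0
  } else t <- (mean(x) - mean(y)) / se
  bf <- jzs_bf10(t, neff = n1 * n2 / (n1 + n2), nu = nu, r = prior_scale)
  new_bf_result(bf, t, n1 = n1, n2 = n2, r = prior_scale,
                test = "two_sample")
}

#' Evidence grade and significance marks for a Bayes factor
#'
#' Significance marks follow the BF > 3 / 10 / 100 convention
#' (`"*"`, `"**"`, `"***"`); the descriptive grade follows the
#' Jeffreys-style wording, symmetric around 1: values in (1/3, 1) are
#' anecdotal evidence for the null, (1/10, 1/3\] moderate, (1/30, 1/10\]
#' strong, (1/100, 1/30\] very strong and below 1/100 extreme, with the
#' mirrored wording above 1; exactly 1 is inconclusive.
#'
#' @param bf10 Positive numeric scalar.
#' @return List with `marks` (`""`, `"*"`, `"**"` or `"***"`),
#'   `grade` (descriptive sentence fragment) and `direction`
#'   (`"H1"`, `"H0"` or `"none"`).
#' @export
#' @examples
#' bf_evidence_label(0.23)$grade  # moderate evidence for the null
bf_evidence_label <- function(bf10) {
  if (!is.numeric(bf10) || length(bf10) != 1 || !is.finite(bf10) ||
      bf10 <= 0)
    stop("domain error: bf10 must be a positive number", call. = FALSE)
  marks <- if (bf10 > 100) "***" else if (bf10 > 10) "**" else
    if (bf10 > 3) "*" else ""
  strength <- function(b) {
    if (b >= 100) "extreme" else if (b >= 30) "very strong" else
      if (b >= 10) "strong" else if (b >= 3) "moderate" else "anecdotal"
  }
  if (bf10 == 1) {
    grade <- "inconclusive"
    direction <- "none"
  } else if (bf10 > 1) {
    grade <- paste(strength(bf10), "evidence for an effect")
    direction <- "H1"
  } else {
    grade <- paste(strength(1 / bf10), "evidence for the null")
    direction <- "H0"
  }
  list(marks = marks, grade = grade, direction = direction)
}

#' Bayes-factor comparison of human and model accuracies
#'
#' Compares participant-level accuracy proportions against a model's
#' accuracy, per category or overall, within matching condition cells
#' (`presentation` x `image_condition`). Two test variants are exposed,
#' since a deterministic network can be treated either way: the
#' `one_sample` variant (default) treats the model's accuracy as a known
#' constant and runs a one-sample JZS test on the human accuracies minus
#' that constant; the `two_sample` variant treats the model's
#' per-category accuracies as a second sample (only meaningful with
#' `scope = "overall"`, where the model contributes one value per
#' category). The variant used is recorded in the output.
#'
#' @param human_table,model_table Accuracy tables from
#'   [compute_accuracy()]; the human table must hold one row per
#'   participant x category x condition, the model table one rater.
#' @param scope `"per_category"` (one test per category and condition
#'   cell) or `"overall"` (participant accuracies pooled over
#'   categories).
#' @param test `"one_sample"` or `"two_sample"`.
#' @param prior_scale Cauchy prior scale.
#' @return Data frame with the condition columns, `category` (or
#'   `"overall"`), `n_humans`, `human_mean`, `model_accuracy`,
#'   `difference` (human minus model), `t`, `bf10`, `grade`, `marks` and
#'   `test`.
#' @export
compare_accuracies <- function(human_table, model_table,
                               scope = c("per_category", "overall"),
                               test = c("one_sample", "two_sample"),
                               prior_scale = sqrt(2) / 2) {
  scope <- match.arg(scope)
  test <- match.arg(test)
  need <- c("rater_id", "presentation", "image_condition", "category",
            "n_correct", "n_trials")
  stopifnot(all(need %in% names(human_table)),
            all(need %in% names(model_table)))
  if (length(unique(model_table$rater_id)) != 1)
    stop("model_table must describe a single model rater", call. = FALSE)
  cells <- unique(human_table[c("presentation", "image_condition")])
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    hsub <- merge(human_table, cells[ci, , drop = FALSE])
    msub <- merge(model_table, cells[ci, , drop = FALSE])
    if (nrow(msub) == 0)
      stop("alignment error: model lacks condition cell ",
           paste(unlist(cells[ci, ]), collapse = "/"), call. = FALSE)
    if (scope == "per_category") {
      cats <- sort(unique(hsub$category))
      if (!all(cats %in% msub$category))
        stop("alignment error: model lacks categories ",
             paste(setdiff(cats, msub$category), collapse = ", "),
             call. = FALSE)
      for (cat in cats) {
        h <- hsub[hsub$category == cat & hsub$n_trials > 0, , drop = FALSE]
        hacc <- h$n_correct / h$n_trials
        macc <- msub$n_correct[msub$category == cat] /
          msub$n_trials[msub$category == cat]
        res <- jzs_bf_paired(hacc - macc, prior_scale = prior_scale)
        rows[[length(rows) + 1L]] <- data.frame(
          cells[ci, , drop = FALSE], category = cat,
          n_humans = length(hacc), human_mean = mean(hacc),
          model_accuracy = macc, difference = mean(hacc) - macc,
          t = res$t_statistic, bf10 = res$bf10,
          grade = res$grade$grade, marks = res$grade$marks,
          test = "one_sample", stringsAsFactors = FALSE)
      }
    } else {
      hagg <- aggregate(list(n_correct = hsub$n_correct,
                             n_trials = hsub$n_trials),
                        by = list(rater_id = hsub$rater_id), FUN = sum)
      hacc <- hagg$n_correct / hagg$n_trials
      if (test == "two_sample") {
        macc_per_cat <- msub$n_correct / msub$n_trials
        res <- jzs_bf_two_sample(hacc, macc_per_cat,
                                 prior_scale = prior_scale)
        macc <- sum(msub$n_correct) / sum(msub$n_trials)
      } else {
        macc <- sum(msub$n_correct) / sum(msub$n_trials)
        res <- jzs_bf_paired(hacc - macc, prior_scale = prior_scale)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cells[ci, , drop = FALSE], category = "overall",
        n_humans = length(hacc), human_mean = mean(hacc),
        model_accuracy = macc, difference = mean(hacc) - macc,
        t = res$t_statistic, bf10 = res$bf10,
        grade = res$grade$grade, marks = res$grade$marks,
        test = test, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
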