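# Multicriteria model evaluation: percentile sweep over per-sample CCL
# values, partial accuracy on the retained subset, and the combined measure
#   m_p = a_p * (n_p / N) * t_p,   m = max_p m_p,  p = 1..99,
# where t_p is the p-th percentile of the CCL values, n_p the number of
# samples with CCL strictly greater than t_p, and a_p the accuracy over
# those samples. m rewards models that are accurate with high anatomical
# confidence over as much of the dataset as possible.

#' Percentile of a set of CCL values
#'
#' @param values non-empty numeric vector of CCL values.
#' @param p percentile index, 1-99.
#' @param method percentile method: `"linear"` interpolates between order
#'   statistics (`stats::quantile` type 7, the default), `"nearest"` uses
#'   the nearest order statistic (type 3). m is threshold-sensitive, so the
#'   method is exposed.
#' @return the threshold `t_p`.
#' @export
ccl_percentile <- function(values, p, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (length(values) == 0) stop("empty CCL vector")
  stopifnot(p >= 1, p <= 99)
  unname(stats::quantile(values, probs = p / 100,
                         type = if (method == "linear") 7L else 3L))
}

#' Percentile sweep of the multicriteria measure
#'
#' For every percentile p in `percentiles`, thresholds the dataset at the
#' p-th percentile of CCL values, keeps samples with CCL strictly greater,
#' and records the subset size `n_p`, partial accuracy `a_p` (0 for an empty
#' subset) and `m_p = a_p * (n_p / N) * t_p`.
#'
#' @param ccl_values numeric vector of per-sample CCL values.
#' @param correct logical vector: was the sample classified correctly?
#' @param percentiles integer percentiles to sweep (default 1:99).
#' @param method percentile method, see [ccl_percentile()].
#' @return a tibble with columns `p`, `t_p`, `n_p`, `a_p`, `m_p`.
#' @export
ccl_sweep <- function(ccl_values, correct, percentiles = 1:99,
                      method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (length(ccl_values) != length(correct))
    stop("ccl_values and correct differ in length")
  if (length(ccl_values) == 0) stop("empty dataset")
  stopifnot(is.logical(correct) || all(correct %in% c(0, 1)))
  correct <- as.logical(correct)
  N <- length(ccl_values)
  t_p <- vapply(percentiles, function(p)
    ccl_percentile(ccl_values, p, method), numeric(1))
  n_p <- vapply(t_p, function(th) sum(ccl_values > th), integer(1))
  a_p <- vapply(t_p, function(th) {
    keep <- ccl_values > th
    if (!any(keep)) 0 else mean(correct[keep])
  }, numeric(1))
  tibble::tibble(p = as.integer(percentiles), t_p = t_p, n_p = n_p,
                 a_p = a_p, m_p = a_p * (n_p / N) * t_p)
}

#' Multicriteria evaluation of a classification model
#'
#' Runs the percentile sweep and maximizes `m_p` over p; ties are broken
#' towards the smallest p (the largest retained dataset).
#'
#' @inheritParams ccl_sweep
#' @return an object of class `usconf_eval` with fields `m`, `p_opt`,
#'   `sweep` (tibble), `N`, and at the optimum `a_opt`, `n_opt`, `t_opt`,
#'   `coverage` (= `n_opt / N`).
#' @export
evaluate_model <- function(ccl_values, correct, percentiles = 1:99,
                           method = c("linear", "nearest")) {
  sw <- ccl_sweep(ccl_values, correct, percentiles, method)
  i_opt <- which.max(sw$m_p)   # which.max takes the first maximum: smallest p
  structure(list(m = sw$m_p[i_opt], p_opt = sw$p[i_opt], sweep = sw,
                 N = length(ccl_values), a_opt = sw$a_p[i_opt],
                 n_opt = sw$n_p[i_opt], t_opt = sw$t_p[i_opt],
                 coverage = sw$n_p[i_opt] / length(ccl_values)),
            class = "usconf_eval")
}

#' @export
print.usconf_eval <- function(x, ...) {
  cat(sprintf(paste0("<usconf_eval> m = %.4f at p_opt = %d ",
                     "(accuracy %.3f over %.1f%% of %d samples, ",
                     "CCL threshold %.3f)\n"),
              x$m, x$p_opt, x$a_opt, 100 * x$coverage, x$N, x$t_opt))
  invisible(x)
}

#' Tidy the percentile sweep of a model evaluation
#'
#' @param x a `usconf_eval` object.
#' @param ... unused.
#' @return the sweep tibble (`p`, `t_p`, `n_p`, `a_p`, `m_p`).
#' @export
tidy.usconf_eval <- function(x, ...) x$sweep

#' One-row summary of a model evaluation
#'
#' @param x a `usconf_eval` object.
#' @param ... unused.
#' @return a one-row tibble with `m`, `p_opt`, `a_opt`, `coverage`, `t_opt`,
#'   `n_opt`, `N`.
#' @export
glance.usconf_eval <- function(x, ...) {
  tibble::tibble(m = x$m, p_opt = x$p_opt, a_opt = x$a_opt,
                 coverage = x$coverage, t_opt = x$t_opt,
                 n_opt = x$n_opt, N = x$N)
}

#' Plot the percentile sweep
#'
#' Shows `t_p`, `n_p / N`, `a_p` and `m_p` as functions of the cutoff
#' percentile p, with the optimum marked.
#'
#' @param object a `usconf_eval` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.usconf_eval <- function(object, ...) {
  sw <- object$sweep
  long <- tidyr::pivot_longer(
    dplyr::mutate(sw, coverage = .data$n_p / object$N),
    cols = c("t_p", "coverage", "a_p", "m_p"),
    names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure,
                         levels = c("a_p", "coverage", "t_p", "m_p"),
                         labels = c("partial accuracy a_p",
                                    "retained fraction n_p/N",
                                    "CCL threshold t_p",
                                    "multicriteria m_p"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$p, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$p_opt, linetype = "dashed") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "cutoff percentile p", y = NULL,
                  title = sprintf("m = %.3f at p = %d", object$m,
                                  object$p_opt)) +
    ggplot2::theme_minimal()
}
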