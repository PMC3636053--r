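#' Empirical false-positive distribution by random bipartition of one class
#'
#' Patients of a single class are split at random into two pseudo-groups of
#' sizes `floor(n/2)` and `ceiling(n/2)` (every patient used each round,
#' sampling without replacement), the permutation t-test is run on the
#' pseudo-labels, and the number of features passing the significance
#' threshold is recorded. Because both pseudo-groups come from one phenotype,
#' every selected feature is a false positive; the distribution of counts
#' over rounds is the empirical false-positive behaviour of the profiling
#' pipeline.
#'
#' When the inner permutation test is exhaustive (few patients, so all
#' balanced assignments are enumerable), the assignment-by-feature t-matrix
#' is computed once and each round's p-values are exact rank lookups in it —
#' numerically identical to re-running the test every round.
#'
#' @param sig A `psp_signature` tibble (may contain both classes).
#' @param class Which class label to bipartition; defaults to the larger
#'   class.
#' @param n_rounds Number of random bipartitions (default 10000).
#' @param alpha Significance threshold (default 0.05).
#' @param bh Threshold BH q-values instead of raw p (default TRUE, matching
#'   the false-positive protocol).
#' @param n_perm Inner permutations per round (default 1000; exhaustive
#'   enumeration replaces it whenever possible).
#' @param seed Integer RNG seed.
#' @inheritParams permutation_pvalue
#' @return Object of class `psp_fp`: list with `counts` (integer vector, one
#'   per round), `summary` (mean / median / mode tibble; ties on the mode
#'   report the smallest, all tied values listed), `histogram` (absolute and
#'   normalised), and the call parameters.
#' @export
fp_distribution <- function(sig, class = NULL, n_rounds = 10000, alpha = 0.05,
                            bh = TRUE, n_perm = 1000, seed,
                            alternative = c("signed", "two.sided"),
                            ties = c("strict", "midp")) {
  alternative <- match.arg(alternative)
  ties <- match.arg(ties)
  if (n_rounds < 1) stop_data("n_rounds must be >= 1")
  if (missing(seed)) stop_data("fp_distribution requires an explicit seed")
  if (is.null(class)) {
    tab <- table(sig$class)
    class <- names(tab)[which.max(tab)]
  }
  sub <- sig[sig$class == class, ]
  n <- nrow(sub)
  if (n < 4) stop_data("false-positive analysis needs a class of >= 4 patients")
  nA <- floor(n / 2)
  x <- sig_matrix(sub)
  set.seed(seed)

  exhaustive <- choose(n, nA) <= n_perm
  counts <- integer(n_rounds)
  skipped <- 0L
  if (exhaustive) {
    asg <- label_assignments(rep(c(TRUE, FALSE), c(nA, n - nA)), n_perm)
    t_all <- assignment_t(asg$assign, x)          # M x F, all balanced splits
    M <- nrow(t_all)
    for (r in seq_len(n_rounds)) {
      obs <- sample.int(M, 1)                      # random split = random row
      p <- perm_p_from_null(t_all[obs, ], t_all, alternative, ties, self = TRUE)
      pass <- if (bh) bh_adjust(p) <= alpha else p <= alpha
      counts[r] <- sum(pass)
    }
  } else {
    for (r in seq_len(n_rounds)) {
      grp_a <- sample.int(n, nA)
      pseudo <- sub
      pseudo$class <- ifelse(seq_len(n) %in% grp_a, "pseudo_A", "pseudo_B")
      if (nA < 2 || n - nA < 2) { skipped <- skipped + 1L; counts[r] <- NA; next }
      res <- permutation_test(pseudo, n_perm = n_perm, seed = NULL,
                              alternative = alternative, ties = ties)
      pass <- if (bh) res$q_bh <= alpha else res$p_perm <= alpha
      counts[r] <- sum(pass)
    }
    if (skipped > 0)
      rlang::warn(sprintf("%d round(s) skipped: degenerate subgroup sizes", skipped))
  }
  ok <- counts[!is.na(counts)]
  tabc <- table(ok)
  modes <- as.integer(names(tabc)[tabc == max(tabc)])
  hist <- tibble::tibble(
    count = as.integer(names(tabc)),
    n = as.integer(tabc),
    frequency = as.integer(tabc) / length(ok)
  )
  structure(list(
    counts = counts,
    summary = tibble::tibble(mean = mean(ok), median = stats::median(ok),
                             mode = min(modes), modes = list(sort(modes)),
                             n_rounds_used = length(ok), n_skipped = skipped),
    histogram = hist,
    class = class, n_patients = n, n_features = ncol(x),
    alpha = alpha, bh = bh, alternative = alternative, ties = ties,
    n_perm = n_perm, exhaustive = exhaustive, seed = seed
  ), class = "psp_fp")
}

#' @export
print.psp_fp <- function(x, ...) {
  cat(sprintf(
    "False-positive distribution: class '%s' (%d patients), %d features, %d rounds\n",
    x$class, x$n_patients, x$n_features, sum(!is.na(x$counts))))
  print(x$summary, ...)
  invisible(x)
}

#' Tidy / glance methods for false-positive distributions
#'
#' `tidy()` returns the histogram (absolute counts and frequencies summing to
#' one); `glance()` the one-row summary.
#'
#' @param x A `psp_fp` object.
#' @param ... Unused.
#' @method tidy psp_fp
#' @export
tidy.psp_fp <- function(x, ...) x$histogram

#' @rdname tidy.psp_fp
#' @method glance psp_fp
#' @export
glance.psp_fp <- function(x, ...) {
  dplyr::bind_cols(x$summary[, c("mean", "median", "mode")],
                   tibble::tibble(n_rounds_used = x$summary$n_rounds_used,
                                  n_features = x$n_features, alpha = x$alpha,
                                  bh = x$bh, seed = x$seed))
}

#' Histogram of false-positive counts (absolute and normalised panels)
#'
#' @param object A `psp_fp` object.
#' @param ... Unused.
#' @method autoplot psp_fp
#' @export
autoplot.psp_fp <- function(object, ...) {
  long <- tidyr::pivot_longer(object$histogram, cols = c("n", "frequency"),
                              names_to = "panel", values_to = "value")
  long$panel <- factor(long$panel, c("n", "frequency"),
                       c("absolute count", "normalised to 1"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$count, y = .data$value,
                                     fill = .data$panel)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::scale_fill_manual(values = c("firebrick", "purple")) +
    ggplot2::labs(x = "significant features per round", y = NULL) +
    ggplot2::theme_minimal()
}
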