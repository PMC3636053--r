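#' Two-sample pooled t-statistic between hit-rate lists
#'
#' `t = (mean(HA) - mean(HB)) / (S_pooled * sqrt(1/n + 1/m))` with the pooled
#' standard deviation built from the (m-1)/(n-1)-denominator sample variances.
#' Degenerate inputs follow the permutation machinery's needs: zero pooled
#' variance with equal means gives 0; zero pooled variance with different
#' means gives a signed infinity sentinel.
#'
#' @param HA,HB Numeric vectors (each of length >= 2) of hit rates for the
#'   two classes.
#' @return A single number (possibly `Inf`/`-Inf`).
#' @export
t_statistic <- function(HA, HB) {
  m <- length(HA); n <- length(HB)
  stopifnot(m >= 2, n >= 2)
  diff <- mean(HA) - mean(HB)
  sp <- sqrt(((m - 1) * stats::var(HA) + (n - 1) * stats::var(HB)) / (m + n - 2))
  if (sp == 0) {
    if (diff == 0) return(0)
    return(sign(diff) * Inf)
  }
  diff / (sp * sqrt(1 / n + 1 / m))
}

# Enumerate (exhaustive) or sample (Monte Carlo) class-label assignments that
# preserve group sizes. Returns a logical matrix (rows = assignments, cols =
# samples, TRUE = "class A"), plus whether it is the full enumeration.
label_assignments <- function(is_a, n_perm) {
  n <- length(is_a); nA <- sum(is_a)
  n_total <- choose(n, nA)
  if (n_total <= n_perm) {
    idx <- utils::combn(n, nA)
    mat <- matrix(FALSE, ncol(idx), n)
    mat[cbind(rep(seq_len(ncol(idx)), each = nA), as.vector(idx))] <- TRUE
    list(assign = mat, exhaustive = TRUE)
  } else {
    mat <- matrix(FALSE, n_perm, n)
    for (i in seq_len(n_perm)) mat[i, sample.int(n, nA)] <- TRUE
    list(assign = mat, exhaustive = FALSE)
  }
}

# t-statistics for every assignment (rows) x every feature (columns), via
# group-sum matrix products. x: samples x features matrix.
assignment_t <- function(assign, x) {
  n <- nrow(x)
  nA <- sum(assign[1, ])
  nB <- n - nA
  A <- matrix(as.numeric(assign), nrow(assign), n)
  sA <- A %*% x
  qA <- A %*% (x^2)
  tot <- matrix(colSums(x), nrow(A), ncol(x), byrow = TRUE)
  tot2 <- matrix(colSums(x^2), nrow(A), ncol(x), byrow = TRUE)
  mA <- sA / nA
  mB <- (tot - sA) / nB
  vA <- pmax(qA - nA * mA^2, 0) / (nA - 1)
  vB <- pmax(tot2 - qA - nB * mB^2, 0) / (nB - 1)
  sp <- sqrt(((nA - 1) * vA + (nB - 1) * vB) / (n - 2))
  tt <- (mA - mB) / (sp * sqrt(1 / nA + 1 / nB))
  # zero pooled sd: equal means -> 0, different means -> signed Inf
  deg <- sp == 0
  if (any(deg)) tt[deg] <- sign((mA - mB)[deg]) * Inf
  tt[is.nan(tt)] <- 0
  tt
}

# Row index of the observed assignment within an enumeration matrix.
observed_row <- function(assign, is_a) {
  which(rowSums(assign == matrix(is_a, nrow(assign), length(is_a),
                                 byrow = TRUE)) == length(is_a))[1]
}

# p-values for observed t's (vector, one per feature) against a null t matrix
# (assignments x features). `self` says the observed assignment is one of the
# null rows (exhaustive mode) so its tie with itself is discounted.
perm_p_from_null <- function(t_obs, t_null, alternative, ties, self) {
  M <- nrow(t_null)
  obs <- matrix(t_obs, M, length(t_obs), byrow = TRUE)
  if (alternative == "two.sided") {
    gt <- colSums(abs(t_null) > abs(obs))
    eq <- colSums(abs(t_null) == abs(obs)) - as.integer(self)
  } else {
    neg <- t_obs < 0
    gt_hi <- colSums(t_null > obs)
    gt_lo <- colSums(t_null < obs)
    gt <- ifelse(neg, gt_lo, gt_hi)
    eq <- colSums(t_null == obs) - as.integer(self)
  }
  eq <- pmax(eq, 0)
  if (ties == "midp") (gt + 0.5 * eq) / M else gt / M
}

#' Empirical permutation p-value for one feature column
#'
#' Class labels are permuted preserving group sizes and the t-statistic is
#' recomputed each time. The default tail rule follows the sign of the
#' observed statistic: for negative (positive) t the p-value is the fraction
#' of null statistics strictly smaller (greater) than it. That rule is
#' faithful to common practice in signature profiling but is a one-tailed
#' test chosen by the data, so its type-I rate on null data is about twice
#' the nominal level, and the strict inequality makes it anti-conservative
#' under the heavy ties of discrete hit rates. `alternative = "two.sided"`
#' with `ties = "midp"` (half-weight to ties) is the calibrated variant; see
#' the methods vignette.
#'
#' When fewer distinct group-size-preserving assignments exist than `n_perm`,
#' the full enumeration is used instead (exact p; the observed assignment is
#' part of the enumeration and never counted against itself).
#'
#' @param x Numeric hit-rate vector, one value per patient.
#' @param labels Two-level class label vector aligned with `x` (each class
#'   size >= 2).
#' @param n_perm Number of label permutations (default 10000).
#' @param seed RNG seed (per-feature seeding keeps results independent of
#'   evaluation order); ignored in exhaustive mode, which is deterministic.
#' @param alternative `"signed"` (default, the sign-adaptive tail rule) or
#'   `"two.sided"`.
#' @param ties `"strict"` (default; ties excluded from the tail count) or
#'   `"midp"` (ties counted with weight 1/2).
#' @return The p-value, with attributes `n_perm_used` and `exhaustive`.
#' @export
permutation_pvalue <- function(x, labels, n_perm = 10000, seed = NULL,
                               alternative = c("signed", "two.sided"),
                               ties = c("strict", "midp")) {
  alternative <- match.arg(alternative)
  ties <- match.arg(ties)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop_data("permutation test needs exactly 2 classes")
  is_a <- labels == classes[1]
  if (sum(is_a) < 2 || sum(!is_a) < 2)
    stop_data("permutation test needs >= 2 samples per class")
  if (!is.null(seed)) set.seed(seed)
  asg <- label_assignments(is_a, n_perm)
  t_null <- assignment_t(asg$assign, matrix(x, ncol = 1))[, 1]
  # in exhaustive mode the observed assignment is a row of the enumeration;
  # taking t_obs from it keeps tie comparisons exact
  t_obs <- if (asg$exhaustive)
    t_null[observed_row(asg$assign, is_a)]
  else assignment_t(matrix(is_a, nrow = 1), matrix(x, ncol = 1))[1, 1]
  p <- perm_p_from_null(t_obs, matrix(t_null, ncol = 1),
                        alternative, ties, self = asg$exhaustive)
  structure(unname(p), n_perm_used = nrow(asg$assign),
            exhaustive = asg$exhaustive)
}

#' Permutation t-test over all features of a signature matrix
#'
#' Vectorised version of [permutation_pvalue()]: one set of label assignments
#' is drawn (or fully enumerated) and applied to every feature column, so the
#' result is reproducible and independent of feature evaluation order.
#'
#' @param sig A `psp_signature` tibble.
#' @inheritParams permutation_pvalue
#' @param seed RNG seed used for the shared assignment draw (Monte Carlo mode
#'   only).
#' @return Tibble: `feature_id`, `t_score`, `p_perm`, `q_bh`, `constant`
#'   (TRUE when the feature is identical across all patients, where the
#'   strict rule degenerates to p = 0), `n_perm_used`, `exhaustive`.
#' @export
permutation_test <- function(sig, n_perm = 10000, seed = NULL,
                             alternative = c("signed", "two.sided"),
                             ties = c("strict", "midp")) {
  alternative <- match.arg(alternative)
  ties <- match.arg(ties)
  classes <- sort(unique(sig$class))
  if (length(classes) != 2) stop_data("permutation test needs exactly 2 classes")
  is_a <- sig$class == classes[1]
  if (sum(is_a) < 2 || sum(!is_a) < 2)
    stop_data("permutation test needs >= 2 samples per class")
  x <- sig_matrix(sig)
  if (!is.null(seed)) set.seed(seed)
  asg <- label_assignments(is_a, n_perm)
  t_null <- assignment_t(asg$assign, x)
  t_obs <- if (asg$exhaustive) t_null[observed_row(asg$assign, is_a), ]
           else assignment_t(matrix(is_a, nrow = 1), x)[1, ]
  p <- perm_p_from_null(t_obs, t_null, alternative, ties, self = asg$exhaustive)
  tibble::tibble(
    feature_id = colnames(x),
    t_score = unname(t_obs),
    p_perm = unname(p),
    q_bh = bh_adjust(p),
    constant = apply(x, 2, function(v) all(v == v[1])),
    n_perm_used = nrow(asg$assign),
    exhaustive = asg$exhaustive
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as an explicit
#' operation so the selection and false-positive protocols name the
#' correction they use.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' iTRAQ-ratio ranking score of a feature for one patient class
#'
#' For every (member protein, patient) pair where the patient reports the
#' protein with ratio `r`, ratios below 1 are inverted (`1/r`; a ratio and its
#' reciprocal contribute identically) and the excess over 1 is accumulated:
#' `S = sum(max(r, 1/r) - 1)`. To stop large features winning on membership
#' count alone, the final score divides `S` by the number of *distinct* member
#' proteins reported by at least one patient of the class — not by the
#' feature size. No reported member gives score 0.
#'
#' @param profiles Profile tibble restricted to a single class (ratios
#'   attached); an error is raised if more than one class label is present.
#' @param members Character vector of feature member proteins.
#' @return One-row tibble: `s_raw` (the unnormalised score `S`), `score`
#'   (`S` divided by the unique-reported-protein count), `n_reported`.
#' @export
rank_score <- function(profiles, members) {
  if (length(unique(profiles$class)) > 1)
    stop_data("rank_score expects profiles of a single class")
  members <- unique(members)
  reported <- character(0)
  s <- 0
  for (i in seq_len(nrow(profiles))) {
    r <- profiles$ratios[[i]]
    if (is.null(r) || length(r) == 0) next
    r <- r[names(r) %in% members]
    if (length(r) == 0) next
    if (any(r <= 0)) stop_data("nonpositive iTRAQ ratio for patient %s",
                               profiles$patient_id[i])
    adj <- ifelse(r < 1, 1 / r, r)
    s <- s + sum(adj - 1)
    reported <- union(reported, names(r))
  }
  u <- length(reported)
  tibble::tibble(s_raw = s, score = if (u == 0) 0 else s / u, n_reported = u)
}

#' Differential-feature selection with permutation p-values and ranking scores
#'
#' Runs the permutation t-test over all features of a signature matrix, and
#' (when ratio-annotated profiles are supplied) attaches the per-class iTRAQ
#' ranking scores for each feature. Significance defaults to raw
#' `p_perm <= alpha`; set `bh = TRUE` to threshold the BH-adjusted q instead
#' (as done in the false-positive protocol).
#'
#' @param sig A `psp_signature` tibble.
#' @param features Optional feature tibble supplying the member sets used for
#'   ranking scores (matched by `feature_id`).
#' @param profiles Optional profile tibble with `ratios` attached.
#' @inheritParams permutation_test
#' @param alpha Significance threshold (default 0.05).
#' @param bh Threshold on BH q-values instead of raw p (default FALSE).
#' @return `FeatureStats` tibble: permutation-test columns plus
#'   `significant`, and `score_<class>` columns when scores were computed.
#' @export
select_features <- function(sig, features = NULL, profiles = NULL,
                            n_perm = 10000, seed = NULL,
                            alternative = c("signed", "two.sided"),
                            ties = c("strict", "midp"),
                            alpha = 0.05, bh = FALSE) {
  stats_tab <- permutation_test(sig, n_perm = n_perm, seed = seed,
                                alternative = match.arg(alternative),
                                ties = match.arg(ties))
  stats_tab$significant <- if (bh) stats_tab$q_bh <= alpha else stats_tab$p_perm <= alpha
  if (!is.null(features) && !is.null(profiles) &&
      any(lengths(profiles$ratios) > 0)) {
    idx <- match(stats_tab$feature_id, features$feature_id)
    for (cl in sort(unique(profiles$class))) {
      pc <- profiles[profiles$class == cl, ]
      stats_tab[[paste0("score_", cl)]] <- vapply(idx, function(i) {
        if (is.na(i)) return(NA_real_)
        rank_score(pc, features$members[[i]])$score
      }, numeric(1))
    }
  }
  stats_tab
}
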