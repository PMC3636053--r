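#' Pathways implicated by significant subnets
#'
#' A pathway is "involved" if it gave rise to at least one significant PDS.
#'
#' @param sig_pds Feature tibble of significant PDSs (`kind == "pds"`).
#' @return Sorted character vector of distinct source pathway IDs.
#' @export
involved_pathways <- function(sig_pds) {
  if (nrow(sig_pds) == 0) return(character(0))
  if (!all(sig_pds$kind == "pds"))
    stop_data("involved_pathways expects PDS features only")
  sort(unique(sig_pds$source_pathway))
}

#' Enrichment of significant-complex overlap on involved pathways
#'
#' Compares how often involved pathways (those contributing a significant
#' PDS) share proteins with a significant complex versus non-involved
#' pathways. A pathway "overlaps" a complex when they share at least
#' `min_shared` proteins (default 1, the most permissive reading).
#'
#' @param involved Character vector of involved pathway IDs (subset of the
#'   pathway collection).
#' @param pathways Pathway tibble (the full collection).
#' @param sig_complexes Feature tibble of significant complexes.
#' @param min_shared Minimum shared-protein count defining overlap.
#' @return One-row tibble: `n_involved`, `n_involved_overlap`,
#'   `frac_involved`, `n_noninvolved`, `n_noninvolved_overlap`,
#'   `frac_noninvolved`, `ratio` (`NA` when a denominator is empty or the
#'   non-involved fraction is zero).
#' @export
overlap_enrichment <- function(involved, pathways, sig_complexes, min_shared = 1) {
  if (!all(involved %in% pathways$pathway_id))
    stop_data("involved pathway IDs missing from pathway collection")
  overlaps <- vapply(pathways$nodes, function(nd) {
    any(vapply(sig_complexes$members,
               function(m) length(intersect(nd, m)) >= min_shared, logical(1)))
  }, logical(1))
  is_inv <- pathways$pathway_id %in% involved
  n_inv <- sum(is_inv); n_non <- sum(!is_inv)
  f_inv <- if (n_inv > 0) sum(overlaps[is_inv]) / n_inv else NA_real_
  f_non <- if (n_non > 0) sum(overlaps[!is_inv]) / n_non else NA_real_
  ratio <- if (!is.na(f_inv) && !is.na(f_non) && f_non > 0) f_inv / f_non else NA_real_
  tibble::tibble(
    n_involved = n_inv, n_involved_overlap = sum(overlaps[is_inv]),
    frac_involved = f_inv,
    n_noninvolved = n_non, n_noninvolved_overlap = sum(overlaps[!is_inv]),
    frac_noninvolved = f_non,
    ratio = ratio
  )
}

#' Jaccard score of two protein sets
#'
#' Intersection over union; 1 iff the sets are equal, 0 iff disjoint.
#'
#' @param a,b Character vectors.
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Co-located PDS/complex pairs and their membership overlap
#'
#' Pairs every significant PDS with every significant complex that overlaps
#' the PDS's source pathway, and reports the Jaccard score of their member
#' sets. A low typical Jaccard shows co-location is not an artefact of the
#' same proteins appearing in both feature types.
#'
#' @param sig_pds Feature tibble of significant PDSs.
#' @param sig_complexes Feature tibble of significant complexes.
#' @param pathways Pathway tibble.
#' @param min_shared Shared-protein threshold tying a complex to a pathway.
#' @param threshold Jaccard value used for the summary fraction (default
#'   0.2).
#' @return Tibble `pds_id`, `complex_id`, `pathway_id`, `jaccard`, with
#'   attribute `frac_below`: the fraction of pairs with Jaccard strictly
#'   below `threshold`.
#' @export
jaccard_overlaps <- function(sig_pds, sig_complexes, pathways,
                             min_shared = 1, threshold = 0.2) {
  pairs <- list()
  for (i in seq_len(nrow(sig_pds))) {
    pw <- sig_pds$source_pathway[i]
    nd <- pathways$nodes[[match(pw, pathways$pathway_id)]]
    for (j in seq_len(nrow(sig_complexes))) {
      if (length(intersect(nd, sig_complexes$members[[j]])) >= min_shared) {
        pairs[[length(pairs) + 1]] <- tibble::tibble(
          pds_id = sig_pds$feature_id[i],
          complex_id = sig_complexes$feature_id[j],
          pathway_id = pw,
          jaccard = jaccard(sig_pds$members[[i]], sig_complexes$members[[j]])
        )
      }
    }
  }
  out <- dplyr::bind_rows(pairs)
  if (nrow(out) == 0)
    out <- tibble::tibble(pds_id = character(), complex_id = character(),
                          pathway_id = character(), jaccard = numeric())
  attr(out, "frac_below") <- if (nrow(out) > 0) mean(out$jaccard < threshold) else NA_real_
  attr(out, "threshold") <- threshold
  out
}

#' Regression of complex ranking scores on co-located PDS scores
#'
#' Ordinary least squares of the complex score on the PDS score for
#' co-located pairs, per patient class when a `stage` column is present.
#' Reports slope (both regression directions — R-squared and the F-test p are
#' direction-invariant for simple regression), intercept, R-squared and the
#' F-test p-value. Pairs with absolute studentised residual above
#' `flag_threshold` are flagged as outliers and a leave-out re-fit is
#' reported; rows named in `exclude` are removed up front.
#'
#' @param pairs Tibble with numeric columns `pds_score`, `complex_score`,
#'   optionally a `stage` column and a `pair_id` column used in the outlier
#'   report.
#' @param exclude Optional vector of `pair_id`s excluded before fitting.
#' @param flag_threshold Studentised-residual cutoff (default 3).
#' @return Tibble, one row per stage: `stage`, `n`, `slope`, `slope_inverse`,
#'   `intercept`, `r_squared`, `p_value`, list-column `outliers`, and
#'   `slope_refit`, `r_squared_refit`, `p_value_refit` (NA when nothing was
#'   flagged).
#' @export
score_regression <- function(pairs, exclude = NULL, flag_threshold = 3) {
  if (!all(c("pds_score", "complex_score") %in% names(pairs)))
    stop_data("pairs must have pds_score and complex_score columns")
  if (is.null(pairs[["stage"]])) pairs$stage <- "all"
  if (is.null(pairs[["pair_id"]]))
    pairs$pair_id <- as.character(seq_len(nrow(pairs)))
  if (!is.null(exclude)) pairs <- pairs[!(pairs$pair_id %in% exclude), ]
  purrr::map_dfr(split(pairs, pairs$stage), function(d) {
    if (nrow(d) < 3) stop_data("score regression needs >= 3 pairs per stage")
    fit <- stats::lm(complex_score ~ pds_score, data = d)
    sm <- suppressWarnings(summary(fit))   # perfect fits warn harmlessly
    # constant response: zero total variance, define R^2 = 0, slope = 0
    if (!is.finite(sm$r.squared)) sm$r.squared <- 0
    pval <- if (is.null(sm$fstatistic)) NA_real_ else
      stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE)
    rs <- tryCatch(stats::rstudent(fit), error = function(e) rep(0, nrow(d)))
    rs[!is.finite(rs)] <- 0
    out_ids <- d$pair_id[abs(rs) > flag_threshold]
    refit <- c(slope = NA_real_, r2 = NA_real_, p = NA_real_)
    if (length(out_ids) > 0 && nrow(d) - length(out_ids) >= 3) {
      d2 <- d[!(d$pair_id %in% out_ids), ]
      f2 <- stats::lm(complex_score ~ pds_score, data = d2)
      s2 <- suppressWarnings(summary(f2))
      refit <- c(slope = unname(stats::coef(f2)[2]), r2 = s2$r.squared,
                 p = if (is.null(s2$fstatistic)) NA_real_ else
                   stats::pf(s2$fstatistic[1], s2$fstatistic[2], s2$fstatistic[3],
                             lower.tail = FALSE))
    }
    inv_slope <- {
      f_inv <- stats::lm(pds_score ~ complex_score, data = d)
      unname(stats::coef(f_inv)[2])
    }
    tibble::tibble(
      stage = d$stage[1], n = nrow(d),
      slope = unname(stats::coef(fit)[2]),
      slope_inverse = inv_slope,
      intercept = unname(stats::coef(fit)[1]),
      r_squared = sm$r.squared,
      p_value = pval,
      outliers = list(out_ids),
      slope_refit = unname(refit["slope"]),
      r_squared_refit = unname(refit["r2"]),
      p_value_refit = unname(refit["p"])
    )
  })
}
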