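#' Propagate direct annotations to all ancestor terms
#'
#' Standard term-enrichment convention: a protein annotated to a term counts
#' for that term and for every ancestor reachable through `is_a` / `part_of`
#' edges (set semantics, so diamond-shaped ancestry counts a protein once per
#' term). The parent graph must be acyclic.
#'
#' @param ontology A `psp_ontology` object ([read_obo_gaf()] /
#'   [gen_ontology()]).
#' @return Tibble `term_id`, list-column `proteins` (sorted), `n_proteins`,
#'   one row per term (terms with no annotated descendant get empty sets).
#' @export
propagate_annotations <- function(ontology) {
  terms <- ontology$terms
  ids <- terms$term_id
  idx <- stats::setNames(seq_along(ids), ids)
  # children adjacency from parent lists
  children <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    for (p in terms$parents[[i]]) {
      j <- idx[[p]]
      children[[j]] <- c(children[[j]], i)
    }
  }
  order <- topo_order(terms$parents, idx)   # leaves-to-root guarantee below
  direct <- split(ontology$annotations$protein_id, ontology$annotations$term_id)
  sets <- vector("list", length(ids))
  # process children before parents: reverse topological order on parent edges
  for (i in order) {
    acc <- direct[[ids[i]]]
    for (ch in children[[i]]) acc <- c(acc, sets[[ch]])
    # `sets[i] <- list(...)`: an empty set must not delete the slot
    sets[i] <- list(sort(unique(c(acc, character(0)))))
  }
  tibble::tibble(term_id = ids, proteins = sets, n_proteins = lengths(sets))
}

# Topological order such that every term comes before its parents
# (children-first). Errors out on cycles.
topo_order <- function(parents, idx) {
  n <- length(parents)
  # out-degree = number of unresolved children; compute children counts
  n_children <- integer(n)
  for (i in seq_len(n)) for (p in parents[[i]]) {
    j <- idx[[p]]; n_children[j] <- n_children[j] + 1L
  }
  # Kahn's algorithm starting from leaves (terms with no children)
  ready <- which(n_children == 0L)
  out <- integer(0)
  remaining <- n_children
  while (length(ready) > 0) {
    i <- ready[1]; ready <- ready[-1]
    out <- c(out, i)
    for (p in parents[[i]]) {
      j <- idx[[p]]
      remaining[j] <- remaining[j] - 1L
      if (remaining[j] == 0L) ready <- c(ready, j)
    }
  }
  if (length(out) < n) stop_data("cycle detected in ontology parent graph")
  out
}

#' Informative terms of an ontology
#'
#' A term is informative when it is annotated (after propagation) to at least
#' `min_count` proteins while none of its direct children exceeds
#' `min_count` — i.e. the deepest terms still broad enough to test. A child
#' at exactly `min_count` does not disqualify its parent ("more than"
#' semantics).
#'
#' @param ontology A `psp_ontology` object.
#' @param min_count Annotation threshold (default 30).
#' @param namespace Optional namespace filter (e.g. `"biological_process"`).
#' @param propagated Use propagated counts (default TRUE) or direct-only.
#' @return Character vector of informative term IDs.
#' @export
informative_terms <- function(ontology, min_count = 30, namespace = NULL,
                              propagated = TRUE) {
  counts <- if (propagated) {
    prop <- propagate_annotations(ontology)
    stats::setNames(prop$n_proteins, prop$term_id)
  } else {
    direct <- table(unique(ontology$annotations)$term_id)
    cnt <- stats::setNames(integer(nrow(ontology$terms)), ontology$terms$term_id)
    cnt[names(direct)] <- as.integer(direct)
    cnt
  }
  terms <- ontology$terms
  keep_ns <- if (is.null(namespace)) rep(TRUE, nrow(terms)) else
    terms$namespace %in% namespace
  idx <- stats::setNames(seq_len(nrow(terms)), terms$term_id)
  child_max <- numeric(nrow(terms))
  for (i in seq_len(nrow(terms))) {
    for (p in terms$parents[[i]]) {
      j <- idx[[p]]
      child_max[j] <- max(child_max[j], counts[[terms$term_id[i]]])
    }
  }
  ok <- keep_ns & counts[terms$term_id] >= min_count & child_max <= min_count
  sort(terms$term_id[ok])
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k)` for `k` annotated members out of a size-`n` feature, drawn
#' from a background of `N` proteins of which `K` are annotated. `K = 0`
#' gives p = 1. The Bonferroni multiplier is the number of terms actually
#' tested for the feature, and the corrected p is capped at 1.
#'
#' @param k Annotated members in the feature.
#' @param K Annotated proteins in the background.
#' @param n Feature size.
#' @param N Background size.
#' @param n_tests Bonferroni multiplier (default 1).
#' @return One-row tibble `p` and `p_bonferroni`.
#' @export
hypergeom_enrichment <- function(k, K, n, N, n_tests = 1) {
  stopifnot(k <= n, K <= N, n <= N)
  p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble::tibble(p = p, p_bonferroni = min(1, p * n_tests))
}

#' Term enrichment of feature sets over informative terms
#'
#' Runs the hypergeometric test for every (feature, term) combination, with
#' per-feature Bonferroni correction over the terms tested.
#'
#' @param features Feature tibble; members must lie inside `background`.
#' @param ontology A `psp_ontology` object.
#' @param terms Term IDs to test (default: [informative_terms()]).
#' @param background Character vector of background proteins (default: all
#'   annotated proteins plus all feature members, so unannotated members
#'   count against enrichment rather than erroring). A user-supplied
#'   background must contain every feature member.
#' @param alpha Significance level applied to the Bonferroni-corrected p.
#' @return Tibble `feature_id`, `term_id`, `k`, `K`, `n`, `N`, `p`,
#'   `p_bonferroni`, `significant`.
#' @export
term_enrichment <- function(features, ontology, terms = NULL,
                            background = NULL, alpha = 0.05) {
  prop <- propagate_annotations(ontology)
  if (is.null(background))
    background <- sort(unique(c(ontology$annotations$protein_id,
                                unlist(features$members))))
  bad <- !vapply(features$members, function(m) all(m %in% background), logical(1))
  if (any(bad))
    stop_data("feature member(s) outside the background set: %s",
              paste(features$feature_id[bad], collapse = ", "))
  if (is.null(terms)) terms <- informative_terms(ontology)
  N <- length(background)
  purrr::map_dfr(seq_len(nrow(features)), function(i) {
    mem <- features$members[[i]]
    purrr::map_dfr(terms, function(tm) {
      ann <- intersect(prop$proteins[[match(tm, prop$term_id)]], background)
      k <- length(intersect(mem, ann))
      res <- hypergeom_enrichment(k, length(ann), length(mem), N,
                                  n_tests = length(terms))
      tibble::tibble(feature_id = features$feature_id[i], term_id = tm,
                     k = k, K = length(ann), n = length(mem), N = N,
                     p = res$p, p_bonferroni = res$p_bonferroni,
                     significant = res$p_bonferroni <= alpha)
    })
  })
}

#' Functional-class-scoring association of features with a term list
#'
#' The association of a feature with a curated term list (e.g. lipid-related
#' terms) is the hit rate `a/n`: the fraction of its `n` members annotated
#' (after propagation) to at least one listed term. Significance comes from a
#' functional-class-scoring null: `n_rand` random protein sets of size `n`
#' are drawn uniformly without replacement from the universe and the p-value
#' is the fraction of random sets whose hit rate strictly exceeds the
#' observed one.
#'
#' @param features Feature tibble.
#' @param term_list Character vector of term IDs; by default descendants of
#'   listed terms also count (`descendants = TRUE`).
#' @param ontology A `psp_ontology` object.
#' @param universe Character vector of proteins to sample from (default: all
#'   proteins with at least one annotation).
#' @param n_rand Number of random sets (default 10000).
#' @param seed Integer RNG seed.
#' @param descendants Close the term list downwards over the ontology.
#' @return Tibble `feature_id`, `a`, `n`, `hit_rate`, `p_fcs`.
#' @export
fcs_association <- function(features, term_list, ontology, universe = NULL,
                            n_rand = 10000, seed = NULL, descendants = TRUE) {
  stopifnot(n_rand >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(universe))
    universe <- sort(unique(ontology$annotations$protein_id))
  terms_used <- if (descendants) term_closure(ontology, term_list) else term_list
  prop <- propagate_annotations(ontology)
  annotated <- sort(unique(unlist(
    prop$proteins[prop$term_id %in% terms_used])))
  is_ann <- universe %in% annotated
  Nu <- length(universe)
  purrr::map_dfr(seq_len(nrow(features)), function(i) {
    mem <- features$members[[i]]
    if (!all(mem %in% universe))
      stop_data("feature %s has members outside the universe", features$feature_id[i])
    n <- length(mem)
    if (n > Nu) stop_data("feature larger than universe")
    a <- sum(mem %in% annotated)
    obs <- a / n
    rand_rate <- vapply(seq_len(n_rand), function(b) {
      sum(is_ann[sample.int(Nu, n)]) / n
    }, numeric(1))
    tibble::tibble(feature_id = features$feature_id[i], a = a, n = n,
                   hit_rate = obs, p_fcs = sum(rand_rate > obs) / n_rand)
  })
}

# All listed terms plus their descendants (terms whose ancestor set meets the
# list), via the parent relation.
term_closure <- function(ontology, term_list) {
  terms <- ontology$terms
  idx <- stats::setNames(seq_len(nrow(terms)), terms$term_id)
  order <- topo_order(terms$parents, idx)   # children before parents
  hit <- terms$term_id %in% term_list
  # walk parents-first (reverse of children-first) so descendants inherit
  for (i in rev(order)) {
    if (!hit[i]) {
      par <- terms$parents[[i]]
      if (length(par) > 0 && any(hit[idx[par]])) hit[i] <- TRUE
    }
  }
  sort(terms$term_id[hit])
}

#' Disjoint-region counts for up to three significant-feature sets
#'
#' Venn bookkeeping across ontology aspects (e.g. the features significant
#' via BP, CC and MF terms): counts of the seven disjoint regions, which sum
#' to the size of the union.
#'
#' @param sets Named list of two or three character vectors.
#' @return Tibble `region`, `count`.
#' @export
venn_counts <- function(sets) {
  stopifnot(length(sets) %in% c(2, 3), !is.null(names(sets)))
  if (length(sets) == 2) sets <- c(sets, list(.empty = character(0)))
  nm <- names(sets)
  u <- unique(unlist(sets))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  member <- matrix(member, ncol = 3)
  key <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
  tab <- table(key)
  out <- tibble::tibble(region = names(tab), count = as.integer(tab))
  out[out$region != "", ]
}
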