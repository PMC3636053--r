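# Independent oracles used to cross-check the package implementation.
# Deliberately naive: plain loops, no shared code with the package internals.

# Connected components by flood fill over an edge list.
oracle_components <- function(nodes, edges) {
  if (length(nodes) == 0) return(list())
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- character(0)
  comps <- list()
  for (start in nodes) {
    if (start %in% seen) next
    queue <- start
    comp <- character(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# Textbook pooled two-sample t, written out long-hand.
oracle_t <- function(a, b) {
  m <- length(a); n <- length(b)
  va <- sum((a - mean(a))^2) / (m - 1)
  vb <- sum((b - mean(b))^2) / (n - 1)
  sp <- sqrt(((m - 1) * va + (n - 1) * vb) / (m + n - 2))
  d <- mean(a) - mean(b)
  if (sp == 0) return(if (d == 0) 0 else sign(d) * Inf)
  d / (sp * sqrt(1 / n + 1 / m))
}

# Brute-force permutation p over ALL group-size-preserving assignments,
# sign-adaptive strict rule.
oracle_perm_p <- function(x, is_a) {
  n <- length(x); nA <- sum(is_a)
  t_obs <- oracle_t(x[is_a], x[!is_a])
  combos <- utils::combn(n, nA)
  t_null <- apply(combos, 2, function(ii) {
    sel <- seq_len(n) %in% ii
    oracle_t(x[sel], x[!sel])
  })
  if (t_obs < 0) sum(t_null < t_obs) / length(t_null)
  else sum(t_null > t_obs) / length(t_null)
}

# Naive O(n^3) Ward agglomeration: Lance-Williams on squared Euclidean
# distances, heights reported on the distance scale (sqrt of merge cost).
oracle_ward_heights <- function(x) {
  n <- nrow(x)
  D <- as.matrix(stats::dist(x))^2
  size <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestd <- Inf
    for (i in which(active)) for (j in which(active)) {
      if (i < j && D[i, j] < bestd) { bestd <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(bestd)
    for (k in which(active)) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        ((size[i] + size[k]) * D[i, k] + (size[j] + size[k]) * D[j, k] -
           size[k] * D[i, j]) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
  }
  heights
}

# Transitive ancestor closure of a parent list, by iterating to fixpoint.
oracle_ancestors <- function(parents) {
  anc <- parents
  repeat {
    changed <- FALSE
    for (id in names(anc)) {
      extra <- unique(unlist(anc[anc[[id]]]))
      new <- sort(unique(c(anc[[id]], extra)))
      if (!identical(new, anc[[id]])) { anc[[id]] <- new; changed <- TRUE }
    }
    if (!changed) return(anc)
  }
}

# --- small fixture builders -------------------------------------------------

# Profile tibble from named lists: detected[[patient]] etc.
make_profiles <- function(detected, classes, ratios = NULL) {
  ids <- names(detected)
  tibble::tibble(
    patient_id = ids,
    class = unname(classes[ids]),
    detected = lapply(unname(detected), function(d) sort(unique(d))),
    ratios = if (is.null(ratios)) vector("list", length(ids))
             else lapply(ids, function(i) ratios[[i]])
  )
}

# One-row pathway tibble from an edge matrix (character, 2 cols).
make_pathway <- function(id, edges, extra_nodes = character(0)) {
  edges <- matrix(as.character(edges), ncol = 2)
  a <- pmin(edges[, 1], edges[, 2]); b <- pmax(edges[, 1], edges[, 2])
  keep <- a != b
  e <- unique(cbind(a[keep], b[keep]))
  tibble::tibble(pathway_id = id, name = id,
                 nodes = list(sort(unique(c(edges[, 1], edges[, 2], extra_nodes)))),
                 edges = list(e))
}

# Feature tibble from a named list of member vectors.
make_features <- function(members, kind = "complex", source_pathway = NA_character_) {
  tibble::tibble(
    feature_id = names(members),
    kind = kind,
    source_pathway = source_pathway,
    members = lapply(unname(members), function(m) sort(unique(m))),
    n_members = lengths(members),
    below_min_size = lengths(members) < 4
  )
}

# Ontology object from a parent list and an annotation table.
make_ontology <- function(parents, annotations = NULL,
                          namespace = "biological_process") {
  ids <- names(parents)
  terms <- tibble::tibble(
    term_id = ids, name = ids, namespace = namespace,
    parents = lapply(unname(parents), function(p) sort(unique(p)))
  )
  ann <- if (is.null(annotations))
    tibble::tibble(protein_id = character(), term_id = character())
  else annotations
  structure(list(terms = terms, annotations = ann), class = "psp_ontology")
}
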