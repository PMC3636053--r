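#' Candidate proteins for subnet mapping
#'
#' A protein is a candidate if it is detected in at least half of the patients
#' of either class ("at least half" of an odd class size rounds up: ceiling of
#' n/2). The returned set is the union over the two classes, so proteins
#' characteristic of either phenotype are retained.
#'
#' @param profiles Profile tibble ([read_detections()] / [gen_cohort()]);
#'   exactly two class labels must be present.
#' @return Sorted character vector of candidate protein IDs.
#' @export
candidate_proteins <- function(profiles) {
  classes <- sort(unique(profiles$class))
  if (length(classes) != 2)
    stop_data("candidate_proteins needs exactly 2 classes, found %d", length(classes))
  per_class <- lapply(classes, function(cl) {
    det <- profiles$detected[profiles$class == cl]
    thr <- ceiling(length(det) / 2)
    counts <- table(unlist(det))
    names(counts)[counts >= thr]
  })
  sort(unique(unlist(per_class)))
}

#' Extract pathway-derived subnets (PDSs) from one or more pathways
#'
#' Each pathway graph is restricted to the candidate proteins (the induced
#' subgraph); removing unmapped proteins fragments the pathway into connected
#' components, and every component with at least `min_size` nodes becomes a
#' PDS. The minimum size keeps hit rates from fluctuating wildly over tiny
#' sets. Isolated nodes are size-1 components and thus always fall below the
#' default minimum.
#'
#' Feature IDs are deterministic: `<pathway_id>_<k>` with components numbered
#' by decreasing size, ties broken by the lexicographically smallest member.
#'
#' @param pathways Pathway tibble ([read_pathways()] / [gen_pathways()]); one
#'   or more rows.
#' @param candidates Character vector of candidate protein IDs.
#' @param min_size Minimum component size retained (default 4).
#' @return Feature tibble (`kind = "pds"`, `source_pathway` set); zero rows if
#'   nothing qualifies.
#' @export
extract_pds <- function(pathways, candidates, min_size = 4) {
  stopifnot(min_size >= 1)
  out <- purrr::pmap(pathways, function(pathway_id, name, nodes, edges, ...) {
    comp <- induced_components(nodes, edges, candidates)
    comp <- comp[lengths(comp) >= min_size]
    if (length(comp) == 0) return(NULL)
    ord <- order(-lengths(comp), vapply(comp, `[[`, character(1), 1))
    comp <- comp[ord]
    feature_table(
      feature_id = sprintf("%s_%d", pathway_id, seq_along(comp)),
      members = comp,
      kind = "pds",
      source_pathway = pathway_id,
      min_size = min_size
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0)
    out <- feature_table(character(), list(), character(), character(), min_size)
  out
}

# Connected components of the subgraph induced on nodes %in% candidates;
# returns a list of sorted member vectors (all sizes, including singletons).
induced_components <- function(nodes, edges, candidates) {
  keep <- intersect(nodes, candidates)
  if (length(keep) == 0) return(list())
  g <- pathway_graph(nodes, edges)
  sub <- igraph::induced_subgraph(g, keep)
  comp <- igraph::components(sub)
  unname(lapply(split(names(comp$membership), comp$membership), sort))
}

#' Catalogue PDSs over a pathway collection
#'
#' Runs [extract_pds()] over every pathway and tabulates how many subnets each
#' pathway contributed (typically one, occasionally two).
#'
#' @inheritParams extract_pds
#' @return A list with `features` (the concatenated PDS tibble) and
#'   `contributions` (tibble `pathway_id`, `n_pds`, one row per input pathway
#'   including zero contributors).
#' @export
pds_catalogue <- function(pathways, candidates, min_size = 4) {
  if (anyDuplicated(pathways$pathway_id))
    stop_data("duplicate pathway IDs: %s",
              paste(unique(pathways$pathway_id[duplicated(pathways$pathway_id)]),
                    collapse = ", "))
  features <- extract_pds(pathways, candidates, min_size)
  counts <- table(factor(features$source_pathway, levels = pathways$pathway_id))
  contributions <- tibble::tibble(pathway_id = names(counts),
                                  n_pds = as.integer(counts))
  list(features = features, contributions = contributions)
}
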