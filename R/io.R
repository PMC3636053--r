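#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% arrange bind_rows distinct filter group_by left_join
#'   mutate n pull rename row_number select summarise ungroup
NULL

# Error helper: data-format problems carry class "psp_data_error" so callers
# (and the command-line wrapper) can distinguish them from usage errors.
stop_data <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "psp_data_error")
}

#' Read per-patient protein detection lists
#'
#' Parses a long-format TSV with one row per detection event and returns one
#' row per patient with the detected proteins as a set (list-column).
#' Exactly two class labels must be present in the cohort; duplicated
#' (patient, protein) rows collapse to one detection.
#'
#' @param path Path to a UTF-8 TSV with a header row and columns
#'   `patient_id`, `class_label` (or the column named by `class_column`) and
#'   `protein_id`.
#' @param class_column Name of the column holding the two-level class label.
#' @param ratios Optional tibble of iTRAQ-style abundance ratios with columns
#'   `patient_id`, `protein_id`, `ratio` (see [read_ratios()]); attached as a
#'   per-patient list-column of named numerics. Every ratio must refer to a
#'   detected protein and be strictly positive.
#' @return A tibble with columns `patient_id`, `class` and list-columns
#'   `detected` (character vectors) and `ratios` (named numeric vectors, or
#'   `NULL`), sorted by patient ID.
#' @export
read_detections <- function(path, class_column = "class_label", ratios = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("patient_id", class_column, "protein_id")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop_data("detections file lacks column(s): %s", paste(missing_cols, collapse = ", "))
  raw <- raw %>% rename(class = dplyr::all_of(class_column))
  if (any(is.na(raw$protein_id) | raw$protein_id == ""))
    stop_data("blank or missing protein_id in detections file")
  if (any(is.na(raw$patient_id) | raw$patient_id == ""))
    stop_data("blank or missing patient_id in detections file")
  profiles_from_rows(raw, ratios)
}

# Shared constructor: long rows (patient_id, class, protein_id) -> profile tibble.
profiles_from_rows <- function(rows, ratios = NULL) {
  classes <- sort(unique(rows$class))
  if (length(classes) != 2)
    stop_data("expected exactly 2 class labels, found %d: %s",
              length(classes), paste(classes, collapse = ", "))
  per_class <- rows %>% distinct(.data$patient_id, .data$class)
  dup <- per_class$patient_id[duplicated(per_class$patient_id)]
  if (length(dup) > 0)
    stop_data("patient(s) assigned to more than one class: %s",
              paste(unique(dup), collapse = ", "))
  prof <- rows %>%
    distinct(.data$patient_id, .data$class, .data$protein_id) %>%
    group_by(.data$patient_id, .data$class) %>%
    summarise(detected = list(sort(unique(.data$protein_id))), .groups = "drop") %>%
    arrange(.data$patient_id)
  if (any(lengths(prof$detected) == 0))
    stop_data("patient with empty detection set")
  prof$ratios <- vector("list", nrow(prof))
  if (!is.null(ratios)) prof <- attach_ratios(prof, ratios)
  prof
}

#' Read an iTRAQ-style protein ratio table
#'
#' @param path TSV with header columns `patient_id`, `protein_id`, `ratio`.
#' @return Tibble with those three columns, `ratio` numeric.
#' @export
read_ratios <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    protein_id = readr::col_character(),
    ratio = readr::col_double()
  ), progress = FALSE)
  if (any(is.na(tab$ratio)) || any(tab$ratio <= 0))
    stop_data("ratios must all be positive numbers")
  tab
}

# Attach a ratio table to a profile tibble as named-numeric list column.
attach_ratios <- function(profiles, ratios) {
  stopifnot(all(c("patient_id", "protein_id", "ratio") %in% names(ratios)))
  if (any(ratios$ratio <= 0)) stop_data("ratios must all be positive numbers")
  split_r <- split(ratios, ratios$patient_id)
  profiles$ratios <- lapply(seq_len(nrow(profiles)), function(i) {
    r <- split_r[[profiles$patient_id[i]]]
    if (is.null(r)) return(NULL)
    bad <- setdiff(r$protein_id, profiles$detected[[i]])
    if (length(bad) > 0)
      stop_data("patient %s has ratios for undetected protein(s): %s",
                profiles$patient_id[i], paste(bad, collapse = ", "))
    r <- r[!duplicated(r$protein_id), ]
    stats::setNames(r$ratio, r$protein_id)
  })
  profiles
}

#' Write detection profiles (and optionally ratios) back to TSV
#'
#' Inverse of [read_detections()]: `read_detections(write_detections(p))`
#' reproduces the same profiles.
#'
#' @param profiles Profile tibble from [read_detections()] or [gen_cohort()].
#' @param path Output TSV path for the long detection table.
#' @param ratios_path Optional output TSV path for the ratio table.
#' @return `path`, invisibly.
#' @export
write_detections <- function(profiles, path, ratios_path = NULL) {
  long <- profiles %>%
    select("patient_id", "class", "detected") %>%
    tidyr::unnest(cols = "detected") %>%
    rename(class_label = "class", protein_id = "detected")
  readr::write_tsv(long, path, progress = FALSE)
  if (!is.null(ratios_path)) {
    rt <- purrr::map2_dfr(profiles$patient_id, profiles$ratios, function(pid, r) {
      if (is.null(r) || length(r) == 0) return(NULL)
      tibble(patient_id = pid, protein_id = names(r), ratio = unname(r))
    })
    readr::write_tsv(rt, ratios_path, progress = FALSE)
  }
  invisible(path)
}

#' Read pathway definitions as undirected gene-pair edge lists
#'
#' One row per gene pair, grouped by pathway. Edge direction, if implied by
#' column order, is ignored; duplicate and reversed pairs collapse to one
#' undirected edge; self-loop rows are dropped with a warning but their node
#' is retained.
#'
#' @param path 4-column TSV with header `pathway_id`, `name`, `gene_a`,
#'   `gene_b`.
#' @return Tibble with one row per pathway: `pathway_id`, `name`, list-columns
#'   `nodes` (character) and `edges` (two-column character matrix, endpoints
#'   sorted within each row).
#' @export
read_pathways <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("pathway_id", "name", "gene_a", "gene_b")
  if (!all(need %in% names(raw)))
    stop_data("pathways file needs columns: %s", paste(need, collapse = ", "))
  if (any(is.na(raw$gene_a) | raw$gene_a == "" | is.na(raw$gene_b) | raw$gene_b == ""))
    stop_data("blank gene ID in pathways file")
  loops <- raw$gene_a == raw$gene_b
  if (any(loops))
    warn(sprintf("dropped %d self-loop edge row(s); nodes retained", sum(loops)))
  pathways_from_edges(raw, keep_loop_nodes = TRUE)
}

# Build the per-pathway tibble from long edge rows.
pathways_from_edges <- function(rows, keep_loop_nodes = TRUE) {
  split_rows <- split(rows, rows$pathway_id)
  out <- purrr::map_dfr(split_rows, function(r) {
    nodes <- sort(unique(c(r$gene_a, r$gene_b)))
    keep <- r$gene_a != r$gene_b
    a <- pmin(r$gene_a[keep], r$gene_b[keep])
    b <- pmax(r$gene_a[keep], r$gene_b[keep])
    e <- unique(cbind(a, b))
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]   # canonical row order
    dimnames(e) <- NULL
    if (!keep_loop_nodes) nodes <- sort(unique(c(e[, 1], e[, 2])))
    tibble(pathway_id = r$pathway_id[1], name = r$name[1],
           nodes = list(nodes), edges = list(e))
  })
  arrange(out, .data$pathway_id)
}

# Convert one pathway row to an igraph object.
pathway_graph <- function(nodes, edges) {
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  g
}

#' Write pathways to the 4-column TSV format
#'
#' Isolated nodes (no incident edge) cannot be represented in an edge list and
#' are omitted; [gen_pathways()] never produces them.
#'
#' @param pathways Pathway tibble as from [read_pathways()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathways <- function(pathways, path) {
  long <- purrr::pmap_dfr(pathways, function(pathway_id, name, nodes, edges, ...) {
    if (nrow(edges) == 0) return(NULL)
    tibble(pathway_id = pathway_id, name = name,
           gene_a = edges[, 1], gene_b = edges[, 2])
  })
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}

#' Read a GMT file of protein complexes (CORUM-like gene sets)
#'
#' @param path Standard GMT: tab-separated `name`, `description`, members...
#' @param min_size Features below this size are loaded but flagged
#'   (`below_min_size`); profiling excludes them. Default 4, the conventional
#'   minimum complex size for hit-rate profiling.
#' @return Feature tibble: `feature_id`, `kind` (= "complex"),
#'   `source_pathway` (`NA`), `members` (list-column), `n_members`,
#'   `below_min_size`.
#' @export
read_gmt <- function(path, min_size = 4) {
  ids <- vapply(strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE),
                `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop_data("duplicate feature_id in GMT: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- fgsea::gmtPathways(path)
  feature_table(
    feature_id = names(sets),
    members = lapply(sets, function(m) sort(unique(m))),
    kind = "complex",
    source_pathway = NA_character_,
    min_size = min_size
  )
}

# Canonical feature-set tibble shared by read_gmt / extract_pds / generators.
feature_table <- function(feature_id, members, kind, source_pathway, min_size = 4) {
  members <- unname(members)
  tibble(
    feature_id = unname(feature_id),
    kind = kind,
    source_pathway = source_pathway,
    members = members,
    n_members = unname(lengths(members)),
    below_min_size = unname(lengths(members)) < min_size
  )
}

#' Write a feature tibble as GMT
#'
#' @param features Feature tibble (see [read_gmt()]).
#' @param path Output path.
#' @param description Description field; defaults to the feature kind.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(features, path, description = NULL) {
  desc <- description %||% features$kind
  lines <- vapply(seq_len(nrow(features)), function(i) {
    paste(c(features$feature_id[i], desc[min(i, length(desc))],
            features$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an OBO 1.2 ontology together with a GAF 2.x annotation file
#'
#' Minimal readers for the two standard Gene Ontology file formats. Only the
#' stanza fields needed downstream are kept: term id, name, namespace and the
#' `is_a` / `relationship: part_of` parent edges. Obsolete terms are excluded;
#' GAF rows with a `NOT` qualifier are excluded (standard GAF semantics);
#' annotations to unknown or obsolete terms are dropped with a warning giving
#' the count. Only direct annotations are stored — ancestor propagation is a
#' separate explicit step ([propagate_annotations()]).
#'
#' @param obo Path to an OBO 1.2 file.
#' @param gaf Path to a GAF 2.x file (tab-separated, `!` comment lines).
#' @return An object of class `psp_ontology`: a list with tibbles `terms`
#'   (`term_id`, `name`, `namespace`, list-column `parents`) and `annotations`
#'   (`protein_id`, `term_id`, direct only).
#' @export
read_obo_gaf <- function(obo, gaf) {
  ont <- read_obo(obo)
  ann <- read_gaf(gaf)
  known <- ont$terms$term_id
  drop <- !(ann$term_id %in% known)
  if (any(drop))
    warn(sprintf("dropped %d annotation(s) to unknown or obsolete terms", sum(drop)))
  ont$annotations <- ann[!drop, ]
  ont
}

#' @rdname read_obo_gaf
#' @export
read_obo <- function(obo) {
  lines <- readLines(obo, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  bounds <- c(starts, length(lines) + 1L)
  terms <- list()
  for (i in seq_along(starts)) {
    if (lines[starts[i]] != "[Term]") next
    body <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    field <- function(key) {
      v <- body[startsWith(body, paste0(key, ":"))]
      trimws(sub("!.*$", "", substring(v, nchar(key) + 2L)))
    }
    if (length(field("is_obsolete")) > 0 && any(field("is_obsolete") == "true")) next
    id <- field("id")
    if (length(id) == 0) next
    isa <- sub(" .*$", "", field("is_a"))
    rel <- field("relationship")
    partof <- sub("^part_of\\s+", "", rel[startsWith(rel, "part_of")])
    partof <- sub(" .*$", "", partof)
    terms[[length(terms) + 1L]] <- tibble(
      term_id = id[1],
      name = if (length(field("name")) > 0) field("name")[1] else NA_character_,
      namespace = if (length(field("namespace")) > 0) field("namespace")[1] else NA_character_,
      parents = list(sort(unique(c(isa, partof))))
    )
  }
  terms <- bind_rows(terms)
  if (nrow(terms) == 0) stop_data("no [Term] stanzas found in %s", obo)
  # parent references must resolve (obsolete parents are silently pruned)
  terms$parents <- lapply(terms$parents, function(p) p[p %in% terms$term_id])
  structure(list(terms = terms,
                 annotations = tibble(protein_id = character(), term_id = character())),
            class = "psp_ontology")
}

#' @rdname read_obo_gaf
#' @export
read_gaf <- function(gaf) {
  tab <- readr::read_tsv(gaf, comment = "!", col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 5) stop_data("GAF file has fewer than 5 columns")
  qualifier <- if (ncol(tab) >= 4) tab[[4]] else NA_character_
  not_rows <- !is.na(qualifier) & grepl("(^|\\|)NOT($|\\|)", qualifier)
  tibble(protein_id = tab[[2]][!not_rows], term_id = tab[[5]][!not_rows]) %>%
    distinct()
}

#' Read a curated term list (one term ID per line)
#'
#' Blank lines and `#` comments are ignored.
#'
#' @param path Text file path.
#' @return Character vector of term IDs.
#' @export
read_term_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[x != "" & !startsWith(x, "#")]
  unique(x)
}

#' Coverage summary: detected proteins absent from every feature collection
#'
#' Reports, per patient, how many detected proteins fall inside at least one
#' supplied feature set and which proteins are covered by none — the proteins
#' that hit-rate profiling cannot see.
#'
#' @param profiles Profile tibble.
#' @param ... One or more feature tibbles (complexes, PDSs).
#' @return Tibble `patient_id`, `n_detected`, `n_covered`, list-column
#'   `uncovered`.
#' @export
coverage_summary <- function(profiles, ...) {
  universe <- sort(unique(unlist(lapply(list(...), function(f) unlist(f$members)))))
  purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    det <- profiles$detected[[i]]
    cov <- det %in% universe
    tibble(patient_id = profiles$patient_id[i],
           n_detected = length(det), n_covered = sum(cov),
           uncovered = list(det[!cov]))
  })
}

# Write a tibble as TSV with "# key=value" provenance header lines.
write_tsv_commented <- function(df, path, params = list()) {
  params <- c(list(tool = paste0("pspnet ", as.character(utils::packageVersion("pspnet")))),
              params)
  hdr <- sprintf("# %s=%s", names(params), vapply(params, function(x)
    paste(format(x, trim = TRUE), collapse = ","), character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
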