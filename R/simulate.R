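#' Generate random connected pathway graphs
#'
#' Each pathway is a uniform random spanning tree over its proteins (so it is
#' connected by construction) plus independent Bernoulli extra edges. A
#' configurable fraction of each pathway's proteins is drawn from a pool
#' shared across pathways, mimicking the heavy member sharing of real pathway
#' databases; the rest are pathway-private.
#'
#' @param n_pathways Number of pathways.
#' @param sizes Integer vector of candidate pathway sizes (sampled with
#'   replacement), all >= 2. Default `8:40`.
#' @param extra_edge_prob Probability of each non-tree edge (default 0.1;
#'   1 gives complete graphs).
#' @param overlap_frac Fraction of nodes drawn from the shared pool
#'   (default 0.2).
#' @param shared_pool_size Size of the shared protein pool (default 200).
#' @param seed Integer RNG seed.
#' @param prefix Protein/pathway ID prefix.
#' @return Pathway tibble as from [read_pathways()].
#' @export
gen_pathways <- function(n_pathways, sizes = 8:40, extra_edge_prob = 0.1,
                         overlap_frac = 0.2, shared_pool_size = 200,
                         seed, prefix = "P") {
  stopifnot(all(sizes >= 2))
  if (missing(seed)) stop_data("gen_pathways requires an explicit seed")
  set.seed(seed)
  shared <- sprintf("%sS%04d", prefix, seq_len(shared_pool_size))
  pick <- function(v) v[sample.int(length(v), 1)]   # no scalar-sample gotcha
  rows <- purrr::map_dfr(seq_len(n_pathways), function(k) {
    sz <- pick(sizes)
    n_shared <- min(round(overlap_frac * sz), shared_pool_size)
    nodes <- c(sample(shared, n_shared),
               sprintf("%s%02dX%04d", prefix, k, seq_len(sz - n_shared)))
    nodes <- sample(nodes)                     # random tree attachment order
    a <- character(0); b <- character(0)
    if (sz > 1) {
      # random recursive tree: node i attaches to a uniform earlier node
      parent <- vapply(2:sz, function(i) sample.int(i - 1, 1), integer(1))
      a <- nodes[parent]; b <- nodes[2:sz]
    }
    if (extra_edge_prob > 0 && sz > 2) {
      all_pairs <- utils::combn(sort(nodes), 2)
      tree_key <- paste(pmin(a, b), pmax(a, b))
      pool <- !(paste(all_pairs[1, ], all_pairs[2, ]) %in% tree_key)
      add <- pool & stats::runif(ncol(all_pairs)) < extra_edge_prob
      a <- c(a, all_pairs[1, add]); b <- c(b, all_pairs[2, add])
    }
    tibble::tibble(pathway_id = sprintf("%s%02d", prefix, k),
                   name = sprintf("synthetic pathway %d", k),
                   gene_a = a, gene_b = b)
  })
  pathways_from_edges(rows)
}

#' Generate a two-class cohort of detection profiles
#'
#' Detection is modelled per (patient, protein) as independent Bernoulli:
#' background proteins are detected with probability `background_p` in every
#' patient; members of the designated signal features are detected with
#' probability `p_detect_A` in class-A patients and `p_detect_B` in class-B
#' patients. This reproduces the defining inconsistency of patient-level
#' proteomics (low overlap between any two detection lists — pairwise Jaccard
#' `p/(2-p)` under the background model) while planting a class-linked signal
#' that hit-rate profiling should recover.
#'
#' iTRAQ-style ratios are attached for every detected protein: log-normal
#' centred at 1 (`sdlog = ratio_sdlog`) for background proteins, multiplied
#' by `signal_ratio_shift` for signal-feature members in class A.
#'
#' @param n_A,n_B Patients per class.
#' @param proteome Character vector of protein IDs, or an integer size.
#' @param background_p Background detection probability (default 0.3).
#' @param signal_features Optional feature tibble whose members carry the
#'   class-linked signal.
#' @param p_detect_A,p_detect_B Detection probabilities for signal-feature
#'   members in classes A and B (defaults 0.9 / 0.2).
#' @param ratio_sdlog Log-normal sd of ratios (default 0.25).
#' @param signal_ratio_shift Multiplicative ratio shift for signal proteins
#'   in class A (default 1.5).
#' @param class_labels Two class label strings (default `c("A", "B")`).
#' @param seed Integer RNG seed.
#' @return Profile tibble (`patient_id`, `class`, `detected`, `ratios`),
#'   sorted by patient ID.
#' @export
gen_cohort <- function(n_A, n_B, proteome, background_p = 0.3,
                       signal_features = NULL, p_detect_A = 0.9,
                       p_detect_B = 0.2, ratio_sdlog = 0.25,
                       signal_ratio_shift = 1.5,
                       class_labels = c("A", "B"), seed) {
  stopifnot(background_p >= 0, background_p <= 1,
            p_detect_A >= 0, p_detect_A <= 1, p_detect_B >= 0, p_detect_B <= 1)
  if (missing(seed)) stop_data("gen_cohort requires an explicit seed")
  if (is.numeric(proteome) && length(proteome) == 1)
    proteome <- sprintf("PROT%05d", seq_len(proteome))
  set.seed(seed)
  signal <- if (is.null(signal_features)) character(0) else
    unique(unlist(signal_features$members))
  missing_sig <- setdiff(signal, proteome)
  if (length(missing_sig) > 0) proteome <- c(proteome, missing_sig)
  is_sig <- proteome %in% signal
  n_tot <- n_A + n_B
  ids <- sprintf("pt%02d", seq_len(n_tot))
  cls <- rep(class_labels, c(n_A, n_B))
  prof <- purrr::map_dfr(seq_len(n_tot), function(i) {
    p_vec <- ifelse(is_sig, if (cls[i] == class_labels[1]) p_detect_A else p_detect_B,
                    background_p)
    det <- proteome[stats::runif(length(proteome)) < p_vec]
    if (length(det) == 0) {
      # profiles must be non-empty; fall back to one background protein so a
      # zero-probability signal stays exactly zero
      pool <- if (any(!is_sig)) proteome[!is_sig] else proteome
      det <- pool[sample.int(length(pool), 1)]
    }
    det <- sort(det)
    mu <- ifelse(det %in% signal & cls[i] == class_labels[1],
                 log(signal_ratio_shift), 0)
    ratios <- stats::setNames(stats::rlnorm(length(det), mu, ratio_sdlog), det)
    tibble::tibble(patient_id = ids[i], class = cls[i],
                   detected = list(det), ratios = list(ratios))
  })
  dplyr::arrange(prof, .data$patient_id)
}

#' Generate a random ontology with a planted informative frontier
#'
#' Builds a rooted random DAG of terms (each non-root term gets one tree
#' parent on the previous level plus optional extra parents) and assigns
#' protein annotations so that exactly `n_informative` designated frontier
#' terms pass the informative-term rule at `min_count`: each frontier term
#' receives at least `min_count` directly annotated proteins while every
#' other term receives strictly fewer and no frontier term is an ancestor of
#' another.
#'
#' @param n_terms Total number of terms (>= n_informative + 1).
#' @param depth Number of levels below the root (>= 1).
#' @param proteins Character vector of available protein IDs.
#' @param n_informative Number of planted informative terms (default 3).
#' @param min_count Informative-term threshold (default 30).
#' @param extra_parent_prob Probability of an extra (DAG) parent per term.
#' @param namespace Namespace tag for all terms.
#' @param seed Integer RNG seed.
#' @return A `psp_ontology` object with attribute `informative`: the planted
#'   frontier term IDs.
#' @export
gen_ontology <- function(n_terms, depth, proteins, n_informative = 3,
                         min_count = 30, extra_parent_prob = 0.1,
                         namespace = "biological_process", seed) {
  stopifnot(depth >= 1, n_terms >= n_informative + 1)
  if (missing(seed)) stop_data("gen_ontology requires an explicit seed")
  blk_size <- min_count + 5   # frontier counts must exceed min_count so no
                              # ancestor can pass the "no child > min_count" test
  if (length(proteins) < n_informative * blk_size + 10)
    stop_data("need at least n_informative * (min_count + 5) + 10 proteins")
  set.seed(seed)
  ids <- sprintf("T:%04d", seq_len(n_terms))
  level <- c(0, sort(sample.int(depth, n_terms - 1, replace = TRUE)))
  parents <- vector("list", n_terms)
  for (i in 2:n_terms) {
    cand <- which(level < level[i])
    par <- cand[sample.int(length(cand), 1)]
    extra <- cand[cand != par & stats::runif(length(cand)) < extra_parent_prob]
    parents[[i]] <- ids[sort(unique(c(par, utils::head(extra, 2))))]
  }
  terms <- tibble::tibble(term_id = ids,
                          name = sprintf("synthetic term %d", seq_len(n_terms)),
                          namespace = namespace, parents = parents)
  ont <- structure(list(terms = terms,
                        annotations = tibble::tibble(protein_id = character(),
                                                     term_id = character())),
                   class = "psp_ontology")
  # frontier: leaf terms (no children), pairwise non-ancestral by construction
  has_child <- ids %in% unlist(parents)
  leaves <- ids[!has_child]
  if (length(leaves) < n_informative)
    stop_data("DAG has too few leaves for the requested frontier")
  frontier <- sort(sample(leaves, n_informative))
  # annotations: frontier terms get disjoint blocks of min_count + 5 proteins
  # (above the threshold, so every ancestor has a child with count > min_count
  # and fails the rule); non-frontier leaves draw 1-2 proteins from a shared
  # 10-protein pool, so no other term can accumulate min_count unique proteins.
  pool <- sample(proteins)
  ann <- list()
  take <- 0
  for (f in frontier) {
    blk <- pool[(take + 1):(take + blk_size)]
    take <- take + blk_size
    ann[[length(ann) + 1]] <- tibble::tibble(protein_id = blk, term_id = f)
  }
  small_pool <- pool[(take + 1):(take + 10)]
  other_leaves <- setdiff(leaves, frontier)
  for (lf in other_leaves) {
    k <- sample.int(2, 1)
    ann[[length(ann) + 1]] <- tibble::tibble(
      protein_id = sample(small_pool, k), term_id = lf)
  }
  ont$annotations <- dplyr::distinct(dplyr::bind_rows(ann))
  attr(ont, "informative") <- frontier
  ont
}

#' Write a `psp_ontology` to OBO 1.2 and GAF 2.1 files
#'
#' @param ontology A `psp_ontology` object.
#' @param obo,gaf Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_obo_gaf <- function(ontology, obo, gaf) {
  hdr <- c("format-version: 1.2", "")
  stanzas <- purrr::map(seq_len(nrow(ontology$terms)), function(i) {
    t <- ontology$terms[i, ]
    c("[Term]",
      paste0("id: ", t$term_id),
      paste0("name: ", t$name),
      paste0("namespace: ", t$namespace),
      paste0("is_a: ", t$parents[[1]]),
      "")
  })
  writeLines(c(hdr, unlist(stanzas)), obo)
  asp <- c(biological_process = "P", cellular_component = "C",
           molecular_function = "F")
  ns <- ontology$terms$namespace[match(ontology$annotations$term_id,
                                       ontology$terms$term_id)]
  gaf_rows <- sprintf("DB\t%s\t%s\t\t%s\tREF\tIEA\t\t%s\t\t\tprotein\ttaxon:9606\t20110423\tDB\t\t",
                      ontology$annotations$protein_id,
                      ontology$annotations$protein_id,
                      ontology$annotations$term_id,
                      ifelse(is.na(asp[ns]), "P", asp[ns]))
  writeLines(c("!gaf-version: 2.1", gaf_rows), gaf)
  invisible(list(obo = obo, gaf = gaf))
}

#' Simulate a complete HCC-like input bundle
#'
#' One call producing every input the pipeline consumes, at the study's
#' conditions: a 6 + 7 two-class cohort with highly inconsistent detection
#' lists (background detection probability 0.3), a pathway collection, a
#' CORUM-like complex collection of which a subset carries class-linked
#' signal, per-patient iTRAQ-style ratios, and a small ontology with a
#' curated term list. Optionally writes the standard files to a directory.
#'
#' @param seed Integer RNG seed (required; all content derives from it).
#' @param out_dir Optional directory; when given, writes `pathways.tsv`,
#'   `complexes.gmt`, `detections.tsv`, `ratios.tsv`, `ontology.obo`,
#'   `annotations.gaf` and `lipid_terms.txt`.
#' @param n_A,n_B Class sizes (default 6 and 7).
#' @param n_pathways Number of pathways (default 40).
#' @param n_complexes Number of complexes (default 60).
#' @param complex_sizes Candidate complex sizes (default `4:25`).
#' @param n_signal_complexes How many complexes carry signal (default 10).
#' @param proteome_size Background proteome size (default 1200).
#' @param background_p Background detection probability (default 0.3).
#' @param p_detect_A,p_detect_B Signal detection probabilities (0.9 / 0.2).
#' @return List: `profiles`, `pathways`, `complexes`, `signal_ids`,
#'   `ontology`, `lipid_terms`, `files` (paths or NULL).
#' @export
simulate_preset <- function(seed, out_dir = NULL, n_A = 6, n_B = 7,
                            n_pathways = 40, n_complexes = 60,
                            complex_sizes = 4:25, n_signal_complexes = 10,
                            proteome_size = 1200, background_p = 0.3,
                            p_detect_A = 0.9, p_detect_B = 0.2) {
  if (missing(seed)) stop_data("simulate_preset requires an explicit seed")
  pathways <- gen_pathways(n_pathways, seed = seed + 1)
  proteome <- sprintf("PROT%05d", seq_len(proteome_size))
  pathway_prot <- unique(unlist(pathways$nodes))
  universe <- unique(c(proteome, pathway_prot))
  set.seed(seed + 2)
  complexes <- feature_table(
    feature_id = sprintf("CPX%03d", seq_len(n_complexes)),
    members = lapply(seq_len(n_complexes), function(i)
      sort(sample(universe, sample(complex_sizes, 1)))),
    kind = "complex", source_pathway = NA_character_
  )
  signal_ids <- complexes$feature_id[seq_len(n_signal_complexes)]
  profiles <- gen_cohort(
    n_A, n_B, universe, background_p = background_p,
    signal_features = complexes[complexes$feature_id %in% signal_ids, ],
    p_detect_A = p_detect_A, p_detect_B = p_detect_B,
    class_labels = c("mod", "poor"), seed = seed + 3)
  ontology <- gen_ontology(60, 3, universe, n_informative = 4, seed = seed + 4)
  lipid_terms <- attr(ontology, "informative")[1:2]
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(out_dir, x)
    write_pathways(pathways, fp("pathways.tsv"))
    write_gmt(complexes, fp("complexes.gmt"))
    write_detections(profiles, fp("detections.tsv"), fp("ratios.tsv"))
    write_obo_gaf(ontology, fp("ontology.obo"), fp("annotations.gaf"))
    writeLines(lipid_terms, fp("lipid_terms.txt"))
    files <- stats::setNames(
      vapply(c("pathways.tsv", "complexes.gmt", "detections.tsv", "ratios.tsv",
               "ontology.obo", "annotations.gaf", "lipid_terms.txt"),
             fp, character(1)),
      c("pathways", "complexes", "detections", "ratios", "obo", "gaf", "terms"))
  }
  list(profiles = profiles, pathways = pathways, complexes = complexes,
       signal_ids = signal_ids, ontology = ontology,
       lipid_terms = lipid_terms, files = files)
}
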