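#' Run the signature-profiling pipeline from a configuration
#'
#' Executes the stages in dependency order — simulate (optional), candidate
#' selection, PDS extraction, hit-rate profiling, bootstrapped clustering,
#' feature selection — and writes every output as TSV (plus Newick for the
#' dendrogram) with `# key=value` header comments echoing the tool version,
#' seed and parameters, so a run can be reproduced from its outputs alone.
#'
#' Configuration is a flat named list (or a YAML file of one). Recognised
#' keys: `simulate` (logical; generate inputs in `out_dir/inputs`),
#' `detections`, `ratios`, `pathways`, `complexes` (input paths when not
#' simulating), `features` (`"pds"`, `"complexes"` or `"both"`), `min_size`,
#' `n_perm`, `alpha`, `bh`, `alternative`, `ties`, `boot_B`, `seed`,
#' `out_dir`. Unknown keys raise a usage error naming the key; a stage whose
#' upstream input is missing raises an error naming the stage.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with the in-memory results (`profiles`,
#'   `features`, `signature`, `boot`, `stats`) and `out_dir`.
#' @export
psp_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  defaults <- list(simulate = FALSE, detections = NULL, ratios = NULL,
                   pathways = NULL, complexes = NULL, features = "pds",
                   min_size = 4, n_perm = 10000, alpha = 0.05, bh = FALSE,
                   alternative = "signed", ties = "strict",
                   boot_B = 1000, seed = 1, out_dir = tempfile("psp_run"))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "psp_usage_error")
  cfg <- utils::modifyList(defaults, config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  echo <- cfg[c("features", "min_size", "n_perm", "alpha", "bh",
                "alternative", "ties", "boot_B", "seed")]

  if (isTRUE(cfg$simulate)) {
    sim <- simulate_preset(seed = cfg$seed, out_dir = file.path(cfg$out_dir, "inputs"))
    profiles <- sim$profiles; pathways <- sim$pathways; complexes <- sim$complexes
  } else {
    if (is.null(cfg$detections))
      stop_data("stage 'profile' is missing its upstream input: detections")
    ratios <- if (!is.null(cfg$ratios)) read_ratios(cfg$ratios) else NULL
    profiles <- read_detections(cfg$detections, ratios = ratios)
    pathways <- if (!is.null(cfg$pathways)) read_pathways(cfg$pathways) else NULL
    complexes <- if (!is.null(cfg$complexes)) read_gmt(cfg$complexes) else NULL
  }

  features <- NULL
  if (cfg$features %in% c("pds", "both")) {
    if (is.null(pathways))
      stop_data("stage 'extract-pds' is missing its upstream input: pathways")
    cand <- candidate_proteins(profiles)
    cat_out <- pds_catalogue(pathways, cand, min_size = cfg$min_size)
    features <- cat_out$features
    write_tsv_commented(feature_export(cat_out$features),
                        file.path(cfg$out_dir, "pds.tsv"), echo)
    write_tsv_commented(cat_out$contributions,
                        file.path(cfg$out_dir, "pds_contributions.tsv"), echo)
  }
  if (cfg$features %in% c("complexes", "both")) {
    if (is.null(complexes))
      stop_data("stage 'profile' is missing its upstream input: complexes")
    features <- dplyr::bind_rows(features, complexes)
  }
  if (is.null(features) || nrow(features) == 0)
    stop_data("stage 'profile' is missing its upstream input: features")

  sig <- build_signature(profiles, features, min_size = cfg$min_size)
  write_signature(sig, file.path(cfg$out_dir, "signature.tsv"), echo)

  boot <- multiscale_bootstrap(sig, B = cfg$boot_B, seed = cfg$seed)
  write_boot_newick(boot, file.path(cfg$out_dir, "dendrogram.nwk"))
  write_tsv_commented(
    dplyr::mutate(boot$nodes, leaves = vapply(.data$leaves, paste,
                                              character(1), collapse = ";")),
    file.path(cfg$out_dir, "cluster_confidence.tsv"), echo)

  stats_tab <- select_features(sig, features = features, profiles = profiles,
                               n_perm = cfg$n_perm, seed = cfg$seed,
                               alternative = cfg$alternative, ties = cfg$ties,
                               alpha = cfg$alpha, bh = cfg$bh)
  write_tsv_commented(stats_tab, file.path(cfg$out_dir, "feature_stats.tsv"), echo)

  invisible(list(profiles = profiles, features = features, signature = sig,
                 boot = boot, stats = stats_tab, out_dir = cfg$out_dir))
}

# Feature tibble -> flat exportable table (members semicolon-joined).
feature_export <- function(features) {
  tibble::tibble(
    feature_id = features$feature_id,
    kind = features$kind,
    source_pathway = features$source_pathway,
    size = features$n_members,
    members = vapply(features$members, paste, character(1), collapse = ";")
  )
}
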