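#' Hit rate of a feature set in one detection list
#'
#' The fraction of a feature's member proteins found in a patient's detected
#' set: `|members ∩ detected| / |members|`. This is the elementary quantity of
#' signature profiling — detection is noisy protein by protein but informative
#' in aggregate over a coherent complex or subnet.
#'
#' @param members Character vector of feature member proteins (non-empty).
#' @param detected Character vector of proteins detected in one patient.
#' @return A fraction in `[0, 1]`.
#' @export
hit_rate <- function(members, detected) {
  members <- unique(members)
  if (length(members) == 0) stop_data("hit_rate: empty feature")
  length(intersect(members, detected)) / length(members)
}

#' Build a patient-by-feature hit-rate signature matrix
#'
#' Each patient's signature profile is the vector of hit rates over the
#' feature collection. Row (patient) and column (feature) order follow the
#' input order; features below the minimum size are excluded with a warning.
#' All-zero rows and columns are retained.
#'
#' @param profiles Profile tibble; at least 2 patients.
#' @param features Feature tibble; at least 1 feature at or above `min_size`.
#' @param min_size Minimum feature size used (default 4).
#' @return A tibble of class `psp_signature`: `patient_id`, `class`, then one
#'   numeric column of exact hit-rate fractions per feature.
#' @export
build_signature <- function(profiles, features, min_size = 4) {
  stopifnot(nrow(profiles) >= 2)
  small <- features$n_members < min_size
  if (any(small)) {
    rlang::warn(sprintf("excluded %d feature(s) below minimum size %d",
                        sum(small), min_size))
    features <- features[!small, ]
  }
  if (nrow(features) == 0) stop_data("no features at or above minimum size")
  vals <- vapply(features$members, function(m) {
    vapply(profiles$detected, function(d) hit_rate(m, d), numeric(1))
  }, numeric(nrow(profiles)))
  vals <- matrix(vals, nrow = nrow(profiles),
                 dimnames = list(NULL, features$feature_id))
  out <- dplyr::bind_cols(
    tibble::tibble(patient_id = profiles$patient_id, class = profiles$class),
    tibble::as_tibble(vals)
  )
  class(out) <- c("psp_signature", class(out))
  out
}

# Numeric matrix view of a signature tibble (patients x features).
sig_matrix <- function(sig) {
  m <- as.matrix(sig[, sig_feature_ids(sig), drop = FALSE])
  rownames(m) <- sig$patient_id
  m
}

# Feature column names of a signature tibble.
sig_feature_ids <- function(sig) {
  setdiff(names(sig), c("patient_id", "class"))
}

# Rebuild a psp_signature from parts.
as_signature <- function(patient_id, class, values) {
  out <- dplyr::bind_cols(tibble::tibble(patient_id = patient_id, class = class),
                          tibble::as_tibble(values))
  class(out) <- c("psp_signature", class(out))
  out
}

#' Write / read a signature matrix as TSV
#'
#' Patients as rows; `patient_id`, `class` (label as second column), then one
#' column per feature.
#'
#' @param sig A `psp_signature` tibble.
#' @param path File path.
#' @param params Optional named list echoed as `# key=value` header comments.
#' @return `path` (writer) or the signature tibble (reader).
#' @export
write_signature <- function(sig, path, params = list()) {
  write_tsv_commented(as.data.frame(sig), path, params)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           class = readr::col_character(),
                           .default = readr::col_double()))
  class(tab) <- c("psp_signature", class(tab))
  tab
}

#' @method autoplot psp_signature
#' @export
autoplot.psp_signature <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = -c("patient_id", "class"),
                              names_to = "feature", values_to = "hit_rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$patient_id,
                                     fill = .data$hit_rate)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$class), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "feature", y = "patient", fill = "hit rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
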