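#' Names of the 18 network features, in canonical order
#'
#' Min/mean/max of strength, shortest path length, closeness, eigenvector
#' centrality and clustering; mean/max of betweenness; and the power-law
#' scaling index of the strength distribution.
#'
#' @return Character vector of length 18.
#' @export
feature_names <- function() {
  c(
    "strength_min", "strength_mean", "strength_max",
    "path_min", "path_mean", "path_max",
    "closeness_min", "closeness_mean", "closeness_max",
    "betweenness_mean", "betweenness_max",
    "eigenvector_min", "eigenvector_mean", "eigenvector_max",
    "clustering_min", "clustering_mean", "clustering_max",
    "powerlaw_alpha"
  )
}

#' Network feature vector of a connectivity matrix
#'
#' Assembles the 18 scalar network characteristics of a subject's weighted
#' SL network: node-level strength, mean shortest path length (1/w edge
#' lengths), closeness, betweenness, eigenvector centrality and weighted
#' clustering, each summarized by its minimum, mean and maximum across
#' nodes (betweenness: mean and maximum only), plus the power-law scaling
#' index fitted to the node strengths.
#'
#' @param W A symmetric SL `connectivity_matrix`, at least 3 nodes.
#' @param clustering_method Passed to [weighted_clustering()].
#' @param powerlaw_method Passed to [powerlaw_fit()].
#' @return A one-row tibble with the columns of [feature_names()].
#' @export
feature_vector <- function(W, clustering_method = "onnela",
                           powerlaw_method = "fixed") {
  s <- strength(W)
  p <- weighted_shortest_paths(W)
  cc <- closeness(p$distances)
  bc <- betweenness(W)
  ec <- eigenvector_centrality(W)
  cl <- weighted_clustering(W, method = clustering_method)
  pl <- powerlaw_fit(s$values, method = powerlaw_method)
  out <- tibble::tibble(
    strength_min = s$min, strength_mean = s$mean, strength_max = s$max,
    path_min = p$min, path_mean = p$mean, path_max = p$max,
    closeness_min = cc$min, closeness_mean = cc$mean, closeness_max = cc$max,
    betweenness_mean = bc$mean, betweenness_max = bc$max,
    eigenvector_min = ec$min, eigenvector_mean = ec$mean,
    eigenvector_max = ec$max,
    clustering_min = cl$min, clustering_mean = cl$mean, clustering_max = cl$max,
    powerlaw_alpha = pl$alpha
  )
  stopifnot(identical(names(out), feature_names()), all(is.finite(unlist(out))))
  out
}

#' Feature table for a whole cohort
#'
#' Runs the full per-subject pipeline — optional band filtering, SL
#' connectivity averaged over epochs, 18 network features — over a cohort
#' tibble, returning the samples-by-features table the classifier consumes.
#'
#' @param cohort Tibble from [generate_cohort()], or one already carrying a
#'   `connectivity` list-column from [cohort_connectivity()].
#' @param params An [sl_params()]; defaults to band-adaptive broadband
#'   parameters.
#' @param band Optional [frequency_band()] applied before SL.
#' @param ... Passed to [feature_vector()].
#' @return Tibble with `subject_id`, `group` and the 18 feature columns.
#' @export
cohort_features <- function(cohort, params = NULL, band = NULL, ...) {
  stopifnot(is.data.frame(cohort))
  if (!"connectivity" %in% names(cohort)) {
    cohort <- cohort_connectivity(cohort, params = params, band = band)
  }
  feats <- purrr::map(cohort$connectivity, feature_vector, ...)
  dplyr::bind_cols(
    dplyr::select(cohort, dplyr::all_of(c("subject_id", "group"))),
    dplyr::bind_rows(feats)
  )
}

#' Export a cohort feature table to CSV
#'
#' One row per subject: `subject_id`, `group`, then the 18 features.
#'
#' @param features Tibble from [cohort_features()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
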