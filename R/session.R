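# Session state: the frozen search result (query, hits, hit sequences,
# parameters) that re-clustering consumes, serialized as one versioned
# JSON document so new cutoffs can be tried across processes without
# repeating the search.

.SESSION_SCHEMA <- 1L

#' Build a session state
#'
#' @param query single sequence record (the search query).
#' @param hits hit `data.frame`.
#' @param hit_sequences record `data.frame` covering every hit subject.
#' @param search_params the [search_params()] used.
#' @param clustering_params the last [clustering_params()] applied.
#' @return a `session_state` list.
#' @export
session_state <- function(query, hits, hit_sequences,
                          search_params = hitclust::search_params(),
                          clustering_params = hitclust::clustering_params()) {
  if (nrow(hits) > 0L &&
      !all(hits$subject_id %in% hit_sequences$accession)) {
    stop("hit_sequences must cover every hit subject id", call. = FALSE)
  }
  structure(list(schema_version = .SESSION_SCHEMA, query = query,
                 hits = hits, hit_sequences = hit_sequences,
                 search_params = search_params,
                 clustering_params = clustering_params),
            class = "session_state")
}

#' Save a session state to JSON
#'
#' @param state a [session_state()].
#' @param path output path (conventionally `state.json`).
#' @export
save_session <- function(state, path) {
  stopifnot(inherits(state, "session_state"))
  doc <- list(
    schema_version = state$schema_version,
    query = as.list(state$query[1, c("accession", "description", "residues")]),
    search_params = unclass(state$search_params),
    clustering_params = list(
      user_cutoff_pct = state$clustering_params$policy$user_cutoff_pct,
      rost_offset_n = state$clustering_params$policy$rost_offset_n,
      length_diff_limit = state$clustering_params$length_diff_limit),
    hits = state$hits,
    sequences = state$hit_sequences[, c("accession", "description",
                                        "residues")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Load a session state from JSON
#'
#' @param path path written by [save_session()].
#' @return a `session_state` list.
#' @export
load_session <- function(path) {
  if (!file.exists(path)) stop("state file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse state file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(doc$schema_version) ||
      !identical(as.integer(doc$schema_version), .SESSION_SCHEMA)) {
    stop("incompatible or missing session schema version in ", path,
         call. = FALSE)
  }
  query <- seq_records(doc$query$accession, doc$query$residues,
                       doc$query$description)
  seqs <- seq_records(doc$sequences$accession, doc$sequences$residues,
                      doc$sequences$description)
  hits <- as.data.frame(doc$hits)
  if (nrow(hits) > 0L) hits$rank <- as.integer(hits$rank)
  sp <- search_params(doc$search_params$evalue_threshold,
                      doc$search_params$matrix,
                      doc$search_params$low_complexity_filter,
                      doc$search_params$max_hits)
  cp <- clustering_params(
    threshold_policy(doc$clustering_params$user_cutoff_pct,
                     doc$clustering_params$rost_offset_n),
    doc$clustering_params$length_diff_limit)
  session_state(query, hits, seqs, sp, cp)
}

#' Re-cluster a saved session at new parameters
#'
#' Runs the two-pass clusterer on the session's stored hit sequences; no
#' search is executed. Deterministic: repeated calls with identical
#' parameters give identical clusters.
#'
#' @param state a [session_state()] (or a path to one).
#' @param new_params a [clustering_params()]; default re-uses the stored
#'   parameters.
#' @return list of finalized clusters.
#' @export
recluster <- function(state, new_params = NULL) {
  if (is.character(state)) state <- load_session(state)
  stopifnot(inherits(state, "session_state"))
  if (is.null(new_params)) new_params <- state$clustering_params
  if (!inherits(new_params, "clustering_params")) {
    stop("new_params must be a clustering_params", call. = FALSE)
  }
  if (nrow(state$hits) == 0L) return(list())
  seqs <- resolve_hit_sequences(state$hits, state$hit_sequences)
  cluster_hits(seqs, new_params, state$hits)
}
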