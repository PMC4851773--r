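# End-to-end wiring: search (or precomputed-hit parsing) -> sequence
# resolution -> two-pass clustering -> annotation -> reports + session
# state. This is what the command-line `run` and `recluster` subcommands
# call; logging goes to stderr via message(), machine artifacts to the
# output directory only.

.log_stage <- function(...) message("[hitclust] ", sprintf(...))

.write_outputs <- function(out_dir, state, clusters, ann_table) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- state$hit_sequences
  colors <- assign_colors(clusters)
  annotations <- if (length(clusters)) {
    annotate_clusters(clusters, ann_table, seqs)
  } else {
    list()
  }
  rows <- build_report_rows(state$hits, clusters, seqs, colors)
  paths <- c(report = file.path(out_dir, "report.tsv"),
             clusters = file.path(out_dir, "clusters.json"),
             summary = file.path(out_dir, "clusters.tsv"),
             state = file.path(out_dir, "state.json"))
  write_hit_report(rows, paths[["report"]])
  write_cluster_report(clusters, annotations, paths[["clusters"]],
                       colors = colors, summary_path = paths[["summary"]])
  save_session(state, paths[["state"]])
  paths
}

#' Run the full pipeline
#'
#' Either BLASTs the query against `db_path` (live mode, needs blastp on
#' the PATH) or takes a precomputed tabular hit file (`hits_path`), then
#' resolves the hit sequences from the database FASTA, clusters them in
#' two passes, annotates the clusters and writes `report.tsv`,
#' `clusters.json`, `clusters.tsv` and `state.json` into `out_dir`. A
#' zero-hit search is a success and produces empty-but-valid artifacts.
#'
#' @param query_path FASTA with the query (first record used).
#' @param db_path FASTA database; hit sequences are resolved from it in
#'   both modes.
#' @param hits_path optional precomputed BLAST tabular file; when given,
#'   no search is executed.
#' @param annotations_path optional per-protein annotation TSV (see
#'   [read_annotation_table()]).
#' @param out_dir output directory, created if needed.
#' @param search_params a [search_params()].
#' @param clust_params a [clustering_params()].
#' @return invisibly, a list with `clusters`, `hits`, `paths`.
#' @export
run_pipeline <- function(query_path, db_path, hits_path = NULL,
                         annotations_path = NULL, out_dir,
                         search_params = hitclust::search_params(),
                         clust_params = clustering_params()) {
  query <- read_fasta(query_path)[1, , drop = FALSE]
  .log_stage("query: %s (%d aa)", query$accession, query$length)
  db <- read_fasta(db_path)
  .log_stage("database: %d sequences", nrow(db))
  if (is.null(hits_path)) {
    hits <- run_search(query, db_path, search_params)
    .log_stage("blastp search: %d hits", nrow(hits))
  } else {
    hits <- parse_blast_tabular(hits_path)
    hits <- hits[hits$evalue <= search_params$evalue_threshold, ,
                 drop = FALSE]
    if (nrow(hits) > search_params$max_hits) {
      hits <- hits[seq_len(search_params$max_hits), , drop = FALSE]
    }
    hits$rank <- seq_len(nrow(hits))
    .log_stage("precomputed hit file: %d hits after e-value filter",
               nrow(hits))
  }
  seqs <- resolve_hit_sequences(hits, db)
  ann_table <- if (!is.null(annotations_path)) {
    read_annotation_table(annotations_path)
  }
  clusters <- if (nrow(hits) > 0L) {
    cluster_hits(seqs, clust_params, hits)
  } else {
    list()
  }
  .log_stage("clustering: %d hits -> %d clusters (cutoff %.1f%%, length diff < %d)",
             nrow(hits), length(clusters),
             clust_params$policy$user_cutoff_pct,
             clust_params$length_diff_limit)
  state <- session_state(query, hits, seqs, search_params, clust_params)
  paths <- .write_outputs(out_dir, state, clusters, ann_table)
  .log_stage("wrote %s", paste(basename(paths), collapse = ", "))
  invisible(list(clusters = clusters, hits = hits, paths = paths))
}

#' Re-cluster a saved session and rewrite the reports
#'
#' Loads `state.json`, re-runs the two-pass clusterer at the new cutoff
#' (no search is executed), and rewrites the report files. With unchanged
#' parameters the rewritten `clusters.json` is byte-identical.
#'
#' @param state_path path to a `state.json` written by [run_pipeline()].
#' @param out_dir output directory (defaults to the state file's).
#' @param identity_cutoff new user cutoff in percent, or `NULL` to keep
#'   the stored one.
#' @param length_diff_limit new pass-1 length rule, or `NULL` to keep.
#' @param annotations_path optional annotation TSV.
#' @return invisibly, a list with `clusters` and `paths`.
#' @export
recluster_session <- function(state_path, out_dir = dirname(state_path),
                              identity_cutoff = NULL,
                              length_diff_limit = NULL,
                              annotations_path = NULL) {
  state <- load_session(state_path)
  cp <- state$clustering_params
  if (!is.null(identity_cutoff)) {
    cp <- clustering_params(
      threshold_policy(identity_cutoff, cp$policy$rost_offset_n),
      if (is.null(length_diff_limit)) cp$length_diff_limit
      else length_diff_limit)
  } else if (!is.null(length_diff_limit)) {
    cp <- clustering_params(cp$policy, length_diff_limit)
  }
  clusters <- recluster(state, cp)
  .log_stage("reclustering: %d hits -> %d clusters (cutoff %.1f%%)",
             nrow(state$hits), length(clusters), cp$policy$user_cutoff_pct)
  state$clustering_params <- cp
  ann_table <- if (!is.null(annotations_path)) {
    read_annotation_table(annotations_path)
  }
  paths <- .write_outputs(out_dir, state, clusters, ann_table)
  invisible(list(clusters = clusters, paths = paths))
}
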