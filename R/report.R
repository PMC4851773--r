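# Output views: the cluster-colored hit report (TSV) and the per-cluster
# summary (JSON, byte-stable). Percent identities are printed with two
# decimals throughout.

#' The 20-color cluster palette
#'
#' Distinct named colors label clusters 1..20; any further cluster falls
#' back to "grey".
#'
#' @return character vector of 20 color names.
#' @export
cluster_palette <- function() {
  c("red", "blue", "green", "orange", "purple", "cyan", "magenta", "gold",
    "brown", "pink", "turquoise", "salmon", "olivedrab", "navy", "maroon",
    "violet", "khaki", "sienna", "plum", "seagreen")
}

#' Assign display colors to clusters
#'
#' @param clusters list of finalized clusters (indexed 1..k).
#' @return named character vector: cluster index -> color name; indices
#'   above 20 all map to "grey".
#' @export
assign_colors <- function(clusters) {
  k <- length(clusters)
  if (k == 0L) return(setNames(character(0), character(0)))
  pal <- cluster_palette()
  cols <- ifelse(seq_len(k) <= length(pal), pal[seq_len(k)], "grey")
  setNames(cols, as.character(seq_len(k)))
}

#' Build the per-hit report rows
#'
#' One row per hit, ordered by rank, carrying the member's display label
#' (with the `"2:"` pass-2 prefix where applicable), its identity to the
#' query, and its cluster's index and color.
#'
#' @param hits hit `data.frame`.
#' @param clusters finalized clusters covering every hit.
#' @param sequences record `data.frame` for sequence lengths.
#' @param colors result of [assign_colors()] (computed when `NULL`).
#' @return `data.frame` with columns rank, accession, label, pident_query,
#'   evalue, bitscore, length, cluster, color.
#' @export
build_report_rows <- function(hits, clusters, sequences, colors = NULL) {
  if (is.null(colors)) colors <- assign_colors(clusters)
  if (nrow(hits) == 0L) {
    return(data.frame(rank = integer(0), accession = character(0),
                      label = character(0), pident_query = numeric(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      length = integer(0), cluster = integer(0),
                      color = character(0), stringsAsFactors = FALSE))
  }
  member_cluster <- list()
  member_label <- list()
  for (cl in clusters) {
    for (j in seq_len(nrow(cl$members))) {
      acc <- cl$members$accession[j]
      member_cluster[[acc]] <- cl$cluster_index
      member_label[[acc]] <- cl$members$display_label[j]
    }
  }
  missing <- setdiff(hits$subject_id, names(member_cluster))
  if (length(missing)) {
    stop("hits not covered by any cluster: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cl_idx <- vapply(hits$subject_id, function(a) member_cluster[[a]],
                   integer(1), USE.NAMES = FALSE)
  data.frame(
    rank = hits$rank,
    accession = hits$subject_id,
    label = vapply(hits$subject_id, function(a) member_label[[a]],
                   character(1), USE.NAMES = FALSE),
    pident_query = hits$pident_query,
    evalue = hits$evalue,
    bitscore = hits$bitscore,
    length = sequences$length[match(hits$subject_id, sequences$accession)],
    cluster = cl_idx,
    color = unname(colors[as.character(cl_idx)]),
    stringsAsFactors = FALSE)
}

#' Write the cluster-colored hit report as TSV
#'
#' @param rows result of [build_report_rows()].
#' @param path output path (conventionally `report.tsv`).
#' @export
write_hit_report <- function(rows, path) {
  out <- rows
  if (nrow(out) == 0L) message("no hits: writing header-only report")
  out$pident_query <- sprintf("%.2f", out$pident_query)
  out$evalue <- format(out$evalue, scientific = TRUE, digits = 3)
  out$bitscore <- sprintf("%.1f", out$bitscore)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.cluster_json_doc <- function(clusters, annotations, colors) {
  lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    ann <- annotations[[i]]
    m <- cl$members
    members <- lapply(seq_len(nrow(m)), function(j) {
      list(accession = m$accession[j],
           identity_to_query = if (is.na(m$identity_to_query[j])) NULL else
             round(m$identity_to_query[j], 2),
           identity_to_rep = round(m$identity_to_rep[j], 2),
           is_representative = m$is_representative[j],
           label = m$display_label[j],
           pass = m$pass_no[j],
           rank = if (is.na(m$rank[j])) NULL else m$rank[j])
    })
    list(architectures = lapply(ann$architectures, function(a)
           list(count = a$count, domains = as.list(a$domains))),
         color = unname(colors[as.character(cl$cluster_index)]),
         index = cl$cluster_index,
         joint_taxonomy = as.list(ann$joint_taxonomy),
         length_max = ann$length_max,
         length_min = ann$length_min,
         members = members,
         n_members_annotated = ann$n_members_annotated,
         pdb_ids = as.list(ann$pdb_ids),
         representative = cl$representative)
  })
}

#' Write the per-cluster report as JSON (plus a TSV summary)
#'
#' The JSON document is byte-stable for identical inputs: keys are emitted
#' in sorted order, percents rounded to two decimals, clusters ordered by
#' index. It contains the full member lists, so the partition can be
#' reconstructed exactly (see [read_cluster_report()]).
#'
#' @param clusters finalized clusters.
#' @param annotations result of [annotate_clusters()] (or `NULL`).
#' @param path output JSON path (conventionally `clusters.json`).
#' @param colors result of [assign_colors()] (computed when `NULL`).
#' @param summary_path optional path for a one-line-per-cluster TSV view.
#' @export
write_cluster_report <- function(clusters, annotations = NULL, path,
                                 colors = NULL, summary_path = NULL) {
  if (is.null(colors)) colors <- assign_colors(clusters)
  if (is.null(annotations)) {
    annotations <- lapply(clusters, function(cl) {
      list(joint_taxonomy = character(0), architectures = list(),
           pdb_ids = character(0),
           length_min = min(cl$members$length),
           length_max = max(cl$members$length),
           n_members = nrow(cl$members), n_members_annotated = 0L)
    })
  }
  doc <- list(schema_version = 1L,
              clusters = .cluster_json_doc(clusters, annotations, colors))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(summary_path)) {
    df <- data.frame(
      cluster = vapply(clusters, `[[`, integer(1), "cluster_index"),
      color = unname(colors[as.character(seq_along(clusters))]),
      representative = vapply(clusters, `[[`, character(1),
                              "representative"),
      n_members = vapply(clusters, function(cl) nrow(cl$members),
                         integer(1)),
      members = vapply(clusters, function(cl)
        paste(cl$members$display_label, collapse = ","), character(1)),
      joint_taxonomy = vapply(annotations, function(a)
        paste(a$joint_taxonomy, collapse = ";"), character(1)),
      architectures = vapply(annotations, function(a)
        paste(vapply(a$architectures, function(x)
          sprintf("%s(x%d)", paste(x$domains, collapse = ";"), x$count),
          character(1)), collapse = " | "), character(1)),
      pdb_ids = vapply(annotations, function(a)
        paste(a$pdb_ids, collapse = ","), character(1)),
      length_min = vapply(annotations, `[[`, 1, "length_min"),
      length_max = vapply(annotations, `[[`, 1, "length_max"),
      stringsAsFactors = FALSE)
    write.table(df, summary_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a cluster report back
#'
#' @param path JSON path written by [write_cluster_report()].
#' @return list with `clusters`: index, representative, member accessions
#'   and labels -- enough to reconstruct the partition exactly.
#' @export
read_cluster_report <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(as.integer(doc$schema_version), 1L)) {
    stop("incompatible cluster report schema in ", path, call. = FALSE)
  }
  list(clusters = lapply(doc$clusters, function(cl) {
    list(index = as.integer(cl$index),
         representative = cl$representative,
         accessions = vapply(cl$members, `[[`, character(1), "accession"),
         labels = vapply(cl$members, `[[`, character(1), "label"),
         pass = vapply(cl$members, function(m) as.integer(m$pass),
                       integer(1)))
  }))
}
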