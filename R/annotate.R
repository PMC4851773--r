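# Per-protein annotations and per-cluster summaries: joint taxonomy
# (deepest common lineage prefix), domain architectures with member
# counts, PDB entries, length range.
#
# The annotation table is a TSV with header
#   accession  protein_name  organism  lineage  domains  pdb  length
# lineage and domains are ";"-separated (root->leaf / N->C order), pdb is
# ","-separated; every cell but accession may be empty. The table replaces
# live UniProt lookups so the whole pipeline runs offline.

.ANN_COLS <- c("accession", "protein_name", "organism", "lineage",
               "domains", "pdb", "length")

.split_semi <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else trimws(strsplit(x, ";")[[1]])
}

#' Read a per-protein annotation table
#'
#' @param path path to the TSV described above.
#' @return `data.frame` keyed by `accession` with list-columns `lineage`,
#'   `domains`, `pdb_ids` and integer `annotated_length`.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                   check.names = FALSE)
  if (!identical(names(df), .ANN_COLS)) {
    stop("annotation table must have header: ",
         paste(.ANN_COLS, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$accession)) {
    stop("duplicate accession(s) in annotation table: ",
         paste(unique(df$accession[duplicated(df$accession)]),
               collapse = ", "), call. = FALSE)
  }
  len <- suppressWarnings(as.integer(df$length))
  bad <- which(nzchar(df$length) & is.na(len))
  if (length(bad)) {
    stop("non-integer length for accession ", df$accession[bad[1L]],
         call. = FALSE)
  }
  out <- data.frame(accession = df$accession,
                    protein_name = df$protein_name,
                    organism = df$organism,
                    annotated_length = len,
                    stringsAsFactors = FALSE)
  out$lineage <- lapply(df$lineage, .split_semi)
  out$domains <- lapply(df$domains, .split_semi)
  out$pdb_ids <- lapply(df$pdb, function(x) {
    if (is.na(x) || !nzchar(x)) character(0)
    else sort(unique(trimws(strsplit(x, ",")[[1]])))
  })
  out
}

#' Write an annotation table in the package's TSV dialect
#'
#' @param ann annotation `data.frame` as returned by
#'   [read_annotation_table()].
#' @param path output path.
#' @export
write_annotation_table <- function(ann, path) {
  df <- data.frame(
    accession = ann$accession,
    protein_name = ann$protein_name,
    organism = ann$organism,
    lineage = vapply(ann$lineage, paste, character(1), collapse = ";"),
    domains = vapply(ann$domains, paste, character(1), collapse = ";"),
    pdb = vapply(ann$pdb_ids, paste, character(1), collapse = ","),
    length = ann$annotated_length,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Joint taxonomy of a set of lineages
#'
#' The longest common prefix (root -> leaf) of all non-empty lineages;
#' empty when the lineages share no root or when none is known.
#'
#' @param lineages list of character vectors, each a root-to-leaf lineage.
#' @return character vector, possibly empty.
#' @export
joint_taxonomy <- function(lineages) {
  stopifnot(is.list(lineages))
  lineages <- lineages[lengths(lineages) > 0L]
  if (length(lineages) == 0L) return(character(0))
  prefix <- lineages[[1]]
  for (ln in lineages[-1]) {
    k <- 0L
    n <- min(length(prefix), length(ln))
    while (k < n && identical(prefix[k + 1L], ln[k + 1L])) k <- k + 1L
    prefix <- prefix[seq_len(k)]
    if (k == 0L) break
  }
  prefix
}

#' Summarize one cluster's annotations
#'
#' Joint taxonomy, distinct domain architectures with member counts
#' (counts descending, ties by first appearance in member order), union of
#' PDB ids, and the length range taken from the actual sequences (all
#' members, annotated or not). Members absent from the table degrade
#' gracefully: they contribute lengths only.
#'
#' @param cluster one cluster (list with `members`).
#' @param table annotation `data.frame` from [read_annotation_table()], or
#'   `NULL`.
#' @param sequences record `data.frame` covering every member.
#' @return list with `joint_taxonomy`, `architectures` (list of
#'   `list(domains, count)`), `pdb_ids`, `length_min`, `length_max`,
#'   `n_members`, `n_members_annotated`.
#' @export
annotate_cluster <- function(cluster, table, sequences) {
  accs <- cluster$members$accession
  idx <- match(accs, sequences$accession)
  if (anyNA(idx)) {
    stop("sequences missing for: ", paste(accs[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  lens <- sequences$length[idx]
  res <- list(joint_taxonomy = character(0), architectures = list(),
              pdb_ids = character(0),
              length_min = min(lens), length_max = max(lens),
              n_members = length(accs), n_members_annotated = 0L)
  if (is.null(table)) return(res)
  aidx <- match(accs, table$accession)
  known <- which(!is.na(aidx))
  res$n_members_annotated <- length(known)
  if (length(known) == 0L) return(res)
  ann <- table[aidx[known], , drop = FALSE]
  res$joint_taxonomy <- joint_taxonomy(ann$lineage)
  res$pdb_ids <- sort(unique(unlist(ann$pdb_ids)))
  # distinct ordered architectures; members without domains contribute none
  keys <- vapply(ann$domains, paste, character(1), collapse = ";")
  has <- which(nzchar(keys))
  if (length(has)) {
    first_seen <- !duplicated(keys[has])
    tab <- table(factor(keys[has], levels = keys[has][first_seen]))
    ord <- order(-as.integer(tab), seq_along(tab))
    res$architectures <- lapply(ord, function(i) {
      list(domains = .split_semi(names(tab)[i]),
           count = as.integer(tab[[i]]))
    })
  }
  res
}

#' Summarize all clusters
#'
#' @param clusters list of finalized clusters.
#' @inheritParams annotate_cluster
#' @return list of [annotate_cluster()] results, in cluster order.
#' @export
annotate_clusters <- function(clusters, table, sequences) {
  lapply(clusters, annotate_cluster, table = table, sequences = sequences)
}

#' Fetch annotations from UniProt (network, opt-in)
#'
#' Best-effort helper that queries the UniProt REST API for each accession
#' and writes a table in the dialect of [read_annotation_table()]. Never
#' called by the core pipeline; requires network access. Unknown
#' accessions are skipped with a warning.
#'
#' @param accessions character vector (deduplicated).
#' @param path output TSV path.
#' @return the annotation `data.frame`, invisibly.
#' @export
fetch_uniprot_annotations <- function(accessions, path) {
  accessions <- unique(accessions)
  rows <- list()
  for (acc in accessions) {
    u <- paste0("https://rest.uniprot.org/uniprotkb/", acc,
                ".tsv?fields=accession,protein_name,organism_name,",
                "lineage,ft_domain,xref_pdb,length")
    txt <- tryCatch(readLines(url(u), warn = FALSE),
                    error = function(e) NULL)
    if (is.null(txt) || length(txt) < 2L) {
      warning("could not fetch annotation for ", acc)
      next
    }
    f <- strsplit(txt[2], "\t", fixed = TRUE)[[1]]
    f <- c(f, rep("", max(0, 7 - length(f))))
    doms <- regmatches(f[5], gregexpr('/note="[^"]+"', f[5]))[[1]]
    doms <- sub('/note="', "", sub('"$', "", doms))
    rows[[acc]] <- data.frame(
      accession = f[1], protein_name = f[2], organism = f[3],
      annotated_length = suppressWarnings(as.integer(f[7])),
      stringsAsFactors = FALSE)
    rows[[acc]]$lineage <- list(trimws(strsplit(f[4], ",")[[1]]))
    rows[[acc]]$domains <- list(doms)
    rows[[acc]]$pdb_ids <- list(setdiff(trimws(strsplit(f[6], ";")[[1]]), ""))
  }
  if (length(rows) == 0L) {
    ann <- read.delim(text = paste(.ANN_COLS, collapse = "\t"),
                      stringsAsFactors = FALSE)
    ann <- data.frame(accession = character(0),
                      protein_name = character(0), organism = character(0),
                      annotated_length = integer(0))
    ann$lineage <- list(); ann$domains <- list(); ann$pdb_ids <- list()
  } else {
    ann <- do.call(rbind, rows)
    rownames(ann) <- NULL
  }
  write_annotation_table(ann, path)
  invisible(ann)
}
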