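# Obtaining the hit list: parse precomputed 12-column BLAST tabular output,
# or drive an external blastp binary with the pipeline defaults.

.HIT_COLS <- c("query_id", "subject_id", "pident_query", "align_length",
               "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
               "evalue", "bitscore")

#' Search parameter set
#'
#' Defaults mirror the pipeline's search configuration: e-value threshold
#' 1e-05, BLOSUM62, low-complexity filter off. `max_hits` defaults to
#' 20000, the display limit of common web BLAST servers.
#'
#' @param evalue_threshold maximum e-value retained (> 0).
#' @param matrix scoring matrix name passed to blastp.
#' @param low_complexity_filter enable SEG filtering (default off).
#' @param max_hits maximum number of subjects retained (>= 1).
#' @return a `search_params` list.
#' @export
search_params <- function(evalue_threshold = 1e-5, matrix = "BLOSUM62",
                          low_complexity_filter = FALSE, max_hits = 20000L) {
  if (!is.numeric(evalue_threshold) || evalue_threshold <= 0) {
    stop("evalue_threshold must be > 0", call. = FALSE)
  }
  if (!is.numeric(max_hits) || max_hits < 1) {
    stop("max_hits must be >= 1", call. = FALSE)
  }
  structure(list(evalue_threshold = evalue_threshold,
                 matrix = as.character(matrix),
                 low_complexity_filter = isTRUE(low_complexity_filter),
                 max_hits = as.integer(max_hits)),
            class = "search_params")
}

.empty_hits <- function() {
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(.HIT_COLS)),
                               .HIT_COLS))
  df$query_id <- character(0)
  df$subject_id <- character(0)
  df$rank <- integer(0)
  df
}

#' Parse BLAST tabular output (outfmt 6)
#'
#' Reads the standard 12-column tab-separated format (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore),
#' ignoring `#` comment lines. Multiple HSPs for one subject are collapsed
#' to the single best HSP (highest bitscore; ties by lowest e-value, then
#' smallest sstart), because the pipeline reports one identity per hit
#' protein. Hits are ordered by bitscore descending (ties: lowest e-value,
#' then first occurrence) and given ranks 1..n.
#'
#' An empty file (after comments) signals "no hits" and yields a 0-row hit
#' table, not an error.
#'
#' @param path path to the tabular file.
#' @return hit `data.frame` with columns `query_id`, `subject_id`,
#'   `pident_query`, `align_length`, `mismatch`, `gapopen`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`, `rank`.
#' @export
parse_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(keep) == 0L) return(.empty_hits())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop(sprintf("line %d: expected 12 tab-separated columns, found %d",
                 keep[bad], nf[bad]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10)
  if (anyNA(num)) {
    bad <- which(apply(num, 1, anyNA))[1L]
    stop(sprintf("line %d: non-numeric value in a numeric column", keep[bad]),
         call. = FALSE)
  }
  hits <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                     stringsAsFactors = FALSE)
  hits[.HIT_COLS[3:12]] <- as.data.frame(num)
  hits$file_order <- seq_len(nrow(hits))
  # best HSP per subject
  o <- order(-hits$bitscore, hits$evalue, hits$sstart, hits$file_order)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits$subject_id), , drop = FALSE]
  # report order
  o <- order(-hits$bitscore, hits$evalue, hits$file_order)
  hits <- hits[o, , drop = FALSE]
  hits$file_order <- NULL
  rownames(hits) <- NULL
  hits$rank <- seq_len(nrow(hits))
  hits
}

#' Write hits back out as BLAST tabular
#'
#' Inverse of [parse_blast_tabular()] for already-collapsed hit tables;
#' used by the synthetic hit-set generator and the precomputed-hits mode.
#'
#' @param hits hit `data.frame`.
#' @param path output path.
#' @export
write_blast_tabular <- function(hits, path) {
  m <- hits[, .HIT_COLS, drop = FALSE]
  write.table(m, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run a blastp search against a FASTA database
#'
#' Formats `db_path` on the fly (makeblastdb) and runs blastp with tabular
#' output, then parses it with [parse_blast_tabular()]. If no blastp
#' executable is discoverable, a condition of class
#' `hitclust_blast_unavailable` is signalled so callers can fall back to
#' precomputed hit files.
#'
#' @param query a single sequence record (1-row record data.frame).
#' @param db_path path to a protein FASTA database.
#' @param params a [search_params()].
#' @return hit `data.frame` (see [parse_blast_tabular()]).
#' @export
run_search <- function(query, db_path, params = search_params()) {
  stopifnot(is.data.frame(query), nrow(query) == 1L)
  if (!file.exists(db_path)) stop("database not found: ", db_path, call. = FALSE)
  n_db <- length(fasta.seqlengths(db_path))
  if (n_db == 0L) return(.empty_hits())
  blastp <- Sys.which("blastp")
  makedb <- Sys.which("makeblastdb")
  if (!nzchar(blastp) || !nzchar(makedb)) {
    cond <- structure(
      class = c("hitclust_blast_unavailable", "error", "condition"),
      list(message = "no blastp/makeblastdb executable on PATH; use a precomputed hit file",
           call = sys.call()))
    stop(cond)
  }
  wd <- tempfile("blastdb")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  qfile <- file.path(wd, "query.fasta")
  write_fasta(query, qfile)
  dbprefix <- file.path(wd, "db")
  out <- file.path(wd, "hits.tsv")
  res <- system2(makedb, c("-in", shQuote(db_path), "-dbtype", "prot",
                           "-out", shQuote(dbprefix)),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(res, "status")) && attr(res, "status") != 0) {
    stop("makeblastdb failed: ", paste(res, collapse = "\n"), call. = FALSE)
  }
  args <- c("-query", shQuote(qfile), "-db", shQuote(dbprefix),
            "-outfmt", "6", "-evalue", format(params$evalue_threshold),
            "-matrix", params$matrix,
            "-seg", if (params$low_complexity_filter) "yes" else "no",
            "-max_target_seqs", params$max_hits,
            "-out", shQuote(out))
  res <- system2(blastp, args, stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(res, "status")) && attr(res, "status") != 0) {
    stop("blastp failed: ", paste(res, collapse = "\n"), call. = FALSE)
  }
  hits <- parse_blast_tabular(out)
  if (nrow(hits) > params$max_hits) hits <- hits[seq_len(params$max_hits), ]
  hits
}

#' Restrict a database to the sequences of a hit list
#'
#' @param hits hit `data.frame`.
#' @param db sequence-record `data.frame` covering every subject id.
#' @return record `data.frame` with one row per hit, in hit (rank) order.
#' @export
resolve_hit_sequences <- function(hits, db) {
  if (nrow(hits) == 0L) return(db[0, , drop = FALSE])
  idx <- match(hits$subject_id, db$accession)
  if (anyNA(idx)) {
    stop("subject id(s) absent from the database: ",
         paste(hits$subject_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- db[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
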