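# FASTA reading/writing and the sequence-record contract.
#
# A set of sequence records is a data.frame with columns
#   accession   first whitespace token of the header (UniProt-style
#               "db|ACC|name" reduced to ACC), unique within the set
#   description remainder of the header ("" when absent)
#   residues    uppercase amino acids; alphabet = 20 standard residues
#               plus B, Z, X, U, O; a trailing "*" stop is stripped on read
#   length      nchar(residues)

.SEQ_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYBZXUO", "")[[1]]

#' Build a set of sequence records
#'
#' @param accession character vector of unique identifiers.
#' @param residues character vector of amino-acid strings (uppercased;
#'   a single trailing `*` is stripped).
#' @param description optional character vector of free-text descriptions.
#' @return A `data.frame` with columns `accession`, `description`,
#'   `residues`, `length`.
#' @export
seq_records <- function(accession, residues, description = "") {
  accession <- as.character(accession)
  residues <- toupper(as.character(residues))
  residues <- sub("\\*$", "", residues)
  description <- rep_len(as.character(description), length(accession))
  if (length(accession) != length(residues)) {
    stop("'accession' and 'residues' must have equal length", call. = FALSE)
  }
  if (any(!nzchar(accession))) stop("empty accession", call. = FALSE)
  dup <- accession[duplicated(accession)]
  if (length(dup)) {
    stop("duplicate accession(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(residues))) {
    stop("empty sequence for: ",
         paste(accession[!nzchar(residues)], collapse = ", "), call. = FALSE)
  }
  bad <- vapply(strsplit(residues, ""), function(ch) {
    w <- which(!ch %in% .SEQ_ALPHABET)
    if (length(w)) w[1L] else 0L
  }, integer(1))
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal residue '%s' at position %d of record '%s'",
                 substr(residues[i], bad[i], bad[i]), bad[i], accession[i]),
         call. = FALSE)
  }
  data.frame(accession = accession, description = description,
             residues = residues, length = nchar(residues),
             stringsAsFactors = FALSE)
}

# Reduce "db|ACC|name"-style UniProt headers to the bare accession.
.clean_accession <- function(token) {
  piped <- grepl("^[^|]+\\|[^|]+\\|", token)
  token[piped] <- vapply(strsplit(token[piped], "|", fixed = TRUE),
                         `[[`, character(1), 2L)
  token
}

# Best-effort line number of the record with index `idx` in a FASTA file,
# used only to make validation errors actionable.
.fasta_record_line <- function(path, idx) {
  lines <- readLines(path, warn = FALSE)
  headers <- which(startsWith(lines, ">"))
  if (idx <= length(headers)) headers[idx] else NA_integer_
}

#' Read a protein FASTA file
#'
#' Headers are split into an accession (first whitespace token, UniProt
#' `db|ACC|name` prefixes reduced to `ACC`) and a description. Sequence
#' lines are concatenated, uppercased, and checked against the protein
#' alphabet (20 standard residues plus B, Z, X, U, O); one trailing `*`
#' stop codon marker is tolerated and stripped. Duplicate accessions and
#' empty sequences are rejected.
#'
#' @param path path to an existing FASTA file.
#' @return A sequence-record `data.frame` (see [seq_records()]), one row per
#'   record in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) stop("no FASTA records in: ", path, call. = FALSE)
  headers <- names(set)
  token <- sub("\\s.*$", "", headers)
  acc <- .clean_accession(token)
  desc <- sub("^\\S+\\s*", "", headers)
  residues <- toupper(gsub("[ \t\r]", "", as.character(set)))
  residues <- sub("\\*$", "", residues)
  dup <- which(duplicated(acc))
  if (length(dup)) {
    stop(sprintf("duplicate accession '%s' (record %d, near line %s) in %s",
                 acc[dup[1L]], dup[1L],
                 .fasta_record_line(path, dup[1L]), path), call. = FALSE)
  }
  empty <- which(!nzchar(residues))
  if (length(empty)) {
    stop(sprintf("empty sequence for '%s' (near line %s) in %s",
                 acc[empty[1L]], .fasta_record_line(path, empty[1L]), path),
         call. = FALSE)
  }
  for (i in seq_along(residues)) {
    ch <- strsplit(residues[i], "")[[1]]
    w <- which(!ch %in% .SEQ_ALPHABET)
    if (length(w)) {
      stop(sprintf(
        "illegal residue '%s' in record '%s' (record starts near line %s) in %s",
        ch[w[1L]], acc[i], .fasta_record_line(path, i), path), call. = FALSE)
    }
  }
  out <- data.frame(accession = unname(acc), description = unname(desc),
                    residues = unname(residues), length = nchar(residues),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write sequence records to FASTA
#'
#' Serializes with 60-column line wrapping; `read_fasta(write_fasta(x))`
#' is the identity on valid record sets.
#'
#' @param records sequence-record `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no records to write", call. = FALSE)
  set <- BStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$accession, records$description),
                       records$accession)
  writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
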