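# Small builders shared across tests. All fixtures are generated in code.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# substitute a fraction of positions (uniform over the other 19 residues)
mutate_protein <- function(res, rate) {
  ch <- strsplit(res, "")[[1]]
  for (i in which(runif(length(ch)) < rate)) {
    ch[i] <- sample(setdiff(AA20, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

tmp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

tmp_tabular <- function(rows) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(rows, f)
  f
}

tab_row <- function(q, s, pident, len, evalue, bitscore,
                    qstart = 1, qend = len, sstart = 1, send = len,
                    mismatch = 0, gapopen = 0) {
  paste(q, s, pident, len, mismatch, gapopen, qstart, qend, sstart, send,
        evalue, bitscore, sep = "\t")
}

# a record set drawn from a few planted families plus loose singletons,
# with length spread that exercises the pass-1 length rule
random_record_set <- function(seed, max_n = 30) {
  set.seed(seed)
  n_fam <- sample(1:4, 1)
  recs <- list()
  acc_i <- 0
  for (f in seq_len(n_fam)) {
    n_mem <- sample(1:6, 1)
    base_len <- sample(40:80, 1)
    base <- random_protein(base_len)
    rate <- runif(1, 0.05, 0.4)
    for (m in seq_len(n_mem)) {
      res <- if (m == 1) base else mutate_protein(base, rate)
      # occasional hard truncation to trip the length rule / pass-2 rescue
      if (m > 1 && runif(1) < 0.25) {
        res <- substr(res, 1, max(10, nchar(res) %/% 2))
      }
      acc_i <- acc_i + 1
      recs[[acc_i]] <- seq_records(sprintf("S%02d", acc_i), res)
    }
  }
  n_extra <- sample(0:4, 1)
  for (e in seq_len(n_extra)) {
    acc_i <- acc_i + 1
    recs[[acc_i]] <- seq_records(sprintf("S%02d", acc_i),
                                 random_protein(sample(30:90, 1)))
  }
  out <- do.call(rbind, recs)
  if (nrow(out) > max_n) out <- out[seq_len(max_n), , drop = FALSE]
  out
}

# synthetic hit table for a record set (every record a hit of a nominal
# query), enough for finalize/report plumbing
fake_hits <- function(records) {
  n <- nrow(records)
  data.frame(query_id = "Q", subject_id = records$accession,
             pident_query = round(runif(n, 20, 100), 2),
             align_length = records$length, mismatch = 0L, gapopen = 0L,
             qstart = 1L, qend = records$length, sstart = 1L,
             send = records$length,
             evalue = 10^-runif(n, 6, 50),
             bitscore = round(runif(n, 50, 500), 1),
             rank = seq_len(n), stringsAsFactors = FALSE)
}

# canonical comparable form of a cluster list: order-independent
canonical_clusters <- function(clusters) {
  cl <- lapply(clusters, function(c) {
    m <- c$members[order(c$members$accession), c("accession", "pass_no")]
    rownames(m) <- NULL
    list(representative = c$representative, members = m)
  })
  cl[order(vapply(cl, `[[`, character(1), "representative"))]
}

anr17_fixture <- function() {
  system.file("extdata", "synthetic_anr17_standin.fasta",
              package = "hitclust")
}
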