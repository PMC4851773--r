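# Synthetic protein families with planted cluster structure, so the whole
# pipeline (parsing, clustering, annotation, reporting) is testable without
# any database download. Families are generated independently, which keeps
# the expected between-family identity near the random-alignment
# background; within-family members are point-substituted copies of a
# family seed sequence, optionally with terminal length jitter, so the
# expected within-family identity is analytic (the substitution rate).

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of one synthetic family
#'
#' @param n_members number of sequences (seed included).
#' @param seed_length length of the family seed sequence, residues.
#' @param within_identity_target expected member-to-seed identity in
#'   percent (substitutions are planted at rate `1 - target/100`).
#' @param length_jitter maximum residues truncated from or appended to a
#'   member terminus (0 = all members full length).
#' @param rng_seed integer seed; generation is deterministic given it.
#' @return a `family_spec` list.
#' @export
family_spec <- function(n_members, seed_length = 120L,
                        within_identity_target = 85,
                        length_jitter = 0L, rng_seed = 1L) {
  if (within_identity_target <= 0 || within_identity_target > 100) {
    stop("within_identity_target must be in (0, 100]", call. = FALSE)
  }
  if (n_members < 1L) stop("n_members must be >= 1", call. = FALSE)
  structure(list(n_members = as.integer(n_members),
                 seed_length = as.integer(seed_length),
                 within_identity_target = as.numeric(within_identity_target),
                 length_jitter = as.integer(length_jitter),
                 rng_seed = as.integer(rng_seed)),
            class = "family_spec")
}

.mutate_seq <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(.AA20, chars[i]), 1L)
  }
  chars
}

#' Generate one synthetic family
#'
#' The first record is the family seed (a uniform random protein); the
#' remaining members are derived from it by point substitutions and at
#' most `length_jitter` terminal truncations/extensions.
#'
#' @param spec a [family_spec()].
#' @param prefix accession prefix; members are named `<prefix>M01`, ...
#' @return sequence-record `data.frame` with `n_members` rows.
#' @export
make_family <- function(spec, prefix = "SYN") {
  stopifnot(inherits(spec, "family_spec"))
  .with_seed(spec$rng_seed, {
    rate <- 1 - spec$within_identity_target / 100
    seed_chars <- sample(.AA20, spec$seed_length, replace = TRUE)
    seqs <- character(spec$n_members)
    seqs[1] <- paste(seed_chars, collapse = "")
    if (spec$n_members > 1L) {
      for (i in 2:spec$n_members) {
        chars <- .mutate_seq(seed_chars, rate)
        if (spec$length_jitter > 0L) {
          amount <- sample.int(spec$length_jitter + 1L, 1L) - 1L
          if (amount > 0L) {
            extend <- stats::runif(1) < 0.5
            at_c_term <- stats::runif(1) < 0.5
            if (extend) {
              extra <- sample(.AA20, amount, replace = TRUE)
              chars <- if (at_c_term) c(chars, extra) else c(extra, chars)
            } else {
              keep <- length(chars) - amount
              chars <- if (at_c_term) chars[seq_len(keep)]
                       else chars[(amount + 1L):length(chars)]
            }
          }
        }
        seqs[i] <- paste(chars, collapse = "")
      }
    }
    seq_records(sprintf("%sM%02d", prefix, seq_len(spec$n_members)), seqs,
                description = sprintf("synthetic member %d",
                                      seq_len(spec$n_members)))
  })
}

.synth_annotations <- function(db, family_of, fragment_accs) {
  fams <- family_of[db$accession]
  ann <- data.frame(accession = db$accession,
                    protein_name = sprintf("synthetic protein %s",
                                           db$accession),
                    organism = sprintf("Synthospecies f%d", fams),
                    annotated_length = db$length,
                    stringsAsFactors = FALSE)
  ann$lineage <- lapply(seq_len(nrow(db)), function(i)
    c("Eukaryota", "Synthozoa", sprintf("Clade%d", fams[i]),
      sprintf("Species%s", db$accession[i])))
  ann$domains <- lapply(seq_len(nrow(db)), function(i) {
    full <- c(sprintf("DOM%dA", fams[i]), sprintf("DOM%dB", fams[i]))
    if (db$accession[i] %in% fragment_accs) full[1] else full
  })
  ann$pdb_ids <- lapply(seq_len(nrow(db)), function(i) {
    if (grepl("M01$", db$accession[i])) sprintf("%dSYN", fams[i])
    else character(0)
  })
  ann
}

#' Generate a synthetic hit set with planted cluster structure
#'
#' Builds independent families, takes the seed of one family as the query,
#' and synthesizes a collapsed hit table covering every database sequence
#' (identity to the query computed by [global_identity()], bit scores
#' monotone in identity times alignment length). Between-family seed
#' identity is asserted below `between_family_identity_max`; violating
#' draws are regenerated with fresh seeds a bounded number of times.
#' Optionally a half-length fragment of one family's seed is planted to
#' exercise the pass-1 length rule and the pass-2 rescue.
#'
#' @param family_specs list of [family_spec()]s (their `rng_seed`s are
#'   overridden by seeds derived from `rng_seed`).
#' @param between_family_identity_max upper bound (percent) tolerated
#'   between family seeds.
#' @param query_from index of the family whose seed becomes the query.
#' @param rng_seed master seed; the whole hit set is deterministic in it.
#' @param fragment_family if non-`NULL`, plant a 50%-length N-terminal
#'   fragment of this family's seed.
#' @param max_retries regeneration attempts when the between-family bound
#'   fails.
#' @return list with `query` (1-row records), `db` (records), `hits` (hit
#'   table in [parse_blast_tabular()] shape), `annotations`, and `truth`
#'   (list of accession vectors, the planted partition).
#' @export
make_hitset <- function(family_specs, between_family_identity_max = 30,
                        query_from = 1L, rng_seed = 1L,
                        fragment_family = NULL, max_retries = 5L) {
  nfam <- length(family_specs)
  stopifnot(nfam >= 1L, query_from >= 1L, query_from <= nfam)
  fam_seeds <- .with_seed(rng_seed,
                          matrix(sample.int(1e8L, nfam * max_retries),
                                 nrow = max_retries))
  families <- NULL
  for (attempt in seq_len(max_retries)) {
    cand <- lapply(seq_len(nfam), function(i) {
      sp <- family_specs[[i]]
      sp$rng_seed <- fam_seeds[attempt, i]
      make_family(sp, prefix = sprintf("F%d", i))
    })
    ok <- TRUE
    if (nfam > 1L) {
      for (i in seq_len(nfam - 1L)) {
        ids <- pair_identities(cand[[i]]$residues[1],
                               vapply((i + 1L):nfam, function(j)
                                 cand[[j]]$residues[1], character(1)))
        if (any(ids$identity_pct >= between_family_identity_max)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      families <- cand
      break
    }
  }
  if (is.null(families)) {
    stop("could not generate families below the between-family identity ",
         "bound in ", max_retries, " attempts", call. = FALSE)
  }
  truth <- lapply(families, function(f) f$accession)
  fragment_accs <- character(0)
  if (!is.null(fragment_family)) {
    stopifnot(fragment_family >= 1L, fragment_family <= nfam)
    seed_res <- families[[fragment_family]]$residues[1]
    frag <- seq_records(sprintf("F%dFRAG", fragment_family),
                        substr(seed_res, 1L, nchar(seed_res) %/% 2L),
                        "synthetic 50% N-terminal fragment")
    families[[fragment_family]] <- rbind(families[[fragment_family]], frag)
    truth[[fragment_family]] <- c(truth[[fragment_family]], frag$accession)
    fragment_accs <- frag$accession
  }
  db <- do.call(rbind, families)
  rownames(db) <- NULL
  query <- seq_records("QUERY", families[[query_from]]$residues[1],
                       "synthetic query (family seed)")
  ids <- pair_identities(query$residues, db$residues)
  bitscore <- round(2 * ids$identity_pct / 100 * ids$aligned_cols, 1)
  hits <- data.frame(
    query_id = "QUERY", subject_id = db$accession,
    pident_query = round(ids$identity_pct, 2),
    align_length = ids$aligned_cols,
    mismatch = round(ids$aligned_cols * (1 - ids$identity_pct / 100)),
    gapopen = 0L,
    qstart = 1L, qend = pmin(query$length, ids$aligned_cols),
    sstart = 1L, send = pmin(db$length, ids$aligned_cols),
    evalue = pmin(1e-6, signif(10^(-pmin(300, bitscore / 2)), 3)),
    bitscore = bitscore,
    stringsAsFactors = FALSE)
  o <- order(-hits$bitscore, hits$subject_id)
  hits <- hits[o, , drop = FALSE]
  rownames(hits) <- NULL
  hits$rank <- seq_len(nrow(hits))
  family_of <- setNames(rep(seq_len(nfam), vapply(truth, length, integer(1))),
                        unlist(truth))
  list(query = query, db = db, hits = hits,
       annotations = .synth_annotations(db, family_of, fragment_accs),
       truth = truth)
}

#' Write a synthetic hit set to disk
#'
#' Emits `query.fasta`, `db.fasta`, `hits.tsv` (BLAST tabular),
#' `annotations.tsv` and `truth.json` under `dir`, the on-disk interface
#' the command-line `run` mode consumes.
#'
#' @param hs result of [make_hitset()].
#' @param dir output directory (created if needed).
#' @return named vector of the paths written.
#' @export
write_hitset <- function(hs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(query = file.path(dir, "query.fasta"),
             db = file.path(dir, "db.fasta"),
             hits = file.path(dir, "hits.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth.json"))
  write_fasta(hs$query, paths[["query"]])
  write_fasta(hs$db, paths[["db"]])
  write_blast_tabular(hs$hits, paths[["hits"]])
  write_annotation_table(hs$annotations, paths[["annotations"]])
  jsonlite::write_json(hs$truth, paths[["truth"]])
  invisible(paths)
}
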