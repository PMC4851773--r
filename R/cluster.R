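# Two-pass greedy clustering of hit sequences.
#
# Pass 1: sequences sorted by decreasing length (ties: ascending accession);
# the longest remaining sequence becomes a representative and absorbs every
# remaining sequence that (1) differs in length by strictly less than the
# limit and (2) reaches the effective identity threshold against it.
# Pass 2: singletons are offered to the representatives of multi-member
# clusters on identity alone (no length rule) and join the best-matching
# one, labelled "2:".
#
# Tie-breaks are fixed so the whole procedure is deterministic; every
# membership carries a re-checkable certificate (identity, aligned columns,
# pass number).

#' Clustering parameter set
#'
#' @param policy a [threshold_policy()]; its user cutoff defaults to 53.
#' @param length_diff_limit strict upper bound on the representative-member
#'   length difference in pass 1, in residues (default 32: a difference of
#'   31 passes, 32 fails).
#' @return a `clustering_params` list.
#' @export
clustering_params <- function(policy = threshold_policy(),
                              length_diff_limit = 32L) {
  if (!inherits(policy, "threshold_policy")) {
    stop("policy must be a threshold_policy", call. = FALSE)
  }
  if (!is.numeric(length_diff_limit) || length_diff_limit < 0) {
    stop("length_diff_limit must be >= 0", call. = FALSE)
  }
  structure(list(policy = policy,
                 length_diff_limit = as.integer(length_diff_limit)),
            class = "clustering_params")
}

# Memoised pairwise identities for one clustering run. Keys are unordered
# accession pairs, so pass 2 reuses alignments already done in pass 1.
new_identity_cache <- function(records) {
  env <- new.env(parent = emptyenv())
  env$residues <- setNames(records$residues, records$accession)
  env$memo <- new.env(parent = emptyenv())
  env
}

.cache_key <- function(a, b) {
  if (a < b) paste0(a, "\r", b) else paste0(b, "\r", a)
}

# identity of `rep_acc` vs each of `accs`; computes only missing pairs,
# batched through pair_identities().
cached_identities <- function(cache, rep_acc, accs) {
  keys <- vapply(accs, .cache_key, character(1), a = rep_acc,
                 USE.NAMES = FALSE)
  miss <- which(!vapply(keys, exists, logical(1), envir = cache$memo,
                        USE.NAMES = FALSE))
  if (length(miss)) {
    st <- pair_identities(cache$residues[[rep_acc]],
                          unname(cache$residues[accs[miss]]))
    for (k in seq_along(miss)) {
      assign(keys[miss[k]],
             c(st$identity_pct[k], st$aligned_cols[k]), envir = cache$memo)
    }
  }
  out <- t(vapply(keys, get, numeric(2), envir = cache$memo,
                  USE.NAMES = FALSE))
  data.frame(identity_pct = out[, 1], aligned_cols = out[, 2])
}

.new_cluster <- function(index, rep_acc, members) {
  list(cluster_index = index, representative = rep_acc, members = members)
}

.member_row <- function(accession, pass_no, identity_to_rep, aligned_cols,
                        length) {
  pass_no <- rep_len(as.integer(pass_no), base::length(accession))
  data.frame(accession = accession, pass_no = pass_no,
             identity_to_rep = identity_to_rep,
             aligned_cols = as.integer(aligned_cols),
             display_label = ifelse(pass_no == 2L,
                                    paste0("2:", accession), accession),
             length = as.integer(length),
             identity_to_query = NA_real_, rank = NA_integer_,
             is_representative = FALSE,
             stringsAsFactors = FALSE)
}

#' Pass 1: greedy length-gated clustering
#'
#' @param sequences sequence-record `data.frame` with unique accessions.
#' @param params a [clustering_params()].
#' @param cache internal identity cache; supply only to share alignments
#'   across passes.
#' @return list of clusters in creation order; each cluster is a list with
#'   `cluster_index`, `representative` and a `members` data.frame.
#' @export
cluster_pass1 <- function(sequences, params = clustering_params(),
                          cache = new_identity_cache(sequences)) {
  stopifnot(is.data.frame(sequences))
  if (nrow(sequences) == 0L) stop("no sequences to cluster", call. = FALSE)
  if (anyDuplicated(sequences$accession)) {
    stop("duplicate accessions in input", call. = FALSE)
  }
  ord <- order(-sequences$length, sequences$accession)
  queue <- sequences[ord, c("accession", "length"), drop = FALSE]
  clusters <- list()
  while (nrow(queue) > 0L) {
    rep_acc <- queue$accession[1L]
    rep_len <- queue$length[1L]
    rest <- queue[-1L, , drop = FALSE]
    members <- .member_row(rep_acc, 1L, 100, rep_len, rep_len)
    members$is_representative <- TRUE
    absorbed <- character(0)
    if (nrow(rest) > 0L) {
      len_ok <- which((rep_len - rest$length) < params$length_diff_limit)
      if (length(len_ok)) {
        st <- cached_identities(cache, rep_acc, rest$accession[len_ok])
        thr <- effective_threshold(st$aligned_cols, params$policy)
        take <- which(st$identity_pct >= thr)
        if (length(take)) {
          idx <- len_ok[take]
          absorbed <- rest$accession[idx]
          members <- rbind(members,
                           .member_row(absorbed, 1L, st$identity_pct[take],
                                       st$aligned_cols[take],
                                       rest$length[idx]))
        }
      }
    }
    clusters[[length(clusters) + 1L]] <-
      .new_cluster(length(clusters) + 1L, rep_acc, members)
    queue <- rest[!rest$accession %in% absorbed, , drop = FALSE]
  }
  clusters
}

#' Pass 2: rescue singletons into existing clusters
#'
#' Each singleton left by pass 1 (usually a fragment or splice variant) is
#' compared to the representative of every multi-member cluster; if it
#' reaches the effective identity threshold for one or more of them it
#' moves into the best match (highest identity; ties: lowest cluster
#' index) with pass number 2 and a `"2:"`-prefixed label. Length
#' differences are ignored. Multi-member clusters never merge or dissolve;
#' when pass 1 produced only singletons there is nothing "existing" to
#' join and the pass is a no-op.
#'
#' @param clusters result of [cluster_pass1()].
#' @param params a [clustering_params()].
#' @param cache identity cache shared with the pass-1 run; if `NULL`,
#'   built from `sequences`.
#' @param sequences the record `data.frame` the clusters were built from
#'   (only needed when no cache is supplied).
#' @return list of clusters, pass-1 creation order preserved.
#' @export
cluster_pass2 <- function(clusters, params = clustering_params(),
                          cache = NULL, sequences = NULL) {
  sizes <- vapply(clusters, function(cl) nrow(cl$members), integer(1))
  multi <- which(sizes >= 2L)
  single <- which(sizes == 1L)
  if (length(multi) == 0L || length(single) == 0L) return(clusters)
  if (is.null(cache)) {
    if (is.null(sequences)) {
      stop("cluster_pass2 needs either the pass-1 identity cache or the sequences",
           call. = FALSE)
    }
    cache <- new_identity_cache(sequences)
  }
  drop <- integer(0)
  for (si in single) {
    acc <- clusters[[si]]$representative
    best_id <- -Inf; best_cl <- NA_integer_; best_cols <- NA_integer_
    for (mi in multi) {
      rep_acc <- clusters[[mi]]$representative
      st <- cached_identities(cache, rep_acc, acc)
      thr <- effective_threshold(st$aligned_cols[1], params$policy)
      if (st$identity_pct[1] >= thr && st$identity_pct[1] > best_id) {
        best_id <- st$identity_pct[1]
        best_cl <- mi
        best_cols <- st$aligned_cols[1]
      }
    }
    if (!is.na(best_cl)) {
      row <- clusters[[si]]$members
      new_row <- .member_row(acc, 2L, best_id, best_cols, row$length[1])
      clusters[[best_cl]]$members <- rbind(clusters[[best_cl]]$members,
                                           new_row)
      drop <- c(drop, si)
    }
  }
  if (length(drop)) clusters <- clusters[-drop]
  for (i in seq_along(clusters)) clusters[[i]]$cluster_index <- i
  clusters
}

#' Final ordering and hit bookkeeping
#'
#' Renumbers clusters 1..k by the best (smallest) hit rank among their
#' members, orders members within each cluster by hit rank, and copies
#' each member's identity to the query from the hit table. With `hits =
#' NULL` (direct clustering of a record set) creation order is kept and
#' rank/query-identity stay `NA`.
#'
#' @param clusters list of clusters (after pass 2).
#' @param hits hit `data.frame` with `subject_id`, `rank`, `pident_query`,
#'   or `NULL`.
#' @return list of clusters ordered and indexed for reporting.
#' @export
finalize_clusters <- function(clusters, hits = NULL) {
  if (length(clusters) == 0L) return(list())
  if (!is.null(hits) && nrow(hits) > 0L) {
    for (i in seq_along(clusters)) {
      m <- clusters[[i]]$members
      idx <- match(m$accession, hits$subject_id)
      m$rank <- hits$rank[idx]
      m$identity_to_query <- hits$pident_query[idx]
      m <- m[order(m$rank, m$accession), , drop = FALSE]
      rownames(m) <- NULL
      clusters[[i]]$members <- m
    }
    best <- vapply(clusters, function(cl) min(cl$members$rank, na.rm = TRUE),
                   numeric(1))
    clusters <- clusters[order(best)]
  }
  for (i in seq_along(clusters)) clusters[[i]]$cluster_index <- i
  clusters
}

#' Cluster a set of hit sequences end to end
#'
#' Runs pass 1, pass 2 and [finalize_clusters()] with one shared identity
#' cache.
#'
#' @param sequences sequence-record `data.frame` (the hit sequences).
#' @param params a [clustering_params()].
#' @param hits optional hit table for final ordering and query identities.
#' @return list of clusters.
#' @export
cluster_hits <- function(sequences, params = clustering_params(),
                         hits = NULL) {
  cache <- new_identity_cache(sequences)
  cl <- cluster_pass1(sequences, params, cache)
  cl <- cluster_pass2(cl, params, cache)
  finalize_clusters(cl, hits)
}

#' Partition view of a cluster list
#'
#' @param clusters list of clusters.
#' @return named list: cluster index (as character) -> sorted member
#'   accessions. Convenient for equality checks.
#' @export
cluster_partition <- function(clusters) {
  out <- lapply(clusters, function(cl) sort(cl$members$accession))
  names(out) <- vapply(clusters, function(cl) as.character(cl$cluster_index),
                       character(1))
  out
}
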