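# Independent oracles:
#  - an affine-gap Needleman-Wunsch DP (score + enumeration of all optimal
#    alignments) written from scratch, to check the production identity
#  - a naive re-implementation of the two-pass greedy clustering
#  - the closed-form twilight-zone curve

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# gap cost model: a gap run of length k costs open + k * ext
nw_oracle <- function(a, b, open = 11, ext = 1, max_paths = 400) {
  A <- strsplit(chartr("UO", "XX", a), "")[[1]]
  B <- strsplit(chartr("UO", "XX", b), "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (A residue vs -)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- .blosum62[A[i], B[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             X[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
    }
  }
  best <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])

  paths <- list()
  walk <- function(i, j, state, pa, pb) {
    if (length(paths) >= max_paths) return()
    if (i == 0 && j == 0) {
      paths[[length(paths) + 1]] <<- list(p = paste(rev(pa), collapse = ""),
                                          s = paste(rev(pb), collapse = ""))
      return()
    }
    v <- switch(state, M = M[i + 1, j + 1], X = X[i + 1, j + 1],
                Y = Y[i + 1, j + 1])
    if (state == "M") {
      s <- .blosum62[A[i], B[j]]
      for (prev in c("M", "X", "Y")) {
        pv <- switch(prev, M = M[i, j], X = X[i, j], Y = Y[i, j])
        if (abs(pv + s - v) < 1e-9 && pv > NEG / 2) {
          walk(i - 1, j - 1, prev, c(pa, A[i]), c(pb, B[j]))
        }
      }
    } else if (state == "X") {
      cand <- list(M = M[i, j + 1] - open - ext, X = X[i, j + 1] - ext,
                   Y = Y[i, j + 1] - open - ext)
      for (prev in names(cand)) {
        if (abs(cand[[prev]] - v) < 1e-9 && cand[[prev]] > NEG / 2) {
          walk(i - 1, j, prev, c(pa, A[i]), c(pb, "-"))
        }
      }
    } else {
      cand <- list(M = M[i + 1, j] - open - ext,
                   X = X[i + 1, j] - open - ext, Y = Y[i + 1, j] - ext)
      for (prev in names(cand)) {
        if (abs(cand[[prev]] - v) < 1e-9 && cand[[prev]] > NEG / 2) {
          walk(i, j - 1, prev, c(pa, "-"), c(pb, B[j]))
        }
      }
    }
  }
  for (st in c("M", "X", "Y")) {
    v <- switch(st, M = M[n + 1, m + 1], X = X[n + 1, m + 1],
                Y = Y[n + 1, m + 1])
    if (abs(v - best) < 1e-9) walk(n, m, st, character(0), character(0))
  }
  list(score = best, alignments = paths)
}

# identity over columns with terminal gap runs trimmed, from an explicit
# aligned pair
oracle_identity_of_alignment <- function(p, s) {
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  gap <- pc == "-" | sc == "-"
  nong <- which(!gap)
  if (length(nong) == 0) return(c(identity_pct = 0, aligned_cols = 0))
  keep <- nong[1]:nong[length(nong)]
  ident <- sum(pc[keep] == sc[keep] & pc[keep] != "-")
  c(identity_pct = 100 * ident / length(keep),
    aligned_cols = length(keep))
}

# every (identity, cols) pair realized by some optimal alignment
oracle_identity_set <- function(a, b) {
  res <- nw_oracle(a, b)
  u <- unique(lapply(res$alignments, function(al)
    round(oracle_identity_of_alignment(al$p, al$s), 6)))
  list(score = res$score, pairs = u)
}

rost_closed_form <- function(L, n = 0) {
  pmin(100, pmax(0, n + 480 * L^(-0.32 * (1 + exp(-L / 1000)))))
}

# ---- naive two-pass greedy clusterer -------------------------------------
# Independent re-statement of the clustering rules, with memoised pairwise
# identities (same identity metric, naive control flow).

oracle_two_pass <- function(records, params) {
  res <- setNames(records$residues, records$accession)
  len <- setNames(records$length, records$accession)
  memo <- new.env(parent = emptyenv())
  idf <- function(x, y) {
    key <- paste(sort(c(x, y)), collapse = "|")
    if (!exists(key, envir = memo)) {
      assign(key, global_identity(res[[x]], res[[y]]), envir = memo)
    }
    get(key, envir = memo)
  }
  pool <- records$accession[order(-records$length, records$accession)]
  clusters <- list()
  while (length(pool) > 0) {
    rep_acc <- pool[1]
    pool <- pool[-1]
    members <- data.frame(accession = rep_acc, pass_no = 1L,
                          stringsAsFactors = FALSE)
    taken <- character(0)
    for (acc in pool) {
      if ((len[[rep_acc]] - len[[acc]]) < params$length_diff_limit) {
        st <- idf(rep_acc, acc)
        if (st$identity_pct >=
            effective_threshold(st$aligned_cols, params$policy)) {
          members <- rbind(members,
                           data.frame(accession = acc, pass_no = 1L,
                                      stringsAsFactors = FALSE))
          taken <- c(taken, acc)
        }
      }
    }
    pool <- setdiff(pool, taken)
    clusters[[length(clusters) + 1]] <- list(representative = rep_acc,
                                             members = members)
  }
  sizes <- vapply(clusters, function(c) nrow(c$members), integer(1))
  singles <- which(sizes == 1)
  multis <- which(sizes >= 2)
  moved <- integer(0)
  if (length(singles) > 0 && length(multis) > 0) {
    for (si in singles) {
      acc <- clusters[[si]]$representative
      best <- NULL
      for (mi in multis) {
        st <- idf(clusters[[mi]]$representative, acc)
        if (st$identity_pct >=
            effective_threshold(st$aligned_cols, params$policy)) {
          if (is.null(best) || st$identity_pct > best$id) {
            best <- list(id = st$identity_pct, cl = mi)
          }
        }
      }
      if (!is.null(best)) {
        clusters[[best$cl]]$members <-
          rbind(clusters[[best$cl]]$members,
                data.frame(accession = acc, pass_no = 2L,
                           stringsAsFactors = FALSE))
        moved <- c(moved, si)
      }
    }
  }
  if (length(moved)) clusters <- clusters[-moved]
  clusters
}

oracle_canonical <- function(oracle_clusters) {
  cl <- lapply(oracle_clusters, function(c) {
    m <- c$members[order(c$members$accession), c("accession", "pass_no")]
    rownames(m) <- NULL
    list(representative = c$representative, members = m)
  })
  cl[order(vapply(cl, `[[`, character(1), "representative"))]
}
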