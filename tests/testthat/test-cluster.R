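# Constructed family: A 100 aa, B a 95 aa close homolog (passes pass 1),
# C a 60 aa fragment (fails the length rule, rescued in pass 2).
abc_fixture <- function() {
  set.seed(1234)
  a <- random_protein(100)
  b <- substr(mutate_protein(a, 0.08), 1, 95)
  c_frag <- mutate_protein(substr(a, 1, 60), 0.08)
  seq_records(c("A", "B", "C"), c(a, b, c_frag))
}

test_that("pass 1 applies the length rule strictly and the identity threshold", {
  recs <- abc_fixture()
  # confirm the fixture is what the trace assumes
  gb <- global_identity(recs$residues[1], recs$residues[2])
  gc <- global_identity(recs$residues[1], recs$residues[3])
  expect_gt(gb$identity_pct, 53)
  expect_gt(gc$identity_pct, 53)

  cl <- cluster_pass1(recs, clustering_params())
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$representative, "A")
  expect_setequal(cl[[1]]$members$accession, c("A", "B"))  # diff 5 < 32
  expect_equal(cl[[2]]$members$accession, "C")             # diff 40 >= 32
  expect_true(all(cl[[1]]$members$pass_no == 1L))
})

test_that("pass 2 rescues the fragment with a 2: label, ignoring length", {
  recs <- abc_fixture()
  cache <- hitclust:::new_identity_cache(recs)
  cl <- cluster_pass1(recs, clustering_params(), cache)
  cl <- cluster_pass2(cl, clustering_params(), cache)
  expect_length(cl, 1L)
  m <- cl[[1]]$members
  expect_setequal(m$accession, c("A", "B", "C"))
  expect_equal(m$pass_no[m$accession == "C"], 2L)
  expect_equal(m$display_label[m$accession == "C"], "2:C")
  expect_true(all(m$pass_no[m$accession != "C"] == 1L))
})

test_that("the length-difference rule is a strict less-than", {
  set.seed(77)
  a <- random_protein(100)
  recs <- seq_records(c("A", "B31", "B32"),
                      c(a, substr(a, 1, 69), substr(a, 1, 68)))
  cl <- cluster_pass1(recs, clustering_params())
  in_a <- cl[[1]]$members$accession
  expect_true("B31" %in% in_a)    # diff 31 < 32 passes
  expect_false("B32" %in% in_a)   # diff 32 fails
})

test_that("identical duplicated sequences form one cluster with accession tie-break", {
  set.seed(8)
  res <- random_protein(50)
  recs <- seq_records(c("ZZZ", "AAA"), c(res, res))
  cl <- cluster_pass1(recs, clustering_params())
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$representative, "AAA")
  expect_setequal(cl[[1]]$members$accession, c("AAA", "ZZZ"))
})

test_that("mutually dissimilar sequences stay singletons and pass 2 is a no-op", {
  set.seed(15)
  recs <- seq_records(sprintf("R%d", 1:6),
                      vapply(rep(60, 6), random_protein, character(1)))
  params <- clustering_params()
  cache <- hitclust:::new_identity_cache(recs)
  p1 <- cluster_pass1(recs, params, cache)
  expect_length(p1, 6L)   # random 60-mers never reach 53%
  p2 <- cluster_pass2(p1, params, cache)
  expect_equal(canonical_clusters(p2), canonical_clusters(p1))
})

test_that("pass 2 leaves multi-member clusters untouched when no singletons exist", {
  set.seed(30)
  a <- random_protein(80)
  b <- random_protein(80)
  recs <- seq_records(c("A1", "A2", "B1", "B2"),
                      c(a, mutate_protein(a, 0.05),
                        b, mutate_protein(b, 0.05)))
  params <- clustering_params()
  cache <- hitclust:::new_identity_cache(recs)
  p1 <- cluster_pass1(recs, params, cache)
  expect_length(p1, 2L)
  p2 <- cluster_pass2(p1, params, cache)
  expect_equal(canonical_clusters(p2), canonical_clusters(p1))
})

test_that("finalize orders clusters by best hit rank and members by rank", {
  set.seed(41)
  a <- random_protein(70)
  b <- random_protein(70)
  recs <- seq_records(c("A1", "A2", "B1"),
                      c(a, mutate_protein(a, 0.05), b))
  hits <- fake_hits(recs)
  # force ranks: B1 is the top hit
  hits$rank <- c(2L, 3L, 1L)
  cl <- cluster_hits(recs, clustering_params(), hits)
  expect_equal(cl[[1]]$representative, "B1")
  expect_equal(cl[[1]]$cluster_index, 1L)
  expect_equal(cl[[2]]$members$accession, c("A1", "A2"))  # rank 2 then 3
  expect_equal(cl[[2]]$members$rank, c(2L, 3L))
  expect_equal(cl[[2]]$members$identity_to_query,
               hits$pident_query[match(c("A1", "A2"), hits$subject_id)])
  expect_true(cl[[2]]$members$is_representative[1])
})

test_that("finalize on an empty cluster list returns an empty list", {
  expect_equal(finalize_clusters(list(), fake_hits(abc_fixture())[0, ]),
               list())
})

test_that("cutoff 100 on distinct sequences yields all singletons", {
  set.seed(52)
  base <- random_protein(60)
  # guaranteed-distinct variants: one fixed substitution each
  variant <- function(i) {
    ch <- strsplit(base, "")[[1]]
    ch[i] <- setdiff(AA20, ch[i])[1]
    paste(ch, collapse = "")
  }
  recs <- seq_records(sprintf("D%d", 1:5),
                      c(base, vapply(seq(10, 40, 10), variant,
                                     character(1))))
  expect_true(length(unique(recs$residues)) == 5)
  cl <- cluster_hits(recs, clustering_params(threshold_policy(100)))
  expect_length(cl, 5L)
})

test_that("all-identical-length, all-above-threshold sets collapse to one cluster", {
  set.seed(53)
  base <- random_protein(120)
  recs <- seq_records(sprintf("E%d", 1:6),
                      c(base, vapply(1:5, function(i)
                        mutate_protein(base, 0.05), character(1))))
  cl <- cluster_hits(recs, clustering_params())
  expect_length(cl, 1L)
})

test_that("the clusterer always produces a partition of the input", {
  for (seed in c(101, 202, 303)) {
    recs <- random_record_set(seed)
    cl <- cluster_hits(recs, clustering_params())
    members <- unlist(lapply(cl, function(c) c$members$accession))
    expect_equal(sort(members), sort(recs$accession))
  }
})

test_that("production clustering equals the naive oracle on random sets", {
  params <- clustering_params()
  for (seed in c(11, 22, 33, 44, 55)) {
    recs <- random_record_set(seed, max_n = 20)
    cache <- hitclust:::new_identity_cache(recs)
    got <- cluster_pass2(cluster_pass1(recs, params, cache), params, cache)
    expect_equal(canonical_clusters(got),
                 oracle_canonical(oracle_two_pass(recs, params)),
                 info = paste("seed", seed))
  }
})

test_that("recluster is deterministic and reproduces cluster_hits", {
  set.seed(61)
  recs <- random_record_set(61, max_n = 15)
  hits <- fake_hits(recs)
  state <- session_state(seq_records("Q", random_protein(50)), hits, recs)
  p <- clustering_params(threshold_policy(40))
  c1 <- recluster(state, p)
  c2 <- recluster(state, p)
  expect_identical(c1, c2)
  expect_identical(c1, cluster_hits(recs, p, hits))
  expect_error(recluster(state, "nope"), "clustering_params")
})

test_that("session state round-trips through JSON", {
  set.seed(62)
  recs <- random_record_set(62, max_n = 10)
  hits <- fake_hits(recs)
  state <- session_state(seq_records("Q", random_protein(50)), hits, recs,
                         search_params(1e-6, max_hits = 500),
                         clustering_params(threshold_policy(70), 20))
  f <- withr::local_tempfile(fileext = ".json")
  save_session(state, f)
  back <- load_session(f)
  expect_equal(back$query$residues, state$query$residues)
  expect_equal(back$hit_sequences, state$hit_sequences)
  expect_equal(back$search_params, state$search_params)
  expect_equal(back$clustering_params, state$clustering_params)
  expect_identical(recluster(back), recluster(state))

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema_version": 99}', bad)
  expect_error(load_session(bad), "schema")
  bad2 <- withr::local_tempfile(fileext = ".json")
  writeLines("not json at all {", bad2)
  expect_error(load_session(bad2), "cannot parse")
})
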