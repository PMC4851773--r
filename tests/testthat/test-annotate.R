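ann_tsv <- function(rows) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("accession\tprotein_name\torganism\tlineage\tdomains\tpdb\tlength",
               rows), f)
  f
}

test_that("read_annotation_table parses the TSV dialect", {
  f <- ann_tsv(c(
    "P1\tNEIL2\tHomo sapiens\tEukaryota;Metazoa;Chordata\tFapy_DNA_glyco;H2TH\t1Q39,1Q3C\t332",
    "P2\t\t\t\t\t\t"))
  tab <- read_annotation_table(f)
  expect_equal(tab$accession, c("P1", "P2"))
  expect_equal(tab$lineage[[1]], c("Eukaryota", "Metazoa", "Chordata"))
  expect_equal(tab$domains[[1]], c("Fapy_DNA_glyco", "H2TH"))
  expect_equal(tab$pdb_ids[[1]], c("1Q39", "1Q3C"))
  expect_equal(tab$annotated_length[1], 332L)
  # empty cells degrade to empty vectors / NA
  expect_equal(tab$pdb_ids[[2]], character(0))
  expect_equal(tab$lineage[[2]], character(0))
  expect_true(is.na(tab$annotated_length[2]))
})

test_that("read_annotation_table validates header, duplicates and lengths", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("acc\tname", "P1\tx"), f)
  expect_error(read_annotation_table(f), "header")

  f2 <- ann_tsv(c("P1\tA\to\t\t\t\t10", "P1\tB\to\t\t\t\t11"))
  expect_error(read_annotation_table(f2), "duplicate")

  f3 <- ann_tsv("P1\tA\to\t\t\t\tabc")
  expect_error(read_annotation_table(f3), "non-integer")
})

test_that("annotation tables round-trip through write_annotation_table", {
  f <- ann_tsv(c(
    "P1\tNEIL2\tHomo sapiens\tEukaryota;Metazoa\tH2TH\t1Q39\t332",
    "P2\tNEIL3\tMus musculus\tEukaryota;Metazoa\tH2TH;zf-GRF;zf-RanBP\t\t605"))
  tab <- read_annotation_table(f)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(tab, f2)
  expect_equal(read_annotation_table(f2), tab)
})

test_that("joint_taxonomy is the longest common lineage prefix", {
  expect_equal(joint_taxonomy(list(
    c("Euk", "Met", "Chor", "Mam", "Homo"),
    c("Euk", "Met", "Chor", "Mam", "Mus"))),
    c("Euk", "Met", "Chor", "Mam"))
  expect_equal(joint_taxonomy(list(c("Euk", "Met"))), c("Euk", "Met"))
  expect_equal(joint_taxonomy(list(c("Bacteria", "Proteo"),
                                   c("Eukaryota", "Metazoa"))),
               character(0))
  # empty lineages are excluded, all-empty gives empty
  expect_equal(joint_taxonomy(list(character(0),
                                   c("Euk", "Met"))), c("Euk", "Met"))
  expect_equal(joint_taxonomy(list(character(0))), character(0))
})

test_that("joint_taxonomy is a prefix of every input lineage (property)", {
  set.seed(9)
  pool <- c("RootA", "RootB")
  for (i in 1:25) {
    k <- sample(1:5, 1)
    lins <- lapply(seq_len(k), function(j) {
      depth <- sample(0:6, 1)
      if (depth == 0) return(character(0))
      c(sample(pool, 1), sprintf("T%d", seq_len(depth - 1) +
                                   sample(0:2, 1)))
    })
    jt <- joint_taxonomy(lins)
    for (ln in lins[lengths(lins) > 0]) {
      expect_true(length(jt) <= length(ln))
      expect_equal(jt, ln[seq_along(jt)])
    }
  }
})

test_that("annotate_cluster summarizes architectures, PDB ids and lengths", {
  recs <- seq_records(c("N1", "N2", "N3"),
                      c(random_protein(605), random_protein(598),
                        random_protein(590)))
  f <- ann_tsv(c(
    "N1\tNEIL3a\tHomo\tEukaryota;Metazoa;Chordata\tH2TH;zf-GRF;zf-RanBP\t1Q39\t605",
    "N2\tNEIL3b\tMus\tEukaryota;Metazoa;Chordata\tH2TH;zf-GRF;zf-RanBP\t1Q3C\t598",
    "N3\tNEIL3c\tDanio\tEukaryota;Metazoa;Chordata\tH2TH\t\t590"))
  tab <- read_annotation_table(f)
  cluster <- list(cluster_index = 1L, representative = "N1",
                  members = data.frame(accession = c("N1", "N2", "N3")))
  ann <- annotate_cluster(cluster, tab, recs)
  expect_equal(ann$joint_taxonomy, c("Eukaryota", "Metazoa", "Chordata"))
  expect_length(ann$architectures, 2L)
  expect_equal(ann$architectures[[1]]$domains,
               c("H2TH", "zf-GRF", "zf-RanBP"))
  expect_equal(ann$architectures[[1]]$count, 2L)
  expect_equal(ann$architectures[[2]]$domains, "H2TH")
  expect_equal(ann$architectures[[2]]$count, 1L)
  expect_equal(ann$pdb_ids, c("1Q39", "1Q3C"))
  expect_equal(ann$length_min, 590L)
  expect_equal(ann$length_max, 605L)
  expect_equal(ann$n_members_annotated, 3L)
})

test_that("annotation degrades gracefully for unannotated members", {
  recs <- seq_records(c("X1", "X2"), c(random_protein(100),
                                       random_protein(80)))
  cluster <- list(cluster_index = 1L, representative = "X1",
                  members = data.frame(accession = c("X1", "X2")))
  ann <- annotate_cluster(cluster, NULL, recs)
  expect_equal(ann$joint_taxonomy, character(0))
  expect_equal(ann$architectures, list())
  expect_equal(ann$length_min, 80L)
  expect_equal(ann$length_max, 100L)
  expect_equal(ann$n_members_annotated, 0L)

  f <- ann_tsv("X1\tprot\torg\tEuk;Met\tDOM1\t2ABC\t100")
  tab <- read_annotation_table(f)
  ann2 <- annotate_cluster(cluster, tab, recs)
  expect_equal(ann2$n_members_annotated, 1L)
  expect_equal(ann2$joint_taxonomy, c("Euk", "Met"))
  expect_equal(ann2$length_min, 80L)   # lengths from sequences, all members
})

test_that("architecture counts are member-order-insensitive, ties by first appearance", {
  recs <- seq_records(c("A", "B", "C", "D"),
                      vapply(rep(50, 4), random_protein, character(1)))
  f <- ann_tsv(c("A\t\t\t\tD1;D2\t\t50",
                 "B\t\t\t\tD3\t\t50",
                 "C\t\t\t\tD1;D2\t\t50",
                 "D\t\t\t\tD3\t\t50"))
  tab <- read_annotation_table(f)
  mk <- function(accs) list(cluster_index = 1L, representative = accs[1],
                            members = data.frame(accession = accs))
  a1 <- annotate_cluster(mk(c("A", "B", "C", "D")), tab, recs)
  a2 <- annotate_cluster(mk(c("D", "C", "B", "A")), tab, recs)
  expect_equal(lapply(a1$architectures, `[[`, "count"), list(2L, 2L))
  # tie order follows first appearance in the member order given
  expect_equal(a1$architectures[[1]]$domains, c("D1", "D2"))
  expect_equal(a2$architectures[[1]]$domains, "D3")
  expect_equal(sort(vapply(a2$architectures, function(x)
    paste(x$domains, collapse = ";"), character(1))),
    sort(vapply(a1$architectures, function(x)
      paste(x$domains, collapse = ";"), character(1))))
})
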