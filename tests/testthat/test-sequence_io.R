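test_that("FASTA headers parse to id + taxon and residues concatenate", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 Bif", "ACDE"), p)
  rec <- read_fasta(p, default_taxon = "Bif")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$id, "p1")
  expect_equal(rec$residues, "ACDE")
  expect_equal(rec$taxon, "Bif")
})

test_that("invalid FASTA input is rejected with informative errors", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDE", ">a", "ACDF"), p)
  expect_error(read_fasta(p), "duplicate sequence id: a")
  writeLines(c(">a", "ACDE", ">b", "ACDEF"), p)
  expect_error(read_fasta(p, aligned = TRUE), "unequal lengths.*b")
  writeLines(c(">a", "ACJE"), p)
  expect_error(read_fasta(p), "illegal character 'J' in record a at position 3")
})

test_that("FASTA round-trips are lossless and wrapping follows the width", {
  set.seed(11)
  n <- 50
  rec <- seq_records(sprintf("s%02d", 1:n), sprintf("tax%02d", 1:n),
                     vapply(sample(20:200, n, TRUE), random_protein,
                            character(1)))
  p <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(rec, p)
  back <- read_fasta(p, taxon_map = setNames(rec$taxon, rec$id))
  expect_equal(back, rec, ignore_attr = TRUE)

  one <- seq_records("w", "t", random_protein(61))
  write_fasta(one, p, wrap = 60)
  lines <- readLines(p)
  expect_equal(length(lines), 3L)  # header + 60 + 1
  expect_equal(nchar(lines[2:3]), c(60L, 1L))

  write_fasta(rec[0, ], p)
  expect_identical(readLines(p), character(0))
})

test_that("group maps build disjoint assignments and reject double listing", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("t1\tin", "t2\tin", "t3\tin", "t4\tout", "t5\tout"), p)
  ga <- read_group_map(p, focal = "in")
  expect_setequal(ga$ingroup, c("t1", "t2", "t3"))
  expect_setequal(ga$outgroup, c("t4", "t5"))
  writeLines(c("t1\tin", "t1\tout"), p)
  expect_error(read_group_map(p, focal = "in"), "more than one group: t1")
})

test_that("a 62-taxon ordinal-scale clade map yields 8 disjoint groups", {
  # mirrors the clade structure of a bifidobacterial-order comparison:
  # named clusters partitioning 62 genomes
  sizes <- c(Scardovia_clade = 5, Gardnerella = 3,
             B_asteroides_cluster_I = 3, B_asteroides_cluster_II = 3,
             B_asteroides_cluster_III = 4, B_longum_cluster = 10,
             B_adolescentis_cluster = 14, other_Bifidobacterium = 20)
  taxa <- sprintf("g%02d", seq_len(sum(sizes)))
  df <- data.frame(taxon = taxa, group = rep(names(sizes), sizes))
  p <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  ga <- read_group_map(p, focal = "Scardovia_clade")
  expect_length(ga$groups, 8L)
  expect_length(unique(unlist(ga$groups)), 62L)
  expect_length(ga$ingroup, 5L)
  expect_length(ga$outgroup, 57L)
})

test_that("hit tables parse, validate column counts, and round-trip", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t98.5\t100\t2\t0\t1\t100\t1\t100\t1e-50\t180.3", p)
  h <- read_hit_table(p, taxon_map = c(s1 = "taxA"))
  expect_equal(h$evalue, 1e-50)
  expect_type(h$evalue, "double")
  expect_equal(h$subject_taxon, "taxA")

  writeLines(c("q1\ts1\t98.5\t100\t2\t0\t1\t100\t1\t100\t1e-50\t180.3",
               "q1\ts2\t90\t100\t2\t0\t1\t100\t1\t100\t1e-20"), p)
  expect_error(read_hit_table(p), "line 2 has 11 columns")

  set.seed(5)
  n <- 1000
  hits <- data.frame(
    query_id = sprintf("q%03d", sample(50, n, TRUE)),
    subject_id = sprintf("s%03d", sample(200, n, TRUE)),
    percent_identity = round(runif(n, 30, 100), 2),
    alignment_length = sample(50:400, n, TRUE),
    mismatches = sample(0:50, n, TRUE), gap_opens = sample(0:5, n, TRUE),
    q_start = 1L, q_end = sample(50:400, n, TRUE),
    s_start = 1L, s_end = sample(50:400, n, TRUE),
    evalue = 10^runif(n, -100, -1), bitscore = round(runif(n, 40, 900), 1),
    subject_taxon = sprintf("tax%02d", sample(20, n, TRUE)))
  write_hit_table(hits, p)
  back <- read_hit_table(p)
  expect_equal(nrow(back), n)
  expect_false(anyNA(back$subject_taxon))
  expect_equal(back$evalue, hits$evalue, tolerance = 1e-12)
})

test_that("unresolved subjects are kept and reported, not dropped", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t98.5\t100\t2\t0\t1\t100\t1\t100\t1e-50\t180.3",
               "q1\ts2\t90\t100\t2\t0\t1\t100\t1\t100\t1e-20\t120"), p)
  expect_warning(h <- read_hit_table(p, taxon_map = c(s1 = "taxA")),
                 "unresolved subject taxa.*s2")
  expect_equal(nrow(h), 2L)
  expect_true(is.na(h$subject_taxon[2]))
})

test_that("newick round-trip preserves topology, lengths and supports", {
  set.seed(2)
  tr <- simulate_tree(12)
  tr$node.label <- as.character(round(runif(tr$Nnode), 3))
  p <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, p)
  back <- read_newick(p)
  expect_equal(rf_distance(tr, back), 0L)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  expect_setequal(back$node.label, tr$node.label)
})

test_that("proteome sets demand named genomes and globally unique ids", {
  a <- seq_records("p1", "gA", "ACDEF")
  b <- seq_records("p1", "gB", "ACDEY")
  expect_error(proteome_set(list(a, b)), "named")
  expect_error(proteome_set(list(gA = a, gB = b)), "duplicate sequence id")
  ps <- proteome_set(list(gA = a, gB = seq_records("p2", "gB", "ACDEY")))
  expect_s3_class(ps, "proteome_set")
})
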