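make_groups <- function() {
  group_assignment(list(ingroup = c("tA", "tB", "tC"),
                        outgroup = c("tX", "tY")), focal = "ingroup")
}

hit_row <- function(q, s, taxon, e) {
  data.frame(query_id = q, subject_id = s, percent_identity = 90,
             alignment_length = 100, mismatches = 10, gap_opens = 0,
             q_start = 1, q_end = 100, s_start = 1, s_end = 100,
             evalue = e, bitscore = 200, subject_taxon = taxon,
             stringsAsFactors = FALSE)
}

test_that("CSP verdicts follow the threshold and exception semantics", {
  g <- make_groups()
  inhits <- do.call(rbind, lapply(1:10, function(i)
    hit_row("q1", paste0("s", i), sample(g$ingroup, 1), 1e-20)))
  set.seed(71)
  calls <- call_csps(inhits, g)
  expect_equal(calls$verdict, "specific")
  expect_equal(calls$n_in_hits, 10L)
  expect_equal(calls$n_out_hits, 0L)

  withx <- rbind(inhits, hit_row("q1", "sx", "tX", 1e-8))
  expect_equal(call_csps(withx, g)$verdict, "not_specific")
  relaxed <- call_csps(withx, g, max_exceptions = 1)
  expect_equal(relaxed$verdict, "specific")
  expect_equal(relaxed$n_out_hits, 1L)
  expect_equal(relaxed$best_out_evalue, 1e-8)

  # an out-group hit above the significance threshold never counts
  weak <- rbind(inhits, hit_row("q1", "sx", "tX", 1e-3))
  expect_equal(call_csps(weak, g)$verdict, "specific")

  # self-hits are excluded; queries with no other hits are orphans
  selfonly <- hit_row("q2", "q2", "tA", 0)
  expect_equal(call_csps(selfonly, g, query_ids = "q2")$verdict, "orphan")

  expect_error(call_csps(hit_row("q1", "s1", "unknown_taxon", 1e-10), g),
               "unresolvable subject taxa: unknown_taxon")
})

test_that("every verdict re-derives from a one-line predicate over the table", {
  set.seed(72)
  g <- make_groups()
  taxa <- c(g$ingroup, g$outgroup)
  hits <- do.call(rbind, lapply(1:300, function(i)
    hit_row(sprintf("q%02d", sample(20, 1)), sprintf("s%03d", i),
            sample(taxa, 1), 10^runif(1, -40, -2))))
  thr <- 1e-5
  calls <- call_csps(hits, g, evalue_threshold = thr)
  for (k in seq_len(nrow(calls))) {
    h <- hits[hits$query_id == calls$query_id[k] &
                hits$subject_id != hits$query_id &
                hits$evalue <= thr, ]
    n_out <- sum(h$subject_taxon %in% g$outgroup)
    want <- if (nrow(h) == 0) "orphan"
    else if (n_out == 0) "specific" else "not_specific"
    expect_equal(calls$verdict[k], want)
  }
})

test_that("the specific set is non-decreasing as the threshold tightens", {
  set.seed(73)
  g <- make_groups()
  taxa <- c(g$ingroup, g$outgroup)
  hits <- do.call(rbind, lapply(1:400, function(i)
    hit_row(sprintf("q%02d", sample(25, 1)), sprintf("s%03d", i),
            sample(taxa, 1), 10^runif(1, -40, -2))))
  thresholds <- c(1e-3, 1e-5, 1e-10, 1e-20)
  specific_sets <- lapply(thresholds, function(t) {
    calls <- call_csps(hits, g, evalue_threshold = t)
    calls$query_id[calls$verdict == "specific"]
  })
  for (k in seq_along(thresholds)[-1])
    expect_true(all(specific_sets[[k - 1]] %in% specific_sets[[k]]))
})

test_that("mini search ranks an identical target first and scores match the
           independent local-DP oracle", {
  set.seed(74)
  q <- random_protein(60)
  targets <- proteome_set(list(
    gA = seq_records(c("hit", "other"), "gA", c(q, random_protein(60))),
    gB = seq_records("far", "gB", random_protein(60))))
  hits <- mini_search(seq_records("query", "qg", q), targets,
                      score_threshold = 30)
  expect_equal(hits$subject_id[1], "hit")
  expect_equal(hits$percent_identity[1], 100)
  expect_equal(hits$q_start[1], 1)
  expect_equal(hits$q_end[1], 60)

  # raw scores against a quadratic-time Smith-Waterman oracle
  for (k in 1:20) {
    a <- random_protein(sample(30:50, 1))
    b <- if (k %% 2 == 0) random_protein(sample(30:50, 1))
    else {  # related pair: mutate a
      ch <- strsplit(a, "")[[1]]
      pos <- sample(length(ch), 8)
      ch[pos] <- sample(AA20, 8, TRUE)
      paste(ch, collapse = "")
    }
    want <- sw_score_oracle(a, b)
    got <- cladesig:::.sw_score_vec(cladesig:::.aa_encode(a),
                                    list(cladesig:::.aa_encode(b)),
                                    cladesig:::.blosum62(), 11, 1)
    expect_equal(got, want, info = paste("pair", k))
    al <- cladesig:::.sw_align(cladesig:::.aa_encode(a),
                               cladesig:::.aa_encode(b),
                               cladesig:::.blosum62(), 11, 1)
    expect_equal(al$score, want, info = paste("pair", k))
  }
})

test_that("random queries produce no hits against unrelated targets", {
  set.seed(75)
  targets <- proteome_set(list(
    g1 = seq_records(paste0("t", 1:10), "g1",
                     vapply(rep(200, 10), random_protein, character(1)))))
  q <- seq_records("rand", "qg", random_protein(200))
  hits <- mini_search(q, targets)
  expect_equal(nrow(hits), 0L)
})

test_that("planted clade-restricted genes are exactly the specific calls", {
  ds <- generate_dataset(sim_config(n_ingroup = 4, n_outgroup = 3,
                                    n_families = 10, n_csi = 0, n_csp = 3,
                                    n_noise_proteins = 1, seed = 77))
  queries <- ds$proteomes[[ds$groups$ingroup[1]]]
  hits <- mini_search(queries, ds$proteomes)
  calls <- call_csps(hits, ds$groups, query_ids = queries$id)
  specific <- sort(calls$query_id[calls$verdict == "specific"])
  want <- sort(paste0(ds$groups$ingroup[1], ".",
                      ds$manifest$csp_events$gene))
  expect_equal(specific, want)
  # shared families are never specific; noise is orphan
  fam_q <- grep("\\.SF", calls$query_id)
  expect_true(all(calls$verdict[fam_q] == "not_specific"))
  noise_q <- grep("\\.N", calls$query_id)
  expect_true(all(calls$verdict[noise_q] == "orphan"))
})
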