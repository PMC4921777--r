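test_that("a clean group-specific insert with conserved flanks is found once,
           with the exact interval and size", {
  x <- signature_msa(n_in = 6, n_out = 4, flank = 40, size = 4)
  g <- signature_groups()
  cands <- find_csi_candidates(x, g)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$col_start, 41L)
  expect_equal(cands$col_end, 44L)
  expect_equal(cands$polarity, "insertion")
  expect_equal(c(cands$size_min, cands$size_max), c(4L, 4L))
  expect_equal(cands$flank_left, 20L)
  expect_equal(cands$flank_right, 20L)
  expect_equal(cands$ingroup_violators, "")
  expect_equal(cands$outgroup_violators, "")
})

test_that("outgroup exceptions are honoured and violators reported", {
  x <- signature_msa()
  # give one outgroup row residues across the candidate interval
  leak <- strsplit(x$residues[7], "")[[1]]
  leak[41:44] <- strsplit(x$residues[1], "")[[1]][41:44]
  x$residues[7] <- paste(leak, collapse = "")
  g <- signature_groups()
  expect_equal(nrow(find_csi_candidates(x, g)), 0L)
  relaxed <- csi_params(max_outgroup_exceptions = 1)
  cands <- find_csi_candidates(x, g, relaxed)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$outgroup_violators, x$taxon[7])
})

test_that("group shortage and unassigned rows are handled as specified", {
  x <- signature_msa(n_in = 6, n_out = 4)
  g1 <- group_assignment(list(ingroup = "in01",
                              outgroup = sprintf("out%02d", 1:4)),
                         focal = "ingroup")
  expect_error(suppressWarnings(find_csi_candidates(x, g1)), ">= 2 rows")
  # unassigned rows are excluded with a warning, not an error
  g2 <- group_assignment(list(ingroup = sprintf("in%02d", 1:6),
                              outgroup = sprintf("out%02d", 1:3)),
                         focal = "ingroup")
  expect_warning(cands <- find_csi_candidates(x, g2), "unassigned")
  expect_equal(nrow(cands), 1L)
})

test_that("detection equals the exhaustive interval-scan oracle on random
           gappy alignments", {
  set.seed(61)
  params <- csi_params(flank_window = 8, min_conserved_per_flank = 3,
                       max_indel_size = 12, display_window = 60)
  g <- group_assignment(list(ingroup = sprintf("r%02d", 1:6),
                             outgroup = sprintf("r%02d", 7:12)),
                        focal = "ingroup")
  n_checked <- 0
  for (k in 1:60) {
    gb <- switch(1 + k %% 3, NULL, 1:6, 7:12)
    x <- random_gap_msa(12, 80, group_block_rows = gb)
    got <- find_csi_candidates(x, g, params)
    want <- csi_oracle(x, g, params)
    expect_equal(nrow(got), nrow(want), info = paste("case", k))
    if (nrow(want) > 0) {
      expect_equal(got$col_start, want$s, info = paste("case", k))
      expect_equal(got$col_end, want$e, info = paste("case", k))
      expect_equal(got$polarity, want$polarity, info = paste("case", k))
      n_checked <- n_checked + nrow(want)
    }
  }
  expect_gt(n_checked, 0)  # the fuzz must actually exercise hits
})

test_that("swapping focal group and outgroup flips polarity on the same
           intervals", {
  set.seed(62)
  g <- signature_groups()
  g_swapped <- group_assignment(
    list(ingroup = g$groups$outgroup, outgroup = g$groups$ingroup),
    focal = "ingroup")
  for (k in 1:10) {
    x <- random_gap_msa(10, 80)
    x$taxon <- c(sprintf("in%02d", 1:6), sprintf("out%02d", 1:4))
    a <- find_csi_candidates(x, g, csi_params(flank_window = 8,
                                              min_conserved_per_flank = 3))
    b <- find_csi_candidates(x, g_swapped, csi_params(flank_window = 8,
                                                      min_conserved_per_flank = 3))
    expect_equal(nrow(a), nrow(b))
    if (nrow(a) > 0) {
      expect_equal(a$col_start, b$col_start)
      expect_equal(a$col_end, b$col_end)
      flip <- c(insertion = "deletion", deletion = "insertion")
      expect_equal(unname(flip[a$polarity]), b$polarity)
    }
  }
})

test_that("raising flank strictness never adds candidates (monotonicity)", {
  set.seed(63)
  g <- group_assignment(list(ingroup = sprintf("r%02d", 1:6),
                             outgroup = sprintf("r%02d", 7:12)),
                        focal = "ingroup")
  for (k in 1:10) {
    x <- random_gap_msa(12, 80)
    loose <- csi_params(flank_window = 8, min_conserved_per_flank = 2,
                        conserved_column_min_fraction = 0.7)
    n_loose <- nrow(find_csi_candidates(x, g, loose))
    for (p in list(csi_params(flank_window = 8, min_conserved_per_flank = 4,
                              conserved_column_min_fraction = 0.7),
                   csi_params(flank_window = 8, min_conserved_per_flank = 2,
                              conserved_column_min_fraction = 0.9))) {
      expect_lte(nrow(find_csi_candidates(x, g, p)), n_loose)
    }
  }
})

test_that("polarity calls follow the outgroup and external references", {
  x <- signature_msa()
  g <- signature_groups()
  cand <- find_csi_candidates(x, g)
  expect_equal(classify_polarity(cand, x, g), "insertion")

  # reversed state: ingroup gapped where outgroup carries residues
  x2 <- x
  x2$taxon <- c(sprintf("out%02d", 1:6), sprintf("in%02d", 1:4))
  g2 <- group_assignment(list(ingroup = sprintf("in%02d", 1:4),
                              outgroup = sprintf("out%02d", 1:6)),
                         focal = "ingroup")
  cand2 <- find_csi_candidates(x2, g2)
  expect_equal(cand2$polarity, "deletion")
  expect_equal(classify_polarity(cand2, x2, g2), "deletion")

  # external references split 50/50 against the outgroup consensus
  L <- nchar(x$residues[1])
  seg <- substr(x$residues[1], 41, 44)
  refs <- seq_records(c("ref1", "ref2"), c("ref1", "ref2"),
                      c(paste0(substr(x$residues[1], 1, 40), seg,
                               substr(x$residues[1], 45, L)),
                        paste0(substr(x$residues[1], 1, 40), "----",
                               substr(x$residues[1], 45, L))),
                      aligned = TRUE)
  expect_equal(classify_polarity(cand, x, g, external_refs = refs),
               "ambiguous")
})

test_that("regions map alignment columns to reference residue coordinates", {
  x <- signature_msa(flank = 40, size = 4)
  g <- signature_groups()
  cand <- find_csi_candidates(x, g)
  # gapless ingroup reference: region = first/last conserved flank column
  expect_equal(unname(map_region(cand, x, "in01", g)), c(21, 64))

  # five reference gaps before the left flank shift the region start by five
  ref <- strsplit(x$residues[1], "")[[1]]
  ref[6:10] <- "-"
  x5 <- x
  x5$residues[1] <- paste(ref, collapse = "")
  cand5 <- find_csi_candidates(x5, g)
  expect_equal(unname(map_region(cand5, x5, "in01", g)), c(16, 59))

  allgap <- x
  row <- strsplit(allgap$residues[1], "")[[1]]
  row[21:40] <- "-"
  allgap$residues[1] <- paste(row, collapse = "")
  cand_a <- find_csi_candidates(allgap, g)
  expect_error(map_region(cand_a, allgap, "in01", g), "all-gap in a flank")
})

test_that("signature excerpts render dash-identity layout and decode back", {
  x <- signature_msa(flank = 40, size = 4)
  g <- signature_groups()
  cand <- find_csi_candidates(x, g)
  block <- format_signature_alignment(x, cand, "in01")
  lines <- strsplit(block, "\n")[[1]]
  expect_equal(length(lines), nrow(x) + 1L)  # marker + all rows
  expect_match(lines[1], "^\\s*\\*{4}\\s*$")
  # a row identical to the reference renders as dashes and dots only
  expect_match(lines[3], "^in02\\s+[-.]+$")
  # outgroup rows show '.' across the candidate interval
  expect_match(lines[8], "\\.{4}")

  dec <- decode_signature_alignment(block)
  cols <- attr(block, "columns")
  want <- substr(x$residues, cols[1], cols[2])
  got <- dec$residues[match(x$id, dec$id)]
  expect_equal(got, unname(want))
  # displayed reference residues stay inside the published 60-100 band
  shown <- gsub("-", "", dec$residues[dec$id == "in01"])
  expect_gte(nchar(shown), 60L)
  expect_lte(nchar(shown), 100L)

  # two identical rows: the second renders as all dashes
  y <- msa(seq_records(c("a", "b"), c("a", "b"),
                       rep(paste0(random_protein(70)), 2)))
  fake <- data.frame(col_start = 30L, col_end = 31L, polarity = "insertion")
  blk <- format_signature_alignment(y, fake, "a",
                                    csi_params(display_window = 60))
  ln <- strsplit(blk, "\n")[[1]]
  expect_match(ln[3], "^b\\s+-+$")
})
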