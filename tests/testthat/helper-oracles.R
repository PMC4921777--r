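# Independent oracles used across the test suite. These deliberately share no
# code with the package internals: plain-R dynamic programming, exhaustive
# interval scans and set arithmetic, kept quadratic/naive and only run at
# small problem sizes.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

blosum62_full <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

# --- global affine alignment, plain-R Needleman-Wunsch-Gotoh ----------------
# Returns score, identity (identical / core columns, terminal-gap columns
# excluded) and per-sequence coverage, mirroring the documented definitions.
nw_oracle <- function(a, b, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  NEG <- -1e30
  M <- matrix(NEG, la + 1, lb + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(la)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(lb)) Y[1, j + 1] <- -(open + j * ext)
  tM <- matrix(NA_integer_, la + 1, lb + 1); tX <- tM; tY <- tM
  tX[-1, 1] <- c(0, rep(1, la - 1)); tY[1, -1] <- c(0, rep(2, lb - 1))
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    s <- blosum62_full[A[i], B[j]]
    cand <- c(M[i, j], X[i, j], Y[i, j])
    tM[i + 1, j + 1] <- which.max(cand) - 1L
    M[i + 1, j + 1] <- max(cand) + s
    cand <- c(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
              Y[i, j + 1] - open - ext)
    tX[i + 1, j + 1] <- which.max(cand) - 1L
    X[i + 1, j + 1] <- max(cand)
    cand <- c(M[i + 1, j] - open - ext, X[i + 1, j] - open - ext,
              Y[i + 1, j] - ext)
    tY[i + 1, j + 1] <- which.max(cand) - 1L
    Y[i + 1, j + 1] <- max(cand)
  }
  fin <- c(M[la + 1, lb + 1], X[la + 1, lb + 1], Y[la + 1, lb + 1])
  score <- max(fin)
  cur <- which.max(fin) - 1L
  i <- la; j <- lb; ops <- integer(0)
  while (i > 0 || j > 0) {
    if (cur == 0) { ops <- c(0L, ops); cur <- tM[i + 1, j + 1]; i <- i - 1; j <- j - 1 }
    else if (cur == 1) { ops <- c(1L, ops); cur <- tX[i + 1, j + 1]; i <- i - 1 }
    else { ops <- c(2L, ops); cur <- tY[i + 1, j + 1]; j <- j - 1 }
  }
  diag_idx <- which(ops == 0L)
  if (length(diag_idx) == 0)
    return(list(score = score, identity = 0, coverage = c(0, 0)))
  core <- seq(min(diag_idx), max(diag_idx))
  ia <- cumsum(ops != 2L); ib <- cumsum(ops != 1L)
  matches <- sum(vapply(core[ops[core] == 0L],
                        function(k) A[ia[k]] == B[ib[k]], logical(1)))
  list(score = score,
       identity = matches / length(core),
       coverage = c(sum(ops[core] != 2L) / la, sum(ops[core] != 1L) / lb))
}

# --- local affine alignment score, plain-R Smith-Waterman-Gotoh -------------
sw_score_oracle <- function(a, b, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  NEG <- -1e30
  M <- matrix(0, la + 1, lb + 1)
  X <- matrix(NEG, la + 1, lb + 1); Y <- X
  best <- 0
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    m <- max(M[i, j], X[i, j], Y[i, j], 0) + blosum62_full[A[i], B[j]]
    M[i + 1, j + 1] <- max(m, 0)
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                           Y[i, j + 1] - open - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, X[i + 1, j] - open - ext,
                           Y[i + 1, j] - ext)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# score an explicit 2-row alignment under the same affine model
score_alignment_pair <- function(ra, rb, open = 11, ext = 1) {
  A <- strsplit(ra, "")[[1]]; B <- strsplit(rb, "")[[1]]
  score <- 0
  runA <- 0L; runB <- 0L
  for (k in seq_along(A)) {
    if (A[k] == "-") {
      runA <- runA + 1L; runB <- 0L
      score <- score - ext - if (runA == 1L) open else 0
    } else if (B[k] == "-") {
      runB <- runB + 1L; runA <- 0L
      score <- score - ext - if (runB == 1L) open else 0
    } else {
      runA <- 0L; runB <- 0L
      score <- score + blosum62_full[A[k], B[k]]
    }
  }
  score
}

# --- exhaustive CSI interval-scan oracle ------------------------------------
# Direct transliteration of the stated detection rule over every interval.
csi_oracle <- function(records, groups, params) {
  taxa <- records$taxon
  ing <- which(taxa %in% groups$ingroup)
  out <- which(taxa %in% groups$outgroup)
  keep_rows <- sort(c(ing, out))
  chars <- do.call(rbind, strsplit(records$residues[keep_rows], ""))
  taxa <- taxa[keep_rows]
  ing <- which(taxa %in% groups$ingroup)
  out <- which(taxa %in% groups$outgroup)
  L <- ncol(chars)
  conserved <- vapply(seq_len(L), function(j) {
    col <- chars[, j]
    if (mean(col == "-") > params$conserved_column_max_gap_fraction)
      return(FALSE)
    res <- col[col != "-" & col != "X"]
    if (length(res) == 0) return(FALSE)
    max(table(res)) / sum(col != "-") >= params$conserved_column_min_fraction
  }, logical(1))
  allgap <- function(r, s, e) all(chars[r, s:e] == "-")
  sat <- list(insertion = list(), deletion = list())
  for (s in seq_len(L)) for (e in s:min(L, s + params$max_indel_size - 1L)) {
    ag <- vapply(seq_len(nrow(chars)), allgap, logical(1), s = s, e = e)
    if (sum(ag[ing]) <= params$max_ingroup_exceptions &&
        sum(!ag[out]) <= params$max_outgroup_exceptions)
      sat$insertion[[length(sat$insertion) + 1]] <-
        c(s = s, e = e)
    if (sum(!ag[ing]) <= params$max_ingroup_exceptions &&
        sum(ag[out]) <= params$max_outgroup_exceptions)
      sat$deletion[[length(sat$deletion) + 1]] <- c(s = s, e = e)
  }
  res <- list()
  for (pat in c("insertion", "deletion")) {
    iv <- sat[[pat]]
    if (length(iv) == 0) next
    df <- as.data.frame(do.call(rbind, iv))
    names(df) <- c("s", "e")
    maximal <- vapply(seq_len(nrow(df)), function(k) {
      contains_k <- df$s <= df$s[k] & df$e >= df$e[k] &
        (df$s < df$s[k] | df$e > df$e[k])
      !any(contains_k)
    }, logical(1))
    df <- df[maximal, , drop = FALSE]
    flank_ok <- vapply(seq_len(nrow(df)), function(k) {
      lw <- seq_len(df$s[k] - 1)
      lw <- lw[lw >= df$s[k] - params$flank_window]
      rw <- seq(df$e[k] + 1, length.out = params$flank_window)
      rw <- rw[rw <= L]
      sum(conserved[lw]) >= params$min_conserved_per_flank &&
        sum(conserved[rw]) >= params$min_conserved_per_flank
    }, logical(1))
    df <- df[flank_ok, , drop = FALSE]
    if (nrow(df) == 0) next
    df <- df[order(df$s), , drop = FALSE]
    merged <- df[1, , drop = FALSE]
    for (k in seq_len(nrow(df))[-1]) {
      last <- merged[nrow(merged), ]
      if (df$s[k] <= last$e) {
        if ((df$e[k] - df$s[k]) > (last$e - last$s))
          merged[nrow(merged), ] <- df[k, ]
      } else merged <- rbind(merged, df[k, ])
    }
    merged$polarity <- pat
    res[[pat]] <- merged
  }
  if (length(res) == 0)
    return(data.frame(s = integer(), e = integer(), polarity = character()))
  out <- do.call(rbind, res)
  out <- out[order(out$s, out$e, out$polarity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- tree oracles -----------------------------------------------------------

# bipartitions of an unrooted tree as canonical strings (smaller side sorted)
bipartitions_oracle <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  ntip <- length(tips)
  below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(ntip))
  parts <- lapply(internal, function(nd) {
    side <- sort(below(nd))
    other <- setdiff(tips, side)
    if (length(side) < 2 || length(other) < 2) return(NULL)
    paste(if (paste(side, collapse = ",") < paste(other, collapse = ","))
      side else other, collapse = ",")
  })
  unique(unlist(parts))
}

rf_oracle <- function(t1, t2) {
  b1 <- bipartitions_oracle(t1); b2 <- bipartitions_oracle(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# additive distance matrix of a tree (path lengths)
tree_distances <- function(tree) ape::cophenetic.phylo(tree)

# --- misc fixtures ----------------------------------------------------------

# an alignment with an ingroup-specific planted gap pattern and fully
# conserved flanks: `flank` identical columns either side of a `size`-column
# insert carried by the ingroup only
signature_msa <- function(n_in = 6, n_out = 4, flank = 40, size = 4,
                          seed = 42) {
  set.seed(seed)
  left <- random_protein(flank)
  right <- random_protein(flank)
  insert <- random_protein(size)
  ids <- c(sprintf("in%02d", seq_len(n_in)), sprintf("out%02d", seq_len(n_out)))
  taxa <- ids
  res <- c(rep(paste0(left, insert, right), n_in),
           rep(paste0(left, strrep("-", size), right), n_out))
  msa(seq_records(ids, taxa, res, aligned = TRUE), family_id = "FAM1")
}

signature_groups <- function(n_in = 6, n_out = 4) {
  group_assignment(list(ingroup = sprintf("in%02d", seq_len(n_in)),
                        outgroup = sprintf("out%02d", seq_len(n_out))),
                   focal = "ingroup")
}

# random gappy MSA for oracle-equivalence fuzzing: conserved backbone with
# random per-row gap blocks and (optionally) a gap block shared by a whole
# row group, the situation a signature scan is meant to pick up
random_gap_msa <- function(nrow_ = 12, ncol_ = 80, n_blocks = 3,
                           group_block_rows = NULL) {
  base <- random_protein(ncol_)
  rows <- vapply(seq_len(nrow_), function(i) {
    s <- strsplit(base, "")[[1]]
    # sprinkle substitutions
    nsub <- rpois(1, ncol_ * 0.1)
    if (nsub > 0) {
      pos <- sample(ncol_, min(nsub, ncol_))
      s[pos] <- sample(AA20, length(pos), replace = TRUE)
    }
    for (b in seq_len(sample(0:n_blocks, 1))) {
      w <- sample(1:12, 1)
      st <- sample(ncol_ - w + 1, 1)
      s[st:(st + w - 1)] <- "-"
    }
    paste(s, collapse = "")
  }, character(1))
  if (!is.null(group_block_rows)) {
    w <- sample(1:8, 1)
    st <- sample(seq(10, ncol_ - w - 10), 1)
    for (r in group_block_rows) {
      s <- strsplit(rows[r], "")[[1]]
      s[st:(st + w - 1)] <- "-"
      rows[r] <- paste(s, collapse = "")
    }
  }
  # avoid all-gap columns
  chars <- do.call(rbind, strsplit(rows, ""))
  bad <- which(colSums(chars != "-") == 0)
  if (length(bad) > 0) {
    chars[1, bad] <- sample(AA20, length(bad), replace = TRUE)
    rows <- apply(chars, 1, paste, collapse = "")
  }
  ids <- sprintf("r%02d", seq_len(nrow_))
  msa(seq_records(ids, ids, rows, aligned = TRUE))
}
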