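# Per-family multiple alignment (progressive, profile-profile with a k-mer
# UPGMA guide tree), conserved-block trimming with relaxed parameters, and
# concatenation into a supermatrix with partition bookkeeping.

#' Construct/validate a multiple sequence alignment
#'
#' @param records aligned sequence-record set (equal lengths, `-` allowed).
#' @param family_id optional family label carried through trimming and
#'   concatenation.
#' @return the records with class `msa`; no column may be all-gap.
#' @export
msa <- function(records, family_id = NULL) {
  validate_records(records$id, records$residues, aligned = TRUE)
  m <- .msa_matrix(records)
  if (ncol(m) > 0L && any(colSums(m != "-") == 0L))
    stop("alignment contains an all-gap column")
  attr(records, "aligned") <- TRUE
  if (!is.null(family_id)) attr(records, "family_id") <- family_id
  class(records) <- c("msa", "data.frame")
  records
}

# character matrix view of an alignment (rows = records)
.msa_matrix <- function(records) {
  n <- nrow(records)
  if (n == 0L) return(matrix(character(0L), 0L, 0L))
  L <- nchar(records$residues[1L])
  matrix(unlist(strsplit(records$residues, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = L, byrow = TRUE,
         dimnames = list(records$id, NULL))
}

.matrix_msa <- function(m, taxa, family_id = NULL) {
  rec <- seq_records(rownames(m), taxa,
                     apply(m, 1L, paste, collapse = ""), aligned = TRUE)
  msa(rec, family_id = family_id)
}

# fractional residue profile of an alignment block (21 x L; gaps contribute 0,
# normalisation by the number of rows so gap-rich columns score low)
.profile <- function(m) {
  n <- nrow(m)
  p <- matrix(0, length(AA_LETTERS), ncol(m), dimnames = list(AA_LETTERS, NULL))
  for (a in AA_LETTERS) p[a, ] <- colSums(m == a)
  p / n
}

# shared 3-mer distance between two unaligned sequences
.kmer_dist <- function(seqs, k = 3L) {
  km <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0L))
    substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
  })
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ti <- table(km[[i]]); tj <- table(km[[j]])
    common <- intersect(names(ti), names(tj))
    shared <- sum(pmin(ti[common], tj[common]))
    denom <- max(1L, min(length(km[[i]]), length(km[[j]])))
    D[i, j] <- D[j, i] <- 1 - shared / denom
  }
  D
}

# merge two alignment matrices along a profile-profile path
.merge_alignments <- function(ma, mb) {
  S <- .blosum62()
  pa <- .profile(ma); pb <- .profile(mb)
  colscore <- t(pa) %*% S %*% pb
  ops <- .profile_nw_path(colscore, GAP_OPEN, GAP_EXT)
  na <- ncol(ma); nb <- ncol(mb)
  ia <- ib <- 0L
  outa <- matrix("-", nrow(ma), length(ops))
  outb <- matrix("-", nrow(mb), length(ops))
  ca <- integer(0L); cb <- integer(0L)  # source column for each output column
  for (k in seq_along(ops)) {
    if (ops[k] != 2L) { ia <- ia + 1L; outa[, k] <- ma[, ia] }
    if (ops[k] != 1L) { ib <- ib + 1L; outb[, k] <- mb[, ib] }
  }
  stopifnot(ia == na, ib == nb)
  out <- rbind(outa, outb)
  rownames(out) <- c(rownames(ma), rownames(mb))
  out
}

#' Progressively align a protein family
#'
#' Pairwise 3-mer distances feed a UPGMA guide tree (unless one is supplied);
#' profiles are then merged leaf-to-root by profile-profile global alignment
#' with affine gaps (BLOSUM62, open 11, extend 1). Deterministic; never
#' produces an all-gap column. For externally aligned families, import the
#' aligned FASTA with [read_fasta()] and wrap it with [msa()] instead.
#'
#' @param family a `protein_family` from [cluster_proteomes()], or a
#'   sequence-record set with >= 2 unaligned records.
#' @param guide optional `ape::phylo` guide tree whose tip labels are the
#'   record ids.
#' @return an [msa()], rows in input-record order.
#' @export
align_family <- function(family, guide = NULL) {
  fid <- NULL
  if (inherits(family, "protein_family")) {
    fid <- family$family_id
    records <- family_records(family)
  } else records <- family
  if (nrow(records) < 2L) stop("cannot align a single-member family")
  n <- nrow(records)
  merges <- if (is.null(guide)) {
    D <- .kmer_dist(records$residues)
    dimnames(D) <- list(records$id, records$id)
    hc <- hclust(as.dist(D), method = "average")
    hc$merge
  } else {
    .guide_merges(guide, records$id)
  }
  blocks <- lapply(seq_len(n), function(i) {
    m <- matrix(strsplit(records$residues[i], "", fixed = TRUE)[[1L]],
                nrow = 1L)
    rownames(m) <- records$id[i]
    m
  })
  merged <- vector("list", n - 1L)
  for (r in seq_len(n - 1L)) {
    pick <- function(x) if (x < 0L) blocks[[-x]] else merged[[x]]
    merged[[r]] <- .merge_alignments(pick(merges[r, 1L]), pick(merges[r, 2L]))
  }
  final <- merged[[n - 1L]][records$id, , drop = FALSE]
  .matrix_msa(final, records$taxon, family_id = fid)
}

# convert a rooted/unrooted guide phylo into an hclust-style merge table
.guide_merges <- function(guide, ids) {
  if (!all(sort(guide$tip.label) == sort(ids)))
    stop("guide tree tips do not match record ids")
  tr <- ape::multi2di(guide)
  if (!ape::is.rooted(tr)) tr <- ape::root(tr, outgroup = tr$tip.label[1L],
                                           resolve.root = TRUE)
  n <- length(tr$tip.label)
  merge <- matrix(0L, n - 1L, 2L)
  node_row <- integer(tr$Nnode)  # merge row representing each internal node
  row <- 0L
  ord <- ape::reorder.phylo(tr, "postorder")
  # process internal nodes in postorder; collapse multifurcations greedily
  kids <- split(ord$edge[, 2L], ord$edge[, 1L])
  for (nd in unique(ord$edge[, 1L])) {
    ch <- kids[[as.character(nd)]]
    code <- function(x) {
      if (x <= n) -match(tr$tip.label[x], ids) else node_row[x - n]
    }
    cur <- code(ch[1L])
    for (k in 2L:length(ch)) {
      row <- row + 1L
      merge[row, ] <- c(cur, code(ch[k]))
      cur <- row
    }
    node_row[nd - n] <- cur
  }
  merge[seq_len(row), , drop = FALSE]
}

#' Trimming parameters for [trim_blocks()]
#'
#' Relaxed block-filter settings: a column is conserved when its most frequent
#' residue (gaps excluded) occurs in more than `conserved_fraction` of all
#' rows and its gap fraction is at most `max_gap_fraction`; blocks are split
#' at runs of more than `max_nonconserved_contig` consecutive non-conserved
#' columns, must begin and end on conserved columns, and must span at least
#' `min_block` columns.
#'
#' @param conserved_fraction strict lower bound on modal-residue row fraction
#'   (default 0.5).
#' @param max_gap_fraction maximum gap fraction of a conserved column
#'   (default 0.5).
#' @param max_nonconserved_contig longest tolerated run of non-conserved
#'   columns inside a block (default 8).
#' @param min_block minimum block length in columns (default 5).
#' @return validated parameter list.
#' @export
trim_params <- function(conserved_fraction = 0.5, max_gap_fraction = 0.5,
                        max_nonconserved_contig = 8L, min_block = 5L) {
  stopifnot(conserved_fraction >= 0, conserved_fraction < 1,
            max_gap_fraction >= 0, max_gap_fraction <= 1,
            max_nonconserved_contig >= 0L, min_block >= 1L)
  list(conserved_fraction = conserved_fraction,
       max_gap_fraction = max_gap_fraction,
       max_nonconserved_contig = as.integer(max_nonconserved_contig),
       min_block = as.integer(min_block))
}

#' Trim an alignment to contiguous conserved blocks
#'
#' @param x an [msa()].
#' @param params a [trim_params()] list.
#' @return list with `msa` (the column-subset alignment), `kept_columns`
#'   (strictly increasing 1-based source columns) and `source_length`,
#'   classed `trimmed_msa`. May keep zero columns.
#' @export
trim_blocks <- function(x, params = trim_params()) {
  m <- .msa_matrix(x)
  n <- nrow(m); L <- ncol(m)
  conserved <- logical(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    res <- col[col != "-"]
    gap_frac <- 1 - length(res) / n
    if (gap_frac > params$max_gap_fraction) next
    if (length(res) == 0L) next
    conserved[j] <- max(table(res)) / n > params$conserved_fraction
  }
  kept <- integer(0L)
  # split at runs of > max_nonconserved_contig consecutive non-conserved cols
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sep <- !r$values & r$lengths > params$max_nonconserved_contig
  if (any(sep)) {  # the separator runs themselves never enter a block
    seg_start <- c(1L, ends[sep] + 1L)
    seg_end <- c(starts[sep] - 1L, L)
  } else {
    seg_start <- 1L
    seg_end <- L
  }
  for (s in seq_along(seg_start)) {
    lo <- seg_start[s]; hi <- seg_end[s]
    if (lo > hi) next
    idx <- lo:hi
    cons_idx <- idx[conserved[idx]]
    if (length(cons_idx) == 0L) next
    lo <- cons_idx[1L]; hi <- cons_idx[length(cons_idx)]
    if (hi - lo + 1L < params$min_block) next
    kept <- c(kept, lo:hi)
  }
  sub <- m[, kept, drop = FALSE]
  rec <- seq_records(x$id, x$taxon,
                     if (length(kept) > 0L)
                       apply(sub, 1L, paste, collapse = "")
                     else rep("", nrow(x)),
                     aligned = TRUE)
  structure(list(msa = if (length(kept) > 0L)
                   msa(rec, family_id = attr(x, "family_id"))
                 else rec,
                 kept_columns = kept,
                 source_length = L,
                 family_id = attr(x, "family_id")),
            class = "trimmed_msa")
}

#' Concatenate trimmed family alignments into a supermatrix
#'
#' Families are concatenated in ascending family-id order. Genomes absent
#' from a family are padded with `-` across that family's partition. Row
#' taxon labels of the per-family alignments must be genome ids.
#'
#' @param trimmed list of `trimmed_msa` (or [msa()]) objects, each carrying a
#'   family id.
#' @param genomes character vector of genome ids forming the supermatrix rows.
#' @return list with `records` (one aligned record per genome) and
#'   `partitions` (family_id, start, end; 1-based inclusive, tiling
#'   1..length), classed `supermatrix`.
#' @export
concatenate_alignments <- function(trimmed, genomes) {
  get_fid <- function(t)
    if (inherits(t, "trimmed_msa")) t$family_id else attr(t, "family_id")
  get_msa <- function(t) if (inherits(t, "trimmed_msa")) t$msa else t
  fids <- vapply(trimmed, function(t) {
    f <- get_fid(t)
    if (is.null(f)) stop("alignment without a family id") else f
  }, character(1L))
  if (anyDuplicated(fids)) stop("duplicate family id among alignments")
  trimmed <- trimmed[order(fids)]
  fids <- sort(fids)
  rows <- setNames(rep("", length(genomes)), genomes)
  parts <- data.frame(family_id = character(0L), start = integer(0L),
                      end = integer(0L), stringsAsFactors = FALSE)
  pos <- 0L
  for (k in seq_along(trimmed)) {
    al <- get_msa(trimmed[[k]])
    len <- if (nrow(al) > 0L) nchar(al$residues[1L]) else 0L
    if (len == 0L) next
    if (anyDuplicated(al$taxon))
      stop("duplicate genome row within family ", fids[k], ": ",
           al$taxon[duplicated(al$taxon)][1L])
    unknown <- setdiff(al$taxon, genomes)
    if (length(unknown) > 0L)
      stop("family ", fids[k], " has rows for unknown genome(s): ",
           paste(unknown, collapse = ", "))
    pad <- strrep("-", len)
    add <- setNames(rep(pad, length(genomes)), genomes)
    add[al$taxon] <- al$residues
    rows[] <- paste0(rows, add)
    parts <- rbind(parts, data.frame(family_id = fids[k], start = pos + 1L,
                                     end = pos + len,
                                     stringsAsFactors = FALSE))
    pos <- pos + len
  }
  rec <- seq_records(genomes, genomes, unname(rows), aligned = TRUE)
  structure(list(records = rec, partitions = parts, length = pos),
            class = "supermatrix")
}

#' Write the partition map of a supermatrix
#'
#' @param sm a [concatenate_alignments()] supermatrix.
#' @param path output file.
#' @param format `"tsv"` (family_id, start, end) or `"raxml"`
#'   (`PROT, family = start-end` lines for external ML runs).
#' @export
write_partitions <- function(sm, path, format = c("tsv", "raxml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(sm$partitions, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  } else {
    writeLines(sprintf("PROT, %s = %d-%d", sm$partitions$family_id,
                       sm$partitions$start, sm$partitions$end), path)
  }
  invisible(path)
}
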