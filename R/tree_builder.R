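# Distance-based phylogeny over the supermatrix: pairwise-deletion distances,
# neighbor joining (via ape), midpoint rooting (via phangorn), column-resampled
# bootstrap supports, and Robinson-Foulds topology comparison.

#' Pairwise distance matrix from an alignment
#'
#' Gap columns are pairwise-deleted: each pair is compared over the columns
#' where neither row has a gap. `model = "p"` gives the mismatch fraction;
#' `model = "poisson"` applies the correction d = -ln(1 - p).
#'
#' @param x an [msa()], a supermatrix from [concatenate_alignments()], or an
#'   aligned sequence-record set with >= 3 rows.
#' @param model `"p"` or `"poisson"`.
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
distance_matrix <- function(x, model = c("p", "poisson")) {
  model <- match.arg(model)
  records <- if (inherits(x, "supermatrix")) x$records else x
  if (nrow(records) < 3L) stop("need at least 3 rows")
  m <- .msa_matrix(records)
  n <- nrow(m)
  gap <- m == "-"
  D <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok))
      stop("no comparable columns for pair ", records$id[i], " / ",
           records$id[j])
    p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    if (model == "poisson") {
      if (p >= 1)
        stop("saturated pair ", records$id[i], " / ", records$id[j],
             " (p >= 1): poisson correction undefined")
      p <- -log(1 - p)
    }
    D[i, j] <- D[j, i] <- p
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration (as implemented in \pkg{ape}). Negative
#' branch lengths are clamped to zero and the total clamped length is reported
#' with a message.
#'
#' @param D symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) >= 3L, isTRUE(all.equal(D, t(D),
                                                          tolerance = 1e-8)))
  tree <- ape::nj(as.dist(D))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message("clamped ", sum(neg), " negative branch length(s); total deficit ",
            format(-sum(tree$edge.length[neg]), digits = 4))
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, so the
#' two most distant leaves are equidistant from the root.
#'
#' @param tree unrooted `ape::phylo` with branch lengths.
#' @return rooted `ape::phylo`.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (all(tree$edge.length == 0)) stop("all branch lengths are zero")
  phangorn::midpoint(tree)
}

#' Neighbor-joining tree with column-resampling bootstrap supports
#'
#' Alignment columns are resampled with replacement `replicates` times; a tree
#' is built per replicate and each internal branch of the full-data tree is
#' annotated with the fraction of replicates containing its bipartition.
#' Deterministic given `seed`.
#'
#' @param x alignment or supermatrix accepted by [distance_matrix()].
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @param model distance model, as in [distance_matrix()].
#' @return unrooted `ape::phylo` with `node.label` supports in `[0, 1]`.
#' @export
bootstrap_support <- function(x, replicates, seed, model = "p") {
  stopifnot(replicates >= 1L)
  records <- if (inherits(x, "supermatrix")) x$records else x
  m <- .msa_matrix(records)
  main <- neighbor_joining(distance_matrix(records, model = model))
  set.seed(seed)
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rec <- seq_records(records$id, records$taxon,
                       apply(m[, cols, drop = FALSE], 1L, paste, collapse = ""),
                       aligned = TRUE)
    reps[[r]] <- suppressMessages(
      neighbor_joining(distance_matrix(rec, model = model)))
  }
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- counts / replicates
  main
}

#' Robinson-Foulds distance between two trees
#'
#' The number of bipartitions present in exactly one of the two trees.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}
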