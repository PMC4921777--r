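# Greedy identity clustering of proteomes into protein families (UCLUST-style
# seeded clustering) and selection of the core families used for the
# concatenated supermatrix.

#' Global identity and coverage between two protein sequences
#'
#' Computes one global alignment with affine gaps (BLOSUM62, gap open 11,
#' extend 1; a gap of length k costs 11 + k). Identity is the fraction of
#' identical columns among aligned columns, excluding terminal-gap columns
#' (columns outside the first/last aligned residue pair); internal gap columns
#' count against identity. Coverage of each sequence is the fraction of its
#' residues lying inside that terminal-gap-free core region.
#'
#' @param a,b residue strings, or single-row sequence-record sets.
#' @return list with `identity`, `coverage` (length-2 numeric, a then b) and
#'   `score` (alignment score in substitution-matrix units).
#' @export
pairwise_identity <- function(a, b) {
  a <- if (is.data.frame(a)) a$residues[1L] else a
  b <- if (is.data.frame(b)) b$residues[1L] else b
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE))
    stop("pairwise_identity expects unaligned sequences")
  st <- .nwg_stats(.aa_encode(a), .aa_encode(b), .blosum62(), GAP_OPEN, GAP_EXT)
  list(identity = st$identity,
       coverage = c(st$coverage_a, st$coverage_b),
       score = st$score)
}

#' Cluster proteomes into protein families by greedy seeded clustering
#'
#' Sequences are processed in deterministic order (length descending, then id
#' ascending). Each sequence joins the first existing seed it matches --
#' global identity >= `id_threshold` and coverage of *both* sequences >=
#' `cov_threshold` -- otherwise it becomes a new seed. When a genome
#' contributes several matches to one family, the member with the highest
#' alignment score to the seed is kept; the others are recorded as rejected
#' paralogs.
#'
#' @param proteomes a [proteome_set()].
#' @param id_threshold minimum pairwise identity (default 0.50).
#' @param cov_threshold minimum mutual alignment coverage (default 0.50).
#' @return list of `protein_family` objects (family_id, seed_id, members,
#'   presence_fraction), with rejected paralogs in attribute `paralogs`.
#' @export
cluster_proteomes <- function(proteomes, id_threshold = 0.5,
                              cov_threshold = 0.5) {
  stopifnot(inherits(proteomes, "proteome_set"))
  stopifnot(id_threshold > 0, id_threshold <= 1,
            cov_threshold > 0, cov_threshold <= 1)
  if (length(proteomes) < 2L) stop("need at least 2 genomes")
  pool <- do.call(rbind, lapply(names(proteomes), function(g) {
    df <- proteomes[[g]]
    if (nrow(df) == 0L) return(NULL)
    data.frame(id = df$id, genome = g, residues = df$residues,
               stringsAsFactors = FALSE)
  }))
  ord <- order(-nchar(pool$residues), pool$id, method = "radix")
  pool <- pool[ord, , drop = FALSE]
  enc <- lapply(pool$residues, .aa_encode)
  S <- .blosum62()

  seeds <- list()          # encoded seed sequences
  seed_row <- integer(0L)  # row in pool for each seed
  assign_seed <- integer(nrow(pool))
  stats <- vector("list", nrow(pool))
  for (k in seq_len(nrow(pool))) {
    hit <- if (length(seeds) > 0L)
      .greedy_first_match(enc[[k]], seeds, S, GAP_OPEN, GAP_EXT,
                          id_threshold, cov_threshold)
    else list(seed = 0L)
    if (hit$seed == 0L) {
      seeds[[length(seeds) + 1L]] <- enc[[k]]
      seed_row <- c(seed_row, k)
      assign_seed[k] <- length(seeds)
      stats[[k]] <- list(identity = 1, coverage_seq = 1, score = NA_real_)
    } else {
      assign_seed[k] <- hit$seed
      stats[[k]] <- list(identity = hit$identity,
                         coverage_seq = hit$coverage_seq, score = hit$score)
    }
  }

  n_gen <- length(proteomes)
  width <- max(3L, nchar(as.character(length(seeds))))
  families <- vector("list", length(seeds))
  paralogs <- list()
  for (f in seq_along(seeds)) {
    rows <- which(assign_seed == f)
    seed_id <- pool$id[seed_row[f]]
    members <- list()
    for (g in unique(pool$genome[rows])) {
      gr <- rows[pool$genome[rows] == g]
      if (length(gr) > 1L) {
        sc <- vapply(gr, function(r) {
          s <- stats[[r]]$score
          if (is.na(s)) Inf else s  # the seed itself always wins
        }, numeric(1L))
        keep <- gr[which.max(sc)]
        rej <- setdiff(gr, keep)
        paralogs[[length(paralogs) + 1L]] <- data.frame(
          family_id = sprintf("F%0*d", width, f), genome = g,
          member_id = pool$id[rej], stringsAsFactors = FALSE)
        gr <- keep
      }
      members[[g]] <- list(id = pool$id[gr], residues = pool$residues[gr],
                           identity = stats[[gr]]$identity,
                           coverage = stats[[gr]]$coverage_seq,
                           score = stats[[gr]]$score)
    }
    families[[f]] <- structure(
      list(family_id = sprintf("F%0*d", width, f), seed_id = seed_id,
           members = members,
           presence_fraction = length(members) / n_gen),
      class = "protein_family")
  }
  attr(families, "paralogs") <- if (length(paralogs) > 0L)
    do.call(rbind, paralogs)
  else
    data.frame(family_id = character(), genome = character(),
               member_id = character(), stringsAsFactors = FALSE)
  families
}

#' Select core families by presence fraction
#'
#' @param families list of families from [cluster_proteomes()].
#' @param presence_threshold minimum fraction of genomes with a member
#'   (default 0.80).
#' @return families with `presence_fraction >= presence_threshold`, sorted by
#'   family id.
#' @export
select_core_families <- function(families, presence_threshold = 0.8) {
  stopifnot(presence_threshold > 0, presence_threshold <= 1)
  keep <- vapply(families, function(f)
    f$presence_fraction >= presence_threshold, logical(1L))
  out <- families[keep]
  out[order(vapply(out, `[[`, character(1L), "family_id"))]
}

#' Flatten families to the tab-separated family table
#'
#' One row per member: family_id, seed_id, genome, member_id, identity,
#' coverage.
#'
#' @param families list of families.
#' @return `data.frame` in family-table column order.
#' @export
family_table <- function(families) {
  rows <- lapply(families, function(f) {
    g <- names(f$members)
    data.frame(family_id = f$family_id, seed_id = f$seed_id, genome = g,
               member_id = vapply(f$members, `[[`, character(1L), "id"),
               identity = vapply(f$members, `[[`, numeric(1L), "identity"),
               coverage = vapply(f$members, `[[`, numeric(1L), "coverage"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(family_id = character(), seed_id = character(),
                      genome = character(), member_id = character(),
                      identity = numeric(), coverage = numeric())
  out
}

# members of a family as a sequence-record set (taxon = genome)
family_records <- function(family) {
  g <- names(family$members)
  seq_records(id = vapply(family$members, `[[`, character(1L), "id"),
              taxon = g,
              residues = vapply(family$members, `[[`, character(1L),
                                "residues"))
}
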