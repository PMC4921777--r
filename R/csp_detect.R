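# Conserved signature protein (CSP) calling: identify query proteins whose
# significant homologs are restricted to the focal group, from a homology hit
# table produced externally or by the built-in Smith-Waterman mini search.

#' Call conserved signature proteins from a hit table
#'
#' A query is `specific` when, among its significant non-self hits (e-value
#' <= `evalue_threshold`), at most `max_exceptions` come from taxa outside the
#' focal group. Queries with no significant non-self hit at all are reported
#' as `orphan`, never as `specific`. Specificity is always relative to the
#' taxon universe represented in the hit table.
#'
#' @param hits `data.frame` from [read_hit_table()] or [mini_search()]; every
#'   `subject_taxon` must resolve to inside/outside the focal group.
#' @param groups a [group_assignment()]; taxa in the focal group count as
#'   in-group, all other assigned taxa as out-group.
#' @param evalue_threshold significance cutoff (default 1e-5).
#' @param max_exceptions tolerated significant out-group hits (default 0).
#' @param query_ids optional character vector of all searched queries; queries
#'   without any hit-table row are then reported as `orphan` rather than
#'   silently missing.
#' @return `data.frame` with one row per query: `query_id`, `group`,
#'   `n_in_hits`, `n_out_hits`, `worst_in_evalue`, `best_out_evalue`,
#'   `verdict` (`specific` / `not_specific` / `orphan`).
#' @export
call_csps <- function(hits, groups, evalue_threshold = 1e-5,
                      max_exceptions = 0L, query_ids = NULL) {
  known <- unlist(groups$groups, use.names = FALSE)
  hits <- hits[hits$subject_id != hits$query_id, , drop = FALSE]  # self-hits
  bad <- unique(hits$subject_taxon[is.na(hits$subject_taxon) |
                                     !(hits$subject_taxon %in% known)])
  if (length(bad) > 0L)
    stop("unresolvable subject taxa: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  missing_q <- setdiff(query_ids, hits$query_id)
  out <- lapply(split(hits, hits$query_id), function(h) {
    sig <- h[h$evalue <= evalue_threshold, , drop = FALSE]
    inn <- sig$subject_taxon %in% groups$ingroup
    n_in <- sum(inn); n_out <- sum(!inn)
    verdict <- if (n_in + n_out == 0L) "orphan"
    else if (n_out <= max_exceptions) "specific"
    else "not_specific"
    data.frame(query_id = h$query_id[1L], group = groups$focal,
               n_in_hits = n_in, n_out_hits = n_out,
               worst_in_evalue = if (n_in > 0L) max(sig$evalue[inn]) else NA_real_,
               best_out_evalue = if (n_out > 0L) min(sig$evalue[!inn]) else NA_real_,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  if (length(missing_q) > 0L)
    out <- c(out, list(data.frame(
      query_id = missing_q, group = groups$focal, n_in_hits = 0L,
      n_out_hits = 0L, worst_in_evalue = NA_real_,
      best_out_evalue = NA_real_, verdict = "orphan",
      stringsAsFactors = FALSE)))
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(query_id = character(), group = character(),
                      n_in_hits = integer(), n_out_hits = integer(),
                      worst_in_evalue = numeric(), best_out_evalue = numeric(),
                      verdict = character(), stringsAsFactors = FALSE)
  out <- out[order(out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Karlin-Altschul-style parameters for the e-value surrogate under BLOSUM62
# with affine gaps 11/1 (the standard gapped values). The surrogate only needs
# to be a documented monotone transform of the raw score and database size:
#   bitscore = (lambda * S - ln K) / ln 2
#   evalue   = m * n * 2^(-bitscore)
KA_LAMBDA <- 0.267
KA_K <- 0.041

.bitscore <- function(score) (KA_LAMBDA * score - log(KA_K)) / log(2)

.evalue <- function(score, m, n) m * n * 2^(-.bitscore(score))

#' All-vs-all local-alignment search over small proteomes
#'
#' A desk-scale homology search: every query is aligned against every target
#' by Smith-Waterman with affine gaps (BLOSUM62, open 11, extend 1). A hit is
#' emitted when the bit score reaches `score_threshold`. E-values are the
#' standard extreme-value transform of the raw score with the gapped BLOSUM62
#' constants (lambda 0.267, K 0.041), with `m` the query length and `n` the
#' total residue count of the target set -- deterministic and monotone in the
#' score, which is all the verdict logic of [call_csps()] requires.
#'
#' @param queries sequence-record set of query proteins.
#' @param targets a [proteome_set()] (genome names become subject taxa).
#' @param score_threshold minimum bit score for emission (default 50).
#' @return hit table `data.frame` (12 standard columns plus `subject_taxon`),
#'   sorted by query then descending bit score.
#' @export
mini_search <- function(queries, targets, score_threshold = 50) {
  stopifnot(nrow(queries) > 0L, length(targets) > 0L)
  S <- .blosum62()
  tdf <- do.call(rbind, lapply(names(targets), function(g) {
    df <- targets[[g]]
    if (nrow(df) == 0L) return(NULL)
    data.frame(id = df$id, taxon = g, residues = df$residues,
               stringsAsFactors = FALSE)
  }))
  tenc <- lapply(tdf$residues, .aa_encode)
  dbsize <- sum(nchar(tdf$residues))
  rows <- list()
  for (q in seq_len(nrow(queries))) {
    qenc <- .aa_encode(queries$residues[q])
    m <- nchar(queries$residues[q])
    scores <- .sw_score_vec(qenc, tenc, S, GAP_OPEN, GAP_EXT)
    hit_idx <- which(.bitscore(scores) >= score_threshold)
    for (t in hit_idx) {
      al <- .sw_align(qenc, tenc[[t]], S, GAP_OPEN, GAP_EXT)
      if (al$score <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = queries$id[q], subject_id = tdf$id[t],
        percent_identity = round(100 * al$matches / al$length, 2),
        alignment_length = al$length, mismatches = al$mismatches,
        gap_opens = al$gap_opens,
        q_start = al$a_start, q_end = al$a_end,
        s_start = al$b_start, s_end = al$b_end,
        evalue = .evalue(al$score, m, dbsize),
        bitscore = round(.bitscore(al$score), 1),
        subject_taxon = tdf$taxon[t], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- as.data.frame(setNames(
      c(list(character(), character()), rep(list(numeric()), 10L)), HIT_COLS))
    out$subject_taxon <- character()
    return(out)
  }
  out[order(out$query_id, -out$bitscore, out$subject_id), , drop = FALSE]
}
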