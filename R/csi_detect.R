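# Conserved signature indel (CSI) detection: scan a multiple sequence
# alignment for group-specific insertion/deletion patterns with conserved
# flanks, call insert/deletion polarity, map candidates onto reference-protein
# coordinates, and render dash-identity signature excerpts.

#' Parameters for CSI detection
#'
#' @param flank_window columns inspected on each side of a candidate
#'   (default 20, i.e. about 40 neighbouring residues in total).
#' @param min_conserved_per_flank minimum conserved columns required in each
#'   flank window (default 5).
#' @param conserved_column_min_fraction minimum fraction of non-gap rows
#'   sharing the modal residue for a column to count as conserved
#'   (default 0.8). `X` never counts toward the modal residue.
#' @param conserved_column_max_gap_fraction maximum gap fraction of a
#'   conserved column (default 0.2).
#' @param max_indel_size largest candidate interval in columns (default 30).
#' @param max_ingroup_exceptions,max_outgroup_exceptions tolerated violators
#'   per side (defaults 0).
#' @param display_window reference residues shown by
#'   [format_signature_alignment()] (default 80; must lie in 60..100).
#' @return validated parameter list, classed `csi_params`.
#' @export
csi_params <- function(flank_window = 20L,
                       min_conserved_per_flank = 5L,
                       conserved_column_min_fraction = 0.8,
                       conserved_column_max_gap_fraction = 0.2,
                       max_indel_size = 30L,
                       max_ingroup_exceptions = 0L,
                       max_outgroup_exceptions = 0L,
                       display_window = 80L) {
  stopifnot(flank_window >= min_conserved_per_flank,
            min_conserved_per_flank >= 0L,
            conserved_column_min_fraction > 0,
            conserved_column_min_fraction <= 1,
            conserved_column_max_gap_fraction >= 0,
            conserved_column_max_gap_fraction <= 1,
            max_indel_size >= 1L,
            max_ingroup_exceptions >= 0L, max_outgroup_exceptions >= 0L,
            display_window >= 60L, display_window <= 100L)
  structure(list(flank_window = as.integer(flank_window),
                 min_conserved_per_flank = as.integer(min_conserved_per_flank),
                 conserved_column_min_fraction = conserved_column_min_fraction,
                 conserved_column_max_gap_fraction =
                   conserved_column_max_gap_fraction,
                 max_indel_size = as.integer(max_indel_size),
                 max_ingroup_exceptions = as.integer(max_ingroup_exceptions),
                 max_outgroup_exceptions = as.integer(max_outgroup_exceptions),
                 display_window = as.integer(display_window)),
            class = "csi_params")
}

# conserved-column flags over the scored rows of an alignment matrix:
# modal non-gap residue (X excluded) shared by >= min_fraction of non-gap
# rows, and gap fraction <= max_gap_fraction of all scored rows
.conserved_columns <- function(m, min_fraction, max_gap_fraction) {
  n <- nrow(m)
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    res <- col[col != "-"]
    if (1 - length(res) / n > max_gap_fraction) return(FALSE)
    res <- res[res != "X"]
    if (length(res) == 0L) return(FALSE)
    ngap <- sum(m[, j] != "-")
    max(table(res)) / ngap >= min_fraction
  }, logical(1L))
}

# split alignment rows into scored ingroup/outgroup index sets
.split_rows <- function(records, groups) {
  ing <- which(records$taxon %in% groups$ingroup)
  out <- which(records$taxon %in% groups$outgroup)
  un <- setdiff(seq_len(nrow(records)), c(ing, out))
  if (length(un) > 0L)
    warning("excluding ", length(un), " unassigned row(s): ",
            paste(utils::head(records$id[un], 5L), collapse = ", "))
  if (length(ing) < 2L || length(out) < 2L)
    stop("both focal group and outgroup need >= 2 rows present in the ",
         "alignment (have ", length(ing), " and ", length(out), ")")
  list(ingroup = ing, outgroup = out)
}

#' Scan an alignment for group-specific conserved signature indels
#'
#' A column interval `I` (at most `max_indel_size` wide) matches the
#' *insertion* pattern when every focal-group row carries at least one residue
#' somewhere in `I` while every outgroup row is all-gap across `I`, and the
#' *deletion* pattern in the reverse case; each side tolerates at most the
#' configured number of violators. Among matching intervals only maximal ones
#' (not contained in a larger matching interval of the same pattern) are kept,
#' and each must show at least `min_conserved_per_flank` conserved columns in
#' the `flank_window` columns on both sides. Overlapping same-pattern
#' candidates are merged into the larger interval. Candidates are returned
#' sorted by left column.
#'
#' @param x an [msa()] whose row taxa are assignable to the groups.
#' @param groups a [group_assignment()]; unassigned rows are excluded with a
#'   warning.
#' @param params a [csi_params()] list.
#' @return `data.frame` with columns `col_start`, `col_end`, `polarity`
#'   (`insertion`/`deletion`), `size_min`, `size_max`, `flank_left`,
#'   `flank_right`, `ingroup_violators`, `outgroup_violators` (comma-joined
#'   taxon lists) and `family_id`.
#' @export
find_csi_candidates <- function(x, groups, params = csi_params()) {
  rows <- .split_rows(x, groups)
  scored <- sort(c(rows$ingroup, rows$outgroup))
  m <- .msa_matrix(x)[scored, , drop = FALSE]
  taxa <- x$taxon[scored]
  ing <- which(scored %in% rows$ingroup)
  out <- which(scored %in% rows$outgroup)
  L <- ncol(m)
  empty <- .empty_candidates()
  if (L == 0L) return(empty)

  gaps <- m == "-"
  # cumulative gap counts: cg[r, j+1] = gaps of row r in columns 1..j
  cg <- cbind(0L, t(apply(gaps, 1L, cumsum)))
  conserved <- .conserved_columns(m, params$conserved_column_min_fraction,
                                  params$conserved_column_max_gap_fraction)

  # all matching intervals per pattern, then maximality, flanks, merging
  found <- list(insertion = list(), deletion = list())
  for (s in seq_len(L)) {
    emax <- min(L, s + params$max_indel_size - 1L)
    for (e in s:emax) {
      len <- e - s + 1L
      g <- cg[, e + 1L] - cg[, s]
      allgap <- g == len
      # insertion: ingroup bears residues, outgroup all-gap
      ing_viol <- ing[allgap[ing]]
      out_viol <- out[!allgap[out]]
      if (length(ing_viol) <= params$max_ingroup_exceptions &&
          length(out_viol) <= params$max_outgroup_exceptions)
        found$insertion[[length(found$insertion) + 1L]] <-
          list(s = s, e = e, iv = ing_viol, ov = out_viol)
      # deletion: ingroup all-gap, outgroup bears residues
      ing_viol <- ing[!allgap[ing]]
      out_viol <- out[allgap[out]]
      if (length(ing_viol) <= params$max_ingroup_exceptions &&
          length(out_viol) <= params$max_outgroup_exceptions)
        found$deletion[[length(found$deletion) + 1L]] <-
          list(s = s, e = e, iv = ing_viol, ov = out_viol)
    }
  }

  res <- list()
  for (pattern in c("insertion", "deletion")) {
    ivs <- found[[pattern]]
    if (length(ivs) == 0L) next
    ss <- vapply(ivs, `[[`, integer(1L), "s")
    ee <- vapply(ivs, `[[`, integer(1L), "e")
    # maximal: no strictly containing interval of the same pattern
    maxend <- tapply(ee, ss, max)
    starts <- as.integer(names(maxend))
    keep <- logical(length(ivs))
    run <- -Inf
    ord <- order(starts)
    runmax <- setNames(numeric(length(starts)), starts)
    for (s in starts[ord]) {
      runmax[as.character(s)] <- run
      run <- max(run, maxend[as.character(s)])
    }
    for (k in seq_along(ivs)) {
      s <- ss[k]; e <- ee[k]
      keep[k] <- (e == maxend[as.character(s)]) &&
        (runmax[as.character(s)] < e)
    }
    ivs <- ivs[keep]
    # flank conservation
    ok <- vapply(ivs, function(iv) {
      lw <- max(1L, iv$s - params$flank_window):(iv$s - 1L)
      lw <- lw[lw >= 1L & lw < iv$s]
      rw <- (iv$e + 1L):min(L, iv$e + params$flank_window)
      rw <- rw[rw > iv$e & rw <= L]
      sum(conserved[lw]) >= params$min_conserved_per_flank &&
        sum(conserved[rw]) >= params$min_conserved_per_flank
    }, logical(1L))
    ivs <- ivs[ok]
    if (length(ivs) == 0L) next
    # merge overlapping candidates of one pattern: keep the larger interval
    ord <- order(vapply(ivs, `[[`, integer(1L), "s"))
    ivs <- ivs[ord]
    merged <- list(ivs[[1L]])
    for (k in seq_along(ivs)[-1L]) {
      last <- merged[[length(merged)]]
      cur <- ivs[[k]]
      if (cur$s <= last$e) {
        if ((cur$e - cur$s) > (last$e - last$s))
          merged[[length(merged)]] <- cur
      } else merged[[length(merged) + 1L]] <- cur
    }
    for (iv in merged) {
      bearing <- if (pattern == "insertion")
        setdiff(ing, iv$iv)
      else
        setdiff(out, iv$ov)
      len <- iv$e - iv$s + 1L
      sizes <- len - (cg[bearing, iv$e + 1L] - cg[bearing, iv$s])
      lw <- max(1L, iv$s - params$flank_window):(iv$s - 1L)
      lw <- lw[lw >= 1L & lw < iv$s]
      rw <- (iv$e + 1L):min(L, iv$e + params$flank_window)
      rw <- rw[rw > iv$e & rw <= L]
      res[[length(res) + 1L]] <- data.frame(
        col_start = iv$s, col_end = iv$e, polarity = pattern,
        size_min = min(sizes), size_max = max(sizes),
        flank_left = sum(conserved[lw]), flank_right = sum(conserved[rw]),
        ingroup_violators = paste(taxa[iv$iv], collapse = ","),
        outgroup_violators = paste(taxa[iv$ov], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$col_start, out$col_end, out$polarity), , drop = FALSE]
  rownames(out) <- NULL
  out$family_id <- if (!is.null(attr(x, "family_id")))
    attr(x, "family_id") else NA_character_
  out
}

.empty_candidates <- function() {
  data.frame(col_start = integer(), col_end = integer(),
             polarity = character(), size_min = integer(),
             size_max = integer(), flank_left = integer(),
             flank_right = integer(), ingroup_violators = character(),
             outgroup_violators = character(), family_id = character(),
             stringsAsFactors = FALSE)
}

#' Call insertion/deletion polarity for a candidate
#'
#' The group bearing residues across the candidate interval defines the
#' derived state: residues in the focal group with a gapped outgroup is an
#' insertion; the reverse is a deletion. Optional external reference rows
#' (e.g. more distant outgroup homologs, aligned to the same columns) can
#' overrule: when they disagree with the outgroup consensus state the call
#' becomes `"ambiguous"`.
#'
#' @param candidate one row of [find_csi_candidates()] output.
#' @param x the scanned [msa()].
#' @param groups the [group_assignment()] used for the scan.
#' @param external_refs optional aligned sequence-record set (same column
#'   space as `x`) of reference rows outside the comparison.
#' @return `"insertion"`, `"deletion"` or `"ambiguous"`.
#' @export
classify_polarity <- function(candidate, x, groups, external_refs = NULL) {
  pol <- candidate$polarity[1L]
  if (is.null(external_refs) || nrow(external_refs) == 0L) return(pol)
  if (nchar(external_refs$residues[1L]) != nchar(x$residues[1L]))
    stop("external reference rows must share the alignment's column space")
  s <- candidate$col_start[1L]; e <- candidate$col_end[1L]
  seg <- substr(external_refs$residues, s, e)
  bears <- vapply(seg, function(z) grepl("[^-]", z), logical(1L),
                  USE.NAMES = FALSE)
  # outgroup consensus state across the interval: bears residues iff deletion
  outgroup_bears <- pol == "deletion"
  if (all(bears == outgroup_bears)) pol else "ambiguous"
}

#' Map a candidate to residue coordinates of a reference sequence
#'
#' The reported region runs from the first conserved column in the left flank
#' window to the last conserved column in the right flank window, expressed as
#' 1-based ungapped residue positions of the reference row (the convention of
#' published signature tables: indel plus conserved flanks).
#'
#' @param candidate one row of [find_csi_candidates()] output.
#' @param x the scanned [msa()].
#' @param reference_id row id of the reference sequence.
#' @param groups the [group_assignment()] used for the scan (conserved columns
#'   are evaluated over the scored rows only).
#' @param params the [csi_params()] used for the scan.
#' @return integer vector `c(start, end)`.
#' @export
map_region <- function(candidate, x, reference_id, groups,
                       params = csi_params()) {
  ref_row <- match(reference_id, x$id)
  if (is.na(ref_row)) stop("reference row not found: ", reference_id)
  rows <- suppressWarnings(.split_rows(x, groups))
  scored <- sort(c(rows$ingroup, rows$outgroup))
  m <- .msa_matrix(x)
  conserved <- .conserved_columns(m[scored, , drop = FALSE],
                                  params$conserved_column_min_fraction,
                                  params$conserved_column_max_gap_fraction)
  L <- ncol(m)
  s <- candidate$col_start[1L]; e <- candidate$col_end[1L]
  lw <- seq_len(s - 1L)
  lw <- lw[lw >= s - params$flank_window]
  rw <- if (e < L) (e + 1L):min(L, e + params$flank_window) else integer(0L)
  if (length(lw) == 0L || length(rw) == 0L)
    stop("candidate has an empty flank window")
  ref <- m[ref_row, ]
  if (all(ref[lw] == "-") || all(ref[rw] == "-"))
    stop("reference ", reference_id, " is all-gap in a flank window")
  lcons <- lw[conserved[lw]]
  rcons <- rw[conserved[rw]]
  if (length(lcons) == 0L || length(rcons) == 0L)
    stop("no conserved column in a flank window")
  ungapped <- cumsum(ref != "-")
  c(start = max(1L, ungapped[lcons[1L]]),
    end = max(1L, ungapped[rcons[length(rcons)]]))
}

#' Render a publication-style dash-identity signature excerpt
#'
#' The reference row is printed in full on the top line together with the
#' ungapped position of its first displayed residue; every other row prints
#' `-` where it matches the reference column, the residue where it differs,
#' and `.` where it is gapped. A marker line of `*` delimits the candidate
#' interval. The displayed window is grown around the candidate until it
#' shows `display_window` reference residues (bounded by the alignment).
#'
#' @param x the scanned [msa()].
#' @param candidate one row of [find_csi_candidates()] output.
#' @param reference_id row id printed on the top line.
#' @param params a [csi_params()] list (`display_window` is used).
#' @return a single character string (the text block).
#' @export
format_signature_alignment <- function(x, candidate, reference_id,
                                       params = csi_params()) {
  m <- .msa_matrix(x)
  ref_row <- match(reference_id, x$id)
  if (is.na(ref_row)) stop("reference row not found: ", reference_id)
  L <- ncol(m)
  s <- candidate$col_start[1L]; e <- candidate$col_end[1L]
  ref <- m[ref_row, ]
  # grow the window alternately left/right until enough reference residues
  lo <- s; hi <- e
  count <- sum(ref[lo:hi] != "-")
  repeat {
    if (count >= params$display_window || (lo == 1L && hi == L)) break
    if (lo > 1L && (hi == L || (s - lo) <= (hi - e))) {
      lo <- lo - 1L
      if (ref[lo] != "-") count <- count + 1L
    } else {
      hi <- hi + 1L
      if (ref[hi] != "-") count <- count + 1L
    }
  }
  cols <- lo:hi
  ids <- x$id
  w <- max(nchar(ids))
  start_coord <- sum(ref[1:lo] != "-")
  if (ref[lo] == "-") start_coord <- start_coord + 1L  # next residue shown
  coord <- as.character(start_coord)
  cw <- nchar(coord)
  pad <- function(z, n) formatC(z, width = -n)
  lines <- character(0L)
  marker <- paste0(strrep(" ", w + cw + 4L),
                   strrep(" ", s - lo), strrep("*", e - s + 1L))
  lines <- c(lines, marker)
  lines <- c(lines, paste0(pad(reference_id, w), "  ", coord, "  ",
                           paste(ref[cols], collapse = "")))
  for (r in seq_len(nrow(m))) {
    if (r == ref_row) next
    row <- m[r, cols]
    shown <- ifelse(row == "-", ".",
                    ifelse(row == ref[cols] & ref[cols] != "-", "-", row))
    lines <- c(lines, paste0(pad(ids[r], w), "  ", strrep(" ", cw), "  ",
                             paste(shown, collapse = "")))
  }
  structure(paste(lines, collapse = "\n"), columns = c(lo, hi))
}

#' Decode a dash-identity excerpt back into its sub-alignment
#'
#' Inverse of [format_signature_alignment()]: reconstructs the displayed
#' sub-alignment (ids and residues, `-` for gaps).
#'
#' @param block text block produced by [format_signature_alignment()].
#' @return aligned sequence-record set (taxon set to the id).
#' @export
decode_signature_alignment <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1L]]
  lines <- lines[!grepl("^\\s*\\**\\s*$", lines)]  # drop the marker line
  toks <- lapply(lines, function(ln) strsplit(trimws(ln), "\\s+")[[1L]])
  ref_tok <- toks[[1L]]
  if (length(ref_tok) != 3L) stop("malformed excerpt: no reference line")
  ref_id <- ref_tok[1L]; ref_seq <- ref_tok[3L]
  refc <- strsplit(ref_seq, "", fixed = TRUE)[[1L]]
  ids <- ref_id
  seqs <- ref_seq
  for (tk in toks[-1L]) {
    if (length(tk) != 2L) stop("malformed excerpt row: ",
                               paste(tk, collapse = " "))
    rc <- strsplit(tk[2L], "", fixed = TRUE)[[1L]]
    dec <- ifelse(rc == ".", "-", ifelse(rc == "-", refc, rc))
    ids <- c(ids, tk[1L])
    seqs <- c(seqs, paste(dec, collapse = ""))
  }
  seq_records(ids, ids, seqs, aligned = TRUE)
}
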