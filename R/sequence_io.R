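# Readers and writers for every external format the pipeline touches:
# FASTA (plain and aligned), tab-separated group maps and id->taxon maps,
# 12/13-column tabular homology hit tables, and newick trees (via ape).
# This is the only file that performs I/O.

# ---- sequence records ------------------------------------------------------

#' Construct a set of sequence records
#'
#' A sequence-record set is a plain `data.frame` with character columns `id`,
#' `taxon` and `residues`. Residues are upper-case amino acids
#' (`ACDEFGHIKLMNPQRSTVWY`, plus `X` for unknown); aligned records may also
#' contain `-`. Ids must be unique within a set and aligned records must all
#' have equal length.
#'
#' @param id character vector of unique sequence ids.
#' @param taxon character vector of genome/organism labels (recycled).
#' @param residues character vector of residue strings.
#' @param aligned logical; if `TRUE` the records form an alignment: `-` is
#'   permitted and all lengths must be equal.
#' @return a `data.frame` with columns `id`, `taxon`, `residues` and an
#'   `aligned` attribute.
#' @export
seq_records <- function(id, taxon, residues, aligned = FALSE) {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  taxon <- rep_len(as.character(taxon), length(id))
  if (length(id) != length(residues))
    stop("id and residues must have equal length")
  validate_records(id, residues, aligned)
  out <- data.frame(id = id, taxon = taxon, residues = residues,
                    stringsAsFactors = FALSE)
  attr(out, "aligned") <- aligned
  out
}

validate_records <- function(id, residues, aligned) {
  if (length(id) == 0L) return(invisible(TRUE))
  if (any(!nzchar(id))) stop("empty sequence id")
  dup <- id[duplicated(id)]
  if (length(dup) > 0L)
    stop("duplicate sequence id: ", dup[1L])
  legal <- paste0(paste(AA_LETTERS, collapse = ""), if (aligned) "-" else "")
  for (k in seq_along(residues)) {
    bad <- regmatches(residues[k],
                      regexpr(sprintf("[^%s]", legal), residues[k]))
    if (length(bad) > 0L && nzchar(bad))
      stop("illegal character '", bad, "' in record ", id[k], " at position ",
           regexpr(sprintf("[^%s]", legal), residues[k]))
    if (!aligned && nchar(residues[k]) == 0L)
      stop("empty sequence in record ", id[k])
  }
  if (aligned) {
    len <- nchar(residues)
    if (length(unique(len)) > 1L) {
      off <- id[which(len != len[1L])[1L]]
      stop("aligned records have unequal lengths (offending record: ", off, ")")
    }
  }
  invisible(TRUE)
}

# ---- FASTA -----------------------------------------------------------------

#' Read a FASTA file of amino-acid sequences
#'
#' Headers are parsed as `>id free-text`: the first whitespace-delimited token
#' is the record id. The taxon label is taken from `taxon_map` when supplied
#' (a named character vector, id -> taxon), otherwise from `default_taxon`,
#' otherwise from the file name without extension.
#'
#' @param path FASTA file.
#' @param aligned logical; if `TRUE`, `-` is allowed and equal lengths are
#'   enforced.
#' @param taxon_map optional named character vector mapping id to taxon.
#' @param default_taxon optional single taxon label for all records.
#' @return a sequence-record set (see [seq_records()]).
#' @export
read_fasta <- function(path, aligned = FALSE, taxon_map = NULL,
                       default_taxon = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(seq_records(character(), character(), character(), aligned))
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not a FASTA file (first line is not a header): ", path)
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1L), 1L)
  res <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1L),
                collapse = "")
  if (length(res) != length(ids))
    stop("FASTA record without sequence lines in ", path)
  res <- gsub("\\s", "", res)
  taxon <- if (!is.null(taxon_map)) {
    unname(taxon_map[ids])
  } else if (!is.null(default_taxon)) {
    rep(default_taxon, length(ids))
  } else {
    rep(sub("\\.[^.]*$", "", basename(path)), length(ids))
  }
  if (anyNA(taxon))
    stop("taxon map does not cover id(s): ",
         paste(ids[is.na(taxon)], collapse = ", "))
  seq_records(ids, taxon, toupper(res), aligned)
}

#' Write sequence records to FASTA
#'
#' Output is byte-stable given identical input and options. Headers are
#' `>id taxon`.
#'
#' @param records a sequence-record set.
#' @param path output file.
#' @param wrap line width for sequence lines (default 60 columns).
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  stopifnot(wrap >= 1L)
  con <- file(path, "wb")  # binary mode: byte-stable across platforms
  on.exit(close(con))
  if (nrow(records) == 0L) return(invisible(path))
  out <- character(0L)
  for (k in seq_len(nrow(records))) {
    s <- records$residues[k]
    starts <- seq(1L, nchar(s), by = wrap)
    out <- c(out, paste0(">", records$id[k], " ", records$taxon[k]),
             substring(s, starts, pmin(starts + wrap - 1L, nchar(s))))
  }
  writeLines(out, con, sep = "\n")
  invisible(path)
}

# ---- proteome sets ---------------------------------------------------------

#' Construct a proteome set
#'
#' A proteome set is a named list mapping genome id to a sequence-record set.
#' Sequence ids must be unique across the whole set.
#'
#' @param genomes named list of sequence-record sets.
#' @return the validated list, classed `proteome_set`.
#' @export
proteome_set <- function(genomes) {
  if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
    stop("proteome set requires named genomes")
  all_ids <- unlist(lapply(genomes, `[[`, "id"), use.names = FALSE)
  dup <- all_ids[duplicated(all_ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id across proteome set: ", dup[1L])
  structure(genomes, class = "proteome_set")
}

#' Read one FASTA file per genome into a proteome set
#'
#' @param files FASTA paths; genome ids default to file names sans extension.
#' @param genomes optional character vector of genome ids, parallel to `files`.
#' @return a [proteome_set()].
#' @export
read_proteomes <- function(files, genomes = NULL) {
  if (is.null(genomes))
    genomes <- sub("\\.[^.]*$", "", basename(files))
  stopifnot(length(genomes) == length(files))
  out <- lapply(seq_along(files), function(k)
    read_fasta(files[k], aligned = FALSE, default_taxon = genomes[k]))
  names(out) <- genomes
  proteome_set(out)
}

#' Write a proteome set, one FASTA per genome
#'
#' @param proteomes a [proteome_set()].
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_proteomes <- function(proteomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(names(proteomes), ".faa"))
  for (k in seq_along(proteomes)) write_fasta(proteomes[[k]], paths[k])
  invisible(paths)
}

# ---- group assignments -----------------------------------------------------

#' Construct a group assignment
#'
#' Named, disjoint taxon sets with one focal (ingroup) set; the outgroup
#' defaults to every assigned taxon outside the focal group.
#'
#' @param groups named list of character vectors (group name -> taxa).
#' @param focal name of the focal group.
#' @param outgroup optional explicit outgroup taxon set.
#' @return a list with elements `groups`, `focal`, `ingroup`, `outgroup`,
#'   classed `group_assignment`.
#' @export
group_assignment <- function(groups, focal, outgroup = NULL) {
  if (!is.list(groups) || is.null(names(groups)))
    stop("groups must be a named list of taxon vectors")
  all_taxa <- unlist(groups, use.names = FALSE)
  dup <- all_taxa[duplicated(all_taxa)]
  if (length(dup) > 0L)
    stop("taxon assigned to more than one group: ", dup[1L])
  if (!focal %in% names(groups))
    stop("focal group '", focal, "' is not a defined group")
  ingroup <- groups[[focal]]
  if (is.null(outgroup))
    outgroup <- setdiff(all_taxa, ingroup)
  if (length(ingroup) == 0L || length(outgroup) == 0L)
    stop("focal group and outgroup must both be non-empty")
  if (length(intersect(ingroup, outgroup)) > 0L)
    stop("focal group and outgroup overlap: ",
         paste(intersect(ingroup, outgroup), collapse = ", "))
  structure(list(groups = groups, focal = focal,
                 ingroup = ingroup, outgroup = outgroup),
            class = "group_assignment")
}

#' Read a tab-separated taxon-to-group map
#'
#' Each line is `taxon<TAB>group`. A taxon listed under two groups is an
#' error. Taxa absent from the file are simply unassigned; downstream scans
#' warn about and exclude unassigned alignment rows.
#'
#' @param path file of `taxon<TAB>group` lines.
#' @param focal name of the focal group.
#' @param outgroup optional explicit outgroup taxon set.
#' @return a [group_assignment()].
#' @export
read_group_map <- function(path, focal, outgroup = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("taxon", "group"), stringsAsFactors = FALSE,
                   quote = "")
  groups <- split(df$taxon, df$group)
  group_assignment(groups, focal = focal, outgroup = outgroup)
}

#' Write the group map consumed by [read_group_map()]
#' @param assignment a [group_assignment()].
#' @param path output file.
#' @export
write_group_map <- function(assignment, path) {
  df <- data.frame(
    taxon = unlist(assignment$groups, use.names = FALSE),
    group = rep(names(assignment$groups),
                lengths(assignment$groups)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a tab-separated id-to-taxon map
#' @param path file of `id<TAB>taxon` lines.
#' @return named character vector (names are ids).
#' @export
read_taxon_map <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("id", "taxon"), stringsAsFactors = FALSE,
                   quote = "")
  setNames(df$taxon, df$id)
}

# ---- hit tables ------------------------------------------------------------

HIT_COLS <- c("query_id", "subject_id", "percent_identity", "alignment_length",
              "mismatches", "gap_opens", "q_start", "q_end", "s_start",
              "s_end", "evalue", "bitscore")

#' Read a 12/13-column tabular homology hit table
#'
#' The standard 12-column tabular dialect (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bit score). An optional 13th column carries the
#' subject taxon and overrides `taxon_map`. Subjects that resolve to no taxon
#' are kept with `NA` and reported in a warning, never silently dropped.
#'
#' @param path hit-table file.
#' @param taxon_map optional named character vector, subject id -> taxon.
#' @return `data.frame` with the 12 standard columns plus `subject_taxon`.
#' @export
read_hit_table <- function(path, taxon_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(
      c(list(character(), character()), rep(list(numeric()), 10L)), HIT_COLS))
    out$subject_taxon <- character()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 12L & nf != 13L)
  if (length(bad) > 0L)
    stop("hit table line ", bad[1L], " has ", nf[bad[1L]],
         " columns (expected 12 or 13)")
  m <- do.call(rbind, lapply(parts, `[`, 1:12))
  out <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                    stringsAsFactors = FALSE)
  num <- apply(m[, 3:12, drop = FALSE], 2L, as.numeric)
  num <- matrix(num, ncol = 10L)
  colnames(num) <- HIT_COLS[3:12]
  if (anyNA(num))
    stop("non-numeric value in hit table ", path)
  out <- cbind(out, as.data.frame(num))
  if (any(out$evalue < 0)) stop("negative e-value in hit table")
  if (any(out$q_start > out$q_end)) stop("q_start > q_end in hit table")
  taxon <- rep(NA_character_, nrow(out))
  if (any(nf == 13L))
    taxon[nf == 13L] <- vapply(parts[nf == 13L], `[`, character(1L), 13L)
  if (!is.null(taxon_map)) {
    need <- is.na(taxon)
    taxon[need] <- unname(taxon_map[out$subject_id[need]])
  }
  out$subject_taxon <- taxon
  if (anyNA(taxon)) {
    un <- unique(out$subject_id[is.na(taxon)])
    warning("unresolved subject taxa for ", length(un), " subject id(s): ",
            paste(utils::head(un, 5L), collapse = ", "),
            if (length(un) > 5L) ", ...")
  }
  out
}

#' Write a hit table in the 13-column tabular dialect
#' @param hits `data.frame` as returned by [read_hit_table()] or
#'   [mini_search()].
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  df <- hits[, c(HIT_COLS, "subject_taxon")]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- newick ----------------------------------------------------------------

#' Read a newick tree
#' @param path newick file.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a newick tree with 10 significant digits on branch lengths
#' @param tree an `ape::phylo` tree.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}
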