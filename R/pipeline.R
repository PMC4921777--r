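# End-to-end pipeline: cluster -> align -> trim -> concatenate -> tree ->
# CSI scan -> CSP scan, with validated configuration, per-stage logging and
# report assembly. The exported functions are the package's entry points; a
# thin command-line wrapper around run_pipeline() ships in inst/scripts/.

#' Pipeline configuration
#'
#' Collects every stage's parameters with their documented defaults and
#' validates bounds. Unknown arguments are rejected.
#'
#' @param id_threshold,cov_threshold clustering thresholds
#'   (see [cluster_proteomes()]; defaults 0.50 / 0.50).
#' @param presence_threshold core-family presence fraction (default 0.80).
#' @param trim [trim_params()] list.
#' @param csi [csi_params()] list.
#' @param evalue_threshold,max_exceptions CSP thresholds (see [call_csps()]).
#' @param csp_score_threshold bit-score cutoff of [mini_search()].
#' @param tree_model distance model, `"poisson"` (default) or `"p"`.
#' @param bootstrap_replicates bootstrap replicate count; 0 disables supports.
#' @param seed run seed for resampling.
#' @return validated configuration, classed `pipeline_config`.
#' @export
pipeline_config <- function(id_threshold = 0.5, cov_threshold = 0.5,
                            presence_threshold = 0.8,
                            trim = trim_params(), csi = csi_params(),
                            evalue_threshold = 1e-5, max_exceptions = 0L,
                            csp_score_threshold = 50,
                            tree_model = "poisson",
                            bootstrap_replicates = 0L, seed = 1L) {
  stopifnot(id_threshold > 0, id_threshold <= 1,
            cov_threshold > 0, cov_threshold <= 1,
            presence_threshold > 0, presence_threshold <= 1,
            evalue_threshold > 0, max_exceptions >= 0L,
            tree_model %in% c("p", "poisson"),
            bootstrap_replicates >= 0L)
  if (!inherits(csi, "csi_params")) csi <- do.call(csi_params, csi)
  trim <- do.call(trim_params, trim[names(trim)])
  structure(list(id_threshold = id_threshold, cov_threshold = cov_threshold,
                 presence_threshold = presence_threshold, trim = trim,
                 csi = csi, evalue_threshold = evalue_threshold,
                 max_exceptions = as.integer(max_exceptions),
                 csp_score_threshold = csp_score_threshold,
                 tree_model = tree_model,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a flat key=value configuration file
#'
#' Sections are `[section]` headers (`clustering`, `trim`, `csi`, `csp`,
#' `tree`); keys match the corresponding [pipeline_config()] /
#' [trim_params()] / [csi_params()] arguments. Unknown sections or keys are
#' rejected.
#'
#' @param path configuration file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  vals <- list(clustering = list(), trim = list(), csi = list(),
               csp = list(), tree = list())
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      if (!section %in% names(vals)) stop("unknown config section: ", section)
    } else {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L || section == "")
        stop("malformed config line: ", ln)
      key <- trimws(kv[1L])
      vals[[section]][[key]] <- as.numeric(trimws(kv[2L]))
    }
  }
  allowed <- list(
    clustering = c("id_threshold", "cov_threshold", "presence_threshold"),
    trim = names(trim_params()),
    csi = names(csi_params()),
    csp = c("evalue_threshold", "max_exceptions", "csp_score_threshold"),
    tree = c("bootstrap_replicates", "seed"))
  for (sec in names(vals)) {
    bad <- setdiff(names(vals[[sec]]), allowed[[sec]])
    if (length(bad) > 0L)
      stop("unknown key in [", sec, "]: ", paste(bad, collapse = ", "))
  }
  args <- c(vals$clustering, vals$csp, vals$tree)
  args$trim <- do.call(trim_params, vals$trim)
  args$csi <- do.call(csi_params, vals$csi)
  do.call(pipeline_config, args)
}

#' Run the full signature-discovery pipeline
#'
#' Clusters the proteomes, selects core families, aligns and trims each core
#' family, concatenates the supermatrix, builds the (midpoint-rooted) tree,
#' scans every multi-row core-family alignment for focal-group CSIs and runs
#' the CSP screen with the focal genomes' proteins as queries. All reports are
#' written to `out_dir`; reruns with the same config and inputs are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param proteomes a [proteome_set()].
#' @param groups a [group_assignment()].
#' @param out_dir output directory (created).
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the in-memory stage results (`families`,
#'   `core`, `alignments`, `supermatrix`, `tree`, `csi`, `csp`) and `out_dir`.
#' @export
run_pipeline <- function(config, proteomes, groups, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(proteomes, "proteome_set"),
            inherits(groups, "group_assignment"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  say("clustering ", length(proteomes), " proteomes")
  families <- stage("cluster", cluster_proteomes(proteomes,
                                                 config$id_threshold,
                                                 config$cov_threshold))
  core <- stage("core", select_core_families(families,
                                             config$presence_threshold))
  say(length(families), " families, ", length(core), " core")
  write.table(family_table(core), file.path(out_dir, "families.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  say("aligning and trimming ", length(core), " core families")
  alignments <- stage("align", lapply(core, align_family))
  trimmed <- stage("trim", lapply(alignments, trim_blocks,
                                  params = config$trim))
  sm <- stage("concat", concatenate_alignments(trimmed, names(proteomes)))
  say("supermatrix: ", sm$length, " columns over ", length(proteomes),
      " genomes")
  write_fasta(sm$records, file.path(out_dir, "supermatrix.fasta"))
  write_partitions(sm, file.path(out_dir, "partitions.tsv"))

  say("building tree (", config$tree_model, " distances)")
  tree <- stage("tree", {
    t0 <- if (config$bootstrap_replicates > 0L)
      bootstrap_support(sm, config$bootstrap_replicates, config$seed,
                        model = config$tree_model)
    else
      suppressMessages(
        neighbor_joining(distance_matrix(sm, model = config$tree_model)))
    midpoint_root(t0)
  })
  write_newick(tree, file.path(out_dir, "tree.nwk"))

  say("scanning core families for CSIs (focal group: ", groups$focal, ")")
  csi <- stage("csi-scan", {
    hits <- lapply(alignments, function(al) {
      ok <- tryCatch({
        suppressWarnings(find_csi_candidates(al, groups, config$csi))
      }, error = function(e) .empty_candidates())
      ok
    })
    out <- do.call(rbind, hits)
    rownames(out) <- NULL
    out
  })
  say(nrow(csi), " CSI candidate(s)")

  say("CSP screen: focal genomes' proteins vs all proteomes")
  csp <- stage("csp-scan", {
    queries <- proteomes[[groups$ingroup[1L]]]
    hits <- mini_search(queries, proteomes,
                        score_threshold = config$csp_score_threshold)
    call_csps(hits, groups, config$evalue_threshold, config$max_exceptions,
              query_ids = queries$id)
  })
  say(sum(csp$verdict == "specific"), " specific protein(s)")

  reports <- render_table_report(csi, csp, groups)
  writeLines(reports$csi, file.path(out_dir, "csi_report.tsv"))
  writeLines(reports$csp, file.path(out_dir, "csp_report.tsv"))
  log <- c(paste("package:", as.character(utils::packageVersion("cladesig"))),
           paste("seed:", config$seed),
           paste("genomes:", length(proteomes)),
           paste("families:", length(families)),
           paste("core_families:", length(core)),
           paste("supermatrix_columns:", sm$length),
           paste("csi_candidates:", nrow(csi)),
           paste("csp_specific:", sum(csp$verdict == "specific")),
           paste("focal_group:", groups$focal))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(list(families = families, core = core, alignments = alignments,
                 trimmed = trimmed, supermatrix = sm, tree = tree,
                 csi = csi, csp = csp, out_dir = out_dir))
}

#' Render signature tables in the published column layout
#'
#' CSI rows carry the protein/family id, reference id, rendered indel size
#' (`"4 aa ins"`, `"2-7 aa ins"`), region, specificity group and violators;
#' CSP rows carry id, length, function passthrough and species specificity.
#'
#' @param candidates CSI candidate `data.frame` (may have `region_start`,
#'   `region_end` and `reference_id` columns from [map_region()]).
#' @param csps CSP call `data.frame` from [call_csps()].
#' @param groups the [group_assignment()] scanned against.
#' @param lengths optional named vector of query lengths for the CSP table.
#' @param functions optional named vector of functional annotations.
#' @return list of two character vectors (`csi`, `csp`), one line per row,
#'   tab-separated with headers.
#' @export
render_table_report <- function(candidates, csps, groups, lengths = NULL,
                                functions = NULL) {
  render_size <- function(smin, smax, pol) {
    tag <- if (pol == "insertion") "ins" else "del"
    if (smin == smax) sprintf("%d aa %s", smin, tag)
    else sprintf("%d-%d aa %s", smin, smax, tag)
  }
  csi_lines <- paste(c("family_id", "reference_id", "indel_size",
                       "indel_region", "specificity", "ingroup_violators",
                       "outgroup_violators"), collapse = "\t")
  if (nrow(candidates) > 0L) {
    for (k in seq_len(nrow(candidates))) {
      cd <- candidates[k, ]
      region <- if (!is.null(cd$region_start) && !is.na(cd$region_start))
        sprintf("%d-%d", cd$region_start, cd$region_end)
      else sprintf("cols %d-%d", cd$col_start, cd$col_end)
      refid <- if (!is.null(cd$reference_id)) cd$reference_id else ""
      csi_lines <- c(csi_lines, paste(
        c(cd$family_id, refid,
          render_size(cd$size_min, cd$size_max, cd$polarity), region,
          groups$focal, cd$ingroup_violators, cd$outgroup_violators),
        collapse = "\t"))
    }
  }
  csp_lines <- paste(c("query_id", "length", "function", "specificity",
                       "n_in_hits", "n_out_hits"), collapse = "\t")
  specific <- csps[csps$verdict == "specific", , drop = FALSE]
  if (nrow(specific) > 0L) {
    for (k in seq_len(nrow(specific))) {
      cp <- specific[k, ]
      len <- if (!is.null(lengths)) lengths[[cp$query_id]] else NA
      fn <- if (!is.null(functions) && !is.null(functions[[cp$query_id]]))
        functions[[cp$query_id]] else "unknown, hypothetical"
      csp_lines <- c(csp_lines, paste(
        c(cp$query_id, len, fn, groups$focal, cp$n_in_hits, cp$n_out_hits),
        collapse = "\t"))
    }
  }
  list(csi = c("# specificity is relative to the taxa supplied in the run",
               csi_lines),
       csp = c("# specificity is relative to the taxon universe of the hit table",
               csp_lines))
}
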