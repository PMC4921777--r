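# Simulator: proteome sets evolved on a known tree with planted clade-specific
# indels (CSIs) and clade-restricted genes (CSPs), plus unrelated noise
# proteins. The manifest records every planted event, giving the pipeline a
# ground-truth acceptance surface.

#' Simulation configuration
#'
#' Defaults mirror a small ordinal-scale comparison: a 12-genome focal clade
#' against 8 outgroup genomes, 100 shared protein families of 300 residues,
#' 15 planted CSIs (sizes 1-7 plus one 20-residue event, the size span of
#' published signature tables) and 5 planted CSPs.
#'
#' @param n_ingroup,n_outgroup leaf counts of the focal clade and outgroup.
#' @param n_families number of shared protein families.
#' @param family_length family length in residues (default 300).
#' @param substitution_rate expected substitutions per site from root to tip
#'   (the tree is scaled to unit height; default 0.2).
#' @param n_csi number of planted CSIs (each in its own family).
#' @param csi_sizes indel sizes in residues; default `1:7` recycled with one
#'   final 20-residue event.
#' @param n_csp number of planted focal-clade-restricted genes.
#' @param n_noise_proteins unrelated random proteins per genome (default 3).
#' @param seed integer RNG seed (mandatory for reproducible runs).
#' @return validated configuration list, classed `sim_config`.
#' @export
sim_config <- function(n_ingroup = 12L, n_outgroup = 8L, n_families = 100L,
                       family_length = 300L, substitution_rate = 0.2,
                       n_csi = 15L, csi_sizes = NULL, n_csp = 5L,
                       n_noise_proteins = 3L, seed = 7L) {
  if (is.null(csi_sizes))
    csi_sizes <- if (n_csi >= 1L) c(rep_len(1:7, n_csi - 1L), 20L)
    else integer(0L)
  stopifnot(n_ingroup >= 3L, n_outgroup >= 3L, n_families >= 1L,
            family_length >= 50L, substitution_rate >= 0,
            n_csi >= 0L, length(csi_sizes) == n_csi, all(csi_sizes >= 1L),
            n_csp >= 0L, n_noise_proteins >= 0L)
  if (n_csi > n_families)
    stop("infeasible config: more CSI events than families")
  structure(list(n_ingroup = as.integer(n_ingroup),
                 n_outgroup = as.integer(n_outgroup),
                 n_families = as.integer(n_families),
                 family_length = as.integer(family_length),
                 substitution_rate = substitution_rate,
                 n_csi = as.integer(n_csi),
                 csi_sizes = as.integer(csi_sizes),
                 n_csp = as.integer(n_csp),
                 n_noise_proteins = as.integer(n_noise_proteins),
                 seed = as.integer(seed)),
            class = "sim_config")
}

AA20 <- setdiff(AA_LETTERS, "X")

#' Simulate a random bifurcating tree
#'
#' Yule (pure-birth) topology -- at each step a uniformly chosen extant tip
#' speciates -- with i.i.d. exponential branch lengths.
#'
#' @param n_leaves number of leaves (>= 3).
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @param mean_branch mean of the exponential branch lengths (default 0.1).
#' @param labels optional tip labels (default `t1..tn`).
#' @return rooted `ape::phylo`.
#' @export
simulate_tree <- function(n_leaves, seed = NULL, mean_branch = 0.1,
                          labels = NULL) {
  if (n_leaves < 3L) stop("need at least 3 leaves")
  if (!is.null(seed)) set.seed(seed)
  tree <- .yule_topology(n_leaves)
  tree$edge.length <- rexp(nrow(tree$edge), rate = 1 / mean_branch)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n_leaves)
    tree$tip.label <- labels[as.integer(sub("^t", "", tree$tip.label))]
  }
  tree
}

.yule_topology <- function(n) {
  nwk <- "(<1>,<2>);"
  k <- 2L
  while (k < n) {
    i <- sample.int(k, 1L)
    nwk <- sub(paste0("<", i, ">"),
               paste0("(<", i, ">,<", k + 1L, ">)"), nwk, fixed = TRUE)
    k <- k + 1L
  }
  for (i in seq_len(n))
    nwk <- sub(paste0("<", i, ">"), paste0("t", i), nwk, fixed = TRUE)
  ape::read.tree(text = nwk)
}

#' Evolve a protein family along a tree
#'
#' The root sequence is uniform over the 20 amino acids; each branch receives
#' a Poisson number of substitution events with mean
#' `rate * branch_length * length`, each event replacing a uniformly chosen
#' unlocked site with one of the 19 other residues (a Jukes-Cantor-style
#' uniform replacement process). No indels occur unless planted afterwards.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param length sequence length in residues (>= 50).
#' @param rate expected substitutions per site per unit branch length.
#' @param seed optional integer RNG seed.
#' @param lock optional logical vector (length `length`); `TRUE` sites never
#'   substitute (used to guarantee conserved indel flanks).
#' @param root_seq optional root residue string.
#' @return named character vector, leaf label -> residue string, with the root
#'   sequence in attribute `root`.
#' @export
evolve_family <- function(tree, length, rate, seed = NULL, lock = NULL,
                          root_seq = NULL) {
  stopifnot(length >= 50L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lock)) lock <- rep(FALSE, length)
  stopifnot(length(lock) == length)
  free <- which(!lock)
  root <- if (is.null(root_seq)) sample(AA20, length, replace = TRUE)
  else strsplit(root_seq, "", fixed = TRUE)[[1L]]
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- root
  # preorder: parents before children
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (r in seq_len(nrow(ord))) {
    parent <- ord[r, 1L]; child <- ord[r, 2L]
    bl <- tree$edge.length[which(tree$edge[, 1L] == parent &
                                   tree$edge[, 2L] == child)]
    s <- seqs[[parent]]
    nev <- rpois(1L, rate * bl * length)
    if (nev > 0L && length(free) > 0L) {
      pos <- sample(free, nev, replace = TRUE)
      for (p in pos) s[p] <- sample(setdiff(AA20, s[p]), 1L)
    }
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                character(1L))
  names(out) <- tree$tip.label
  attr(out, "root") <- paste(root, collapse = "")
  out
}

#' Plant a clade-specific indel into a family
#'
#' An insertion places one fixed random segment of `size` residues at
#' `position` (the segment occupies positions `position..position+size-1`
#' afterwards) in every leaf below `branch`; a deletion removes
#' `position..position+size-1` there. With `lock_flanks` (default) the 20
#' residues on each side of the event -- and, for deletions, the deleted
#' segment itself in the retained copies -- are homogenised to the
#' across-leaf consensus, emulating the conserved context in which published
#' signature indels sit.
#'
#' @param sequences named character vector (leaf -> residues), equal lengths.
#' @param tree rooted `ape::phylo` over the sequence names.
#' @param branch internal node id or tip label; carriers are the leaves below.
#' @param type `"insertion"` or `"deletion"`.
#' @param size indel size in residues (>= 1).
#' @param position 1-based site; `position + size - 1` must stay inside the
#'   sequence, with at least 20 residues on either side.
#' @param lock_flanks homogenise the flanking context (default `TRUE`).
#' @return list with `sequences` (modified vector) and `event` (a one-row
#'   `data.frame`: branch, type, size, position, clade as comma-joined leaf
#'   labels).
#' @export
plant_csi <- function(sequences, tree, branch, type = c("insertion", "deletion"),
                      size, position, lock_flanks = TRUE) {
  type <- match.arg(type)
  if (size < 1L) stop("indel size must be >= 1")
  len <- nchar(sequences[1L])
  stopifnot(all(nchar(sequences) == len))
  flank <- 20L
  if (position - flank < 1L || position + size - 1L + flank > len)
    stop("event at position ", position, " (size ", size,
         ") leaves no room for ", flank, "-residue flanks in length ", len)
  carriers <- .clade_tips(tree, branch)
  if (!all(carriers %in% names(sequences)))
    stop("carrier leaves missing from sequences")
  chars <- strsplit(sequences, "", fixed = TRUE)
  if (lock_flanks) {
    span <- c(seq.int(position - flank, position - 1L),
              if (type == "deletion") seq.int(position, position + size - 1L),
              seq.int(position + (if (type == "deletion") size else 0L),
                      min(len, position + (if (type == "deletion") size else 0L)
                          + flank - 1L)))
    span <- unique(span[span >= 1L & span <= len])
    for (j in span) {
      col <- vapply(chars, `[`, character(1L), j)
      modal <- names(which.max(table(col)))
      for (k in seq_along(chars)) chars[[k]][j] <- modal
    }
  }
  if (type == "insertion") {
    segment <- paste(sample(AA20, size, replace = TRUE), collapse = "")
    for (nm in carriers) {
      s <- chars[[nm]]
      chars[[nm]] <- c(s[seq_len(position - 1L)],
                       strsplit(segment, "", fixed = TRUE)[[1L]],
                       s[position:len])
    }
  } else {
    for (nm in carriers) {
      s <- chars[[nm]]
      chars[[nm]] <- s[-(position:(position + size - 1L))]
    }
  }
  out <- vapply(chars, paste, character(1L), collapse = "")
  names(out) <- names(sequences)
  list(sequences = out,
       event = data.frame(branch = as.character(branch), type = type,
                          size = as.integer(size),
                          position = as.integer(position),
                          clade = paste(sort(carriers), collapse = ","),
                          stringsAsFactors = FALSE))
}

# tips below a node (or the tip itself when `branch` is a tip label)
.clade_tips <- function(tree, branch) {
  if (is.character(branch) && branch %in% tree$tip.label) return(branch)
  node <- as.integer(branch)
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1L]]]
}

#' Generate a full synthetic dataset with planted signatures
#'
#' Builds a rooted tree whose focal clade (`ing_*` leaves) and outgroup
#' (`out_*` leaves) are sister subtrees, scales it to unit height, evolves
#' `n_families` protein families over it, plants every CSI on the focal-clade
#' stem (one family per event, flanks locked so each event is detectable at
#' default scan parameters), adds focal-clade-restricted CSP genes and
#' per-genome random noise proteins, and records everything in a manifest.
#' Byte-deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `proteomes` (a [proteome_set()]), `groups`
#'   (a [group_assignment()], focal group `"ingroup"`) and `manifest` (list:
#'   `true_tree`, `families`, `csi_events`, `csp_events`).
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ing_labels <- sprintf("ing_%02d", seq_len(config$n_ingroup))
  out_labels <- sprintf("out_%02d", seq_len(config$n_outgroup))
  ting <- simulate_tree(config$n_ingroup, labels = ing_labels)
  tout <- simulate_tree(config$n_outgroup, labels = out_labels)
  stem <- rexp(2L, rate = 10)
  nwk_in <- sub(";$", "", ape::write.tree(ting))
  nwk_out <- sub(";$", "", ape::write.tree(tout))
  tree <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", nwk_in, stem[1L],
                                        nwk_out, stem[2L]))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth  # unit height
  genomes <- c(ing_labels, out_labels)
  ntip <- length(tree$tip.label)
  stem_node <- ape::getMRCA(tree, ing_labels)

  # assign CSI events to distinct families, mixed insertion/deletion
  fam_ids <- sprintf("SF%03d", seq_len(config$n_families))
  csi_fams <- if (config$n_csi > 0L)
    sample(fam_ids, config$n_csi) else character(0L)
  csi_events <- NULL
  flen <- config$family_length
  members <- setNames(vector("list", length(fam_ids)), fam_ids)
  proteins <- setNames(lapply(genomes, function(g) list()), genomes)
  for (f in seq_along(fam_ids)) {
    fid <- fam_ids[f]
    ev_idx <- match(fid, csi_fams)
    lock <- rep(FALSE, flen)
    ev <- NULL
    if (!is.na(ev_idx)) {
      size <- config$csi_sizes[ev_idx]
      type <- if (ev_idx %% 2L == 1L) "insertion" else "deletion"
      position <- sample(seq.int(21L, flen - size + 1L - 20L), 1L)
      span <- seq.int(position - 20L, position + size - 1L + 20L)
      lock[span] <- TRUE
      ev <- list(type = type, size = size, position = position)
    }
    seqs <- evolve_family(tree, flen, config$substitution_rate, lock = lock)
    if (!is.null(ev)) {
      planted <- plant_csi(seqs, tree, stem_node, ev$type, ev$size,
                           ev$position, lock_flanks = TRUE)
      seqs <- planted$sequences
      csi_events <- rbind(csi_events,
                          cbind(family_id = fid, planted$event,
                                stringsAsFactors = FALSE))
    }
    ids <- paste0(genomes, ".", fid)
    members[[fid]] <- setNames(ids, genomes)
    for (g in genomes)
      proteins[[g]][[length(proteins[[g]]) + 1L]] <-
        c(id = paste0(g, ".", fid), residues = unname(seqs[g]))
  }

  # focal-clade-restricted genes (CSPs), evolved on the ingroup subtree only
  csp_events <- NULL
  if (config$n_csp > 0L) {
    for (k in seq_len(config$n_csp)) {
      glen <- sample(100:400, 1L)
      gseqs <- evolve_family(ting, glen, config$substitution_rate)
      gid <- sprintf("CSP%02d", k)
      for (g in ing_labels)
        proteins[[g]][[length(proteins[[g]]) + 1L]] <-
          c(id = paste0(g, ".", gid), residues = unname(gseqs[g]))
      csp_events <- rbind(csp_events,
                          data.frame(gene = gid, clade = "ingroup",
                                     stringsAsFactors = FALSE))
    }
  }

  # unrelated noise proteins
  if (config$n_noise_proteins > 0L) {
    for (g in genomes) for (k in seq_len(config$n_noise_proteins)) {
      nlen <- sample(80:400, 1L)
      proteins[[g]][[length(proteins[[g]]) + 1L]] <-
        c(id = sprintf("%s.N%02d", g, k),
          residues = paste(sample(AA20, nlen, replace = TRUE), collapse = ""))
    }
  }

  pset <- proteome_set(lapply(genomes, function(g) {
    recs <- do.call(rbind, proteins[[g]])
    seq_records(recs[, "id"], g, recs[, "residues"])
  }) |> setNames(genomes))
  groups <- group_assignment(list(ingroup = ing_labels, outgroup = out_labels),
                             focal = "ingroup")
  if (is.null(csi_events))
    csi_events <- data.frame(family_id = character(), branch = character(),
                             type = character(), size = integer(),
                             position = integer(), clade = character(),
                             stringsAsFactors = FALSE)
  if (is.null(csp_events))
    csp_events <- data.frame(gene = character(), clade = character(),
                             stringsAsFactors = FALSE)
  list(proteomes = pset, groups = groups,
       manifest = list(true_tree = tree, families = members,
                       csi_events = csi_events, csp_events = csp_events,
                       config = config))
}
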