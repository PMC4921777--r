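# Amino-acid alphabet and substitution-matrix plumbing shared by the
# alignment engine. The residue alphabet is the 20 standard amino acids plus
# X (unknown); '-' marks gaps in aligned records and never enters the engine.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

.pkg_cache <- new.env(parent = emptyenv())

# BLOSUM62 restricted to our alphabet, as an integer matrix whose row/column
# order matches AA_LETTERS (so 0-based codes index it directly in C++).
.blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    m <- env$BLOSUM62[AA_LETTERS, AA_LETTERS]
    storage.mode(m) <- "integer"
    .pkg_cache$blosum62 <- m
  }
  .pkg_cache$blosum62
}

# byte -> 0-based code lookup (NA for anything outside the alphabet)
.aa_lookup <- function() {
  if (is.null(.pkg_cache$lookup)) {
    lk <- rep(NA_integer_, 256)
    lk[utf8ToInt(paste(AA_LETTERS, collapse = "")) + 1L] <- seq_along(AA_LETTERS) - 1L
    .pkg_cache$lookup <- lk
  }
  .pkg_cache$lookup
}

# Encode an unaligned residue string to 0-based integer codes.
.aa_encode <- function(x) {
  codes <- .aa_lookup()[utf8ToInt(x) + 1L]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop("illegal residue '", substr(x, bad, bad), "' at position ", bad,
         call. = FALSE)
  }
  codes
}

.aa_decode <- function(codes) {
  paste(AA_LETTERS[codes + 1L], collapse = "")
}

# Default affine gap costs (BLOSUM62 with gap open 11, extend 1; a gap of
# length k costs 11 + k).
GAP_OPEN <- 11
GAP_EXT <- 1
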