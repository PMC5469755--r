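# Kimura two-parameter and patristic distances, neighbor joining, rooting.

#' Transition/transversion counts for one sequence pair
#'
#' Counts are taken over columns where BOTH residues are unambiguous bases
#' (pairwise deletion): any gap, 'N' or ambiguity code excludes the column
#' for this pair only. Transitions are A<->G and C<->T; every other
#' mismatch is a transversion. Ambiguity codes are never partially matched.
#'
#' @param seq_a,seq_b Character vectors of residues, or strings; equal
#'   length.
#' @return List of class `stygo_pair_counts` with elements `P` (transition
#'   proportion), `Q` (transversion proportion) and `n_sites` (compared
#'   columns).
#' @export
pair_counts <- function(seq_a, seq_b) {
  if (length(seq_a) == 1L) seq_a <- strsplit(toupper(seq_a), "")[[1L]]
  if (length(seq_b) == 1L) seq_b <- strsplit(toupper(seq_b), "")[[1L]]
  if (length(seq_a) != length(seq_b)) {
    stop("sequences differ in length (", length(seq_a), " vs ",
         length(seq_b), ")")
  }
  bases <- c("A", "C", "G", "T")
  keep <- seq_a %in% bases & seq_b %in% bases
  n <- sum(keep)
  if (n == 0L) stop("no overlap: zero comparable sites for this pair")
  a <- seq_a[keep]
  b <- seq_b[keep]
  diff <- a != b
  ts <- diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                (a == "C" & b == "T") | (a == "T" & b == "C"))
  structure(list(P = sum(ts) / n, Q = sum(diff & !ts) / n, n_sites = n),
            class = "stygo_pair_counts")
}

#' Kimura two-parameter distance from pair counts
#'
#' d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q), in substitutions per site.
#' When the logarithm arguments are non-positive the pair is saturated and
#' the distance is returned as `Inf` (clustering treats it as above any
#' threshold).
#'
#' @param counts A [pair_counts()] result, or a transition proportion if
#'   `Q` is also given.
#' @param Q Transversion proportion (when `counts` is the numeric `P`).
#' @return Distance in substitutions/site; `Inf` when saturated.
#' @export
k2p_distance <- function(counts, Q = NULL) {
  if (inherits(counts, "stygo_pair_counts")) {
    P <- counts$P; Q <- counts$Q
  } else {
    P <- counts
    if (is.null(Q)) stop("supply pair_counts() output or both P and Q")
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(Inf)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' @param alignment A `stygo_alignment` with at least 2 sequences.
#' @return Symmetric numeric matrix (labels as dimnames) with attribute
#'   `kind = "K2P"`; saturated pairs are `Inf`.
#' @export
k2p_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "stygo_alignment"))
  n <- length(alignment$ids)
  if (n < 2L) stop("need at least 2 sequences")
  m <- matrix(0, n, n, dimnames = list(alignment$ids, alignment$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- tryCatch(
        k2p_distance(pair_counts(alignment$mat[i, ], alignment$mat[j, ])),
        error = function(e) {
          stop("pair (", alignment$ids[i], ", ", alignment$ids[j], "): ",
               conditionMessage(e))
        })
      m[i, j] <- m[j, i] <- d
    }
  }
  attr(m, "kind") <- "K2P"
  m
}

#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths on the unique path between
#' tips i and j.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Symmetric matrix with attribute `kind = "patristic"`.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths; supply a tree with lengths")
  }
  m <- ape::cophenetic.phylo(tree)
  m <- m[tree$tip.label, tree$tip.label]
  attr(m, "kind") <- "patristic"
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Q-criterion NJ (via \pkg{ape}). Negative estimated branch
#' lengths are clamped to 0 and the total deficit reported in a message.
#' Saturated (`Inf`) entries are an error: supply an externally built tree
#' instead.
#'
#' @param matrix Symmetric distance matrix with labels, >= 3 taxa.
#' @return Unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(matrix) {
  if (nrow(matrix) < 3L) stop("need at least 3 taxa")
  if (any(!is.finite(matrix))) {
    stop("distance matrix contains saturated (infinite) entries; ",
         "supply an external Newick tree instead of neighbor joining")
  }
  tr <- ape::nj(stats::as.dist(matrix))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message("neighbor_joining: clamped ", sum(neg),
            " negative branch length(s); total deficit ",
            format(-sum(tr$edge.length[neg]), digits = 4))
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Midpoint-root a tree
#'
#' Roots the tree at the midpoint of the longest tip-to-tip path; patristic
#' distances are unchanged. A tree whose branch lengths are all zero is
#' rooted at an arbitrary internal node with a warning.
#'
#' @param tree Unrooted (or rooted) [ape::phylo] tree with branch lengths.
#' @return Rooted tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (all(tree$edge.length == 0)) {
    warning("all branch lengths zero; rooting at an arbitrary node")
    return(ape::root(tree, outgroup = tree$tip.label[1L],
                     resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

#' Write a distance matrix as square CSV
#'
#' @param matrix Labelled square matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distmat <- function(matrix, path) {
  df <- data.frame(label = rownames(matrix), matrix,
                   check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a distance matrix (square CSV or PHYLIP square format)
#'
#' @param path Input path. CSV must have a `label` header column; PHYLIP
#'   square input starts with the taxon count on its own line.
#' @return Labelled symmetric matrix.
#' @export
read_distmat <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^\\s*[0-9]+\\s*$", first)) {           # PHYLIP square
    n <- as.integer(trimws(first))
    tab <- read.table(path, skip = 1L, header = FALSE,
                      stringsAsFactors = FALSE)
    if (nrow(tab) != n) stop("PHYLIP matrix: expected ", n, " rows")
    m <- as.matrix(tab[, -1L, drop = FALSE])
    dimnames(m) <- list(tab[[1L]], tab[[1L]])
  } else {
    tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    dimnames(m) <- list(tab[[1L]], tab[[1L]])
  }
  storage.mode(m) <- "double"
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8) stop("matrix not symmetric")
  m
}
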