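# Independent oracles and small builders shared across the suite.

toy_alignment <- function(seqs, locus = "COI") new_alignment(seqs, locus)

# patristic oracle: explicit path enumeration through the parent map
patristic_oracle <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- numeric(ntip + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(i) {
    nodes <- integer(0)
    while (parent[i] != 0) { nodes <- c(nodes, i); i <- parent[i] }
    nodes
  }
  m <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1)) {
    pi <- path_to_root(i)
    for (j in (i + 1):ntip) {
      pj <- path_to_root(j)
      shared <- intersect(pi, pj)
      d <- sum(elen[setdiff(c(pi, pj), shared)])
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}

# brute-force enumeration of all rooted-subtree partitions of a tree
tips_under <- function(tree, node, ntip) {
  if (node <= ntip) return(tree$tip.label[node])
  unlist(lapply(tree$edge[tree$edge[, 1] == node, 2],
                tips_under, tree = tree, ntip = ntip))
}
enumerate_subtree_partitions <- function(tree, node = NULL) {
  ntip <- length(tree$tip.label)
  if (is.null(node)) node <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  if (!length(kids)) return(list(list(tree$tip.label[node])))
  own <- list(list(sort(tips_under(tree, node, ntip))))
  sub <- lapply(kids, function(k) enumerate_subtree_partitions(tree, k))
  combos <- list(list())
  for (s in sub) {
    combos <- unlist(lapply(combos, function(cm)
      lapply(s, function(x) c(cm, x))), recursive = FALSE)
  }
  c(own, combos)
}

# brute-force pure-character-attribute scan: all positions x states x blocks
pure_ca_oracle <- function(alignment, partition, focal = NULL) {
  if (is.null(focal)) focal <- names(partition$blocks)
  states <- c("A", "C", "G", "T", "-")
  resolve <- stygodelim:::IUPAC_RESOLVE
  out <- list()
  for (sp in focal) {
    rb <- which(alignment$ids %in% partition$blocks[[sp]])
    others <- setdiff(focal, sp)
    ro <- which(alignment$ids %in% unlist(partition$blocks[others]))
    if (!length(rb)) next
    for (p in seq_len(alignment$length)) {
      for (s in states) {
        fixed <- all(alignment$mat[rb, p] == s)
        if (!fixed) next
        excl <- !length(ro) ||
          !any(vapply(alignment$mat[ro, p],
                      function(ch) s %in% resolve[[ch]], logical(1)))
        if (excl) {
          out[[length(out) + 1L]] <- data.frame(
            species = sp, locus = alignment$locus, position = p,
            state = s, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(species = character(), locus = character(),
                      position = integer(), state = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# random alignment with ambiguities and gaps for diagnostics fuzzing
random_blocked_alignment <- function(n_blocks = 3, per_block = 3,
                                     ncol = 120, locus = "COI") {
  chars <- c("A", "C", "G", "T")
  ids <- character(0); seqs <- character(0); labels <- character(0)
  block_base <- replicate(n_blocks,
                          paste(sample(chars, ncol, TRUE), collapse = ""))
  for (b in seq_len(n_blocks)) {
    for (k in seq_len(per_block)) {
      s <- strsplit(block_base[b], "")[[1]]
      nmut <- rpois(1, 3)
      if (nmut) {
        at <- sample(ncol, min(nmut, ncol))
        s[at] <- sample(c(chars, "N", "R", "Y", "-"), length(at), TRUE)
      }
      ids <- c(ids, sprintf("b%d_s%d", b, k))
      seqs <- c(seqs, paste(s, collapse = ""))
      labels <- c(labels, sprintf("block%d", b))
    }
  }
  list(alignment = new_alignment(setNames(seqs, ids), locus),
       partition = partition_from_labels(setNames(labels, ids)))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
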