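# Fair-proportion evolutionary distinctness and between-group comparison.

#' Fair-proportion evolutionary distinctness per tip
#'
#' ED(tip) = sum over the branches e on the root-to-tip path of
#' length(e) / n(e), where n(e) is the number of tips descending from e:
#' each branch's length is split equally among the tips it supports, so a
#' species on a long branch with few congeners scores high. The values
#' sum exactly to the total branch length of the tree. Units follow the
#' tree: substitutions per site on a molecular tree, Myr on a chronogram.
#'
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @return Data frame (tip, ED), in tip-label order.
#' @export
fair_proportion_ed <- function(tree) {
  if (!ape::is.rooted(tree)) {
    stop("unrooted input: apply midpoint_root() first")
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  ndesc <- integer(ntip + tree$Nnode)
  ndesc[seq_len(ntip)] <- 1L
  for (k in seq_len(nrow(ord))) {
    ndesc[ord[k, 1L]] <- ndesc[ord[k, 1L]] + ndesc[ord[k, 2L]]
  }
  # accumulate len/n down the tree, walking edges parents-first
  acc <- numeric(ntip + tree$Nnode)
  idx <- rev(seq_len(nrow(ord)))
  tree_key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  ord_key <- paste(ord[, 1L], ord[, 2L])
  idx <- match(ord_key[idx], tree_key)
  for (k in idx) {
    p <- tree$edge[k, 1L]; v <- tree$edge[k, 2L]
    acc[v] <- acc[p] + tree$edge.length[k] / ndesc[v]
  }
  data.frame(tip = tree$tip.label, ED = acc[seq_len(ntip)],
             stringsAsFactors = FALSE)
}

#' Summarise an ED table
#'
#' @param ed Data frame (tip, ED) from [fair_proportion_ed()], or a
#'   numeric vector of ED values.
#' @param groups Optional named vector or factor mapping tips to groups.
#' @return List with `min`, `max`, `ratio` (exact max/min),
#'   `ratio_rounded` (1 decimal), and `groups` (named list of values) when
#'   grouping is supplied. A zero minimum flags the ratio as undefined.
#' @export
ed_summary <- function(ed, groups = NULL) {
  vals <- if (is.data.frame(ed)) setNames(ed$ED, ed$tip) else ed
  if (!length(vals)) stop("empty ED table")
  out <- list(min = min(vals), max = max(vals))
  if (out$min == 0) {
    warning("minimum ED is 0; max/min ratio undefined")
    out$ratio <- NA_real_
    out$ratio_rounded <- NA_real_
  } else {
    out$ratio <- out$max / out$min
    out$ratio_rounded <- round(out$ratio, 1L)
  }
  if (!is.null(groups)) {
    out$groups <- split(unname(vals), groups[names(vals)])
  }
  out
}

#' Mann-Whitney rank-sum test (exact for small samples)
#'
#' Two-sided test of a location difference between two groups of ED
#' values. When both groups have at most 8 observations the null
#' distribution of U is enumerated exactly over all arrangements (ties
#' handled by enumeration); otherwise the normal approximation with tie
#' and continuity corrections is used.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return List with `U` (statistic for group `a`), `p` (two-sided),
#'   `exact` (logical).
#' @export
rank_sum_test <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  n1 <- length(a); n2 <- length(b)
  u_stat <- function(x, y) {
    sum(vapply(x, function(v) sum(v > y) + 0.5 * sum(v == y), numeric(1)))
  }
  U <- u_stat(a, b)
  if (length(unique(c(a, b))) == 1L) {
    warning("all values identical across groups; p = 1")
    return(list(U = U, p = 1, exact = TRUE))
  }
  if (n1 <= 8L && n2 <= 8L) {
    pool <- c(a, b)
    idx <- combn(n1 + n2, n1)
    us <- apply(idx, 2L, function(i) u_stat(pool[i], pool[-i]))
    p <- min(1, 2 * min(mean(us <= U), mean(us >= U)))
    return(list(U = U, p = p, exact = TRUE))
  }
  N <- n1 + n2
  r <- rank(c(a, b))
  ties <- table(r)
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), exact = FALSE)
}
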