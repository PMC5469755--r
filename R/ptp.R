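# Maximum-likelihood Poisson tree processes (PTP) species delimitation.
#
# Branch lengths (expected substitutions) are modelled as draws from two
# exponential classes: "between" (speciation) branches connect the root to
# each species' stem, "within" (coalescent) branches lie inside species
# subtrees. Each class has its own rate; the MLE rate for a class with n
# branches of total length S is n/S, contributing n*log(n/S) - n to the
# log-likelihood.

PTP_LENGTH_FLOOR <- 1e-9   # substituted for zero-length branches

class_loglik <- function(lengths) {
  n <- length(lengths)
  if (!n) return(0)
  S <- sum(lengths)
  n * log(n / S) - n
}

# children list, entering-edge length per node, floored
ptp_precompute <- function(tree, floor = PTP_LENGTH_FLOOR) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  children <- vector("list", nnode)
  len <- rep(NA_real_, nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    children[[p]] <- c(children[[p]], v)
    len[v] <- max(tree$edge.length[e], floor)
  }
  root <- ntip + 1L
  # postorder node sequence (children before parents), root last
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  po <- c(ord[, 2L], root)
  sub_n <- integer(nnode); sub_S <- numeric(nnode)
  min_tip <- character(nnode)
  tipsets <- vector("list", nnode)
  for (v in po) {
    ch <- children[[v]]
    if (is.null(ch)) {
      tipsets[[v]] <- v
      min_tip[v] <- tree$tip.label[v]
    } else {
      sub_n[v] <- sum(1L + sub_n[ch])
      sub_S[v] <- sum(len[ch] + sub_S[ch])
      tipsets[[v]] <- unlist(tipsets[ch], use.names = FALSE)
      min_tip[v] <- min(min_tip[ch])
    }
  }
  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  list(ntip = ntip, root = root, children = children, parent = parent,
       len = len,
       sub_n = sub_n, sub_S = sub_S, tipsets = tipsets, min_tip = min_tip,
       n_edges = nrow(tree$edge), total_S = sum(len[-root], na.rm = TRUE))
}

nodeset_loglik <- function(pc, nodes) {
  n_w <- sum(pc$sub_n[nodes])
  S_w <- sum(pc$sub_S[nodes])
  ll_w <- if (n_w) n_w * log(n_w / S_w) - n_w else 0
  n_b <- pc$n_edges - n_w
  S_b <- pc$total_S - S_w
  ll_b <- if (n_b) n_b * log(n_b / S_b) - n_b else 0
  ll_w + ll_b
}

nodeset_to_partition <- function(pc, nodes, tree, support = NULL) {
  blocks <- lapply(nodes, function(v) tree$tip.label[pc$tipsets[[v]]])
  new_partition(blocks, method = "PTP", support = support)
}

#' Branch class assignment under a species partition
#'
#' A branch is "within" iff the tips below it all belong to one block and
#' its parent node also subtends only that block; otherwise it is
#' "between". For clade-compatible partitions this makes the "between"
#' branches the connected subtree spanning the root and each block's stem.
#'
#' @param tree Rooted [ape::phylo] tree.
#' @param partition A `stygo_partition` over the tip labels.
#' @param assume_rooted Accept a basal multifurcation as rooted.
#' @return Character vector ("within"/"between"), one entry per edge row.
#' @export
ptp_branch_classes <- function(tree, partition, assume_rooted = FALSE) {
  if (!assume_rooted && !ape::is.rooted(tree)) {
    stop("unrooted input: root the tree first (see midpoint_root)")
  }
  lab <- partition_labels(partition)
  missing <- setdiff(tree$tip.label, names(lab))
  if (length(missing)) stop("tip '", missing[1L], "' not in partition")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  block <- character(nnode)        # "" = mixed
  block[seq_len(ntip)] <- lab[tree$tip.label]
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  kids <- split(ord[, 2L], ord[, 1L])
  for (p in unique(ord[, 1L])) {
    b <- unique(block[kids[[as.character(p)]]])
    block[p] <- if (length(b) == 1L && all(b != "")) b else ""
  }
  ifelse(block[tree$edge[, 2L]] != "" & block[tree$edge[, 1L]] != "",
         "within", "between")
}

#' PTP log-likelihood of a partition on a tree
#'
#' @param tree Rooted tree with branch lengths.
#' @param partition A `stygo_partition` over the tips.
#' @param floor Branch-length floor substituted for zero-length branches.
#' @return Log-likelihood (each class at its MLE rate).
#' @export
ptp_loglik <- function(tree, partition, floor = PTP_LENGTH_FLOOR) {
  cls <- ptp_branch_classes(tree, partition)
  lens <- pmax(tree$edge.length, floor)
  class_loglik(lens[cls == "within"]) + class_loglik(lens[cls == "between"])
}

enum_antichains <- function(pc, v, cap) {
  # all antichains of nodes covering the subtree of v
  ch <- pc$children[[v]]
  if (is.null(ch)) return(list(v))
  parts <- lapply(ch, enum_antichains, pc = pc, cap = cap)
  combos <- list(integer(0))
  for (p in parts) {
    combos <- unlist(lapply(combos, function(cm) {
      lapply(p, function(x) c(cm, x))
    }), recursive = FALSE)
    if (length(combos) > cap) stop("partition count exceeds cap")
  }
  c(list(v), combos)
}

count_antichains <- function(pc, v) {
  ch <- pc$children[[v]]
  if (is.null(ch)) return(1)
  1 + prod(vapply(ch, count_antichains, numeric(1), pc = pc))
}

#' Fit the ML-PTP species delimitation model
#'
#' Starting from a single species spanning all tips (every branch
#' "within"), the search moves the speciation frontier down the tree:
#' splitting a species node converts the branches entering its children
#' into "between" branches. `method = "exhaustive"` scores every
#' rooted-subtree partition and is used automatically when the tree admits
#' at most `max_partitions` of them; the heuristic search walks the best
#' split at each step all the way down to the all-singleton state (so
#' likelihood plateaus cannot trap it), then refines the best states
#' visited by split/merge hill climbing (ties broken by the smallest tip
#' label of the moved subtree). Optional seeded random restarts explore
#' alternative split orders and yield nonparametric per-block support
#' (fraction of restarts recovering the block).
#'
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @param method "auto" (default), "greedy" or "exhaustive".
#' @param n_restarts Number of random-restart searches (greedy only).
#' @param seed Integer seed for the restarts.
#' @param max_partitions Cap under which "auto" uses the exhaustive search.
#' @param floor Branch-length floor.
#' @param assume_rooted Treat a basal multifurcation as a rooted tree
#'   (used when zero-length branches near the root of a rooted tree have
#'   been collapsed); by default basal polytomies are rejected as
#'   unrooted.
#' @return Object of class `stygo_ptp`: list with `partition`,
#'   `lambda_within`, `lambda_between`, `log_likelihood`,
#'   `branch_classes`, `n_species`, `method`.
#' @export
ptp_fit <- function(tree, method = c("auto", "greedy", "exhaustive"),
                    n_restarts = 0L, seed = NULL,
                    max_partitions = 20000, floor = PTP_LENGTH_FLOOR,
                    assume_rooted = FALSE) {
  method <- match.arg(method)
  if (!assume_rooted && !ape::is.rooted(tree)) {
    stop("unrooted input: apply midpoint_root() first")
  }
  if (length(tree$tip.label) < 2L) stop("need at least 2 tips")
  pc <- ptp_precompute(tree, floor)
  if (method == "auto") {
    method <- if (count_antichains(pc, pc$root) <= max_partitions)
      "exhaustive" else "greedy"
  }

  # Monotone frontier descent: repeatedly apply the best split (the whole
  # path down to singletons is walked, so likelihood plateaus between the
  # one-species state and the optimum cannot trap the search), keeping the
  # best state visited. Ties and the randomized restarts choose among
  # improving splits; determinism via the smallest tip label.
  greedy_run <- function(randomized = FALSE, n_refine = 8L, beam = 4L) {
    if (randomized) beam <- 1L
    state_key <- function(nodes) paste(sort(nodes), collapse = ",")
    frontier <- list(list(nodes = pc$root,
                          ll = nodeset_loglik(pc, pc$root)))
    path_nodes <- list(pc$root)
    path_ll <- frontier[[1L]]$ll
    repeat {
      nxt <- list()
      seen <- character(0)
      for (st in frontier) {
        nodes <- st$nodes
        cand <- which(vapply(nodes, function(v)
          !is.null(pc$children[[v]]), logical(1)))
        if (!length(cand)) next
        gains <- vapply(cand, function(i) {
          v <- nodes[i]
          nodeset_loglik(pc, c(nodes[-i], pc$children[[v]])) - st$ll
        }, numeric(1))
        keep <- if (randomized) {
          imp <- which(gains > 1e-10)
          if (length(imp)) sample(imp, 1L) else {
            top <- which(gains >= max(gains) - 1e-12)
            top[order(pc$min_tip[nodes[cand[top]]])][1L]
          }
        } else {
          utils::head(order(gains, pc$min_tip[nodes[cand]],
                            decreasing = c(TRUE, FALSE),
                            method = "radix"), beam)
        }
        for (i in keep) {
          v <- nodes[cand[i]]
          nd <- c(nodes[-cand[i]], pc$children[[v]])
          k <- state_key(nd)
          if (k %in% seen) next
          seen <- c(seen, k)
          nxt[[length(nxt) + 1L]] <- list(nodes = nd,
                                          ll = st$ll + gains[i])
        }
      }
      if (!length(nxt)) break
      ord <- order(vapply(nxt, `[[`, numeric(1), "ll"),
                   decreasing = TRUE)
      frontier <- nxt[utils::head(ord, beam)]
      for (st in frontier) {
        path_nodes[[length(path_nodes) + 1L]] <- st$nodes
        path_ll <- c(path_ll, st$ll)
      }
    }
    # refine the best states visited during the descent
    starts <- utils::head(order(path_ll, decreasing = TRUE), n_refine)
    best <- NULL
    for (k in starts) {
      res <- hill_climb(path_nodes[[k]], path_ll[k])
      if (is.null(best) || res$ll > best$ll + 1e-12) best <- res
    }
    best
  }

  # local refinement: best-improvement hill climbing over split moves
  # (species node -> its children) and merge moves (a sibling set of
  # species nodes -> their parent), until no move improves
  hill_climb <- function(nodes, ll) {
    repeat {
      moves <- list()
      gains <- numeric(0)
      keys <- character(0)
      for (i in seq_along(nodes)) {
        v <- nodes[i]
        if (!is.null(pc$children[[v]])) {
          moves[[length(moves) + 1L]] <-
            c(nodes[-i], pc$children[[v]])
          keys <- c(keys, pc$min_tip[v])
        }
      }
      parents <- unique(pc$parent[nodes[nodes != pc$root]])
      for (u in parents) {
        ch <- pc$children[[u]]
        if (all(ch %in% nodes)) {
          moves[[length(moves) + 1L]] <-
            c(setdiff(nodes, ch), u)
          keys <- c(keys, pc$min_tip[u])
        }
      }
      if (!length(moves)) break
      gains <- vapply(moves, function(nd)
        nodeset_loglik(pc, nd) - ll, numeric(1))
      if (max(gains) <= 1e-10) break
      top <- which(gains >= max(gains) - 1e-12)
      pick <- top[order(keys[top])][1L]
      nodes <- moves[[pick]]
      ll <- ll + gains[pick]
    }
    # tie-break: among (near-)equal-likelihood optima prefer the fewest
    # species, i.e. apply merge moves that do not lower the likelihood
    repeat {
      merged <- FALSE
      parents <- unique(pc$parent[nodes[nodes != pc$root]])
      for (u in parents) {
        ch <- pc$children[[u]]
        if (all(ch %in% nodes)) {
          cand <- c(setdiff(nodes, ch), u)
          ll2 <- nodeset_loglik(pc, cand)
          if (ll2 >= ll - 1e-9) {
            nodes <- cand
            ll <- max(ll, ll2)
            merged <- TRUE
            break
          }
        }
      }
      if (!merged) break
    }
    list(nodes = nodes, ll = ll)
  }

  if (method == "exhaustive") {
    sets <- enum_antichains(pc, pc$root, cap = max_partitions * 10)
    lls <- vapply(sets, nodeset_loglik, numeric(1), pc = pc)
    top <- which(lls >= max(lls) - 1e-9)    # ties: fewest species wins
    best <- top[which.min(lengths(sets[top]))]
    nodes <- sets[[best]]
    ll <- lls[best]
    support <- NULL
  } else {
    base <- greedy_run(FALSE)
    runs <- list(base)
    if (n_restarts > 0L) {
      if (!is.null(seed)) set.seed(seed)
      for (r in seq_len(n_restarts)) runs[[r + 1L]] <- greedy_run(TRUE)
    }
    lls <- vapply(runs, `[[`, numeric(1), "ll")
    best <- runs[[which.max(lls)]]
    nodes <- best$nodes
    ll <- best$ll
    support <- NULL
    if (n_restarts > 0L) {
      keyset <- lapply(runs, function(r) {
        vapply(r$nodes, function(v)
          paste(sort(tree$tip.label[pc$tipsets[[v]]]), collapse = "\r"),
          character(1))
      })
      bk <- vapply(nodes, function(v)
        paste(sort(tree$tip.label[pc$tipsets[[v]]]), collapse = "\r"),
        character(1))
      support <- vapply(bk, function(k)
        mean(vapply(keyset, function(s) k %in% s, logical(1))), numeric(1))
      ord <- order(vapply(nodes, function(v) pc$min_tip[v], character(1)))
      support <- unname(support[ord])
    }
  }

  part <- nodeset_to_partition(pc, nodes, tree, support = support)
  cls <- ptp_branch_classes(tree, part, assume_rooted = TRUE)
  lens <- pmax(tree$edge.length, floor)
  n_w <- sum(cls == "within"); S_w <- sum(lens[cls == "within"])
  n_b <- sum(cls == "between"); S_b <- sum(lens[cls == "between"])
  structure(list(
    partition = part,
    lambda_within = if (n_w) n_w / S_w else NA_real_,
    lambda_between = if (n_b) n_b / S_b else NA_real_,
    log_likelihood = ll,
    branch_classes = cls,
    n_species = length(part$blocks),
    method = method), class = "stygo_ptp")
}

#' @export
print.stygo_ptp <- function(x, ...) {
  cat("ML-PTP delimitation (", x$method, " search): ", x$n_species,
      " species, logL = ", format(x$log_likelihood, digits = 6), "\n",
      "  lambda_within = ", format(x$lambda_within, digits = 4),
      ", lambda_between = ", format(x$lambda_between, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Serialise a PTP result to JSON
#'
#' @param result A `stygo_ptp` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ptp_json <- function(result, path) {
  jsonlite::write_json(list(
    method = result$method,
    n_species = result$n_species,
    log_likelihood = result$log_likelihood,
    lambda_within = result$lambda_within,
    lambda_between = result$lambda_between,
    blocks = result$partition$blocks,
    support = result$partition$support),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Haplotype-tree PTP delimitation from sequence data
#'
#' The standard route for single-locus PTP: identical haplotypes are
#' collapsed to one representative, a neighbor-joining tree is built from
#' the K2P matrix of unique haplotypes, midpoint-rooted, internal
#' branches below the data's resolution are collapsed to multifurcations
#' and remaining branches floored at that resolution (the PTP model
#' assumes positive branch lengths, and estimated lengths below one
#' substitution carry no rate-class information), the ML-PTP model is
#' fitted and the resulting blocks are expanded back to all specimens.
#'
#' @param alignment A `stygo_alignment`.
#' @param tol Branch-length resolution: branches below it are collapsed,
#'   those kept are floored at it. Default one substitution,
#'   1/alignment length.
#' @param ... Passed to [ptp_fit()].
#' @return A `stygo_ptp` whose partition covers every specimen; the
#'   haplotype tree used is attached as element `tree`.
#' @export
ptp_delimit <- function(alignment, tol = NULL, ...) {
  stopifnot(inherits(alignment, "stygo_alignment"))
  if (is.null(tol)) tol <- 1 / alignment$length
  hap <- haplotype_classes(alignment)
  reps <- alignment$ids[!duplicated(hap)]
  m <- k2p_matrix(alignment)
  if (length(reps) < 3L) {
    stop("need at least 3 distinct haplotypes for a haplotype tree")
  }
  tree <- ape::di2multi(midpoint_root(neighbor_joining(m[reps, reps])),
                        tol = tol)
  tree$edge.length <- pmax(tree$edge.length, tol)
  fit <- ptp_fit(tree, assume_rooted = TRUE, ...)
  rep_lab <- partition_labels(fit$partition)
  rep_of <- setNames(reps[match(hap, hap[match(reps, alignment$ids)])],
                     alignment$ids)
  full <- partition_from_labels(
    setNames(rep_lab[rep_of[alignment$ids]], alignment$ids),
    method = "PTP")
  full$support <- fit$partition$support
  fit$partition <- full
  fit$n_species <- length(full$blocks)
  fit$tree <- tree
  fit
}
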