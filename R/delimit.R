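# Distance-threshold species delimitation, partition consensus and the
# haplotype-sharing screen across syntopic species pairs.

#' Delimitation configuration
#'
#' Default thresholds follow the empirically calibrated species boundaries
#' for crustaceans: 4\% pairwise K2P divergence and 16\% patristic COI
#' divergence.
#'
#' @param k2p_threshold K2P divergence threshold (proportion; default 0.04).
#' @param patristic_threshold Patristic threshold (default 0.16).
#' @param linkage "single" (default) or "complete".
#' @return List of class `stygo_delim_config`.
#' @export
delimitation_config <- function(k2p_threshold = 0.04,
                                patristic_threshold = 0.16,
                                linkage = c("single", "complete")) {
  stopifnot(k2p_threshold > 0, patristic_threshold > 0)
  structure(list(k2p_threshold = k2p_threshold,
                 patristic_threshold = patristic_threshold,
                 linkage = match.arg(linkage)),
            class = "stygo_delim_config")
}

#' Threshold clustering of a distance matrix into putative species
#'
#' Single linkage: blocks are the connected components of the graph with
#' an edge between i and j iff d(i, j) < threshold; saturated (`Inf`)
#' pairs never receive an edge. Complete linkage: blocks are agglomerated
#' (smallest-index-first among ties) while the maximum intra-block
#' distance stays below the threshold.
#'
#' @param matrix Symmetric labelled distance matrix (`Inf` allowed).
#' @param threshold Divergence threshold (> 0); pairs at or above it are
#'   split.
#' @param linkage "single" (default) or "complete".
#' @param method Method tag recorded on the partition.
#' @return A `stygo_partition`.
#' @export
threshold_clusters <- function(matrix, threshold,
                               linkage = c("single", "complete"),
                               method = NULL) {
  linkage <- match.arg(linkage)
  if (is.null(dim(matrix)) || nrow(matrix) == 0L) stop("empty matrix")
  stopifnot(threshold > 0)
  ids <- rownames(matrix)
  n <- nrow(matrix)
  if (is.null(method)) {
    kind <- attr(matrix, "kind")
    method <- if (is.null(kind)) "threshold" else paste0("threshold-", kind)
  }
  if (linkage == "single") {
    # union-find over edges d < threshold
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- matrix[i, j]
        if (is.finite(d) && d < threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    blocks <- split(ids, comp)
  } else {
    # agglomerative complete linkage, deterministic merge order
    blocks <- as.list(ids)
    bmax <- function(a, b) {          # complete-linkage distance
      max(matrix[a, b, drop = FALSE])
    }
    repeat {
      k <- length(blocks)
      if (k < 2L) break
      best <- NULL; best_d <- Inf
      for (i in seq_len(k - 1L)) {
        for (j in (i + 1L):k) {
          d <- bmax(blocks[[i]], blocks[[j]])
          if (is.finite(d) && d < best_d) { best_d <- d; best <- c(i, j) }
        }
      }
      if (is.null(best) || best_d >= threshold) break
      blocks[[best[1L]]] <- c(blocks[[best[1L]]], blocks[[best[2L]]])
      blocks[[best[2L]]] <- NULL
    }
  }
  new_partition(blocks, method = method)
}

#' Consensus (meet) of several partitions
#'
#' Two specimens are conspecific in the consensus iff they are conspecific
#' in ALL input partitions: the finest common coarsening rule matching the
#' requirement that delimitation methods agree.
#'
#' @param partitions List of `stygo_partition` objects over the same
#'   specimens.
#' @return A `stygo_partition` with method "consensus".
#' @export
consensus_partition <- function(partitions) {
  stopifnot(length(partitions) >= 2L)
  labs <- lapply(partitions, partition_labels)
  ids <- sort(names(labs[[1L]]))
  for (l in labs[-1L]) {
    if (!identical(sort(names(l)), ids)) {
      stop("partitions cover different specimen sets")
    }
  }
  key <- vapply(ids, function(id) {
    paste(vapply(labs, function(l) l[[id]], character(1)), collapse = "|")
  }, character(1))
  partition_from_labels(setNames(key, ids), method = "consensus")
}

#' Haplotype identity classes for one locus
#'
#' Two sequences belong to the same haplotype class when they are
#' identical after excluding, for that pair, every column where either has
#' a non-ACGT character; classes are the connected components of this
#' (pairwise) relation.
#'
#' @param alignment A `stygo_alignment`.
#' @return Named integer vector: specimen id -> haplotype class index.
#' @export
haplotype_classes <- function(alignment) {
  mat <- alignment$mat
  n <- nrow(mat)
  ok <- matrix(mat %in% c("A", "C", "G", "T"), nrow = n)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        keep <- ok[i, ] & ok[j, ]
        if (all(mat[i, keep] == mat[j, keep])) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  setNames(match(comp, sort(unique(comp))), alignment$ids)
}

#' Screen for haplotypes shared between delimited species
#'
#' Reports every haplotype class observed in two or more blocks of the
#' partition. An empty report is the "all haplotypes species-specific"
#' verdict (no sign of gene flow or introgression). With
#' `syntopic_only = TRUE` the screen is restricted to block pairs that
#' co-occur at at least one site (the natural crossing experiments).
#'
#' @param alignments Named list of `stygo_alignment` objects (one per
#'   locus), or a single alignment.
#' @param partition A `stygo_partition` covering every sequenced specimen.
#' @param occurrences Optional occurrence data frame (needed for site ids
#'   and for `syntopic_only`).
#' @param syntopic_only Restrict to syntopic block pairs.
#' @return Data frame (locus, haplotype, species_a, species_b, sites);
#'   zero rows when all haplotypes are species-specific.
#' @export
lineage_sharing_screen <- function(alignments, partition,
                                   occurrences = NULL,
                                   syntopic_only = FALSE) {
  if (inherits(alignments, "stygo_alignment")) {
    alignments <- setNames(list(alignments), alignments$locus)
  }
  lab <- partition_labels(partition)
  syn_pairs <- NULL
  if (syntopic_only) {
    if (is.null(occurrences)) stop("syntopic_only requires occurrences")
    syn <- detect_syntopy(occurrences)
    syn_pairs <- unique(paste(pmin(syn$species_a, syn$species_b),
                              pmax(syn$species_a, syn$species_b),
                              sep = "\r"))
  }
  out <- list()
  for (locus in names(alignments)) {
    aln <- alignments[[locus]]
    missing <- setdiff(aln$ids, names(lab))
    if (length(missing)) {
      stop("specimen '", missing[1L], "' in ", locus,
           " alignment but absent from partition")
    }
    hap <- haplotype_classes(aln)
    for (h in unique(hap)) {
      carriers <- names(hap)[hap == h]
      blocks <- unique(lab[carriers])
      if (length(blocks) < 2L) next
      hap_str <- paste(aln$mat[match(carriers[1L], aln$ids), ],
                       collapse = "")
      pairs <- combn(sort(blocks), 2L)
      for (k in seq_len(ncol(pairs))) {
        a <- pairs[1L, k]; b <- pairs[2L, k]
        if (!is.null(syn_pairs) &&
            !(paste(a, b, sep = "\r") %in% syn_pairs)) next
        sites <- ""
        if (!is.null(occurrences)) {
          sa <- occurrences$site_id[occurrences$specimen_id %in%
                                      carriers[lab[carriers] == a]]
          sb <- occurrences$site_id[occurrences$specimen_id %in%
                                      carriers[lab[carriers] == b]]
          sites <- paste(sort(intersect(sa, sb)), collapse = ";")
        }
        out[[length(out) + 1L]] <- data.frame(
          locus = locus, haplotype = hap_str,
          species_a = a, species_b = b, sites = sites,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(locus = character(), haplotype = character(),
                      species_a = character(), species_b = character(),
                      sites = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
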