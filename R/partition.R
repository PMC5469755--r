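# Species partitions: the delimitation output and the input to
# diagnostics and conservation accounting.

#' Construct a species partition
#'
#' @param blocks List of character vectors of specimen ids; blocks must be
#'   disjoint, non-empty and jointly cover all specimens.
#' @param method Method tag, e.g. "threshold-K2P", "threshold-patristic",
#'   "PTP", "consensus", "user".
#' @param support Optional numeric vector in [0, 1], one value per block.
#' @return Object of class `stygo_partition`.
#' @export
new_partition <- function(blocks, method = "user", support = NULL) {
  if (!length(blocks)) stop("empty partition")
  if (any(!lengths(blocks))) stop("empty block in partition")
  members <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("blocks not disjoint: specimen '",
         members[anyDuplicated(members)], "' appears twice")
  }
  # deterministic order: blocks sorted by their smallest member
  blocks <- lapply(blocks, sort)
  ord <- order(vapply(blocks, `[`, character(1), 1L))
  blocks <- blocks[ord]
  if (!is.null(support)) {
    stopifnot(length(support) == length(blocks),
              all(support >= 0 & support <= 1))
    support <- support[ord]
  }
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    names(blocks) <- sprintf("sp%02d", seq_along(blocks))
  }
  structure(list(blocks = blocks, method = method, support = support),
            class = "stygo_partition")
}

#' Build a partition from a label vector
#'
#' @param labels Character (or factor) vector of block labels named by
#'   specimen id.
#' @param method Method tag.
#' @return A `stygo_partition`.
#' @export
partition_from_labels <- function(labels, method = "user") {
  if (is.null(names(labels))) stop("labels must be named by specimen id")
  blocks <- split(names(labels), as.character(labels))
  new_partition(blocks, method = method)
}

#' Block membership lookup
#'
#' @param partition A `stygo_partition`.
#' @return Named character vector: specimen id -> block name.
#' @export
partition_labels <- function(partition) {
  stopifnot(inherits(partition, "stygo_partition"))
  out <- rep(names(partition$blocks), lengths(partition$blocks))
  names(out) <- unlist(partition$blocks, use.names = FALSE)
  out
}

#' Number of blocks in a partition
#' @param partition A `stygo_partition`.
#' @return Integer.
#' @export
n_blocks <- function(partition) length(partition$blocks)

#' Compare two partitions as set systems (block names ignored)
#'
#' @param a,b `stygo_partition` objects.
#' @return `TRUE` iff the two partitions induce the same grouping.
#' @export
partition_equal <- function(a, b) {
  ka <- sort(unname(vapply(a$blocks, function(x)
    paste(sort(x), collapse = "\r"), character(1))))
  kb <- sort(unname(vapply(b$blocks, function(x)
    paste(sort(x), collapse = "\r"), character(1))))
  identical(ka, kb)
}

#' @export
print.stygo_partition <- function(x, ...) {
  cat("Species partition (", x$method, "): ", length(x$blocks),
      " blocks, ", sum(lengths(x$blocks)), " specimens\n", sep = "")
  invisible(x)
}

#' Write a partition as two-column CSV (specimen_id, species_block)
#' @param partition A `stygo_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  lab <- partition_labels(partition)
  write.csv(data.frame(specimen_id = names(lab), species_block = unname(lab),
                       stringsAsFactors = FALSE),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a partition from two-column CSV
#' @param path CSV with columns specimen_id, species_block.
#' @param method Method tag to attach.
#' @return A `stygo_partition`.
#' @export
read_partition <- function(path, method = "user") {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  partition_from_labels(setNames(df$species_block, df$specimen_id),
                        method = method)
}
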