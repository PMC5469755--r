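# Shared data model: alignments, occurrence tables, taxonomy maps.
# External position indices are 1-based everywhere (R's native convention,
# and the convention of published diagnosis tables).

#' IUPAC nucleotide alphabet accepted by the package
#'
#' The four bases, the eleven ambiguity ("wobble") codes, 'N' and the
#' alignment gap '-'. 'N' and '-' are kept distinct: diagnostics treat the
#' gap as a character state while distance computations exclude both.
#'
#' @format Character vector of allowed (uppercase) residue symbols.
#' @export
STYGO_ALPHABET <- c("A", "C", "G", "T",
                    "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N", "-")

# Resolution sets of every symbol (what bases a symbol may stand for).
# '-' resolves only to itself; 'N' to all four bases (never the gap).
IUPAC_RESOLVE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"), "-" = "-")

#' Construct a validated alignment
#'
#' @param seqs Named character vector of sequences (strings), or a character
#'   matrix with one row per sequence and rownames giving specimen ids.
#' @param locus Marker name, e.g. "COI", "28S", "ITS", "H3".
#' @return An object of class `stygo_alignment`: a list with elements
#'   `locus`, `ids`, `mat` (character matrix of uppercase residues, one row
#'   per specimen) and `length` (number of columns).
#' @export
new_alignment <- function(seqs, locus) {
  if (is.matrix(seqs)) {
    ids <- rownames(seqs)
    mat <- toupper(seqs)
  } else {
    ids <- names(seqs)
    if (is.null(ids)) stop("sequences must be named by specimen id")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- names(seqs)[which(lens != lens[1L])[1L]]
      stop("ragged alignment: sequence '", bad, "' has length ",
           nchar(seqs[bad]), ", expected ", lens[1L])
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- ids
  }
  if (any(ids == "") || anyNA(ids)) stop("empty specimen id")
  if (anyDuplicated(ids)) {
    stop("duplicate specimen id: ", ids[anyDuplicated(ids)])
  }
  if (ncol(mat) < 1L) stop("alignment has zero columns")
  bad <- which(!(mat %in% STYGO_ALPHABET))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(mat)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(mat)) + 1L
    stop("illegal character '", mat[i, j], "' in sequence '", ids[i],
         "' at position ", j)
  }
  structure(list(locus = locus, ids = ids, mat = mat, length = ncol(mat)),
            class = "stygo_alignment")
}

#' @export
print.stygo_alignment <- function(x, ...) {
  cat("Alignment [", x$locus, "]: ", length(x$ids), " sequences x ",
      x$length, " columns\n", sep = "")
  invisible(x)
}

#' Read a FASTA alignment
#'
#' Residues are normalised to uppercase; any character outside the IUPAC
#' alphabet (plus '-' and 'N') is rejected with its 1-based position.
#'
#' @param path Path to a FASTA file.
#' @param locus Marker name stored with the alignment.
#' @return A [new_alignment()] object.
#' @export
read_fasta <- function(path, locus) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = FALSE,
                             forceDNAtolower = FALSE)
  if (!length(recs)) stop("empty FASTA file: ", path)
  seqs <- vapply(recs, function(s) paste(s, collapse = ""), character(1))
  names(seqs) <- names(recs)
  new_alignment(seqs, locus)
}

#' Write an alignment to FASTA
#'
#' @param alignment A `stygo_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  stopifnot(inherits(alignment, "stygo_alignment"))
  seqs <- apply(alignment$mat, 1L, paste, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = alignment$ids,
                      file.out = path, nbchar = 70)
  invisible(path)
}

#' Read a Newick tree
#'
#' Accepts a Newick string or a file path. Missing branch lengths are set
#' to 0 with a warning; duplicate tip labels are an error.
#'
#' @param text Newick string (containing "(") or path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(text) {
  tr <- tryCatch(
    if (grepl("(", text, fixed = TRUE)) ape::read.tree(text = text)
    else ape::read.tree(file = text),
    error = function(e) stop("invalid Newick: ", conditionMessage(e)),
    warning = function(w) stop("invalid Newick: ", conditionMessage(w)))
  if (is.null(tr)) stop("invalid Newick: could not parse input")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip label: ",
         tr$tip.label[anyDuplicated(tr$tip.label)])
  }
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch lengths set to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch length in input tree")
  tr
}

#' Write a tree to a Newick string or file
#'
#' @param tree An [ape::phylo] tree.
#' @param path Optional output path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree, digits = 15))
  ape::write.tree(tree, file = path, digits = 15)
  invisible(ape::write.tree(tree, digits = 15))
}

occ_required_cols <- c("specimen_id", "species", "site_id",
                       "lat", "lon", "country", "basin")

#' Validate an occurrence table
#'
#' @param df Data frame with columns `specimen_id`, `species`, `site_id`,
#'   `lat`, `lon`, `country`, `basin` (WGS84 decimal degrees).
#' @return The validated data frame, with class `stygo_occurrences` added.
#' @export
as_occurrences <- function(df) {
  miss <- setdiff(occ_required_cols, names(df))
  if (length(miss)) stop("missing occurrence columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$site_id == "" | is.na(df$site_id))) stop("empty site_id")
  if (any(is.na(df$lat)) || any(df$lat < -90 | df$lat > 90)) {
    stop("latitude out of range [-90, 90]")
  }
  if (any(is.na(df$lon)) || any(df$lon < -180 | df$lon > 180)) {
    stop("longitude out of range [-180, 180]")
  }
  if (anyDuplicated(df[c("specimen_id", "site_id")])) {
    stop("duplicate (specimen_id, site_id) record")
  }
  class(df) <- c("stygo_occurrences", "data.frame")
  df
}

#' Read a georeferenced occurrence table
#'
#' @param path CSV file with the columns listed in [as_occurrences()].
#' @return A validated occurrence data frame.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  as_occurrences(read.csv(path, stringsAsFactors = FALSE,
                          comment.char = "#"))
}

#' Read a taxonomy map (nominal name to revised species)
#'
#' The map records, for every revised (post-split) species, the nominal
#' name under which its populations were previously filed; several revised
#' species typically map back to one nominal species.
#'
#' @param path CSV file with columns `nominal` and `revised`.
#' @return Data frame with columns `nominal`, `revised`.
#' @export
read_taxonomy_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(c("nominal", "revised"), names(df))
  if (length(miss)) stop("missing taxonomy-map columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$revised)) {
    stop("revised species mapped more than once: ",
         df$revised[anyDuplicated(df$revised)])
  }
  df
}
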