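# Character-based molecular diagnoses: pure character attributes (CAs),
# i.e. single alignment states fixed in every member of a species and
# excluded from every other compared species.

#' Pure character attributes (molecular diagnosis) per species
#'
#' Position p with state s is diagnostic for block B iff (i) every member
#' of B present in the alignment carries exactly s at p (an ambiguity
#' code never qualifies; 'N' disqualifies fixation) and (ii) no member of
#' any other compared block can carry s: an outside ambiguity whose
#' resolution set contains s disqualifies a base diagnosis, an outside
#' gap disqualifies a gap diagnosis, and an outside 'N' disqualifies any
#' base. The gap '-' is a legal diagnostic state. Comparison is flat
#' (each focal block against all other focal blocks), matching published
#' per-species diagnoses against a focal complex.
#'
#' @param alignments A `stygo_alignment` or named list of them (per
#'   locus).
#' @param partition A `stygo_partition`.
#' @param focal Character vector of block names forming the comparison
#'   set; defaults to all blocks.
#' @return Object of class `stygo_diagnosis`: data frame (species, locus,
#'   position, state) with positions strictly increasing within species x
#'   locus, plus attribute `na_entries` — data frame (species, locus) of
#'   blocks with no sequence data at a locus.
#' @export
pure_character_attributes <- function(alignments, partition, focal = NULL) {
  if (inherits(alignments, "stygo_alignment")) {
    alignments <- setNames(list(alignments), alignments$locus)
  }
  if (is.null(focal)) focal <- names(partition$blocks)
  unknown <- setdiff(focal, names(partition$blocks))
  if (length(unknown)) stop("unknown block: ", unknown[1L])
  states <- c("A", "C", "G", "T", "-")
  rows <- list()
  na_entries <- list()
  for (locus in names(alignments)) {
    aln <- alignments[[locus]]
    if (!length(aln$ids)) stop("empty alignment for locus ", locus)
    # per-cell resolution-set membership, precomputed per state
    can_be <- lapply(states, function(s) {
      memb <- vapply(STYGO_ALPHABET,
                     function(ch) s %in% IUPAC_RESOLVE[[ch]], logical(1))
      matrix(memb[match(aln$mat, STYGO_ALPHABET)], nrow = nrow(aln$mat))
    })
    names(can_be) <- states
    rows_of <- lapply(partition$blocks[focal],
                      function(b) which(aln$ids %in% b))
    for (sp in focal) {
      if (!length(partition$blocks[[sp]])) stop("block with zero members")
      rb <- rows_of[[sp]]
      if (!length(rb)) {
        na_entries[[length(na_entries) + 1L]] <-
          data.frame(species = sp, locus = locus, stringsAsFactors = FALSE)
        next
      }
      ro <- setdiff(unlist(rows_of[setdiff(focal, sp)]), integer(0))
      found_pos <- integer(0); found_state <- character(0)
      for (s in states) {
        fixed_in <- colSums(matrix(aln$mat[rb, , drop = FALSE] == s,
                                   nrow = length(rb))) == length(rb)
        if (!any(fixed_in)) next
        if (length(ro)) {
          excluded_out <- colSums(can_be[[s]][ro, , drop = FALSE]) == 0L
        } else {
          excluded_out <- rep(TRUE, aln$length)
        }
        hit <- which(fixed_in & excluded_out)
        found_pos <- c(found_pos, hit)
        found_state <- c(found_state, rep(s, length(hit)))
      }
      if (length(found_pos)) {
        o <- order(found_pos)
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, locus = locus, position = found_pos[o],
          state = found_state[o], stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), locus = character(),
               position = integer(), state = character(),
               stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "na_entries") <- if (length(na_entries))
    do.call(rbind, na_entries) else
    data.frame(species = character(), locus = character(),
               stringsAsFactors = FALSE)
  attr(tab, "loci") <- names(alignments)
  class(tab) <- c("stygo_diagnosis", "data.frame")
  tab
}

#' Diagnostic-site counts per species and locus
#'
#' @param table A `stygo_diagnosis` (or compatible data frame); "na"
#'   entries count as 0.
#' @param species,loci Optional vectors fixing the rows/columns of the
#'   count table (defaults to those present).
#' @return List with `counts` (data frame species x locus), `min`, `max`.
#' @export
diagnosis_counts <- function(table, species = NULL, loci = NULL) {
  na_e <- attr(table, "na_entries")
  if (is.null(species)) {
    species <- sort(unique(c(table$species,
                             if (!is.null(na_e)) na_e$species)))
  }
  if (is.null(loci)) {
    loci <- unique(c(attr(table, "loci"), table$locus))
  }
  counts <- matrix(0L, length(species), length(loci),
                   dimnames = list(species, loci))
  if (nrow(table)) {
    tt <- table(factor(table$species, species), factor(table$locus, loci))
    counts[] <- as.integer(tt)
  }
  df <- data.frame(species = species, counts, check.names = FALSE,
                   row.names = NULL, stringsAsFactors = FALSE)
  list(counts = df,
       min = if (length(counts)) min(counts) else 0L,
       max = if (length(counts)) max(counts) else 0L)
}

locus_display <- function(locus) if (locus == "28S") "28 S" else locus

#' Format a species diagnosis in the published table style
#'
#' Per-locus "position STATE" lists in the order 28S, COI, ITS (further
#' loci such as H3 appended only when they carry diagnostic sites);
#' loci without data or without diagnostic sites print "na".
#'
#' @param table A `stygo_diagnosis`.
#' @param species Species (block) name present in the table.
#' @return Single formatted string.
#' @export
format_diagnosis <- function(table, species) {
  na_e <- attr(table, "na_entries")
  known <- unique(c(table$species, if (!is.null(na_e)) na_e$species))
  if (!(species %in% known)) stop("unknown species: ", species)
  core <- c("28S", "COI", "ITS")
  extra <- setdiff(unique(table$locus[table$species == species]), core)
  parts <- character(0)
  for (locus in c(core, extra)) {
    sub <- table[table$species == species & table$locus == locus, ,
                 drop = FALSE]
    entry <- if (nrow(sub)) {
      paste(paste(sub$position, sub$state), collapse = ", ")
    } else "na"
    parts <- c(parts, paste0(locus_display(locus), ": ", entry))
  }
  paste(parts, collapse = " | ")
}

#' Parse a published-style molecular diagnosis string
#'
#' Accepts strings of the form "28S: 182 T, 212 A | COI: 79 G | ITS: na"
#' (the separators "|" or locus headers ending in ":"). In validation
#' mode, tokens that are not "position STATE" pairs (e.g. a position with
#' a missing state) and positions that break the strictly-increasing
#' order within a locus are reported as flags rather than silently
#' dropped or corrected.
#'
#' @param text Diagnosis string.
#' @param species Species name to attach.
#' @param validate Collect anomaly flags (default TRUE).
#' @return A `stygo_diagnosis`-like data frame with attribute `flags`
#'   (character vector of anomaly messages).
#' @export
parse_diagnosis <- function(text, species = "species", validate = TRUE) {
  flags <- character(0)
  chunks <- strsplit(text, "|", fixed = TRUE)[[1L]]
  rows <- list()
  na_entries <- list()
  for (chunk in chunks) {
    m <- regmatches(chunk, regexec("^\\s*([0-9A-Za-z ]+?)\\s*:\\s*(.*)$",
                                   chunk))[[1L]]
    if (length(m) != 3L) {
      flags <- c(flags, paste0("unparseable locus chunk: '",
                               trimws(chunk), "'"))
      next
    }
    locus <- gsub(" ", "", m[2L])
    body <- trimws(m[3L])
    if (body == "na" || body == "-" || body == "") {
      na_entries[[length(na_entries) + 1L]] <- data.frame(
        species = species, locus = locus, stringsAsFactors = FALSE)
      next
    }
    toks <- trimws(strsplit(body, ",")[[1L]])
    toks <- toks[toks != ""]
    prev <- -Inf
    for (tok in toks) {
      tm <- regmatches(tok, regexec("^([0-9]+)\\s*(-|[ACGT])$", tok))[[1L]]
      if (length(tm) != 3L) {
        flags <- c(flags, paste0(locus, ": bad token '", tok, "'"))
        next
      }
      pos <- as.integer(tm[2L])
      if (validate && pos <= prev) {
        flags <- c(flags, paste0(locus, ": position ", pos,
                                 " breaks increasing order"))
      }
      prev <- max(prev, pos)
      rows[[length(rows) + 1L]] <- data.frame(
        species = species, locus = locus, position = pos, state = tm[3L],
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), locus = character(),
               position = integer(), state = character(),
               stringsAsFactors = FALSE)
  attr(tab, "na_entries") <- if (length(na_entries))
    do.call(rbind, na_entries) else
    data.frame(species = character(), locus = character(),
               stringsAsFactors = FALSE)
  attr(tab, "flags") <- flags
  class(tab) <- c("stygo_diagnosis", "data.frame")
  tab
}

#' Write a diagnosis table as CSV
#' @param table A `stygo_diagnosis`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagnosis <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
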