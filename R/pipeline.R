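# Pipeline orchestration: distances -> tree -> delimitation -> sharing
# screen -> ED -> diagnostics -> conservation, from one config, with
# reproducible CSV/JSON outputs.

stage_note <- function(stage, msg) message("[", stage, "] ", msg)

out_header <- function(seed) {
  paste0("# stygodelim ", as.character(packageVersion("stygodelim")),
         " | seed=", if (is.null(seed)) "none" else seed)
}

write_with_header <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out_header(seed), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full integrative delimitation pipeline
#'
#' Stages (each skipped with a logged notice when its inputs are absent):
#' K2P distances on the barcode locus and threshold clustering; patristic
#' distances on the supplied or internally built (NJ + midpoint-rooted)
#' tree and threshold clustering; ML-PTP on the rooted tree; consensus
#' (meet) of the partitions — the headline species hypothesis, matching
#' the requirement that methods agree; haplotype-sharing screen across
#' loci; fair-proportion ED; pure-character-attribute diagnoses; range /
#' endemism / rank table and richness accounting.
#'
#' @param alignments Named list of `stygo_alignment` objects (or paths to
#'   FASTA files, named by locus), or NULL.
#' @param tree An [ape::phylo], Newick string/path, or NULL to build a
#'   neighbor-joining tree from the barcode K2P matrix.
#' @param occurrences Occurrence data frame or CSV path, or NULL.
#' @param taxonomy_map Data frame or CSV path (nominal, revised), or NULL.
#' @param config A [delimitation_config()].
#' @param rank_thresholds Passed to [conservation_rank()].
#' @param barcode Locus used for distance delimitation (default "COI").
#' @param out_dir Output directory (created if missing), or NULL to skip
#'   writing files.
#' @param seed Seed recorded in output headers and used for PTP restarts.
#' @param ptp_restarts Random restarts for [ptp_fit()].
#' @return List of class `stygo_report` with the computed components.
#' @export
run_pipeline <- function(alignments = NULL, tree = NULL,
                         occurrences = NULL, taxonomy_map = NULL,
                         config = delimitation_config(),
                         rank_thresholds = list(), barcode = "COI",
                         out_dir = NULL, seed = NULL, ptp_restarts = 0L) {
  if (!is.null(alignments)) {
    alignments <- lapply(setNames(names(alignments), names(alignments)),
                         function(locus) {
                           a <- alignments[[locus]]
                           if (is.character(a)) read_fasta(a, locus) else a
                         })
  }
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(occurrences)) occurrences <- read_occurrences(occurrences)
  if (is.character(taxonomy_map)) taxonomy_map <- read_taxonomy_map(taxonomy_map)

  res <- list(config = config, seed = seed)
  partitions <- list()

  if (!is.null(alignments) && barcode %in% names(alignments)) {
    stage_note("k2p", paste0("distance matrix on ", barcode))
    res$k2p <- k2p_matrix(alignments[[barcode]])
    partitions$k2p <- threshold_clusters(res$k2p, config$k2p_threshold,
                                         config$linkage)
    if (is.null(tree)) {
      stage_note("tree", "building NJ tree from K2P matrix")
      tree <- midpoint_root(neighbor_joining(res$k2p))
    }
  } else {
    stage_note("k2p", "no barcode alignment; distance delimitation skipped")
  }

  if (!is.null(tree)) {
    if (!ape::is.rooted(tree)) tree <- midpoint_root(tree)
    res$tree <- tree
    res$patristic <- patristic_matrix(tree)
    partitions$patristic <- threshold_clusters(
      res$patristic, config$patristic_threshold, config$linkage,
      method = "threshold-patristic")
    stage_note("ptp", "ML-PTP delimitation")
    res$ptp <- if (!is.null(alignments) && barcode %in% names(alignments)) {
      # haplotype-tree route (collapsed identical sequences)
      ptp_delimit(alignments[[barcode]], n_restarts = ptp_restarts,
                  seed = seed)
    } else {
      ptp_fit(tree, n_restarts = ptp_restarts, seed = seed)
    }
    partitions$ptp <- res$ptp$partition
    res$ed <- fair_proportion_ed(tree)
  } else {
    stage_note("tree", "no tree; PTP, patristic and ED stages skipped")
  }

  if (length(partitions) >= 2L) {
    res$consensus <- consensus_partition(unname(partitions))
  } else if (length(partitions) == 1L) {
    res$consensus <- partitions[[1L]]
  }
  res$partitions <- partitions

  if (!is.null(alignments) && !is.null(res$consensus)) {
    stage_note("sharing", "haplotype-sharing screen")
    res$sharing <- lineage_sharing_screen(alignments, res$consensus,
                                          occurrences)
    stage_note("diagnosis", "pure character attributes")
    res$diagnosis <- pure_character_attributes(alignments, res$consensus)
  }

  if (!is.null(occurrences)) {
    res$ranges <- range_summary(occurrences)
    res$syntopy <- detect_syntopy(occurrences)
    species_ed <- NULL
    if (!is.null(res$ed) && !is.null(res$consensus)) {
      lab <- partition_labels(res$consensus)
      common <- intersect(res$ed$tip, names(lab))
      if (length(common)) {
        by_block <- tapply(setNames(res$ed$ED, res$ed$tip)[common],
                           lab[common], mean)
        species_ed <- setNames(as.numeric(by_block), names(by_block))
      }
    }
    if (!is.null(species_ed) &&
        all(res$ranges$species %in% names(species_ed))) {
      res$conservation <- conservation_table(res$ranges, species_ed,
                                             rank_thresholds)
    }
    if (!is.null(taxonomy_map)) {
      stage_note("richness", "richness accounting")
      res$richness <- richness_accounting(occurrences, taxonomy_map)
    }
  } else {
    stage_note("geo", "no occurrences; conservation stages skipped")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(partitions)) {
      write_partition(partitions[[nm]],
                      file.path(out_dir, paste0("partition_", nm, ".csv")))
    }
    if (!is.null(res$consensus)) {
      write_partition(res$consensus,
                      file.path(out_dir, "partition_consensus.csv"))
    }
    if (!is.null(res$ptp)) {
      write_ptp_json(res$ptp, file.path(out_dir, "ptp.json"))
    }
    if (!is.null(res$sharing)) {
      write_with_header(res$sharing,
                        file.path(out_dir, "sharing_report.csv"), seed)
    }
    if (!is.null(res$ed)) {
      write_with_header(res$ed, file.path(out_dir, "ed.csv"), seed)
    }
    if (!is.null(res$diagnosis)) {
      write_diagnosis(res$diagnosis, file.path(out_dir, "diagnosis.csv"))
    }
    if (!is.null(res$conservation)) {
      write_with_header(res$conservation,
                        file.path(out_dir, "conservation.csv"), seed)
    }
    if (!is.null(res$richness)) {
      jsonlite::write_json(res$richness[c("site", "country", "basin",
                                          "increased_sites")],
                           file.path(out_dir, "richness.json"),
                           dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
    }
    summary <- list(
      version = as.character(packageVersion("stygodelim")),
      seed = if (is.null(seed)) NA else seed,
      n_partitions = length(partitions),
      n_consensus_species = if (is.null(res$consensus)) NA else
        n_blocks(res$consensus),
      config = unclass(config))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(res, class = "stygo_report")
}

#' @export
print.stygo_report <- function(x, ...) {
  cat("stygodelim pipeline report\n")
  if (!is.null(x$consensus)) {
    cat("  consensus species hypothesis: ", n_blocks(x$consensus),
        " species\n", sep = "")
  }
  for (nm in names(x$partitions)) {
    cat("  ", nm, ": ", n_blocks(x$partitions[[nm]]), " blocks\n",
        sep = "")
  }
  if (!is.null(x$sharing)) {
    cat("  shared haplotypes across species: ", nrow(x$sharing), "\n",
        sep = "")
  }
  invisible(x)
}
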