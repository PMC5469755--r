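# Synthetic-data generator. Emulates the statistical structure the
# delimitation analysis assumes: clusters of near-identical haplotypes per
# species (intra-specific K2P divergence well below 4%), deep divergence
# between species (K2P above 4%), species-specific haplotypes at every
# locus, and occurrence point clouds with occasional planted syntopy.

#' Simulation configuration
#'
#' Defaults describe the benchmark complex: 16 species with 4 sampled
#' individuals each; species-tree branch lengths drawn from Exp(rate 12.5)
#' (mean 0.08 substitutions/site, keeping even genus-scale path sums below
#' K2P saturation) and within-species branches from Exp(rate 8000)
#' (mean 1.25e-4: species are tight clusters of near-identical
#' haplotypes, with intra-specific divergence far below 1\% while
#' inter-specific divergence exceeds 4\%). Sequences
#' evolve under the Kimura two-parameter model (transition/transversion
#' rate ratio kappa), matching the K2P distance estimator. Geography
#' places each species' sites uniformly in a disjoint geodesic disc.
#'
#' @param n_species Number of species (>= 1).
#' @param tips_per_species Sampled individuals per species.
#' @param lambda_between Exponential rate of speciation-class branch
#'   lengths (1/substitutions).
#' @param lambda_within Exponential rate of within-species branch lengths.
#' @param loci Named list of per-locus settings `list(length=, kappa=)`.
#' @param geography Data frame (species, center_lat, center_lon,
#'   radius_km, n_sites, country, basin) or NULL for an automatic grid.
#' @param syntopy Data frame (species_a, species_b) of site-sharing
#'   injections, or an integer count of injections, or NULL.
#' @param intra_max,inter_min COI K2P bounds asserted after generation
#'   (defaults 0.01 and 0.04, the benchmark's divergence structure).
#' @param seed Integer seed (mandatory for reproducible output).
#' @return List of class `stygo_sim_config`.
#' @export
simulation_config <- function(n_species = 16L, tips_per_species = 4L,
                              lambda_between = 12.5, lambda_within = 8000,
                              loci = list(
                                COI = list(length = 658L, kappa = 4),
                                `28S` = list(length = 600L, kappa = 2),
                                ITS = list(length = 600L, kappa = 2),
                                H3 = list(length = 328L, kappa = 2)),
                              geography = NULL, syntopy = NULL,
                              intra_max = 0.01, inter_min = 0.04,
                              seed) {
  stopifnot(n_species >= 1L, tips_per_species >= 1L,
            lambda_between > 0, lambda_within > 0)
  for (l in loci) stopifnot(l$length >= 1L, l$kappa > 0)
  if (missing(seed)) stop("seed is mandatory for randomized output")
  if (is.null(geography)) {
    k <- ceiling(sqrt(n_species))
    i <- seq_len(n_species) - 1L
    geography <- data.frame(
      species = sprintf("sp%02d", seq_len(n_species)),
      center_lat = 45 + 0.4 * (i %/% k),
      center_lon = 14 + 0.5 * (i %% k),
      radius_km = 10, n_sites = 3L,
      country = ifelse(i %% k < k / 2, "Slovenia", "Croatia"),
      basin = ifelse(i %/% k < k / 2, "Danube", "Adriatic"),
      stringsAsFactors = FALSE)
  }
  if (is.numeric(syntopy) && length(syntopy) == 1L) {
    sp <- geography$species
    if (syntopy > length(sp) %/% 2) stop("too many syntopy injections")
    syntopy <- data.frame(
      species_a = sp[2 * seq_len(syntopy) - 1L],
      species_b = sp[2 * seq_len(syntopy)], stringsAsFactors = FALSE)
  }
  structure(list(n_species = as.integer(n_species),
                 tips_per_species = as.integer(tips_per_species),
                 lambda_between = lambda_between,
                 lambda_within = lambda_within,
                 loci = loci, geography = geography, syntopy = syntopy,
                 intra_max = intra_max, inter_min = inter_min,
                 seed = as.integer(seed)),
            class = "stygo_sim_config")
}

# random join topology over the given labels (Yule/coalescent topology law)
random_topology_newick <- function(labels) {
  frags <- as.list(labels)
  while (length(frags) > 1L) {
    i <- sample.int(length(frags), 2L)
    merged <- paste0("(", frags[[i[1L]]], ",", frags[[i[2L]]], ")")
    frags[[max(i)]] <- NULL
    frags[[min(i)]] <- merged
  }
  frags[[1L]]
}

#' Simulate a species tree with within-species subtrees
#'
#' A pure-birth species topology whose branches are drawn from
#' Exp(`lambda_between`); each species tip is replaced by a subtree over
#' its sampled individuals with branches from Exp(`lambda_within`).
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed; NULL continues the current RNG stream.
#' @return List with `tree` (rooted [ape::phylo]) and `partition` (the
#'   true `stygo_partition`).
#' @export
simulate_tree <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  ns <- config$n_species
  tps <- config$tips_per_species
  sp_labels <- sprintf("sp%02d", seq_len(ns))
  tip_of <- lapply(sp_labels, function(s)
    sprintf("%s_t%d", s, seq_len(tps)))
  names(tip_of) <- sp_labels
  sp_topo <- if (ns == 1L) sp_labels else
    random_topology_newick(sp_labels)
  within <- vapply(sp_labels, function(s) {
    if (tps == 1L) tip_of[[s]] else random_topology_newick(tip_of[[s]])
  }, character(1))
  full <- sp_topo
  for (s in rev(sp_labels)) {      # longest-first irrelevant: ids padded
    full <- sub(s, within[[s]], full, fixed = TRUE)
  }
  tree <- ape::read.tree(text = paste0(full, ";"))
  part <- new_partition(tip_of, method = "user")
  tree$edge.length <- rep(0, nrow(tree$edge))
  cls <- ptp_branch_classes(tree, part)
  nb <- sum(cls == "between"); nw <- sum(cls == "within")
  tree$edge.length[cls == "between"] <- rexp(nb, config$lambda_between)
  tree$edge.length[cls == "within"] <- rexp(nw, config$lambda_within)
  list(tree = tree, partition = part)
}

# K80 transition probability matrix for branch length d (subst/site)
k80_pmatrix <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  e4 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  same <- 0.25 + 0.25 * e4 + 0.5 * e2
  ts <- 0.25 + 0.25 * e4 - 0.5 * e2
  tv <- 0.25 - 0.25 * e4
  # state order A, C, G, T; transitions A<->G, C<->T
  matrix(c(same, tv, ts, tv,
           tv, same, tv, ts,
           ts, tv, same, tv,
           tv, ts, tv, same), 4L, 4L, byrow = TRUE)
}

#' Simulate an alignment along a tree under the K2P substitution model
#'
#' Root sequence uniform over \{A,C,G,T\}; sites evolve independently
#' along each branch with the Kimura two-parameter transition matrix at
#' the branch's length.
#'
#' @param tree Rooted tree with branch lengths (substitutions/site).
#' @param length Alignment length (columns).
#' @param kappa Transition/transversion rate ratio.
#' @param locus Locus name recorded on the alignment.
#' @param seed Optional seed; NULL continues the current RNG stream.
#' @return A `stygo_alignment` over the tree's tips.
#' @export
simulate_sequences <- function(tree, length, kappa = 4, locus = "COI",
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ntip <- base::length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nnode, length)
  root <- ntip + 1L
  states[root, ] <- sample.int(4L, length, replace = TRUE)
  ord <- rev(seq_len(nrow(tree$edge)))   # reversed postorder: parents first
  po <- ape::reorder.phylo(tree, "postorder")$edge
  lens <- tree$edge.length[match(paste(po[, 1L], po[, 2L]),
                                 paste(tree$edge[, 1L], tree$edge[, 2L]))]
  for (k in rev(seq_len(nrow(po)))) {
    p <- po[k, 1L]; v <- po[k, 2L]
    P <- k80_pmatrix(lens[k], kappa)
    parent <- states[p, ]
    child <- integer(length)
    for (s in 1:4) {
      idx <- which(parent == s)
      if (base::length(idx)) {
        child[idx] <- sample.int(4L, base::length(idx), replace = TRUE,
                                 prob = P[s, ])
      }
    }
    states[v, ] <- child
  }
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L,
                function(r) paste(bases[r], collapse = ""))
  names(seqs) <- tree$tip.label
  new_alignment(seqs, locus)
}

#' Simulate an occurrence table
#'
#' Each species' sites are placed uniformly in its geodesic disc;
#' specimens are assigned to sites round-robin. Syntopy injections merge
#' one site of species B into a site of species A so the two species
#' co-occur there.
#'
#' @param partition True `stygo_partition` (blocks named by species).
#' @param geography Geography data frame (see [simulation_config()]).
#' @param syntopy Injection data frame (species_a, species_b) or NULL.
#' @param seed Optional seed; NULL continues the current RNG stream.
#' @return Occurrence data frame.
#' @export
simulate_occurrences <- function(partition, geography, syntopy = NULL,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  recs <- list()
  sites_of <- list()
  for (i in seq_len(nrow(geography))) {
    g <- geography[i, ]
    sp <- g$species
    members <- partition$blocks[[sp]]
    if (is.null(members)) stop("species ", sp, " absent from partition")
    ns <- min(g$n_sites, length(members))
    r <- g$radius_km * sqrt(runif(ns))
    th <- runif(ns, 0, 2 * pi)
    lat <- g$center_lat + r * cos(th) / 111.195
    lon <- g$center_lon + r * sin(th) /
      (111.195 * cos(g$center_lat * pi / 180))
    sites <- data.frame(site_id = sprintf("%s_s%d", sp, seq_len(ns)),
                        lat = lat, lon = lon, stringsAsFactors = FALSE)
    sites_of[[sp]] <- sites
    slot <- rep(seq_len(ns), length.out = length(members))
    recs[[sp]] <- data.frame(
      specimen_id = members, species = sp,
      site_id = sites$site_id[slot], lat = sites$lat[slot],
      lon = sites$lon[slot], country = g$country, basin = g$basin,
      stringsAsFactors = FALSE)
  }
  occ <- do.call(rbind, recs)
  rownames(occ) <- NULL
  if (!is.null(syntopy) && nrow(syntopy)) {
    used_b <- character(0)
    for (k in seq_len(nrow(syntopy))) {
      a <- syntopy$species_a[k]; b <- syntopy$species_b[k]
      if (b %in% used_b) stop("species ", b, " reused as injection target")
      used_b <- c(used_b, b)
      target <- sites_of[[a]][1L, ]
      donor <- sites_of[[b]]$site_id[1L]
      sel <- occ$species == b & occ$site_id == donor
      occ$site_id[sel] <- target$site_id
      occ$lat[sel] <- target$lat
      occ$lon[sel] <- target$lon
    }
  }
  as_occurrences(occ)
}

#' Generate a mutually consistent truth bundle
#'
#' Simulates tree, per-locus alignments and occurrences under one seed
#' and asserts the benchmark divergence structure on the COI alignment
#' (maximum intra-specific K2P below `intra_max`, minimum inter-specific
#' above `inter_min`). If the assertion fails, generation is retried with
#' the next derived seed and the retry count reported in a message and in
#' the `attempts` element.
#'
#' @param config A [simulation_config()].
#' @param max_attempts Retry budget (default 200).
#' @return List of class `stygo_truth_bundle`: `tree`, `partition`,
#'   `alignments` (named list), `occurrences`, `config`, `attempts`.
#' @export
simulate_truth_bundle <- function(config, max_attempts = 200L) {
  stopifnot(inherits(config, "stygo_sim_config"))
  set.seed(config$seed)
  attempt_seeds <- sample.int(.Machine$integer.max, max_attempts)
  for (attempt in seq_len(max_attempts)) {
    set.seed(attempt_seeds[attempt])
    tp <- simulate_tree(config, seed = NULL)
    alns <- lapply(names(config$loci), function(locus) {
      lc <- config$loci[[locus]]
      simulate_sequences(tp$tree, lc$length, lc$kappa, locus = locus,
                         seed = NULL)
    })
    names(alns) <- names(config$loci)
    occ <- simulate_occurrences(tp$partition, config$geography,
                                config$syntopy, seed = NULL)
    ok <- TRUE
    if ("COI" %in% names(alns) && config$n_species > 1L) {
      m <- k2p_matrix(alns$COI)
      lab <- partition_labels(tp$partition)[rownames(m)]
      same <- outer(lab, lab, "==")
      diag(same) <- NA
      intra <- m[same & !is.na(same)]
      inter <- m[!same & !is.na(same)]
      ok <- all(is.finite(m)) &&
        (!length(intra) || max(intra) < config$intra_max) &&
        (!length(inter) || min(inter) > config$inter_min)
    }
    if (ok) {
      if (attempt > 1L) {
        message("simulate_truth_bundle: divergence assertion needed ",
                attempt - 1L, " retr",
                if (attempt == 2L) "y" else "ies")
      }
      return(structure(list(tree = tp$tree, partition = tp$partition,
                            alignments = alns, occurrences = occ,
                            config = config, attempts = attempt),
                       class = "stygo_truth_bundle"))
    }
  }
  stop("divergence assertion failed after ", max_attempts, " attempts")
}
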