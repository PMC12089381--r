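#' Density-based clustering of beads under periodic boundaries
#'
#' DBSCAN on minimum-image distances: beads with at least `n_min` neighbors
#' (excluding themselves) within `eps` are core beads; non-core beads join
#' a cluster iff they neighbor one of its core beads; remaining beads are
#' noise (label 0).  Expansion proceeds in ascending bead order with a
#' LIFO stack, so labels are deterministic.
#'
#' @param positions N x 3 coordinates, nm.
#' @param box cubic box side, nm.
#' @param eps neighborhood radius, nm (default 1).
#' @param n_min minimum neighbor count for a core bead (default 2).
#' @param chain integer chain id per bead (optional; enables chain-level
#'   results).
#' @return object of class `phos_clusters`: `labels` (0 = noise),
#'   `is_core`, `eps`, `n_min`, `chain`, `chain_clusters` (list of cluster
#'   label sets per chain, when `chain` given).
#' @export
cluster_beads <- function(positions, box, eps = 1.0, n_min = 2,
                          chain = NULL) {
  n <- nrow(positions)
  if (is.null(n) || n == 0) stop("empty input")
  stopifnot(eps > 0, n_min >= 1)
  nb <- vector("list", n)
  deg <- integer(n)
  d2max <- eps^2
  for (i in seq_len(n)) {
    dd <- sweep(positions, 2, positions[i, ], "-")
    dd <- dd - box * round(dd / box)
    hit <- which(rowSums(dd^2) <= d2max)
    hit <- hit[hit != i]
    nb[[i]] <- hit
    deg[i] <- length(hit)
  }
  is_core <- deg >= n_min
  labels <- integer(n)                 # 0 = unvisited/noise
  lab <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !is_core[i]) next
    lab <- lab + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (labels[v] != 0L) next
      labels[v] <- lab
      if (is_core[v]) {
        new <- nb[[v]][labels[nb[[v]]] == 0L]
        if (length(new)) stack <- c(stack, new)
      }
    }
  }
  out <- list(labels = labels, is_core = is_core, eps = eps, n_min = n_min,
              chain = chain)
  if (!is.null(chain))
    out$chain_clusters <- lapply(split(labels, chain),
                                 function(l) sort(unique(l[l > 0])))
  class(out) <- "phos_clusters"
  out
}

#' @export
print.phos_clusters <- function(x, ...) {
  k <- max(x$labels)
  cat("<phos_clusters>", length(x$labels), "beads,", k, "clusters,",
      sum(x$labels == 0), "noise (eps =", x$eps, "nm, n_min =", x$n_min, ")\n")
  invisible(x)
}

# largest cluster by chain membership (any-bead rule); ties -> lowest label
largest_cluster_label <- function(cl, chains = NULL) {
  labs <- cl$labels
  ch <- cl$chain
  if (!is.null(chains)) {
    keep <- ch %in% chains
    labs <- labs[keep]; ch <- ch[keep]
  }
  pos <- labs > 0
  if (!any(pos)) return(NA_integer_)
  sizes <- vapply(split(ch[pos], labs[pos]),
                  function(v) length(unique(v)), integer(1))
  as.integer(names(sizes)[which.max(sizes)])   # which.max: lowest label on tie
}

#' Fraction of chains in the largest cluster
#'
#' A chain belongs to a cluster if any of its beads does.  The largest
#' cluster is the one containing the most chains (ties broken by lowest
#' label).  When `substrate_chains` is given, only those chains are counted
#' (and define the largest cluster).
#'
#' @param cl `phos_clusters` built with chain ids.
#' @param substrate_chains optional chain ids to restrict to.
#' @param rule `"any"` (default) or `"majority"` bead membership.
#' @return fraction in \[0, 1\].
#' @export
condensate_fraction <- function(cl, substrate_chains = NULL, rule = "any") {
  if (is.null(cl$chain)) stop("clustering lacks a chain map")
  chains <- if (is.null(substrate_chains)) sort(unique(cl$chain))
            else substrate_chains
  big <- largest_cluster_label(cl, chains)
  if (is.na(big)) return(0)
  inbig <- vapply(chains, function(c0) {
    l <- cl$labels[cl$chain == c0]
    if (rule == "any") any(l == big) else mean(l == big) > 0.5
  }, logical(1))
  mean(inbig)
}

#' Fraction of enzyme chains attached to the condensate
#'
#' The condensate is the largest cluster among substrate chains only; an
#' enzyme counts as attached iff any of its beads carries that label.
#'
#' @param cl `phos_clusters` with chain ids.
#' @param enzyme_chains enzyme chain ids.
#' @return fraction of enzymes attached.
#' @export
enzyme_attachment <- function(cl, enzyme_chains) {
  if (length(enzyme_chains) == 0) stop("no enzymes declared")
  substrate <- setdiff(unique(cl$chain), enzyme_chains)
  big <- largest_cluster_label(cl, substrate)
  if (is.na(big)) return(0)
  att <- vapply(enzyme_chains, function(c0)
    any(cl$labels[cl$chain == c0] == big), logical(1))
  mean(att)
}

#' Periodic-aware condensate center
#'
#' Per-axis circular mean of the cluster bead coordinates: each coordinate
#' is mapped to an angle on \[0, 2 pi), the mean resultant angle is mapped
#' back.  Invariant (modulo the box) under translation by lattice vectors.
#'
#' @param positions M x 3 coordinates of the cluster beads, nm.
#' @param box cubic box side, nm.
#' @return length-3 center, nm, in \[0, box).
#' @export
condensate_center <- function(positions, box) {
  if (is.null(nrow(positions)) || nrow(positions) == 0) stop("empty cluster")
  vapply(1:3, function(k) {
    th <- 2 * pi * positions[, k] / box
    ang <- atan2(mean(sin(th)), mean(cos(th)))
    (ang %% (2 * pi)) * box / (2 * pi)
  }, numeric(1))
}

#' Radial density profile around the condensate center
#'
#' Counts per species in spherical shells, normalized by shell volume
#' `4 pi / 3 (r_out^3 - r_in^3)`.
#'
#' @param positions N x 3 coordinates, nm.
#' @param species factor/character per bead.
#' @param center length-3 center, nm.
#' @param box cubic box side, nm.
#' @param bin_width shell width, nm (default 0.5).
#' @param r_max maximum radius (default `box / 2`).
#' @return data frame `r_in`, `r_out`, one density column per species
#'   (beads/nm^3).
#' @export
radial_density <- function(positions, species, center, box,
                           bin_width = 0.5, r_max = box / 2) {
  if (bin_width <= 0) stop("zero bin width")
  dd <- sweep(positions, 2, center, "-")
  dd <- dd - box * round(dd / box)
  r <- sqrt(rowSums(dd^2))
  edges <- seq(0, r_max, by = bin_width)
  if (max(edges) < r_max) edges <- c(edges, max(edges) + bin_width)
  nb <- length(edges) - 1
  vol <- 4 * pi / 3 * (edges[-1]^3 - edges[-length(edges)]^3)
  sp <- sort(unique(as.character(species)))
  out <- data.frame(r_in = edges[-length(edges)], r_out = edges[-1])
  for (s in sp) {
    rs <- r[species == s & r < max(edges)]
    cnt <- tabulate(findInterval(rs, edges, rightmost.closed = TRUE), nb)
    out[[s]] <- cnt / vol
  }
  out
}

#' Phospho-serine share per radial shell
#'
#' `pSer / (Ser + pSer)` per shell from a [radial_density()] profile with
#' `Ser` and `pSer` columns; shells with no serine beads are NA.
#'
#' @param profile data frame with `Ser` and `pSer` density columns.
#' @return numeric vector per shell.
#' @export
pser_fraction_profile <- function(profile) {
  if (!all(c("Ser", "pSer") %in% names(profile)))
    stop("profile must have Ser and pSer densities")
  tot <- profile$Ser + profile$pSer
  ifelse(tot > 0, profile$pSer / tot, NA_real_)
}

#' Distribution of pSer per chain, split by phase
#'
#' @param chem integer (0/1) per phosphosite bead.
#' @param site_chain chain id per phosphosite bead.
#' @param cl `phos_clusters` with chain ids (all beads).
#' @param substrate_chains optional restriction for the largest cluster.
#' @return list `dense`, `dilute`: integer tables of pSer count per chain.
#' @export
pser_per_chain_distribution <- function(chem, site_chain, cl,
                                        substrate_chains = NULL) {
  chains <- if (is.null(substrate_chains)) sort(unique(site_chain))
            else substrate_chains
  big <- largest_cluster_label(cl, chains)
  counts <- vapply(chains, function(c0) sum(chem[site_chain == c0]),
                   numeric(1))
  indense <- vapply(chains, function(c0)
    !is.na(big) && any(cl$labels[cl$chain == c0] == big), logical(1))
  list(dense = table(factor(counts[indense], levels = 0:max(counts, 0))),
       dilute = table(factor(counts[!indense], levels = 0:max(counts, 0))))
}

#' Per-residue interaction-energy decomposition
#'
#' For each residue of a group (e.g. the enzyme chain), the summed pair
#' energy with a disjoint partner set, split into Ashbaugh-Hatch, Yukawa
#' and cation-pi terms.  Each group-partner pair is attributed in full to
#' the group residue, so the components sum to the total group-partner
#' interaction energy.
#'
#' @param positions N x 3 coordinates, nm.
#' @param topology `phos_topology`.
#' @param params `phos_params`.
#' @param box cubic box side, nm.
#' @param group bead indices of the group (1-based).
#' @param partner bead indices of the partner set; must be disjoint.
#' @return data frame `bead`, `ah`, `yukawa`, `cation_pi`.
#' @export
energy_decomposition <- function(positions, topology, params, box,
                                 group, partner) {
  if (length(intersect(group, partner)))
    stop("group and partner sets overlap")
  type <- type_index(topology$beads$code, params)
  m <- cpp_energy_decomposition(positions, type, as.integer(topology$rigid),
                                topology$bonds - 1L,
                                engine_params(topology, params), box,
                                as.integer(group - 1L),
                                as.integer(partner - 1L))
  data.frame(bead = group, ah = m[, 1], yukawa = m[, 2], cation_pi = m[, 3])
}

#' Dissolution onset frame
#'
#' First frame at which the condensate fraction drops below a threshold
#' share of its initial plateau.
#'
#' @param fractions condensate fraction per frame.
#' @param plateau_frames frames used for the initial plateau.
#' @param threshold relative threshold (default 0.975).
#' @return frame index, or NA if never.
#' @export
dissolution_onset <- function(fractions, plateau_frames = 5,
                              threshold = 0.975) {
  plat <- mean(fractions[seq_len(min(plateau_frames, length(fractions)))])
  i <- which(fractions < threshold * plat)
  if (length(i)) i[1] else NA_integer_
}
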