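#' Assemble a simulation topology from sequence models
#'
#' Concatenates chains into a bead table with consecutive bonds inside each
#' chain, rigid-group ids, phosphosite bookkeeping (Ser vs pSer bead types)
#' and the kinase active-site annotation.
#'
#' @param chains list of `phos_sequence` objects.
#' @param params a `phos_params` object.
#' @param enzyme_chains indices (into `chains`) of enzyme chains; their
#'   annotated `active_site` (author numbers) provides the contact-detection
#'   beads.
#' @return object of class `phos_topology`: bead data frame (`chain`,
#'   `resnum`, `code`), `bonds` (2-column matrix, 1-based), `rigid`
#'   (integer per bead), `phosphosites` (bead indices), `active_site`
#'   (3 bead indices), `enzyme_chains`.
#' @export
system_topology <- function(chains, params, enzyme_chains = integer()) {
  beads <- data.frame(chain = integer(), resnum = integer(),
                      code = character())
  bonds <- matrix(integer(), 0, 2)
  rigid <- integer()
  phossites <- integer()
  active <- integer()
  next_rigid <- 0L
  off <- 0L
  for (ci in seq_along(chains)) {
    sq <- chains[[ci]]
    n <- length(sq$codes)
    beads <- rbind(beads, data.frame(chain = ci, resnum = sq$numbering,
                                     code = sq$codes))
    if (n > 1)
      bonds <- rbind(bonds, cbind(off + seq_len(n - 1), off + seq_len(n - 1) + 1L))
    rg <- integer(n)
    for (g in sq$rigid_groups) {
      next_rigid <- next_rigid + 1L
      rg[match(g, sq$numbering)] <- next_rigid
    }
    rigid <- c(rigid, rg)
    phossites <- c(phossites, off + match(sq$phosphosites, sq$numbering))
    if (ci %in% enzyme_chains) {
      as_num <- sq$annotations$active_site
      if (is.null(as_num))
        stop("enzyme chain ", ci, " lacks an active_site annotation")
      active <- c(active, off + match(as_num, sq$numbering))
    }
    off <- off + n
  }
  if (length(enzyme_chains) && length(active) != 3 * length(enzyme_chains))
    stop("each enzyme must annotate exactly 3 active-site residues")
  structure(list(beads = beads, bonds = bonds, rigid = rigid,
                 phosphosites = phossites, active_site = active,
                 enzyme_chains = as.integer(enzyme_chains),
                 chains = chains),
            class = "phos_topology")
}

#' @export
print.phos_topology <- function(x, ...) {
  cat("<phos_topology>", nrow(x$beads), "beads,",
      length(unique(x$beads$chain)), "chains,",
      nrow(x$bonds), "bonds,", length(x$phosphosites), "phosphosites\n")
  invisible(x)
}

#' Random non-overlapping initial chain placement
#'
#' Each chain is grown as a self-avoiding-ish random walk with the bond rest
#' length; chains are translated to random positions rejecting placements
#' that put any bead within `min_dist` of an existing bead (minimum image).
#'
#' @param topology `phos_topology`.
#' @param box cubic box side, nm.
#' @param min_dist overlap threshold, nm.
#' @param r0 bond rest length, nm.
#' @param max_tries placement attempts per chain.
#' @return N x 3 coordinate matrix, nm.
#' @export
random_initial_positions <- function(topology, box, min_dist = 0.6,
                                     r0 = 0.38, max_tries = 200) {
  chains <- split(seq_len(nrow(topology$beads)), topology$beads$chain)
  pos <- matrix(NA_real_, nrow(topology$beads), 3)
  placed <- matrix(numeric(), 0, 3)
  for (idx in chains) {
    n <- length(idx)
    for (try in seq_len(max_tries)) {
      local <- matrix(0, n, 3)
      for (k in seq_len(n)[-1]) {
        for (attempt in 1:100) {
          d <- rnorm(3); d <- d / sqrt(sum(d^2)) * r0
          cand <- local[k - 1, ] + d
          prev <- local[seq_len(k - 2), , drop = FALSE]
          if (nrow(prev) == 0 ||
              min(rowSums(sweep(prev, 2, cand, "-")^2)) > 0.45^2) break
          if (attempt == 100)  # restart the walk from the last bead
            local[k - 1, ] <- local[max(1, k - 5), ] + 0.01 * rnorm(3)
        }
        local[k, ] <- cand
      }
      shift <- runif(3, 0, box)
      cand <- sweep(local, 2, shift, "+")
      ok <- TRUE
      if (nrow(placed)) {
        for (k in seq_len(n)) {
          dd <- sweep(placed, 2, cand[k, ], "-")
          dd <- dd - box * round(dd / box)
          if (min(rowSums(dd^2)) < min_dist^2) { ok <- FALSE; break }
        }
      }
      if (ok) { pos[idx, ] <- cand; placed <- rbind(placed, cand); break }
    }
    if (anyNA(pos[idx, ])) stop("could not place chain without overlap; ",
                                "box too small?")
  }
  pos
}

#' Build the desk-scale toy validation system
#'
#' One two-bead substrate chain - a sticky anchor bead (custom code `"u"`,
#' hydropathy 1, charge 0) bonded to the single phosphosite Ser - plus a
#' small rigid "enzyme": a compact active-site triangle (Asp-Phe-Gly,
#' mirroring the kinase catalytic triad, edge 0.3 nm) with a back bead
#' behind its centroid.  The design makes the four-state projection of the
#' dynamics as Markovian as a desk-scale system allows: binding energy is
#' carried almost entirely by the anchor (the toy overrides Ser and pSer
#' to hydropathy 0.15, so the chemical identity barely couples to binding
#' stability and the bound ensemble has no chemistry-selected internal
#' sub-states), the compact enzyme has a single adsorption site (no slow
#' surface hopping) and the all-three-distances contact condition covers
#' most of the bound ensemble, so phosphorylation chemistry acts uniformly
#' over the bound state.  The toy pSer differs from Ser by a slightly
#' larger repulsive core (sigma 0.60 vs 0.518 nm, charge 0), keeping
#' `dU_P` nonzero but small.  The pair-energy scale `eps_ah = 10` kJ/mol
#' makes the bound state metastable: both bound and unbound states are
#' visited hundreds of times on 1e7-step runs and phosphorylation cycles
#' complete.
#'
#' @param box cubic box side, nm.
#' @param params optional `phos_params`; defaults to the `hps` table with
#'   a raised pair-energy scale, the sticky anchor code `"u"` and the
#'   neutral toy pSer row.
#' @param edge active-site triangle edge length, nm.
#' @param seed RNG seed for the initial placement.
#' @return list with `topology`, `params`, `positions`.
#' @export
build_toy_validation_system <- function(box = 12, params = NULL, edge = 0.3,
                                        seed = 1) {
  if (is.null(params))
    params <- load_parameter_set("hps", overrides = list(
      eps_ah = 10,
      table = data.frame(code = c("u", "S", "p"),
                         mass = c(100, 87.08, 167.05),
                         sigma = c(0.5, 0.518, 0.60),
                         lambda = c(1, 0.15, 0.15),
                         charge = c(0, 0, 0))))
  substrate <- sequence_model(c("u", "S"), offset = 1,
                              phosphosites = 2, name = "toy_substrate")
  enzyme <- sequence_model(c("D", "F", "G", "K"), offset = 149,
                           rigid_groups = list(body = 149:152),
                           annotations = list(active_site = c(149, 150, 151)),
                           name = "toy_enzyme")
  topo <- system_topology(list(substrate, enzyme), params,
                          enzyme_chains = 2L)
  # active-site triangle (edge `edge`) in the z = 0 plane with the back
  # bead behind its centroid, so the docking minimum of the phosphosite on
  # the face normal satisfies the all-three-distances contact criterion
  a <- edge
  tri <- rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0))
  tet <- rbind(tri, c(a / 2, a * sqrt(3) / 6, -0.5))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  pos <- matrix(0, 6, 3)
  pos[1:2, ] <- cbind(c(0, params$bond_r0), 0, 0)
  pos[1:2, ] <- sweep(pos[1:2, ], 2, c(box / 4, box / 2, box / 2), "+")
  pos[3:6, ] <- sweep(tet, 2, c(3 * box / 4, box / 2, box / 2), "+")
  list(topology = topo, params = params, positions = pos)
}

# save/restore .Random.seed without assuming it exists
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}
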