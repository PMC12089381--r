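#' Simulation configuration
#'
#' Collects the Langevin and Monte-Carlo settings.  Defaults follow the
#' production setup of the method: 0.01 ps timestep, 300 K, friction
#' 0.001 ps^-1 (per axis, on velocity), rotational drag 4 ps^-1, one MC
#' check every 200 MD steps, contact criterion 1 nm against all three
#' active-site beads, reservoir trigger at half the box side.
#'
#' @param n_steps number of MD steps.
#' @param dt timestep, ps.
#' @param temperature K.
#' @param friction translational friction, ps^-1.
#' @param rot_friction rotational drag per principal axis, ps^-1.
#' @param box_side cubic box side, nm.
#' @param mc_interval MD steps between MC checks.
#' @param contact_cutoff nm; all three phosphosite/active-site distances
#'   must fall below it.
#' @param reservoir_distance nm; all three distances must exceed it for a
#'   reservoir-exchange attempt.  Defaults to `box_side / 2`.
#' @param reservoir_interval MC checks between reservoir-exchange attempts
#'   (default 1 = every check).  Throttling the attempt frequency does not
#'   change rate ratios, but keeps the identity-exchange timescale above
#'   the MSM lag on desk-scale systems.
#' @param phospho_interval MC checks between phosphorylation attempts
#'   (default 1 = every contact check); same rationale as
#'   `reservoir_interval` for the chemically driven edge.
#' @param dmu_p chemical potential difference ADP - ATP driving the
#'   phosphorylation step, kJ/mol (0 = equilibrium chemistry;
#'   [DMU_PHYSIOLOGICAL] = -48).
#' @param reservoir_enabled logical; validation runs only.
#' @param mc_enabled logical; FALSE gives plain equilibrium MD.
#' @param frame_stride MD steps between recorded frames (the Markov time
#'   base of downstream MSM analysis).
#' @param pos_stride MD steps between recorded position snapshots (0 = off).
#' @param seed integer RNG seed; recorded in every output.
#' @return object of class `phos_config`.
#' @export
sim_config <- function(n_steps = 1e6, dt = 0.01, temperature = 300,
                       friction = 0.001, rot_friction = 4, box_side = 30,
                       mc_interval = 200, contact_cutoff = 1.0,
                       reservoir_distance = box_side / 2,
                       reservoir_interval = 1, phospho_interval = 1,
                       dmu_p = 0,
                       reservoir_enabled = FALSE, mc_enabled = TRUE,
                       frame_stride = 200, pos_stride = 0, seed = 1) {
  stopifnot(dt > 0, mc_interval >= 1, n_steps >= 1, frame_stride >= 1,
            reservoir_interval >= 1, phospho_interval >= 1)
  if (reservoir_distance > box_side / 2)
    stop("reservoir_distance must not exceed half the box side")
  structure(list(n_steps = n_steps, dt = dt, temperature = temperature,
                 friction = friction, rot_friction = rot_friction,
                 box_side = box_side, mc_interval = mc_interval,
                 contact_cutoff = contact_cutoff,
                 reservoir_distance = reservoir_distance,
                 reservoir_interval = as.integer(reservoir_interval),
                 phospho_interval = as.integer(phospho_interval),
                 dmu_p = dmu_p,
                 reservoir_enabled = reservoir_enabled,
                 mc_enabled = mc_enabled, frame_stride = frame_stride,
                 pos_stride = pos_stride, seed = as.integer(seed)),
            class = "phos_config")
}

config_for_cpp <- function(config) {
  list(dt = config$dt, temperature = config$temperature,
       friction = config$friction, rot_friction = config$rot_friction,
       box = config$box_side, n_steps = as.numeric(config$n_steps),
       mc_interval = as.integer(config$mc_interval),
       mc_enabled = isTRUE(config$mc_enabled),
       contact_cutoff = config$contact_cutoff,
       reservoir_distance = config$reservoir_distance,
       reservoir_interval = as.integer(config$reservoir_interval %||% 1L),
       phospho_interval = as.integer(config$phospho_interval %||% 1L),
       dmu_p = config$dmu_p,
       reservoir_enabled = isTRUE(config$reservoir_enabled),
       frame_stride = as.integer(config$frame_stride),
       pos_stride = as.integer(config$pos_stride),
       seed = as.numeric(config$seed))
}

EVENT_KINDS <- c("contact", "phospho_attempt", "phospho_accept",
                 "dephospho_accept", "reservoir_attempt", "reservoir_accept")

#' Run a hybrid MD/MC simulation
#'
#' Advances Langevin dynamics (BAOAB splitting; rigid groups translated and
#' rotated as bodies) in blocks of `mc_interval` steps.  After each block
#' the contact criterion is evaluated; if a phosphosite is in contact with
#' the enzyme active site (all three distances below the cutoff; the
#' closest site only), one Metropolis phosphorylation/dephosphorylation
#' swap is attempted with acceptance `min(1, exp(-beta dU_P - beta dmu_P))`
#' in the forward (Ser to pSer) direction and the sign-flipped exponent in
#' reverse.  With the reservoir enabled, a detailed-balance identity swap
#' is attempted whenever all three distances exceed the reservoir trigger.
#' Bit-reproducible for a fixed seed.
#'
#' @param topology `phos_topology`.
#' @param params `phos_params`.
#' @param config `phos_config`.
#' @param positions N x 3 initial coordinates, nm; defaults to
#'   [random_initial_positions()].
#' @param velocities N x 3 initial velocities, nm/ps, or NULL to draw from
#'   Maxwell-Boltzmann at the configured temperature.
#' @param chem integer per phosphosite, 0 = Ser, 1 = pSer.
#' @param feature_beads bead indices whose minimum active-site distance is
#'   recorded per frame (default: the phosphosites).
#' @return object of class `phos_trajectory`: list with `frames` (time ns,
#'   chem matrix, site contact-criterion distance matrix, feature
#'   distances, potential energy), `events` (data frame), `final`
#'   (positions, velocities, chem), `config`, and optionally `positions`
#'   (3 x N x frames array).
#' @export
run_hybrid_simulation <- function(topology, params, config,
                                  positions = NULL, velocities = NULL,
                                  chem = NULL, feature_beads = NULL) {
  if (is.null(positions))
    positions <- random_initial_positions(topology, config$box_side)
  if (is.null(chem)) chem <- integer(length(topology$phosphosites))
  if (is.null(feature_beads)) feature_beads <- topology$phosphosites
  if (length(topology$active_site) < 3 && (config$mc_enabled))
    stop("topology lacks an active-site annotation")
  codes <- topology$beads$code
  type <- type_index(codes, params)
  psite <- topology$phosphosites
  ser_type <- type_index(rep("S", length(psite)), params)
  pser_type <- type_index(rep("p", length(psite)), params)
  res <- cpp_run_simulation(
    positions, velocities, type, as.integer(topology$rigid),
    topology$bonds - 1L, engine_params(topology, params),
    config_for_cpp(config),
    as.integer(psite - 1L), ser_type, pser_type, as.integer(chem),
    as.integer(topology$active_site - 1L), as.integer(feature_beads - 1L))
  ev <- data.frame(time = res$events$time,
                   kind = EVENT_KINDS[res$events$kind + 1L],
                   site = res$events$site, dU = res$events$dU,
                   prob = res$events$prob,
                   accepted = as.logical(res$events$accepted))
  out <- list(frames = res$frames, events = ev,
              final = list(positions = res$final_pos,
                           velocities = res$final_vel,
                           chem = res$final_chem),
              n_checks = res$n_checks, config = config)
  if (!is.null(res$positions)) out$positions <- res$positions
  class(out) <- "phos_trajectory"
  out
}

#' @export
print.phos_trajectory <- function(x, ...) {
  cat("<phos_trajectory>", length(x$frames$time), "frames,",
      nrow(x$events), "events, seed", x$config$seed, "\n")
  invisible(x)
}

#' Contact detection between phosphosites and the enzyme active site
#'
#' A phosphosite is in contact when all three minimum-image distances to
#' the active-site beads are below the cutoff.  If several sites are in
#' contact, only the closest (smallest mean distance; ties broken by lowest
#' bead index) is returned.
#'
#' @param positions N x 3 coordinates, nm.
#' @param topology `phos_topology` (must annotate the active site).
#' @param cutoff nm.
#' @param box cubic box side, nm.
#' @return the bead index of the selected phosphosite, or `NA_integer_`.
#' @export
detect_contact <- function(positions, topology, cutoff = 1.0, box = Inf) {
  if (length(topology$active_site) < 3)
    stop("topology lacks an active-site annotation")
  best <- NA_integer_; best_mean <- Inf
  for (b in topology$phosphosites) {
    d <- vapply(topology$active_site, function(a) {
      dd <- positions[b, ] - positions[a, ]
      if (is.finite(box)) dd <- dd - box * round(dd / box)
      sqrt(sum(dd^2))
    }, numeric(1))
    if (all(d < cutoff) && mean(d) < best_mean) {
      best <- b; best_mean <- mean(d)
    }
  }
  best
}

#' Single Metropolis phosphorylation attempt
#'
#' Computes `dU_P = U(pSer) - U(Ser)` over the pair interactions of the
#' site bead (exactly the full-system difference, since only that bead
#' changes identity) and accepts with `min(1, exp(-beta (dU_P + dmu_P)))`
#' for Ser to pSer, or the sign-flipped exponent for the reverse.
#'
#' @param positions N x 3 coordinates, nm.
#' @param topology `phos_topology`.
#' @param params `phos_params`.
#' @param site phosphosite bead index.
#' @param chem 0 if the site is currently Ser, 1 if pSer.
#' @param dmu_p kJ/mol.
#' @param box box side, nm.
#' @param u uniform random number in \[0,1) (supply for reproducibility;
#'   defaults to `runif(1)`).
#' @return list `accepted`, `dU_P`, `prob`, `chem` (updated).
#' @export
attempt_phospho_swap <- function(positions, topology, params, site, chem,
                                 dmu_p, box, u = runif(1)) {
  if (!site %in% topology$phosphosites) stop("site is not a phosphosite")
  du <- site_energy_delta(positions, topology, params, site, box)
  beta <- 1 / (GAS_CONSTANT * params$temperature)
  lnA <- if (chem == 0) -beta * (du + dmu_p) else beta * (du + dmu_p)
  prob <- min(1, exp(lnA))
  acc <- u < prob
  list(accepted = acc, dU_P = du, prob = prob,
       chem = if (acc) 1L - as.integer(chem) else as.integer(chem))
}

#' Single reservoir-exchange attempt
#'
#' Detailed-balance Metropolis swap of the substrate chemical identity,
#' allowed only when all three phosphosite/active-site distances exceed the
#' trigger distance.  No chemical driving term.
#'
#' @inheritParams attempt_phospho_swap
#' @param trigger nm; reservoir distance.
#' @return list `attempted`, `accepted`, `dU_D`, `prob`, `chem`.
#' @export
attempt_reservoir_exchange <- function(positions, topology, params, site,
                                       chem, trigger, box, u = runif(1)) {
  if (!site %in% topology$phosphosites) stop("site is not a phosphosite")
  d <- vapply(topology$active_site, function(a) {
    dd <- positions[site, ] - positions[a, ]
    dd <- dd - box * round(dd / box)
    sqrt(sum(dd^2))
  }, numeric(1))
  if (!all(d > trigger))
    return(list(attempted = FALSE, accepted = FALSE, dU_D = NA_real_,
                prob = NA_real_, chem = as.integer(chem)))
  du <- site_energy_delta(positions, topology, params, site, box)
  if (chem == 1) du <- -du      # proposed direction: flip current identity
  beta <- 1 / (GAS_CONSTANT * params$temperature)
  prob <- min(1, exp(-beta * du))
  acc <- u < prob
  list(attempted = TRUE, accepted = acc, dU_D = du, prob = prob,
       chem = if (acc) 1L - as.integer(chem) else as.integer(chem))
}

# U(pSer) - U(Ser) for the site bead over its non-bonded pair interactions.
site_energy_delta <- function(positions, topology, params, site, box) {
  type <- type_index(topology$beads$code, params)
  par <- engine_params(topology, params)
  u_ser <- cpp_site_energy(positions, type, as.integer(topology$rigid),
                           topology$bonds - 1L, par, box, site - 1L,
                           type_index("S", params))
  u_pser <- cpp_site_energy(positions, type, as.integer(topology$rigid),
                            topology$bonds - 1L, par, box, site - 1L,
                            type_index("p", params))
  u_pser - u_ser
}

#' Total potential energy and components
#'
#' @param positions N x 3 coordinates, nm.
#' @param topology `phos_topology`.
#' @param params `phos_params`.
#' @param box box side, nm.
#' @return list `total`, `ah`, `yukawa`, `cation_pi`, `bond`, `force`.
#' @export
total_energy <- function(positions, topology, params, box) {
  type <- type_index(topology$beads$code, params)
  cpp_total_energy(positions, type, as.integer(topology$rigid),
                   topology$bonds - 1L, engine_params(topology, params), box)
}
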