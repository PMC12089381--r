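#' Generate a discrete trajectory from a continuous-time Markov cycle
#'
#' Exact Gillespie sampling of an n-state continuous-time chain with the
#' given rate matrix, recorded at a fixed stride.  The analytic cycle
#' affinity `-RT log(prod k_fwd / prod k_bwd)` over the 1 -> 2 -> ... -> 1
#' cycle is stored alongside, so the generator doubles as the oracle for
#' the local-detailed-balance estimator.
#'
#' @param rates n x n rate matrix (off-diagonal, per unit time); the cycle
#'   edges must all be positive.
#' @param n_steps number of recorded Markov steps.
#' @param stride recording interval in the generator's time unit.
#' @param temperature K (for the stored affinity).
#' @param seed RNG seed.
#' @param init initial state.
#' @return `phos_dtraj` with attributes `affinity` (kJ/mol), `rates`.
#' @export
generate_markov_cycle <- function(rates, n_steps, stride = 1,
                                  temperature = 300, seed = 1, init = 1L) {
  n <- nrow(rates)
  diag(rates) <- 0
  if (any(rates < 0)) stop("rates must be non-negative")
  exit <- rowSums(rates)
  if (any(exit == 0)) stop("absorbing state implied by the rates")
  fwd <- c(seq_len(n - 1), n); bwd <- c(2:n, 1)
  kf <- rates[cbind(fwd, bwd)]; kb <- rates[cbind(bwd, fwd)]
  if (any(kf <= 0) || any(kb <= 0))
    stop("all cycle edges need positive rates for a defined affinity")
  affinity <- -GAS_CONSTANT * temperature * log(prod(kf) / prod(kb))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  out <- integer(n_steps)
  s <- as.integer(init)
  t_now <- 0
  t_next_jump <- rexp(1, exit[s])
  for (i in seq_len(n_steps)) {
    t_rec <- i * stride
    while (t_next_jump <= t_rec) {
      s <- sample.int(n, 1, prob = rates[s, ])
      t_next_jump <- t_next_jump + rexp(1, exit[s])
    }
    out[i] <- s
  }
  structure(out, affinity = affinity, rates = rates, stride = stride,
            class = "phos_dtraj")
}

#' Rate matrix of a driven 4-state cycle with a given affinity
#'
#' Convenience constructor: a detailed-balanced 4-state cycle (uniform
#' rates `k0`) with the 2 -> 3 edge biased symmetrically,
#' `k23 = k0 exp(-dmu/2RT)` and `k32 = k0 exp(+dmu/2RT)`, so the stored
#' affinity equals `dmu` while neither direction saturates the recording
#' stride.
#'
#' @param dmu target cycle affinity, kJ/mol (negative = clockwise driving).
#' @param k0 base rate.
#' @param temperature K.
#' @return 4 x 4 rate matrix.
#' @export
driven_cycle_rates <- function(dmu, k0 = 0.1, temperature = 300) {
  K <- matrix(0, 4, 4)
  fwd <- c(1, 2, 3, 4); bwd <- c(2, 3, 4, 1)
  K[cbind(fwd, bwd)] <- k0
  K[cbind(bwd, fwd)] <- k0
  K[2, 3] <- k0 * exp(-dmu / (2 * GAS_CONSTANT * temperature))
  K[3, 2] <- k0 * exp(dmu / (2 * GAS_CONSTANT * temperature))
  K
}

#' Generate censored exponential first-event times
#'
#' Single-exponential events at rate `r_p`, or binding-conditioned events
#' (the observed time is the sum of an exponential binding step at `r_b`
#' and an exponential phosphorylation step at `r_p`), right-censored at
#' `t_tot`.
#'
#' @param n_sim number of replicas.
#' @param r_p phosphorylation rate (inverse time unit).
#' @param t_tot censoring horizon.
#' @param r_b binding rate; `Inf` for the single-exponential process.
#' @param site site label.
#' @param seed RNG seed.
#' @return `phos_events` table.
#' @export
generate_exponential_events <- function(n_sim, r_p, t_tot, r_b = Inf,
                                        site = "S1", seed = 1) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  t <- rexp(n_sim, r_p)
  if (is.finite(r_b)) t <- t + rexp(n_sim, r_b)
  t[t > t_tot] <- NA
  event_table(seq_len(n_sim), rep(site, n_sim), t, t_tot)
}

#' Generate a droplet-plus-gas bead configuration
#'
#' One dense spherical cluster of chains plus dispersed dilute chains in a
#' periodic cubic box, with per-chain phosphosite flags and ground-truth
#' membership.  The droplet may be centered anywhere, including straddling
#' the boundary.
#'
#' @param n_dense,n_dilute chain counts in the droplet and the gas.
#' @param chain_len beads per chain.
#' @param droplet_radius nm.
#' @param box cubic box side, nm.
#' @param bond_len intra-chain spacing, nm.
#' @param pser_per_chain pSer count assigned per chain (recycled); serines
#'   are every other bead up to the available count.
#' @param center droplet center (length 3, nm); default box middle.
#' @param seed RNG seed.
#' @return list `positions`, `chain`, `species` ("Ser", "pSer", "X"),
#'   `chem` (0/1 per phosphosite bead), `site_chain`, `dense_chains`,
#'   `dilute_chains`.
#' @export
generate_droplet_gas <- function(n_dense = 20, n_dilute = 5, chain_len = 10,
                                 droplet_radius = 4, box = 30,
                                 bond_len = 0.38, pser_per_chain = 0,
                                 center = rep(box / 2, 3), seed = 1) {
  n_chains <- n_dense + n_dilute
  need_vol <- n_chains * chain_len * bond_len^3
  if (need_vol > box^3 / 4) stop("overfilled box")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  pser_per_chain <- rep_len(pser_per_chain, n_chains)
  pos <- matrix(0, n_chains * chain_len, 3)
  chain <- rep(seq_len(n_chains), each = chain_len)
  placed <- matrix(numeric(), 0, 3)
  min_sep <- 0.42                      # keeps starting forces finite
  clear_of <- function(x, other) {
    nrow(other) == 0 ||
      min(rowSums(sweep(other, 2, x, "-")^2)) > min_sep^2
  }
  walk <- function(start, other) {
    p <- matrix(NA_real_, chain_len, 3)
    p[1, ] <- start
    for (k in seq_len(chain_len)[-1]) {
      ok <- FALSE
      for (a in 1:200) {
        d <- rnorm(3)
        cand <- p[k - 1, ] + d / sqrt(sum(d^2)) * bond_len
        if (clear_of(cand, rbind(other, p[seq_len(k - 2), , drop = FALSE]))) {
          p[k, ] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) return(NULL)
    }
    p
  }
  for (c0 in seq_len(n_dense)) {
    repeat {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      rr <- droplet_radius * runif(1)^(1 / 3) * 0.8
      start <- center + u * rr
      if (!clear_of(start, placed)) next
      p <- walk(start, placed)
      if (is.null(p)) next
      d <- sweep(p, 2, center, "-")
      if (max(sqrt(rowSums(d^2))) <= droplet_radius) break
    }
    pos[chain == c0, ] <- p
    placed <- rbind(placed, p)
  }
  for (c0 in n_dense + seq_len(n_dilute)) {
    p <- NULL
    while (is.null(p)) {
      repeat {
        start <- runif(3, 0, box)
        dd <- start - center
        dd <- dd - box * round(dd / box)
        if (sqrt(sum(dd^2)) > droplet_radius + 3) break
      }
      p <- walk(start, placed)
    }
    pos[chain == c0, ] <- p
    placed <- rbind(placed, p)
  }
  pos <- pos - box * floor(pos / box)
  species <- rep("X", nrow(pos))
  chem <- integer(0); site_chain <- integer(0)
  for (c0 in seq_len(n_chains)) {
    idx <- which(chain == c0)
    ser_idx <- idx[seq(1, chain_len, by = 2)]
    np <- min(pser_per_chain[c0], length(ser_idx))
    st <- c(rep(1L, np), rep(0L, length(ser_idx) - np))
    species[ser_idx] <- ifelse(st == 1, "pSer", "Ser")
    chem <- c(chem, st)
    site_chain <- c(site_chain, rep(c0, length(ser_idx)))
  }
  list(positions = pos, chain = chain, species = species, chem = chem,
       site_chain = site_chain, dense_chains = seq_len(n_dense),
       dilute_chains = n_dense + seq_len(n_dilute))
}
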