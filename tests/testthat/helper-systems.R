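# Shared builders and cached simulation results for the test suite.
# Everything is generated in code at test time; nothing is read from disk
# except the packaged fixtures.

RT300 <- 0.00831446 * 300

# toy parameter set used across engine tests (see the methods vignette for
# the rationale behind the toy's pair-energy scale and bead overrides)
toy_params <- function(eps = 10) {
  load_parameter_set("hps", overrides = list(
    eps_ah = eps,
    table = data.frame(code = c("u", "S", "p"),
                       mass = c(100, 87.08, 167.05),
                       sigma = c(0.5, 0.518, 0.60),
                       lambda = c(1, 0.15, 0.15),
                       charge = c(0, 0, 0))))
}

# small random free-bead system for energy bookkeeping tests
random_system <- function(n = 8, box = 6, seed = 1, codes = NULL) {
  set.seed(seed)
  if (is.null(codes))
    codes <- sample(c("G", "S", "F", "K", "D", "A"), n, replace = TRUE)
  chains <- list(sequence_model(codes, name = "rand"))
  topo <- system_topology(chains, load_parameter_set("modified_hps"))
  pos <- matrix(runif(n * 3, 0, box), n, 3)
  # pull bonded neighbours to sane bond lengths
  for (k in 2:n) {
    d <- pos[k, ] - pos[k - 1, ]
    pos[k, ] <- pos[k - 1, ] + 0.4 * d / sqrt(sum(d^2))
  }
  list(topology = topo, positions = pos, box = box)
}

# session cache for expensive simulations shared between tests
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# Toy validation run at a given driving value; settings documented in the
# methods vignette (friction 1/ps for a 2-bead substrate, attempt throttles
# keeping every cycle edge slower than the MSM lag, reservoir trigger just
# outside the interaction range so identity exchange is uniform over the
# unbound ensemble, molecule-level binding coordinate).
TOY_LAG <- 25

toy_validation_run <- function(dmu, n_steps = 8e7, seed = 42) {
  cached(sprintf("toy_dmu_%g_%g_%d", dmu, n_steps, seed), {
    sys <- build_toy_validation_system(box = 12)
    cfg <- sim_config(n_steps = n_steps, box_side = 12, friction = 1,
                      reservoir_enabled = TRUE, reservoir_distance = 2.5,
                      reservoir_interval = 20, phospho_interval = 60,
                      dmu_p = dmu, frame_stride = 200, seed = seed)
    tr <- run_hybrid_simulation(sys$topology, sys$params, cfg,
                                positions = sys$positions,
                                feature_beads = c(1, 2))
    dmol <- pmin(tr$frames$features[, 1], tr$frames$features[, 2])
    bound <- assign_two_states(dmol, cutoff = 1.8, soft_margin = 0.15)
    dtraj <- build_cycle_trajectory(bound, tr$frames$chem[, 1],
                                    burn_in = 100)
    list(traj = tr, dtraj = dtraj)
  })
}
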