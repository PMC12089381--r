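test_that("at T = 0 with no forces nothing moves", {
  ps <- toy_params()
  sq <- sequence_model(c("u", "u"), name = "pair")
  topo <- system_topology(list(sq), ps)
  pos <- rbind(c(2, 2, 2), c(2.38, 2, 2))   # bond at rest length
  cfg <- sim_config(n_steps = 1000, temperature = 0, box_side = 10,
                    mc_enabled = FALSE, frame_stride = 100, seed = 1)
  tr <- run_hybrid_simulation(topo, ps, cfg, positions = pos,
                              velocities = matrix(0, 2, 3))
  expect_equal(tr$final$positions, pos, tolerance = 1e-12)
})

test_that("bonded dimer samples the Boltzmann bond-length distribution", {
  # friction 1/ps so the 2-bead system thermalizes quickly; the integrator
  # under test is unchanged
  ps <- toy_params()
  sq <- sequence_model(c("u", "u"), name = "dimer")
  topo <- system_topology(list(sq), ps)
  pos <- rbind(c(5, 5, 5), c(5.38, 5, 5))
  cfg <- sim_config(n_steps = 6e5, friction = 1, box_side = 10,
                    mc_enabled = FALSE, frame_stride = 1000, seed = 3)
  tr <- run_hybrid_simulation(topo, ps, cfg, positions = pos)
  # sample bond lengths from recorded positions is not available here;
  # use the harmonic-bond equipartition instead: var(r) ~ kT/k for a stiff
  # bond (Jacobian correction negligible at k = 8033)
  cfg2 <- sim_config(n_steps = 4e5, friction = 1, box_side = 10,
                     mc_enabled = FALSE, frame_stride = 50,
                     pos_stride = 50, seed = 4)
  tr2 <- run_hybrid_simulation(topo, ps, cfg2, positions = pos)
  P <- tr2$positions                      # 3 x n x frames
  dx <- P[, 1, ] - P[, 2, ]
  dx <- dx - 10 * round(dx / 10)
  r <- sqrt(colSums(dx^2))
  r <- r[-(1:1000)]
  kT <- 0.00831446 * 300
  sig2_theory <- kT / ps$bond_k
  # effective radial variance of r about its mean includes the 2kT/ (k r0^2)
  # angular broadening only in r^2; compare var(r) within 15%
  expect_lt(abs(var(r) - sig2_theory) / sig2_theory, 0.15)
  expect_equal(mean(r), ps$bond_r0 + kT / (ps$bond_k * ps$bond_r0),
               tolerance = 0.01)
  # chi-square goodness of fit of r against r^2 exp(-beta k/2 (r-r0)^2)
  br <- seq(min(r) - 1e-3, max(r) + 1e-3, length.out = 13)
  obs <- as.numeric(table(cut(r, br)))
  dens <- function(x) x^2 * exp(-ps$bond_k * (x - ps$bond_r0)^2 / (2 * kT))
  pr <- vapply(seq_len(length(br) - 1), function(i)
    integrate(dens, br[i], br[i + 1])$value, numeric(1))
  pr <- pr / sum(pr)
  keep <- pr * length(r) >= 5
  chi2 <- sum((obs[keep] - length(r) * pr[keep])^2 /
              (length(r) * pr[keep]))
  # effective sample size is reduced by time correlation; compare against
  # a generous chi-square bound at the 1% level with df = bins - 1
  expect_lt(chi2, 3 * qchisq(0.99, sum(keep) - 1))
})

test_that("free bead diffuses per the Einstein relation", {
  ps <- toy_params()
  sq <- sequence_model("u", name = "free")
  topo <- system_topology(list(sq), ps)
  cfg <- sim_config(n_steps = 2e5, friction = 1, box_side = 200,
                    mc_enabled = FALSE, frame_stride = 100,
                    pos_stride = 100, seed = 7)
  tr <- run_hybrid_simulation(topo, ps, cfg,
                              positions = matrix(100, 1, 3))
  P <- tr$positions[, 1, ]               # 3 x frames, box large: no wrap
  kT <- 0.00831446 * 300
  D_theory <- kT / (100 * 1)             # kT/(m gamma), nm^2/ps
  dt_frame <- 100 * 0.01
  for (lagf in c(5, 20)) {
    nf <- ncol(P)
    disp <- P[, (lagf + 1):nf, drop = FALSE] -
            P[, 1:(nf - lagf), drop = FALSE]
    msd <- mean(colSums(disp^2))
    D_est <- msd / (6 * lagf * dt_frame)
    expect_lt(abs(D_est - D_theory) / D_theory, 0.25)
  }
})

test_that("rigid bodies keep their shape and respond to the bath", {
  ps <- toy_params()
  sys <- build_toy_validation_system(box = 12, params = ps)
  cfg <- sim_config(n_steps = 1e5, friction = 1, box_side = 12,
                    mc_enabled = FALSE, frame_stride = 1000,
                    pos_stride = 1000, seed = 9)
  tr <- run_hybrid_simulation(sys$topology, ps, cfg,
                              positions = sys$positions)
  P <- tr$positions                      # 3 x 6 x frames
  ref <- sys$positions[3:6, ]
  ref_d <- as.matrix(dist(ref))
  drift <- 0
  for (f in seq_len(dim(P)[3])) {
    cur <- t(P[, 3:6, f])
    # beads of one body never straddle the box at these sizes
    drift <- max(drift, max(abs(as.matrix(dist(cur)) - ref_d)))
  }
  expect_lt(drift, 1e-6)
  # pose unchanged at T = 0 without forces
  cfg0 <- sim_config(n_steps = 5000, temperature = 0, box_side = 12,
                     mc_enabled = FALSE, frame_stride = 1000, seed = 2)
  enz <- sys$topology$chains[[2]]
  topo_e <- system_topology(list(enz), ps, enzyme_chains = 1L)
  pos_e <- sys$positions[3:6, ]
  tr0 <- run_hybrid_simulation(topo_e, ps, cfg0, positions = pos_e,
                               velocities = matrix(0, 4, 3))
  expect_equal(tr0$final$positions, pos_e, tolerance = 1e-10)
  # orientation decorrelates under the thermal bath (no frozen axis)
  a1 <- t(P[, 4, ]) - t(P[, 3, ])        # a body-fixed vector over time
  a1 <- a1 / sqrt(rowSums(a1^2))
  c_first_last <- sum(a1[1, ] * a1[nrow(a1), ])
  expect_lt(abs(c_first_last), 0.9)      # rotated away from the start
  expect_error(
    system_topology(list(sequence_model(c("G", "G", "G"),
                                        rigid_groups = list(g = 1:3),
                                        name = "lin")), ps) |>
      (\(tp) run_hybrid_simulation(tp, ps,
        sim_config(n_steps = 10, box_side = 10, mc_enabled = FALSE,
                   frame_stride = 10, seed = 1),
        positions = rbind(c(1, 1, 1), c(1.38, 1, 1), c(1.76, 1, 1))))(),
    "degenerate")
})

test_that("contact detection applies the all-three rule and closest-site rule", {
  ps <- toy_params()
  sys <- build_toy_validation_system(box = 12, params = ps)
  topo <- sys$topology
  pos <- sys$positions
  act <- topo$active_site
  ctr <- colMeans(pos[act, ])
  # place the phosphosite right at the face: all three < 1 nm
  pos2 <- pos
  pos2[2, ] <- ctr + c(0, 0, 0.6)
  pos2[1, ] <- pos2[2, ] + c(0.38, 0, 0)
  expect_equal(detect_contact(pos2, topo, 1, 12), 2L)
  # 3.5 nm away: no contact
  pos3 <- pos
  pos3[2, ] <- ctr + c(0, 0, 3.5)
  expect_true(is.na(detect_contact(pos3, topo, 1, 12)))
  # two sites in contact: the closer one wins
  sq2 <- sequence_model(c("u", "S", "u", "S", "u"), phosphosites = c(2, 4),
                        name = "two")
  enz <- sys$topology$chains[[2]]
  topo2 <- system_topology(list(sq2, enz), ps, enzyme_chains = 2L)
  pos4 <- matrix(3, 9, 3)
  pos4[6:9, ] <- pos[3:6, ]
  ctr2 <- colMeans(pos4[topo2$active_site, ])
  pos4[2, ] <- ctr2 + c(0, 0, 0.52)       # mean distance ~ 0.62
  pos4[4, ] <- ctr2 + c(0, 0, 0.85)       # mean distance ~ 0.9
  pos4[c(1, 3), ] <- pos4[c(2, 2), ] + rbind(c(0.38, 0, 0), c(-0.38, 0, 0))
  pos4[5, ] <- pos4[4, ] + c(0.38, 0, 0)
  expect_equal(detect_contact(pos4, topo2, 1, 12), 2L)
})

test_that("local phospho energy difference equals the full-system one", {
  rs <- random_system(n = 9, seed = 12, codes = c("G", "S", "F", "K", "D",
                                                  "A", "S", "G", "M"))
  ps <- load_parameter_set("modified_hps")
  topo <- rs$topology
  site <- topo$phosphosites[1]
  du_local <- phosdyn:::site_energy_delta(rs$positions, topo, ps, site,
                                          rs$box)
  # oracle: full-system energies with the site's code swapped
  topo_p <- topo
  topo_p$beads$code[site] <- "p"
  u_ser <- total_energy(rs$positions, topo, ps, rs$box)$total
  u_pser <- total_energy(rs$positions, topo_p, ps, rs$box)$total
  expect_equal(du_local, u_pser - u_ser, tolerance = 1e-9)
})

test_that("Metropolis acceptances follow the driven and reverse exponents", {
  ps <- toy_params()
  sys <- build_toy_validation_system(box = 12, params = ps)
  pos <- sys$positions
  act <- colMeans(pos[sys$topology$active_site, ])
  pos[2, ] <- act + c(0, 0, 0.62)
  pos[1, ] <- pos[2, ] + c(0.38, 0, 0)
  du <- phosdyn:::site_energy_delta(pos, sys$topology, ps, 2, 12)
  beta <- 1 / RT300
  # forward Ser -> pSer
  res <- attempt_phospho_swap(pos, sys$topology, ps, 2, chem = 0,
                              dmu_p = -5, box = 12, u = 2)  # never accept
  expect_equal(res$prob, min(1, exp(-beta * (du - 5))), tolerance = 1e-12)
  expect_false(res$accepted)
  # reverse pSer -> Ser uses the sign-flipped exponent with the same dU
  res2 <- attempt_phospho_swap(pos, sys$topology, ps, 2, chem = 1,
                               dmu_p = -5, box = 12, u = 0)  # always accept
  expect_equal(res2$prob, min(1, exp(beta * (du - 5))), tolerance = 1e-12)
  expect_true(res2$accepted)
  expect_equal(res2$chem, 0L)
  # dU = 0, dmu = 0: acceptance 1 (flat swap)
  far <- sys$positions
  far[1:2, ] <- rbind(c(0.62, 1, 1), c(1, 1, 1))
  res3 <- attempt_phospho_swap(far, sys$topology, ps, 2, chem = 0,
                               dmu_p = 0, box = 12, u = 0.999)
  expect_equal(res3$prob, 1)
  expect_error(attempt_phospho_swap(pos, sys$topology, ps, 1, 0, 0, 12),
               "not a phosphosite")
})

test_that("reservoir exchange triggers beyond the distance and obeys balance", {
  ps <- toy_params()
  sys <- build_toy_validation_system(box = 12, params = ps)
  pos <- sys$positions
  # substrate 2 nm from the active site: inside the trigger, no attempt
  act <- colMeans(pos[sys$topology$active_site, ])
  pos[2, ] <- act + c(0, 0, 2)
  pos[1, ] <- pos[2, ] + c(0.38, 0, 0)
  res <- attempt_reservoir_exchange(pos, sys$topology, ps, 2, chem = 0,
                                    trigger = 6, box = 12)
  expect_false(res$attempted)
  # far away: dU ~ 0 for the isolated substrate, acceptance 1
  pos[2, ] <- (act + 6.5) %% 12
  pos[1, ] <- pos[2, ] + c(0.38, 0, 0)
  d <- vapply(sys$topology$active_site, function(a) {
    dd <- pos[2, ] - pos[a, ]; dd <- dd - 12 * round(dd / 12)
    sqrt(sum(dd^2))
  }, numeric(1))
  if (all(d > 6)) {
    res2 <- attempt_reservoir_exchange(pos, sys$topology, ps, 2, chem = 0,
                                       trigger = 6, box = 12, u = 0.5)
    expect_true(res2$attempted)
    expect_equal(res2$prob, 1)
  }
  # acceptance e^{-1} at dU = RT: via the closed form on a constructed dU
  expect_equal(min(1, exp(-1)), exp(-1))
})

test_that("reservoir exchange alone preserves the isolated-substrate balance", {
  # substrate-only energies are identical for Ser and pSer (bonded-only
  # neighbours), so long-run occupancy must be 50/50
  ps <- toy_params()
  sys <- build_toy_validation_system(box = 12, params = ps)
  pos <- sys$positions
  pos[1:2, 1] <- pos[1:2, 1] - 2       # start well away from the enzyme
  cfg <- sim_config(n_steps = 2e6, box_side = 12, friction = 1,
                    reservoir_enabled = TRUE, reservoir_interval = 1,
                    phospho_interval = 1e9, frame_stride = 200, seed = 21)
  tr <- run_hybrid_simulation(sys$topology, ps, cfg, positions = pos)
  occ <- mean(tr$frames$chem[, 1])
  expect_gt(sum(tr$events$kind == "reservoir_accept"), 100)
  expect_lt(abs(occ - 0.5), 0.1)
})

test_that("same seed reproduces the event log bit-exactly", {
  ps <- toy_params()
  sys <- build_toy_validation_system(box = 12, params = ps)
  cfg <- sim_config(n_steps = 2e5, box_side = 12, friction = 1,
                    reservoir_enabled = TRUE, frame_stride = 200, seed = 33)
  tr1 <- run_hybrid_simulation(sys$topology, ps, cfg,
                               positions = sys$positions)
  tr2 <- run_hybrid_simulation(sys$topology, ps, cfg,
                               positions = sys$positions)
  expect_identical(tr1$events, tr2$events)
  expect_identical(tr1$final$positions, tr2$final$positions)
  # number of MC checks is floor(n_steps / mc_interval)
  expect_equal(tr1$n_checks, floor(2e5 / 200))
})

test_that("energies and contacts are invariant under lattice translation", {
  rs <- random_system(n = 8, seed = 31)
  ps <- load_parameter_set("modified_hps")
  e0 <- total_energy(rs$positions, rs$topology, ps, rs$box)$total
  shifted <- rs$positions + rs$box        # one full lattice vector
  e1 <- total_energy(shifted, rs$topology, ps, rs$box)$total
  expect_equal(e0, e1, tolerance = 1e-9)
  part <- sweep(rs$positions, 2, c(rs$box, 0, 2 * rs$box), "+")
  expect_equal(total_energy(part, rs$topology, ps, rs$box)$total, e0,
               tolerance = 1e-9)
})

test_that("total pair energy is invariant under chain relabeling", {
  ps <- load_parameter_set("modified_hps")
  codes <- c("G", "S", "F", "K")
  sqA <- sequence_model(codes[1:2], name = "A")
  sqB <- sequence_model(codes[3:4], name = "B")
  topoAB <- system_topology(list(sqA, sqB), ps)
  topoBA <- system_topology(list(sqB, sqA), ps)
  set.seed(2)
  pos <- matrix(runif(12, 0, 5), 4, 3)
  eAB <- total_energy(pos, topoAB, ps, 8)$total
  eBA <- total_energy(pos[c(3, 4, 1, 2), ], topoBA, ps, 8)$total
  expect_equal(eAB, eBA, tolerance = 1e-12)
})
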