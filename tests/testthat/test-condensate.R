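test_that("clustering follows the neighbor-count core rule", {
  # two 3-bead chains, closest inter-chain distance 0.9 nm -> one cluster
  p1 <- rbind(c(1, 1, 1), c(1.38, 1, 1), c(1.76, 1, 1))
  p2 <- sweep(p1, 2, c(0, 0.9, 0), "+")
  cl <- cluster_beads(rbind(p1, p2), box = 20, eps = 1, n_min = 2,
                      chain = rep(1:2, each = 3))
  expect_equal(max(cl$labels), 1)
  # at 1.2 nm separation: two clusters
  p2b <- sweep(p1, 2, c(0, 1.2, 0), "+")
  cl2 <- cluster_beads(rbind(p1, p2b), box = 20, eps = 1, n_min = 2,
                       chain = rep(1:2, each = 3))
  expect_equal(max(cl2$labels), 2)
  expect_error(cluster_beads(matrix(numeric(), 0, 3), 10), "empty")
})

test_that("pairs split across the periodic boundary join one cluster", {
  # brute-force minimum-image oracle built into the expectation: wrapped
  # distance 0.5 nm across the x face
  pos <- rbind(c(0.2, 5, 5), c(9.7, 5, 5), c(0.2, 5.7, 5), c(9.7, 5.7, 5))
  cl <- cluster_beads(pos, box = 10, eps = 1, n_min = 2)
  expect_equal(length(unique(cl$labels)), 1)
  expect_true(all(cl$labels == cl$labels[1]))
})

test_that("condensate fraction uses any-bead chain membership", {
  # 5 hand-built chains: 3 clustered, 2 isolated
  mk_chain <- function(orig) sweep(rbind(c(0, 0, 0), c(0.4, 0, 0)), 2,
                                   orig, "+")
  pos <- rbind(mk_chain(c(2, 2, 2)), mk_chain(c(2.5, 2.5, 2)),
               mk_chain(c(2, 3, 2)), mk_chain(c(8, 8, 8)),
               mk_chain(c(14, 14, 14)))
  cl <- cluster_beads(pos, box = 20, eps = 1, n_min = 1,
                      chain = rep(1:5, each = 2))
  expect_equal(condensate_fraction(cl), 3 / 5)
  # all isolated: largest cluster holds one chain
  pos2 <- rbind(mk_chain(c(2, 2, 2)), mk_chain(c(8, 8, 8)),
                mk_chain(c(14, 14, 14)))
  cl2 <- cluster_beads(pos2, box = 20, eps = 1, n_min = 1,
                       chain = rep(1:3, each = 2))
  expect_equal(condensate_fraction(cl2), 1 / 3)
})

test_that("enzyme attachment counts enzymes sharing the substrate cluster", {
  gen <- generate_droplet_gas(n_dense = 10, n_dilute = 0, chain_len = 8,
                              droplet_radius = 2.2, box = 25, seed = 2)
  # pick two droplet beads that are certainly core (>= 3 close neighbours)
  deg <- vapply(seq_len(nrow(gen$positions)), function(i) {
    dd <- sweep(gen$positions, 2, gen$positions[i, ], "-")
    sum(rowSums(dd^2) <= 0.9^2) - 1L
  }, integer(1))
  anchors <- which(deg >= 3)[1:2]
  # 5 "enzymes": 2 touching the droplet at the anchors, 3 far away
  enz <- rbind(gen$positions[anchors[1], ] + c(0.5, 0, 0),
               gen$positions[anchors[2], ] + c(0, 0.5, 0),
               c(20, 20, 20), c(22, 3, 20), c(3, 22, 20))
  pos <- rbind(gen$positions, enz)
  chain <- c(gen$chain, 10 + (1:5))
  cl <- cluster_beads(pos, box = 25, eps = 1, n_min = 2, chain = chain)
  expect_equal(enzyme_attachment(cl, 10 + (1:5)), 0.4)
  expect_error(enzyme_attachment(cl, integer()), "no enzymes")
})

test_that("periodic center matches the unwrapped-coordinates oracle", {
  set.seed(4)
  blob <- matrix(rnorm(300, 0, 1.5), 100, 3)
  box <- 20
  # wholly inside the box: circular mean equals the arithmetic mean
  inside <- sweep(blob, 2, c(10, 10, 10), "+")
  expect_equal(condensate_center(inside, box), colMeans(inside),
               tolerance = 1e-3)
  # straddling a face: compare with unwrapped mean re-wrapped
  strad <- sweep(blob, 2, c(0.5, 10, 10), "+")
  wrapped <- strad - box * floor(strad / box)
  ctr <- condensate_center(wrapped, box)
  oracle <- colMeans(strad) %% box
  expect_equal(ctr, oracle, tolerance = 1e-2)
  # single bead: itself
  expect_equal(condensate_center(matrix(c(3, 4, 5), 1), box), c(3, 4, 5))
  # invariance under lattice translation
  shift <- wrapped + box
  expect_equal(condensate_center(shift - box * floor(shift / box), box),
               ctr, tolerance = 1e-9)
})

test_that("radial densities normalize by shell volume and conserve counts", {
  set.seed(6)
  box <- 12
  pos <- matrix(runif(3000 * 3, 0, box), ncol = 3)
  prof <- radial_density(pos, rep("X", 3000), center = rep(box / 2, 3),
                         box = box, bin_width = 0.5, r_max = 5)
  # uniform beads: flat profile at the bulk density (ignore tiny first bins)
  bulk <- 3000 / box^3
  expect_lt(max(abs(prof$X[-(1:3)] - bulk)) / bulk, 0.25)
  # conservation: sum density x volume = counts within r_max
  vol <- 4 * pi / 3 * (prof$r_out^3 - prof$r_in^3)
  d <- sweep(pos, 2, rep(box / 2, 3), "-")
  d <- d - box * round(d / box)
  n_in <- sum(sqrt(rowSums(d^2)) < max(prof$r_out))
  expect_equal(sum(prof$X * vol), n_in, tolerance = 1e-9)
  expect_error(radial_density(pos, rep("X", 3000), rep(6, 3), box,
                              bin_width = 0), "zero bin width")
})

test_that("pSer share per shell follows the constructed ratio", {
  prof <- data.frame(r_in = 0:2, r_out = 1:3,
                     Ser = c(2, 0, 1), pSer = c(1, 0, 1))
  fr <- pser_fraction_profile(prof)
  expect_equal(fr, c(1 / 3, NA, 0.5))
  noP <- data.frame(Ser = c(1, 2), pSer = c(0, 0))
  expect_equal(pser_fraction_profile(noP), c(0, 0))
})

test_that("per-chain pSer distributions split by phase and conserve counts", {
  gen <- generate_droplet_gas(n_dense = 6, n_dilute = 4, chain_len = 6,
                              droplet_radius = 1.8, box = 25,
                              pser_per_chain = c(rep(0, 6), rep(2, 4)),
                              seed = 8)
  cl <- cluster_beads(gen$positions, box = 25, eps = 1, n_min = 2,
                      chain = gen$chain)
  dist <- pser_per_chain_distribution(gen$chem, gen$site_chain, cl)
  expect_equal(sum(dist$dense) + sum(dist$dilute), 10)
  # dense phase chains are unphosphorylated in this construction
  expect_equal(unname(dist$dense["0"]), 6)
  expect_equal(unname(dist$dilute["2"]), 4)
})

test_that("energy decomposition sums to the total group-partner energy", {
  rs <- random_system(n = 10, seed = 3)
  group <- 1:4; partner <- 6:10
  dec <- energy_decomposition(rs$positions, rs$topology,
                              load_parameter_set("modified_hps"), rs$box,
                              group, partner)
  ps <- load_parameter_set("modified_hps")
  # direct oracle: explicit double loop over the R pair potentials
  codes <- rs$topology$beads$code
  tot <- 0
  for (i in group) for (j in partner) {
    r <- sqrt(sum((rs$positions[i, ] - rs$positions[j, ] -
                   rs$box * round((rs$positions[i, ] - rs$positions[j, ]) /
                                  rs$box))^2))
    pp <- pair_params(i, j, rs$topology, ps)
    tot <- tot + ashbaugh_hatch_energy(r, pp$sigma_ij,
                                       pp$scale * pp$lambda_ij,
                                       ps$eps_ah, ps$cutoff_ah) +
      yukawa_energy(r, ps$table$charge[match(codes[i], ps$table$code)],
                    ps$table$charge[match(codes[j], ps$table$code)],
                    ps$debye_length, ps$dielectric, ps$cutoff_yukawa) +
      cation_pi_energy(r, codes[i], codes[j], ps) * pp$scale
  }
  expect_equal(sum(dec$ah + dec$yukawa + dec$cation_pi), tot,
               tolerance = 1e-9)
  # partner set without charges has a zero Yukawa component
  expect_error(energy_decomposition(rs$positions, rs$topology, ps, rs$box,
                                    1:4, 4:8), "overlap")
})

test_that("dissolution onset finds the first sustained drop", {
  fr <- c(1, 1, 0.99, 1, 0.98, 0.9, 0.8, 0.7)
  expect_equal(dissolution_onset(fr, plateau_frames = 4), 6)
  expect_true(is.na(dissolution_onset(rep(1, 10))))
})
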