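#' Two-state (bound/unbound) assignment from distance features
#'
#' Produces hard bound/unbound labels from per-frame distance features,
#' then relabels low-confidence frames (soft probability in (0.30, 0.70))
#' by transition-based state assignment: an uncertain stretch between two
#' firmly assigned frames carries the previous firm state up to the
#' midpoint and the next firm state after it; leading/trailing stretches
#' take the nearest firm state.
#'
#' Methods:
#' * `"threshold"`: bound iff the contact-criterion distance (first feature
#'   column, or the row minimum for multi-column features) is below
#'   `cutoff`; the soft probability ramps linearly across
#'   `cutoff * (1 +/- soft_margin)`.
#' * `"vamp_linear"`: projects the features on the dominant non-trivial
#'   singular function of the whitened time-lagged correlation (a linear
#'   VAMP approximation), splits at the midpoint between the two
#'   1-d cluster centers, with a logistic soft probability.
#'
#' @param features numeric matrix (frames x distances) or vector.
#' @param method `"threshold"` or `"vamp_linear"`.
#' @param cutoff nm, threshold method.
#' @param soft_margin relative half-width of the uncertain band.
#' @param lag lag (frames) for the VAMP correlations.
#' @return logical vector, TRUE = bound.
#' @export
assign_two_states <- function(features, method = c("threshold", "vamp_linear"),
                              cutoff = 1.0, soft_margin = 0.2, lag = 10) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (method == "threshold") {
    d <- if (ncol(features) == 1) features[, 1] else apply(features, 1, min)
    lo <- cutoff * (1 - soft_margin); hi <- cutoff * (1 + soft_margin)
    p_bound <- pmin(1, pmax(0, (hi - d) / (hi - lo)))
  } else {
    z <- vamp_projection(features, lag)
    km <- stats::kmeans(matrix(z, ncol = 1),
                        centers = matrix(range(z), 2, 1), iter.max = 50)
    cen <- sort(km$centers[, 1])
    scale <- max(1e-12, diff(cen) / 8)
    p_lower <- 1 / (1 + exp((z - mean(cen)) / scale))
    # bound = the cluster with smaller mean distance feature
    dmean <- if (ncol(features) == 1) features[, 1] else rowMeans(features)
    lower_is_bound <- mean(dmean[z < mean(cen)]) < mean(dmean[z >= mean(cen)])
    p_bound <- if (lower_is_bound) p_lower else 1 - p_lower
  }
  labels <- p_bound >= 0.5
  labels <- tbsa_filter(labels, p_bound)
  if (all(labels) || all(!labels))
    stop("trajectory never visits one of the two states; ",
         "refusing to build a single-state MSM")
  labels
}

# dominant non-trivial linear VAMP singular function of the features
vamp_projection <- function(X, lag) {
  n <- nrow(X)
  if (n <= lag + 1) stop("trajectory shorter than the VAMP lag")
  X0 <- X[seq_len(n - lag), , drop = FALSE]
  Xt <- X[(lag + 1):n, , drop = FALSE]
  mu0 <- colMeans(X0); mut <- colMeans(Xt)
  X0 <- sweep(X0, 2, mu0); Xt <- sweep(Xt, 2, mut)
  C00 <- crossprod(X0) / nrow(X0)
  Ctt <- crossprod(Xt) / nrow(Xt)
  C0t <- crossprod(X0, Xt) / nrow(X0)
  W0 <- mat_invsqrt(C00); Wt <- mat_invsqrt(Ctt)
  K <- W0 %*% C0t %*% Wt
  sv <- svd(K)
  proj <- sweep(as.matrix(X), 2, mu0) %*% (W0 %*% sv$u[, 1])
  as.numeric(proj)
}

mat_invsqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep)) %*%
    t(e$vectors[, keep, drop = FALSE])
}

# transition-based relabeling of frames with soft probability in (0.30, 0.70)
tbsa_filter <- function(labels, p, lower = 0.30, upper = 0.70) {
  uncertain <- p > lower & p < upper
  if (!any(uncertain)) return(labels)
  if (all(uncertain)) stop("no firmly assigned frames for state assignment")
  runs <- rle(uncertain)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  n <- length(labels)
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    prev <- if (i0 > 1) labels[i0 - 1L] else NA
    nxt <- if (i1 < n) labels[i1 + 1L] else NA
    if (is.na(prev)) labels[i0:i1] <- nxt
    else if (is.na(nxt) || prev == nxt) labels[i0:i1] <- prev
    else {                       # split at the transition midpoint
      mid <- i0 + (i1 - i0) %/% 2L
      labels[i0:mid] <- prev
      if (mid < i1) labels[(mid + 1L):i1] <- nxt
    }
  }
  labels
}

#' Discretize a trajectory onto the 4-state phosphorylation cycle
#'
#' States: 1 = unbound/Ser, 2 = bound/Ser, 3 = bound/pSer, 4 = unbound/pSer.
#'
#' @param bound logical per frame (TRUE = bound).
#' @param chem integer per frame (0 = Ser, 1 = pSer).
#' @param markov_step MD steps per frame (bookkeeping only).
#' @param burn_in number of leading frames to discard.
#' @return object of class `phos_dtraj` (integer states with attributes).
#' @export
build_cycle_trajectory <- function(bound, chem, markov_step = 1e4,
                                   burn_in = 0) {
  if (length(bound) != length(chem)) stop("length mismatch")
  s <- ifelse(chem == 0, ifelse(bound, 2L, 1L), ifelse(bound, 3L, 4L))
  if (burn_in > 0) s <- s[-seq_len(burn_in)]
  structure(s, markov_step = markov_step, class = "phos_dtraj")
}

#' Non-reversible maximum-likelihood transition matrix
#'
#' Sliding-window transition counts at lag `tau`;
#' `T_ij = C_ij / sum_j C_ij`.  No reversibility constraint.
#'
#' @param dtraj integer state sequence, or list of sequences.
#' @param tau lag, Markov steps.
#' @param n_states number of states (default: max observed).
#' @return object of class `phos_msm`: `T` (row-stochastic), `C` (counts),
#'   `tau`, `eigenvalues`, `stationary`.
#' @export
estimate_transition_matrix <- function(dtraj, tau, n_states = NULL) {
  trajs <- if (is.list(dtraj)) dtraj else list(dtraj)
  if (is.null(n_states)) n_states <- max(vapply(trajs, max, numeric(1)))
  C <- matrix(0, n_states, n_states)
  for (s in trajs) {
    s <- as.integer(s)
    n <- length(s)
    if (n <= tau) stop("trajectory shorter than the lag")
    from <- s[seq_len(n - tau)]
    to <- s[(tau + 1):n]
    for (k in seq_along(from)) C[from[k], to[k]] <- C[from[k], to[k]] + 1
  }
  rs <- rowSums(C)
  if (any(rs == 0))
    stop("state(s) ", paste(which(rs == 0), collapse = ", "),
         " have no outgoing counts at lag ", tau,
         " (disconnected at this lag)")
  Tm <- C / rs
  ev <- eigen(Tm)
  ord <- order(Mod(ev$values), decreasing = TRUE)
  vals <- ev$values[ord]
  pi_left <- tryCatch({
    le <- eigen(t(Tm))
    v <- Re(le$vectors[, which.max(Mod(le$values))])
    v / sum(v)
  }, error = function(e) rep(NA_real_, n_states))
  structure(list(T = Tm, C = C, tau = tau, eigenvalues = vals,
                 stationary = pi_left, n_states = n_states),
            class = "phos_msm")
}

#' @export
print.phos_msm <- function(x, ...) {
  cat("<phos_msm>", x$n_states, "states, lag", x$tau, "steps\n")
  print(round(x$T, 4))
  invisible(x)
}

#' First-order transition rates from a transition matrix
#'
#' `k_ij = T_ij(tau) / tau` for `i != j`, in per-Markov-step units.  The
#' first-order-in-lag approximation is isolated here so an alternative
#' (e.g. a matrix logarithm) can be swapped in.
#'
#' @param model `phos_msm`.
#' @return matrix of rates (diagonal NA).
#' @export
transition_rates <- function(model) {
  if (model$tau == 0) stop("lag must be positive")
  k <- model$T / model$tau
  diag(k) <- NA_real_
  k
}

#' Dissipated heat per forward cycle from local detailed balance
#'
#' For the n-state unidirectional cycle 1 -> 2 -> ... -> n -> 1,
#' `dmu_cycle = -RT log(prod k_fwd / prod k_bwd)`.  Negative for clockwise
#' driving.  Invariant under uniform rescaling of all rates.
#'
#' @param k rate matrix (as from [transition_rates()]).
#' @param temperature K.
#' @return kJ/mol.
#' @export
delta_mu_cycle <- function(k, temperature = 300) {
  n <- nrow(k)
  fwd <- c(seq_len(n - 1), n); bwd <- c(2:n, 1)
  kf <- k[cbind(fwd, bwd)]
  kb <- k[cbind(bwd, fwd)]
  if (any(!is.finite(kf)) || any(!is.finite(kb)) || any(kf <= 0) || any(kb <= 0))
    stop("zero or missing rate on a cycle edge: affinity undefined ",
         "(forward: ", paste(signif(kf, 3), collapse = " "),
         "; backward: ", paste(signif(kb, 3), collapse = " "), ")")
  -GAS_CONSTANT * temperature * log(prod(kf) / prod(kb))
}

#' Cycle affinity with block-bootstrap uncertainty
#'
#' Re-estimates the MSM and the cycle affinity on circular block-bootstrap
#' replicates of the discrete trajectory.
#'
#' @param dtraj integer state sequence (or list).
#' @param tau lag, Markov steps.
#' @param temperature K.
#' @param n_boot bootstrap replicates.
#' @param block_len block length (default `10 * tau`).
#' @param seed RNG seed.
#' @return list `value` (point estimate), `mean`, `sem` (bootstrap),
#'   `boot` (replicate values; failed replicates dropped).
#' @export
estimate_dmu_cycle <- function(dtraj, tau, temperature = 300, n_boot = 30,
                               block_len = 10 * tau, seed = 1) {
  est <- function(s) delta_mu_cycle(transition_rates(
    estimate_transition_matrix(s, tau)), temperature)
  point <- est(dtraj)
  bt <- bootstrap_observable(dtraj, est, n_boot = n_boot,
                             block_len = block_len, seed = seed)
  list(value = point, mean = bt$mean, sem = bt$sem, boot = bt$replicates)
}

#' Edge-resolved free-energy differences
#'
#' `RT log(k_ij / k_ji)` for each edge of the cycle; for the undriven
#' edges this is the equilibrium free-energy difference of the two states,
#' for the chemically driven edge it shifts linearly with the applied
#' chemical potential.
#'
#' @param k rate matrix.
#' @param temperature K.
#' @return named vector, one entry per cycle edge ("1-2", "2-3", ...).
#' @export
edge_log_ratios <- function(k, temperature = 300) {
  n <- nrow(k)
  fwd <- c(seq_len(n - 1), n); bwd <- c(2:n, 1)
  v <- GAS_CONSTANT * temperature * log(k[cbind(fwd, bwd)] / k[cbind(bwd, fwd)])
  stats::setNames(v, paste0(fwd, "-", bwd))
}

#' Implied timescales
#'
#' `t_i(tau) = -tau / log |lambda_i(tau)|` for every eigenvalue other than
#' the unit eigenvalue.  A plateau across lags indicates Markovianity.
#' Negative eigenvalues use the modulus and are flagged oscillatory;
#' zero eigenvalues are reported as timescale 0 (below resolution).
#'
#' @param model `phos_msm`.
#' @return data frame `eigenvalue`, `timescale` (Markov steps),
#'   `oscillatory`.
#' @export
implied_timescales <- function(model) {
  ev <- model$eigenvalues
  ev <- ev[-which.max(Mod(ev))]      # drop the stationary eigenvalue
  m <- Mod(ev)
  ts <- ifelse(m <= 0, 0, -model$tau / log(m))
  data.frame(eigenvalue = ev, timescale = ts,
             oscillatory = Re(ev) < 0 | abs(Im(ev)) > 1e-12)
}

#' Chapman-Kolmogorov test
#'
#' Compares the directly estimated transition matrix at lag `n tau` with
#' the n-th power of the lag-`tau` model, with 95% bootstrap confidence
#' intervals on both from circular block resampling.
#'
#' @param dtraj integer state sequence (or list).
#' @param tau base lag.
#' @param n_values integer multiples of `tau` to test.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return data frame with columns `n`, `from`, `to`, `estimated`,
#'   `predicted`, and 95% CI bounds for both; attribute `pass` is the
#'   fraction of entries whose CIs overlap.
#' @export
ck_test <- function(dtraj, tau, n_values = c(1, 2, 4, 8), n_boot = 100,
                    seed = 1) {
  base <- estimate_transition_matrix(dtraj, tau)
  ns <- base$n_states
  rows <- list()
  for (n in n_values) {
    est <- estimate_transition_matrix(dtraj, n * tau, n_states = ns)$T
    pred <- matpow(base$T, n)
    bt_est <- bootstrap_observable(
      dtraj, function(s) as.numeric(estimate_transition_matrix(s, n * tau,
                                                               n_states = ns)$T),
      n_boot = n_boot, block_len = max(10 * tau, 2 * n * tau), seed = seed)
    bt_pred <- bootstrap_observable(
      dtraj, function(s) as.numeric(matpow(
        estimate_transition_matrix(s, tau, n_states = ns)$T, n)),
      n_boot = n_boot, block_len = max(10 * tau, 2 * n * tau), seed = seed + 1)
    qe <- apply(bt_est$replicates, 2, stats::quantile,
                probs = c(0.025, 0.975), na.rm = TRUE)
    qp <- apply(bt_pred$replicates, 2, stats::quantile,
                probs = c(0.025, 0.975), na.rm = TRUE)
    idx <- expand.grid(from = seq_len(ns), to = seq_len(ns))
    rows[[length(rows) + 1]] <- data.frame(
      n = n, from = idx$from, to = idx$to,
      estimated = as.numeric(est), predicted = as.numeric(pred),
      est_lo = qe[1, ], est_hi = qe[2, ], pred_lo = qp[1, ], pred_hi = qp[2, ])
  }
  out <- do.call(rbind, rows)
  overlap <- pmax(out$est_lo, out$pred_lo) <= pmin(out$est_hi, out$pred_hi)
  attr(out, "pass") <- mean(overlap)
  out
}

matpow <- function(M, n) {
  R <- diag(nrow(M))
  for (i in seq_len(n)) R <- R %*% M
  R
}

#' Circular block bootstrap of a trajectory observable
#'
#' Resamples the discrete trajectory in circular blocks of `block_len`
#' frames, re-runs the estimator on each replicate, and returns the mean
#' and the bootstrap SEM (the standard deviation of the replicate
#' distribution).  Estimators may return vectors.
#'
#' @param dtraj integer sequence (or list; trajectories are resampled
#'   independently and passed as a list to the estimator).
#' @param estimator function of a trajectory (or list).
#' @param n_boot number of replicates (>= 2).
#' @param block_len block length, frames.
#' @param seed RNG seed.
#' @return list `mean`, `sem`, `replicates` (matrix, one row per
#'   replicate; estimator errors yield NA rows).
#' @export
bootstrap_observable <- function(dtraj, estimator, n_boot = 100,
                                 block_len = 50, seed = 1) {
  if (n_boot < 2) stop("n_boot must be at least 2 for an SEM")
  trajs <- if (is.list(dtraj)) dtraj else list(dtraj)
  if (any(vapply(trajs, length, 1L) <= block_len))
    stop("block_len must be shorter than every trajectory")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  one <- function() {
    rep_trajs <- lapply(trajs, function(s) {
      n <- length(s)
      nb <- ceiling(n / block_len)
      starts <- sample.int(n, nb, replace = TRUE)
      idx <- unlist(lapply(starts, function(st)
        ((st - 1L + seq_len(block_len) - 1L) %% n) + 1L))
      s[idx[seq_len(n)]]
    })
    tryCatch(estimator(if (length(rep_trajs) == 1) rep_trajs[[1]] else rep_trajs),
             error = function(e) NA_real_)
  }
  reps <- lapply(seq_len(n_boot), function(i) one())
  p <- max(vapply(reps, length, 1L))
  mat <- do.call(rbind, lapply(reps, function(r)
    if (length(r) == p) as.numeric(r) else rep(NA_real_, p)))
  list(mean = colMeans(mat, na.rm = TRUE),
       sem = apply(mat, 2, stats::sd, na.rm = TRUE),
       replicates = mat)
}
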