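#' Event table constructor
#'
#' First-phosphorylation times per replica and site, with right-censoring
#' at the replica length.  One row per (replica, site); `t_p = NA` marks a
#' censored replica (no event before `t_tot`).
#'
#' @param replica integer replica id.
#' @param site site label (author numbering or name).
#' @param t_p event time, same unit as `t_tot` (NA if censored).
#' @param t_tot replica length.
#' @return data frame of class `phos_events`.
#' @export
event_table <- function(replica, site, t_p, t_tot) {
  stopifnot(length(replica) == length(site), length(site) == length(t_p))
  t_tot <- rep_len(t_tot, length(replica))
  bad <- !is.na(t_p) & (t_p <= 0 | t_p > t_tot)
  if (any(bad)) stop("event times must satisfy 0 < t_p <= t_tot")
  structure(data.frame(replica = replica, site = site, t_p = t_p,
                       t_tot = t_tot), class = c("phos_events", "data.frame"))
}

#' Uniform-prior maximum-likelihood phosphorylation rate
#'
#' For at most one event per replica (first-passage convention):
#' `r_P = (n + 1) / Theta`, `var(r_P) = (n + 1) / Theta^2`, with
#' `Theta = sum(t_p) + (N_sim - n) t_tot` the total exposure; censored
#' replicas contribute their full length.
#'
#' @param table `phos_events` data frame.
#' @param site site to estimate.
#' @return list `rate`, `variance`, `n_events`, `exposure`, `n_sim`
#'   (units: inverse of the table's time unit).
#' @export
phospho_rate_mle <- function(table, site) {
  tb <- table[table$site == site, ]
  if (nrow(tb) == 0) stop("no replicas for site ", site)
  if (anyDuplicated(tb$replica)) stop("at most one event per replica per site")
  n <- sum(!is.na(tb$t_p))
  theta <- sum(tb$t_p, na.rm = TRUE) + sum(is.na(tb$t_p) * tb$t_tot) +
    0 # censored replicas only; observed replicas contribute t_p
  # note: (N_sim - n) t_tot equals the censored-replica sum when t_tot is
  # constant, and generalizes it when replica lengths differ
  if (theta <= 0) stop("zero total exposure")
  list(rate = (n + 1) / theta, variance = (n + 1) / theta^2,
       n_events = n, exposure = theta, n_sim = nrow(tb))
}

#' Normalized inverse cumulative histogram of event times
#'
#' Each time bin holds the event counts of that bin plus all later bins,
#' divided by the number of replicas: a non-increasing survival-like curve
#' whose first bin equals `n / N_sim`.  Right-censoring leaves the tail
#' flat at zero beyond the last event.
#'
#' @param table `phos_events`.
#' @param site site label.
#' @param n_bins number of time bins up to `t_tot`.
#' @return data frame `t` (left bin edges), `value`; attributes `n_events`,
#'   `n_sim`.
#' @export
survival_curve <- function(table, site, n_bins = 50) {
  tb <- table[table$site == site, ]
  times <- tb$t_p[!is.na(tb$t_p)]
  if (length(times) == 0) stop("no events for site ", site,
                               ": degenerate curve, fit refused")
  t_tot <- max(tb$t_tot)
  edges <- seq(0, t_tot, length.out = n_bins + 1)
  counts <- graphics::hist(times, breaks = edges, plot = FALSE)$counts
  value <- rev(cumsum(rev(counts))) / nrow(tb)
  structure(data.frame(t = edges[-length(edges)], value = value),
            n_events = length(times), n_sim = nrow(tb))
}

#' Fit a survival curve with a single or binding-conditioned exponential
#'
#' Models for the complement of the event-time CDF:
#' * `"single"`: `exp(-r_P t)`;
#' * `"conditioned"`: the event time is the sum of a binding step (rate
#'   `r_B`) and a phosphorylation step (rate `r_P`), giving
#'   `r_B r_P / (r_B - r_P) (exp(-r_P t)/r_P - exp(-r_B t)/r_B)`; the
#'   exchange symmetry is resolved by assigning the larger rate to `r_B`,
#'   and the `r_B -> r_P` degeneracy switches to the analytic limit
#'   `(1 + r t) exp(-r t)`.
#'
#' Least squares on the binned curve, scaled by its `t = 0` plateau so that
#' censoring does not bias the shape fit.  Bins are weighted by the inverse
#' binomial variance of the empirical survival values (`y(1-y)/N`, floored),
#' which is what carries the information about the fast binding component
#' into the fit.
#'
#' @param curve output of [survival_curve()].
#' @param model `"single"` or `"conditioned"`.
#' @return list of class `phos_survfit`: `model`, `r_P`, `r_B` (NA for
#'   single), `sse` (weighted), `fitted`.
#' @export
fit_survival <- function(curve, model = c("single", "conditioned")) {
  model <- match.arg(model)
  t <- curve$t
  y <- curve$value / max(curve$value)
  n_sim <- attr(curve, "n_sim")
  w <- if (is.null(n_sim)) rep(1, length(y))
       else 1 / pmax(y * (1 - y) / n_sim, 1e-4)
  if (model == "single") {
    pos <- y > 0
    r0 <- max(1e-8, -stats::coef(stats::lm(log(y[pos]) ~ t[pos] - 1))[[1]])
    f <- function(lr) sum(w * (y - exp(-exp(lr) * t))^2)
    op <- stats::optimize(f, interval = log(r0) + c(-5, 5))
    rP <- exp(op$minimum)
    fit <- exp(-rP * t)
    out <- list(model = model, r_P = rP, r_B = NA_real_,
                sse = sum(w * (y - fit)^2), fitted = fit)
  } else {
    single <- fit_survival(curve, "single")
    f <- function(p) {
      v <- conditioned_survival(t, exp(p[1]), exp(p[1]) + exp(p[2]))
      sum(w * (y - v)^2)
    }
    op <- stats::optim(c(log(single$r_P), log(10 * single$r_P)), f,
                       method = "Nelder-Mead",
                       control = list(maxit = 3000, reltol = 1e-12))
    rP <- exp(op$par[1]); rB <- exp(op$par[1]) + exp(op$par[2])
    fit <- conditioned_survival(t, rP, rB)
    out <- list(model = model, r_P = rP, r_B = rB,
                sse = op$value, fitted = fit)
  }
  class(out) <- "phos_survfit"
  out
}

# complement of the event-time CDF for the binding-conditioned process,
# with the analytic r_B -> r_P limit
conditioned_survival <- function(t, rP, rB) {
  if (abs(rB - rP) < 1e-8 * rP) (1 + rP * t) * exp(-rP * t)
  else rB * rP / (rB - rP) * (exp(-rP * t) / rP - exp(-rB * t) / rB)
}

#' Maximum-likelihood survival fit on raw event times
#'
#' Alternative estimator to the binned [fit_survival()]: maximizes the
#' censored likelihood of the raw first-event times under the
#' binding-conditioned two-step model (or the single exponential).
#' Asymptotically efficient, hence the preferred estimator when the fast
#' binding rate is close to the information limit of the sample.
#'
#' @param table `phos_events`.
#' @param site site label.
#' @param model `"single"` or `"conditioned"`.
#' @return `phos_survfit` (without `fitted` values).
#' @export
fit_survival_ml <- function(table, site, model = c("conditioned", "single")) {
  model <- match.arg(model)
  tb <- table[table$site == site, ]
  t <- tb$t_p[!is.na(tb$t_p)]
  if (length(t) == 0) stop("no events for site ", site)
  n_cens <- sum(is.na(tb$t_p))
  t_tot <- max(tb$t_tot)
  if (model == "single") {
    # closed form: rate = events / exposure
    theta <- sum(t) + n_cens * t_tot
    out <- list(model = model, r_P = length(t) / theta, r_B = NA_real_,
                sse = NA_real_, fitted = NULL)
  } else {
    nll <- function(p) {
      rP <- exp(p[1]); rB <- exp(p[1]) + exp(p[2])
      dens <- rB * rP / (rB - rP) * (exp(-rP * t) - exp(-rB * t))
      S <- conditioned_survival(t_tot, rP, rB)
      -(sum(log(pmax(dens, 1e-300))) + n_cens * log(max(S, 1e-300)))
    }
    r0 <- length(t) / (sum(t) + n_cens * t_tot)
    op <- stats::optim(c(log(r0), log(5 * r0)), nll,
                       control = list(maxit = 3000, reltol = 1e-12))
    out <- list(model = model, r_P = exp(op$par[1]),
                r_B = exp(op$par[1]) + exp(op$par[2]),
                sse = NA_real_, fitted = NULL)
  }
  class(out) <- "phos_survfit"
  out
}

#' @export
print.phos_survfit <- function(x, ...) {
  cat("<phos_survfit>", x$model, " r_P =", signif(x$r_P, 4),
      if (!is.na(x$r_B)) paste(" r_B =", signif(x$r_B, 4)),
      " sse =", signif(x$sse, 3), "\n")
  invisible(x)
}

#' Pairwise phosphorylation-order probabilities
#'
#' For each ordered site pair (i, j), the fraction of replicas in which
#' site i is phosphorylated before site j, among replicas where the order
#' is decidable: both observed (compare times), or exactly one observed
#' (the observed one counts as first).  Replicas with both sites censored
#' are excluded; pairs with no decidable replica are NA; the diagonal is
#' NA.
#'
#' @param table `phos_events` covering all sites.
#' @return square matrix of probabilities, sites in sorted order.
#' @export
order_probability_matrix <- function(table) {
  sites <- sort(unique(table$site))
  reps <- sort(unique(table$replica))
  tp <- matrix(NA_real_, length(reps), length(sites),
               dimnames = list(reps, sites))
  for (k in seq_len(nrow(table)))
    tp[as.character(table$replica[k]), as.character(table$site[k])] <-
      table$t_p[k]
  P <- matrix(NA_real_, length(sites), length(sites),
              dimnames = list(sites, sites))
  for (i in seq_along(sites)) for (j in seq_along(sites)) {
    if (i == j) next
    ti <- tp[, i]; tj <- tp[, j]
    decid <- !(is.na(ti) & is.na(tj))
    wins <- (!is.na(ti) & is.na(tj)) |
      (!is.na(ti) & !is.na(tj) & ti < tj)
    if (any(decid)) P[i, j] <- sum(wins) / sum(decid)
  }
  P
}

#' Arrival-order histogram for one site
#'
#' Over replicas in which the site fired, counts how many other sites were
#' already phosphorylated at its event time (n = 0 .. n_sites - 1).
#' Censored replicas are excluded and reported.
#'
#' @param table `phos_events`.
#' @param site site label.
#' @return list `counts` (named vector over n), `n_censored`.
#' @export
arrival_order_histogram <- function(table, site) {
  sites <- sort(unique(table$site))
  if (!site %in% sites) stop("invalid site: ", site)
  reps <- sort(unique(table$replica))
  ns <- length(sites)
  counts <- stats::setNames(integer(ns), 0:(ns - 1))
  censored <- 0L
  for (r in reps) {
    tb <- table[table$replica == r, ]
    t_site <- tb$t_p[tb$site == site]
    if (length(t_site) != 1 || is.na(t_site)) { censored <- censored + 1L; next }
    prior <- sum(!is.na(tb$t_p) & tb$site != site & tb$t_p < t_site)
    counts[prior + 1L] <- counts[prior + 1L] + 1L
  }
  list(counts = counts, n_censored = censored)
}

#' Contact rate with the enzyme active site
#'
#' Events per unit time per replica (a contact event is the entry into the
#' all-three-distances criterion, i.e. a rising edge), averaged over
#' replicas with the SEM across replicas.
#'
#' @param counts data frame with columns `replica`, `site`, `count`,
#'   `time` (one row per replica/site).
#' @param site site label.
#' @return list `rate`, `sem`, `n_replicas`.
#' @export
contact_rate <- function(counts, site) {
  tb <- counts[counts$site == site, ]
  if (nrow(tb) == 0 || any(tb$time <= 0)) stop("zero-length input")
  r <- tb$count / tb$time
  list(rate = mean(r),
       sem = if (nrow(tb) > 1) stats::sd(r) / sqrt(nrow(tb)) else NA_real_,
       n_replicas = nrow(tb))
}

#' Build a per-replica contact-count table from engine event logs
#'
#' @param runs list of `phos_trajectory` objects (equilibrium runs).
#' @param sites site labels, one per phosphosite column.
#' @return data frame `replica`, `site`, `count`, `time` (ns).
#' @export
contact_count_table <- function(runs, sites = NULL) {
  rows <- list()
  for (ri in seq_along(runs)) {
    tr <- runs[[ri]]
    t_tot <- max(tr$frames$time)
    ev <- tr$events[tr$events$kind == "contact", ]
    nsite <- ncol(tr$frames$chem)
    if (is.null(sites)) sites <- seq_len(nsite)
    for (s in seq_len(nsite))
      rows[[length(rows) + 1]] <- data.frame(
        replica = ri, site = sites[s], count = sum(ev$site == s),
        time = t_tot)
  }
  do.call(rbind, rows)
}

#' Pearson correlation between phosphorylation and contact rates
#'
#' @param r_p,r_c matched per-site rate vectors.
#' @return sample Pearson correlation coefficient.
#' @export
rate_contact_correlation <- function(r_p, r_c) {
  if (length(r_p) != length(r_c)) stop("site lists must match")
  if (length(r_p) < 3) stop("need at least 3 sites")
  stats::cor(r_p, r_c)
}

#' First-phosphorylation event table from driven engine runs
#'
#' @param runs list of `phos_trajectory` objects from driven simulations.
#' @param sites site labels per phosphosite column.
#' @return `phos_events` data frame (times in ns).
#' @export
first_phospho_table <- function(runs, sites = NULL) {
  rows <- list()
  for (ri in seq_along(runs)) {
    tr <- runs[[ri]]
    t_tot <- max(tr$frames$time)
    nsite <- ncol(tr$frames$chem)
    if (is.null(sites)) sites <- seq_len(nsite)
    acc <- tr$events[tr$events$kind == "phospho_accept", ]
    for (s in seq_len(nsite)) {
      ts <- acc$time[acc$site == s]
      rows[[length(rows) + 1]] <- data.frame(
        replica = ri, site = sites[s],
        t_p = if (length(ts)) min(ts) else NA_real_, t_tot = t_tot)
    }
  }
  tab <- do.call(rbind, rows)
  event_table(tab$replica, tab$site, tab$t_p, tab$t_tot)
}
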