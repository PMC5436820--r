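# Shared fixtures and independent oracles.
#
# The oracles here deliberately avoid the package's own code paths:
# truncated pmfs are renormalised by explicit enumeration, ECDF gaps by
# double loops, medians by sorting.

# truncated-at-zero pmf by enumeration over 1..kmax, renormalised
oracle_trunc_pmf <- function(y, mu, theta, kmax = 400L) {
  f <- if (is.finite(theta)) {
    function(k) dnbinom(k, size = theta, mu = mu)
  } else {
    function(k) dpois(k, mu)
  }
  f(y) / sum(f(seq_len(kmax)))
}

# hurdle log-likelihood by per-observation enumeration
oracle_hurdle_loglik <- function(counts, pi, mu, theta) {
  ll <- 0
  for (i in seq_along(counts)) {
    y <- counts[i]
    ll <- ll + if (y == 0) log(1 - pi[i]) else
      log(pi[i]) + log(oracle_trunc_pmf(y, mu[i], theta))
  }
  ll
}

# two-sample KS statistic by double loop over pooled points
oracle_ks_D <- function(x, y) {
  pts <- c(x, y)
  gaps <- vapply(pts, function(t)
    abs(mean(x <= t) - mean(y <= t)), numeric(1))
  max(gaps)
}

# draw one hurdle dataset with known coefficients
gen_hurdle_data <- function(n, bz, bc, theta, seed,
                            p_ntz = 0.4, pot_size = 3, pot_mu = 22) {
  set.seed(seed)
  ntz <- rbinom(n, 1, p_ntz)
  pots <- pmax(1, rnbinom(n, size = pot_size, mu = pot_mu))
  eta_z <- bz[1] + bz[2] * ntz + bz[3] * pots + bz[4] * ntz * pots
  mu <- exp(bc[1] + bc[2] * ntz + bc[3] * pots + bc[4] * ntz * pots)
  pos <- runif(n) < plogis(eta_z)
  y <- integer(n)
  if (any(pos)) {
    if (is.finite(theta)) {
      p0 <- pnbinom(0, size = theta, mu = mu[pos])
      y[pos] <- qnbinom(runif(sum(pos), p0, 1), size = theta, mu = mu[pos])
    } else {
      p0 <- ppois(0, mu[pos])
      y[pos] <- qpois(runif(sum(pos), p0, 1), mu[pos])
    }
  }
  list(y = y, ntz = ntz, pots = pots)
}

# small fast config: 3 months, few boats, used where a full season is
# unnecessary
small_config <- function(seed = 1L, ...) {
  cfg <- default_config(seed = seed)
  months <- cfg$months[c(1, 2, 6), ]
  fields <- unclass(cfg)
  fields$months <- months
  fields$species_mix_by_month <- cfg$species_mix_by_month[c(1, 2, 6), ]
  fields$berried_prob_by_month_species <-
    cfg$berried_prob_by_month_species[c(1, 2, 6), ]
  fields$n_boats_main <- 20L
  fields$n_boats_lodge <- 4L
  fields$survey_days_per_month <- 8L
  dots <- list(...)
  for (k in names(dots)) fields[[k]] <- dots[[k]]
  do.call(sim_config, fields)
}

# boat-record data.frame builder
make_records <- function(date, weight, fishers = 3L, pots = 20L,
                         lobsters = NULL, site = "Main",
                         activity = "lobster_fishing") {
  n <- max(length(date), length(weight))
  weight <- rep_len(weight, n)
  if (is.null(lobsters)) lobsters <- ifelse(weight > 0, 1L, 0L)
  data.frame(date = as.Date(rep_len(date, n)), site = rep_len(site, n),
             activity = rep_len(activity, n),
             n_fishers = rep_len(fishers, n), n_pots = rep_len(pots, n),
             n_lobsters = rep_len(lobsters, n), total_weight_kg = weight)
}

# the published display-rounded 2015 monthly estimates used as a fixture
published_monthly_table <- function() {
  read.csv(system.file("extdata", "monthly_landings_2015.csv",
                       package = "palinurid"), comment.char = "#")
}
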