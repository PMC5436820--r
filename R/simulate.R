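# Synthetic fishery generator
#
# Simulates whole seasons of a pot-based spiny lobster fishery with the
# statistical structure the estimators assume: daily boat activity is
# Bernoulli with a month-specific boat activity coefficient (BAC), and
# the lobster count landed by an active boat follows a hurdle process —
# a logistic model for whether any lobster is caught, and a
# zero-truncated negative-binomial (or Poisson-limit) model for the
# positive count, both on NTZ status x pots. Every simulated boat-day is
# realised down to individual lobsters, so ground-truth landings are the
# exact sum of simulated catch weights.

HURDLE_TERMS <- c("intercept", "ntz", "pots", "ntz_pots")

#' Synthetic fishery configuration
#'
#' Bundles every parameter of the generator. All randomness downstream of
#' a config flows from its `seed`; per-month RNG sub-streams are derived
#' from it so month k is reproducible regardless of which other months are
#' generated.
#'
#' @param n_boats_main,n_boats_lodge,n_upstream_boats fleet composition.
#'   Upstream boats fish but are never counted at either landing site
#'   (the raising estimator adds them as a constant).
#' @param mean_fishers_per_boat,fishers_sd crew-size distribution
#'   (discretised normal, clamped to 1..8).
#' @param pot_mean,pot_sd pots per active boat; drawn from a negative
#'   binomial matched to this mean/sd, truncated at >= 1.
#' @param months data.frame with columns `year, month, days_in_month,
#'   ntz_open` (logical), `bac_true` (probability a boat fishes on a
#'   given day), `price_mga_per_kg`.
#' @param p_inactive probability that a boat not lobster fishing stays
#'   beached rather than going to sea on another activity. The default 0
#'   (every non-lobster boat is at sea on other work) makes the
#'   activity-ratio BAC estimator consistent for `bac_true`; positive
#'   values let tests demonstrate the estimator's inactive-boat bias.
#' @param hurdle_coefs_zero,hurdle_coefs_count length-4 named vectors
#'   (`intercept, ntz, pots, ntz_pots`): logit-scale coefficients for
#'   P(count > 0) and log-scale coefficients for the conditional count
#'   mean.
#' @param nb_dispersion positive dispersion theta of the NB2 count part
#'   (`Inf` gives the Poisson limit).
#' @param species_mix_by_month months x species matrix of catch
#'   composition weights; each row sums to 1.
#' @param berried_prob_by_month_species months x species matrix of
#'   P(berried | female).
#' @param prop_female probability a lobster is female.
#' @param tl_distribution data.frame `species, mean, sd` of total length
#'   (mm), truncated to (80, 450).
#' @param cl_from_tl data.frame `species, sex, slope, intercept, noise_sd`
#'   mapping total length to carapace length (mm).
#' @param weight_from_tl numeric `c(coefficient, exponent)` of the
#'   allometric weight W(kg) = a * TL(mm)^b.
#' @param survey_days_per_month days per month on which both landing
#'   sites are surveyed.
#' @param sample_fraction fraction of returning boats sampled on a survey
#'   day; must exceed 0.5, matching the survey protocol.
#' @param seed integer RNG seed.
#' @return validated object of class `sim_config`.
#' @seealso [default_config()], [simulate_season()]
#' @export
sim_config <- function(n_boats_main, n_boats_lodge, n_upstream_boats = 5L,
                       mean_fishers_per_boat, fishers_sd = 0.7,
                       pot_mean, pot_sd, months, p_inactive = 0,
                       hurdle_coefs_zero, hurdle_coefs_count,
                       nb_dispersion,
                       species_mix_by_month, berried_prob_by_month_species,
                       prop_female = 0.53,
                       tl_distribution, cl_from_tl, weight_from_tl,
                       survey_days_per_month = 15L,
                       sample_fraction = 0.85, seed = 1L) {
  if (!is_count(n_boats_main) || n_boats_main < 1)
    stop_field("n_boats_main", "need at least one boat")
  if (!is_count(n_boats_lodge)) stop_field("n_boats_lodge", "count >= 0")
  if (!is_count(n_upstream_boats)) stop_field("n_upstream_boats", "count >= 0")
  if (mean_fishers_per_boat < 1)
    stop_field("mean_fishers_per_boat", "must be >= 1")
  if (pot_sd < 0) stop_field("pot_sd", "must be >= 0")
  if (pot_mean < 1) stop_field("pot_mean", "must be >= 1")
  req <- c("year", "month", "days_in_month", "ntz_open", "bac_true",
           "price_mga_per_kg")
  if (!all(req %in% names(months)))
    stop_field("months", paste("needs columns", paste(req, collapse = ",")))
  if (any(months$bac_true < 0 | months$bac_true > 1))
    stop_field("bac_true", "probabilities must lie in [0,1]")
  if (any(months$days_in_month < 28 | months$days_in_month > 31))
    stop_field("days_in_month", "must be 28..31")
  for (nm in c("hurdle_coefs_zero", "hurdle_coefs_count")) {
    v <- get(nm)
    if (length(v) != 4L)
      stop_field(nm, "need 4 coefficients (intercept, ntz, pots, ntz_pots)")
  }
  if (is.na(nb_dispersion) || nb_dispersion <= 0)
    stop_field("nb_dispersion", "must be positive (Inf = Poisson)")
  smix <- as.matrix(species_mix_by_month)
  if (ncol(smix) != length(LOBSTER_SPECIES) || nrow(smix) != nrow(months))
    stop_field("species_mix_by_month", "must be months x 7 species")
  if (any(smix < 0) || any(abs(rowSums(smix) - 1) > 1e-8))
    stop_field("species_mix_by_month",
               "rows must be simplex weights summing to 1")
  bmat <- as.matrix(berried_prob_by_month_species)
  if (any(bmat < 0 | bmat > 1))
    stop_field("berried_prob_by_month_species", "probabilities in [0,1]")
  if (prop_female < 0 || prop_female > 1)
    stop_field("prop_female", "probability in [0,1]")
  if (p_inactive < 0 || p_inactive > 1)
    stop_field("p_inactive", "probability in [0,1]")
  if (sample_fraction <= 0.5 || sample_fraction > 1)
    stop_field("sample_fraction", "must lie in (0.5, 1]")
  if (!is_count(survey_days_per_month) || survey_days_per_month < 1)
    stop_field("survey_days_per_month", "positive count")
  if (any(survey_days_per_month > months$days_in_month))
    stop_field("survey_days_per_month", "exceeds days in month")
  cfg <- list(
    n_boats_main = as.integer(n_boats_main),
    n_boats_lodge = as.integer(n_boats_lodge),
    n_upstream_boats = as.integer(n_upstream_boats),
    mean_fishers_per_boat = mean_fishers_per_boat, fishers_sd = fishers_sd,
    pot_mean = pot_mean, pot_sd = pot_sd, months = months,
    p_inactive = p_inactive,
    hurdle_coefs_zero = stats::setNames(as.numeric(hurdle_coefs_zero),
                                        HURDLE_TERMS),
    hurdle_coefs_count = stats::setNames(as.numeric(hurdle_coefs_count),
                                         HURDLE_TERMS),
    nb_dispersion = nb_dispersion,
    species_mix_by_month = smix,
    berried_prob_by_month_species = bmat,
    prop_female = prop_female,
    tl_distribution = tl_distribution, cl_from_tl = cl_from_tl,
    weight_from_tl = as.numeric(weight_from_tl),
    survey_days_per_month = as.integer(survey_days_per_month),
    sample_fraction = sample_fraction, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default configuration emulating the 2015 Sainte Luce season
#'
#' Fleet of 74 boats (62 Main, 7 Lodge, 5 upstream), 3.6 fishers per boat
#' (sd 0.7), 22.0 pots per boat (sd 13.5), eight months February-September
#' with the NTZ open July-September, month-specific activity levels, and
#' a beach price stepping from 15,000 to 20,000 MGA per kg at the July
#' opening. Hurdle coefficients, size distributions and the allometric
#' weight are calibration choices documented in the methods vignette; the
#' male P. homarus length-length relation predicts ~186 mm total length
#' at 60 mm carapace length.
#'
#' @param seed integer seed stored in the config.
#' @return a [sim_config()].
#' @export
default_config <- function(seed = 1L) {
  months <- data.frame(
    year = 2015L, month = 2:9,
    days_in_month = c(28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L),
    ntz_open = c(rep(FALSE, 5), rep(TRUE, 3)),
    bac_true = c(0.74, 0.47, 0.67, 0.19, 0.09, 0.80, 0.80, 0.50),
    price_mga_per_kg = c(rep(15000, 5), rep(20000, 3)))
  closed_mix <- c(0.44, 0.46, 0.04, 0.03, 0.02, 0.008, 0.002)
  open_mix <- c(0.78, 0.16, 0.02, 0.02, 0.015, 0.004, 0.001)
  smix <- rbind(matrix(closed_mix, 5, 7, byrow = TRUE),
                matrix(open_mix, 3, 7, byrow = TRUE))
  colnames(smix) <- LOBSTER_SPECIES
  bmat <- matrix(0.15, 8, 7, dimnames = list(NULL, LOBSTER_SPECIES))
  bmat[, "P_homarus"] <- c(0.35, 0.35, 0.20, 0.20, 0.20, 0.30, 0.30, 0.30)
  bmat[, "P_longipes"] <- c(0.35, 0.35, 0.15, 0.15, 0.15, 0.15, 0.15, 0.15)
  tl <- data.frame(
    species = LOBSTER_SPECIES,
    mean = c(205, 208, 230, 220, 180, 170, 175),
    sd = c(32, 30, 40, 35, 30, 30, 30))
  cl <- expand.grid(species = LOBSTER_SPECIES, sex = c("male", "female"),
                    stringsAsFactors = FALSE)
  cl$slope <- ifelse(cl$species == "P_homarus" & cl$sex == "male",
                     1 / 3.1, 0.335)
  cl$intercept <- 0
  cl$noise_sd <- 2.5
  sim_config(
    n_boats_main = 62L, n_boats_lodge = 7L, n_upstream_boats = 5L,
    mean_fishers_per_boat = 3.6, fishers_sd = 0.7,
    pot_mean = 22.0, pot_sd = 13.5, months = months,
    hurdle_coefs_zero = c(intercept = -1.2, ntz = 0.2, pots = 0.065,
                          ntz_pots = 0.020),
    hurdle_coefs_count = c(intercept = -0.2, ntz = 0.5, pots = 0.025,
                           ntz_pots = 0.012),
    nb_dispersion = 1.5,
    species_mix_by_month = smix,
    berried_prob_by_month_species = bmat,
    prop_female = 0.53,
    tl_distribution = tl, cl_from_tl = cl,
    weight_from_tl = c(8e-8, 2.9),
    survey_days_per_month = 15L, sample_fraction = 0.85, seed = seed)
}

# pots per active boat: NB matched to (mean, sd), truncated at >= 1.
# sd^2 <= mean degenerates gracefully to Poisson.
.draw_pots <- function(n, mean, sd) {
  if (n == 0L) return(integer())
  if (sd^2 > mean) {
    size <- mean^2 / (sd^2 - mean)
    p0 <- stats::pnbinom(0, size = size, mu = mean)
    stats::qnbinom(stats::runif(n, p0, 1), size = size, mu = mean)
  } else {
    p0 <- stats::ppois(0, mean)
    stats::qpois(stats::runif(n, p0, 1), mean)
  }
}

# zero-truncated count draw with NB2 mean mu, dispersion theta (Inf=Poisson)
.draw_truncated_count <- function(mu, theta) {
  n <- length(mu)
  if (n == 0L) return(integer())
  if (is.finite(theta)) {
    p0 <- stats::pnbinom(0, size = theta, mu = mu)
    stats::qnbinom(stats::runif(n, p0, 1), size = theta, mu = mu)
  } else {
    p0 <- stats::ppois(0, mu)
    stats::qpois(stats::runif(n, p0, 1), mu)
  }
}

.hurdle_eta <- function(coefs, ntz, pots) {
  # intercept enters through a unit covariate so an infinite intercept
  # (degenerate always-crossed hurdle) propagates cleanly
  coefs[1L] + coefs[2L] * ntz + coefs[3L] * pots + coefs[4L] * (ntz * pots)
}

#' Simulate one season of fishery monitoring data
#'
#' Realises every boat-day of the configured season: activity, pots,
#' hurdle-process lobster counts, and individual lobsters
#' (species, sex, berried status, lengths, allometric weight). Landing-site
#' surveys are generated for `survey_days_per_month` days per month — both
#' sites counted, and more than half the returning boats sampled — and
#' individual lobsters are reported for sampled boats only. Ground truth
#' records the exact monthly landings (sum of all simulated boat-day
#' weights, sampled or not), the activity probabilities, and the hurdle
#' coefficients used.
#'
#' @param config a [sim_config()].
#' @param census if `TRUE`, every boat (including upstream) is attributed
#'   to the Main site, all days are surveyed, and every returning boat is
#'   sampled — the full-enumeration regime under which the raising
#'   estimator must reproduce ground truth exactly.
#' @return list with elements `daily_surveys` (data.frame),
#'   `boat_records` (data.frame), `lobsters` (data.frame), `surveys`
#'   (list of [daily_survey()] objects), and `ground_truth`.
#' @export
simulate_season <- function(config, census = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  n_site <- c(Main = config$n_boats_main, Lodge = config$n_boats_lodge,
              upstream = config$n_upstream_boats)
  if (census) {
    n_site <- c(Main = sum(n_site), Lodge = 0L, upstream = 0L)
  }
  boat_site <- rep(names(n_site), n_site)
  n_boats <- length(boat_site)
  months <- config$months
  theta <- config$nb_dispersion

  daily_rows <- list(); record_rows <- list(); lobster_rows <- list()
  truth_landings <- numeric(nrow(months))
  truth_counts <- numeric(nrow(months))

  for (m in seq_len(nrow(months))) {
    set.seed(derive_seed(config$seed, m))
    mi <- months[m, ]
    ndays <- mi$days_in_month
    ntz <- as.numeric(mi$ntz_open)
    nbd <- n_boats * ndays
    day_of <- rep(seq_len(ndays), each = n_boats)
    site_of <- rep(boat_site, ndays)
    dates <- as.Date(sprintf("%04d-%02d-01", mi$year, mi$month)) + (day_of - 1L)

    # each boat-day: lobster fishing w.p. bac_true; otherwise at sea on
    # another activity unless it stays beached (p_inactive)
    lobstering <- stats::runif(nbd) < mi$bac_true
    at_sea <- lobstering |
      (!lobstering & stats::runif(nbd) >= config$p_inactive)
    na <- sum(lobstering)
    pots <- integer(nbd)
    pots[lobstering] <- .draw_pots(na, config$pot_mean, config$pot_sd)
    fishers <- integer(nbd)
    n_sea <- sum(at_sea)
    fishers[at_sea] <- pmin(8L, pmax(1L, as.integer(round(
      stats::rnorm(n_sea, config$mean_fishers_per_boat,
                   config$fishers_sd)))))

    counts <- integer(nbd)
    if (na > 0L) {
      eta_z <- .hurdle_eta(config$hurdle_coefs_zero, ntz, pots[lobstering])
      pos <- stats::runif(na) < stats::plogis(eta_z)
      mu <- exp(.hurdle_eta(config$hurdle_coefs_count, ntz,
                            pots[lobstering]))
      y <- integer(na)
      y[pos] <- .draw_truncated_count(mu[pos], theta)
      counts[lobstering] <- y
    }

    # individual lobsters for every positive boat-day
    total <- sum(counts)
    weights <- numeric(nbd)
    lob <- NULL
    if (total > 0L) {
      owner <- rep(which(counts > 0L), counts[counts > 0L])
      sp_idx <- sample.int(length(LOBSTER_SPECIES), total, replace = TRUE,
                           prob = config$species_mix_by_month[m, ])
      sp <- LOBSTER_SPECIES[sp_idx]
      tld <- config$tl_distribution
      ti <- match(sp, tld$species)
      # truncated-normal total length via inverse CDF on (80, 450) mm
      lo <- stats::pnorm(80, tld$mean[ti], tld$sd[ti])
      hi <- stats::pnorm(450, tld$mean[ti], tld$sd[ti])
      tl_mm <- stats::qnorm(stats::runif(total, lo, hi),
                            tld$mean[ti], tld$sd[ti])
      sex <- ifelse(stats::runif(total) < config$prop_female,
                    "female", "male")
      clmap <- config$cl_from_tl
      ci <- match(paste(sp, sex), paste(clmap$species, clmap$sex))
      cl_mm <- clmap$slope[ci] * tl_mm + clmap$intercept[ci] +
        stats::rnorm(total, 0, clmap$noise_sd[ci])
      cl_mm <- pmin(pmax(cl_mm, 1), tl_mm - 1)
      berried <- sex == "female" &
        stats::runif(total) < config$berried_prob_by_month_species[m, sp_idx]
      w_kg <- config$weight_from_tl[1L] * tl_mm^config$weight_from_tl[2L]
      rs <- rowsum(w_kg, owner)
      weights[as.integer(rownames(rs))] <- rs[, 1L]
      lob <- data.frame(date = dates[owner], species = sp, tl_mm = tl_mm,
                        cl_mm = cl_mm, sex = sex, berried = berried,
                        boat_day = owner, stringsAsFactors = FALSE)
    }
    truth_landings[m] <- sum(weights)
    truth_counts[m] <- total

    # survey design: both sites visited on the chosen days
    sdays <- if (census) seq_len(ndays) else
      sort(sample.int(ndays, config$survey_days_per_month))
    for (d in sdays) {
      idx_day <- which(day_of == d)
      date_d <- as.Date(sprintf("%04d-%02d-%02d", mi$year, mi$month, d))
      for (s in c("Main", "Lodge")) {
        idx <- idx_day[site_of[idx_day] == s]
        n_at_sea <- sum(at_sea[idx])
        inactive <- length(idx) - n_at_sea
        daily_rows[[length(daily_rows) + 1L]] <- data.frame(
          date = date_d, site = s, boats_at_sea = n_at_sea,
          boats_inactive = inactive)
        returning <- idx[at_sea[idx]]
        if (length(returning)) {
          ns <- if (census) length(returning) else
            min(length(returning),
                ceiling(config$sample_fraction * length(returning)))
          sampled <- if (ns == length(returning)) returning else
            sort(sample(returning, ns))
          record_rows[[length(record_rows) + 1L]] <- data.frame(
            date = date_d, site = s,
            activity = ifelse(lobstering[sampled], "lobster_fishing",
                              "other"),
            n_fishers = fishers[sampled], n_pots = pots[sampled],
            n_lobsters = counts[sampled],
            total_weight_kg = weights[sampled])
          if (!is.null(lob)) {
            keep <- lob$boat_day %in% sampled
            if (any(keep))
              lobster_rows[[length(lobster_rows) + 1L]] <-
                lob[keep, setdiff(names(lob), "boat_day"), drop = FALSE]
          }
        }
      }
    }
  }

  daily <- do.call(rbind, daily_rows)
  records <- if (length(record_rows)) do.call(rbind, record_rows) else
    data.frame(date = as.Date(character()), site = character(),
               activity = character(), n_fishers = integer(),
               n_pots = integer(), n_lobsters = integer(),
               total_weight_kg = numeric())
  lobsters <- if (length(lobster_rows)) do.call(rbind, lobster_rows) else
    data.frame(date = as.Date(character()), species = character(),
               tl_mm = numeric(), cl_mm = numeric(), sex = character(),
               berried = logical())
  rownames(records) <- rownames(lobsters) <- rownames(daily) <- NULL

  mkeys <- sprintf("%04d-%02d", months$year, months$month)
  ground_truth <- list(
    monthly_landings_kg = stats::setNames(truth_landings, mkeys),
    monthly_lobster_count = stats::setNames(truth_counts, mkeys),
    bac_true = stats::setNames(months$bac_true, mkeys),
    hurdle_coefs_zero = config$hurdle_coefs_zero,
    hurdle_coefs_count = config$hurdle_coefs_count,
    nb_dispersion = config$nb_dispersion,
    n_boats = n_boats)

  list(daily_surveys = daily, boat_records = records, lobsters = lobsters,
       surveys = assemble_surveys(daily, records),
       ground_truth = ground_truth)
}
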