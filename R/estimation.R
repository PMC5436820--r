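# Catch/effort raising estimator
#
# Monthly landings L = E x C, effort E = D x B x F, boat activity
# coefficient B = A / T. All chains are computed at full precision;
# rounding is confined to display (see monthly_report).

#' Boat activity coefficient for one landing-site survey
#'
#' The fraction of the fleet engaged in lobster fishing. The activity
#' ratio observed among sampled returning boats is applied to the full
#' count of boats at sea plus inactive boats, giving the estimated number
#' of active boats A; B = A / T with T the total count. A is kept
#' fractional.
#'
#' @param survey a [daily_survey()].
#' @return list of class `bac_observation` with fields `A`, `T` and `B`.
#' @export
compute_bac <- function(survey) {
  stopifnot(inherits(survey, "daily_survey"))
  total <- survey$boats_at_sea + survey$boats_inactive
  if (total == 0L)
    stop("BAC undefined: no boats at sea or inactive on ",
         format(survey$date), call. = FALSE)
  n_sampled <- nrow(survey$records)
  if (survey$boats_at_sea > 0L && n_sampled == 0L)
    stop("BAC needs sampled boats: ", survey$boats_at_sea,
         " at sea but none sampled on ", format(survey$date), call. = FALSE)
  ratio <- if (n_sampled == 0L) 0 else
    sum(survey$records$activity == "lobster_fishing") / n_sampled
  A <- total * ratio
  structure(list(A = A, T = total, B = A / total), class = "bac_observation")
}

.filter_month <- function(dates, month) month_key(dates) == month

#' Monthly mean boat activity coefficient
#'
#' Mean of per-survey BAC over Main-site surveys only; the small and
#' erratic Lodge fleet is excluded by protocol.
#'
#' @param surveys list of [daily_survey()] objects.
#' @param month `"YYYY-MM"` string.
#' @return proportion in `[0, 1]`.
#' @export
monthly_bac <- function(surveys, month) {
  keep <- vapply(surveys, function(s)
    s$site == "Main" && month_key(s$date) == month, logical(1L))
  if (!any(keep))
    stop("no Main-site surveys in month ", month, call. = FALSE)
  mean(vapply(surveys[keep], function(s) compute_bac(s)$B, numeric(1L)))
}

#' Monthly fleet size
#'
#' Mean total boats (at sea plus inactive, both sites) over days on which
#' both landing sites were surveyed, plus a constant number of upstream
#' boats that never appear in either count.
#'
#' @param surveys list of [daily_survey()] objects.
#' @param month `"YYYY-MM"`.
#' @param upstream_boats boats added to every monthly estimate (default 5).
#' @return fleet size in boats (possibly fractional).
#' @export
monthly_fleet_size <- function(surveys, month, upstream_boats = 5) {
  keep <- vapply(surveys, function(s) month_key(s$date) == month, logical(1L))
  ss <- surveys[keep]
  if (!length(ss)) stop("no surveys in month ", month, call. = FALSE)
  dates <- vapply(ss, function(s) format(s$date), character(1L))
  sites <- vapply(ss, function(s) s$site, character(1L))
  both <- intersect(dates[sites == "Main"], dates[sites == "Lodge"])
  if (!length(both))
    stop("no day in ", month, " with both sites surveyed", call. = FALSE)
  totals <- vapply(both, function(d) {
    sum(vapply(ss[dates == d], function(s)
      s$boats_at_sea + s$boats_inactive, numeric(1L)))
  }, numeric(1L))
  mean(totals) + upstream_boats
}

#' Monthly mean CPUE
#'
#' Mean catch per boat-day over sampled lobster-fishing boats, in kg per
#' boat-day (for raising landings) or lobsters per boat-day (for count
#' modelling). Zero-catch lobster-fishing boats are true zeros and count
#' toward the mean.
#'
#' @param records boat-record data.frame (see [read_boat_records()]).
#' @param month `"YYYY-MM"`.
#' @param unit `"kg_per_boatday"` or `"lobsters_per_boatday"`.
#' @return mean CPUE.
#' @export
monthly_cpue <- function(records, month,
                         unit = c("kg_per_boatday", "lobsters_per_boatday")) {
  unit <- match.arg(unit)
  sub <- records[.filter_month(records$date, month) &
                   records$activity == "lobster_fishing", , drop = FALSE]
  if (!nrow(sub))
    stop("no lobster-fishing boat records in month ", month, call. = FALSE)
  if (unit == "kg_per_boatday") mean(sub$total_weight_kg)
  else mean(sub$n_lobsters)
}

#' Assemble one monthly estimate from its components
#'
#' Applies the raising identities E = D x B x F, L = E x C, V = L x P at
#' full precision.
#'
#' @param month `"YYYY-MM"` label.
#' @param D days in the month (28..31).
#' @param B boat activity coefficient in `[0, 1]`.
#' @param F_boats fleet size (> 0).
#' @param C mean CPUE, kg per boat-day (>= 0).
#' @param P price, MGA per kg (>= 0).
#' @param n survey occasions (metadata only).
#' @param imputed flag marking an imputed month.
#' @return list of class `monthly_estimate` with D, n, B, F, E, C, L, P, V.
#' @export
monthly_estimate <- function(month, D, B, F_boats, C, P, n = NA_integer_,
                             imputed = FALSE) {
  if (!is_count(D) || D < 28 || D > 31) stop_field("D", "must be 28..31")
  if (!is.finite(B) || B < 0 || B > 1) stop_field("B", "must lie in [0,1]")
  if (!is.finite(F_boats) || F_boats <= 0) stop_field("F", "must be > 0")
  if (!is.finite(C) || C < 0) stop_field("C", "must be >= 0")
  if (!is.finite(P) || P < 0) stop_field("P", "must be >= 0")
  E <- D * B * F_boats
  L <- E * C
  structure(list(month = month, D = D, n = n, B = B, F = F_boats, E = E,
                 C = C, L = L, P = P, V = L * P, imputed = imputed),
            class = "monthly_estimate")
}

#' Raise a whole season from survey data
#'
#' Runs [monthly_bac()], [monthly_fleet_size()] and [monthly_cpue()] for
#' every month present in the surveys and assembles [monthly_estimate()]s.
#'
#' @param surveys list of [daily_survey()] objects.
#' @param records boat-record data.frame.
#' @param prices a [price_schedule()].
#' @param upstream_boats passed to [monthly_fleet_size()].
#' @return list of `monthly_estimate`, one per month, chronological.
#' @export
estimate_season <- function(surveys, records, prices,
                            upstream_boats = 5) {
  mk <- sort(unique(vapply(surveys, function(s) month_key(s$date),
                           character(1L))))
  lapply(mk, function(m) {
    first <- as.Date(paste0(m, "-01"))
    D <- as.integer(format(seq(first, by = "1 month", length.out = 2)[2L] - 1,
                           "%d"))
    n_occ <- sum(vapply(surveys, function(s)
      s$site == "Main" && month_key(s$date) == m, logical(1L)))
    monthly_estimate(
      month = m, D = D,
      B = monthly_bac(surveys, m),
      F_boats = monthly_fleet_size(surveys, m, upstream_boats),
      C = monthly_cpue(records, m, "kg_per_boatday"),
      P = price_at(prices, first), n = n_occ)
  })
}

#' Impute a missing month's landings from donor months
#'
#' The unsampled month's landings are the mean of the named donor months'
#' landings (e.g. January from February and March). Imputation is always
#' explicit: no month is imputed unless asked for.
#'
#' @param estimates list of [monthly_estimate()].
#' @param target_month `"YYYY-MM"` to impute.
#' @param donor_months character vector of estimated months.
#' @return imputed landings in kg.
#' @export
impute_month <- function(estimates, target_month, donor_months) {
  have <- vapply(estimates, function(e) e$month, character(1L))
  missing <- setdiff(donor_months, have)
  if (length(missing))
    stop("donor month(s) not estimated: ", paste(missing, collapse = ", "),
         call. = FALSE)
  mean(vapply(estimates[match(donor_months, have)], function(e) e$L,
              numeric(1L)))
}

#' Season totals
#'
#' Sums landings and value over monthly estimates, including imputed
#' months.
#'
#' @param estimates list of [monthly_estimate()] (at most 12).
#' @return list `total_kg`, `total_value_mga`, `n_imputed`.
#' @export
season_summary <- function(estimates) {
  stopifnot(length(estimates) <= 12L)
  list(total_kg = sum(vapply(estimates, function(e) e$L, numeric(1L))),
       total_value_mga = sum(vapply(estimates, function(e) e$V, numeric(1L))),
       n_imputed = sum(vapply(estimates, function(e) isTRUE(e$imputed),
                              logical(1L))))
}

#' Percent change of a value against a reference mean
#'
#' Two conventions: `"increase"` is 100 (v - mean(ref)) / mean(ref) — a
#' value equal to the reference mean gives 0% — and `"ratio"` is
#' 100 v / mean(ref) — equality gives 100%.
#'
#' @param value the value compared.
#' @param reference_values reference vector with positive mean.
#' @param convention `"increase"` or `"ratio"`.
#' @return percentage.
#' @export
percent_change <- function(value, reference_values,
                           convention = c("increase", "ratio")) {
  convention <- match.arg(convention)
  ref <- mean(reference_values)
  if (!is.finite(ref) || ref <= 0)
    stop_field("reference_values", "reference mean must be positive")
  if (convention == "increase") 100 * (value - ref) / ref
  else 100 * value / ref
}

#' Sample-size adequacy against an accuracy threshold
#'
#' Accuracy of a sample mean as one minus its finite-population-corrected
#' relative standard error:
#' `1 - (sd / sqrt(n)) * sqrt((N - n) / (N - 1)) / mean`.
#' A sample is adequate when accuracy meets the threshold (90% by
#' default). A census (n = N) or a zero-variance sample is fully accurate.
#'
#' @param n sample size (1..N).
#' @param N population size.
#' @param sample_sd sample standard deviation.
#' @param sample_mean positive sample mean.
#' @param accuracy_threshold default 0.90.
#' @return list `accuracy`, `adequate`.
#' @export
sample_adequacy <- function(n, N, sample_sd, sample_mean,
                            accuracy_threshold = 0.90) {
  if (n < 1 || n > N) stop_field("n", "must satisfy 1 <= n <= N")
  if (!is.finite(sample_mean) || sample_mean <= 0)
    stop_field("sample_mean", "must be positive")
  fpc <- if (N == 1) 0 else sqrt((N - n) / (N - 1))
  accuracy <- 1 - (sample_sd / sqrt(n)) * fpc / sample_mean
  list(accuracy = accuracy, adequate = accuracy >= accuracy_threshold)
}

#' Display-rounded monthly report table
#'
#' One row per month with columns D, n, B, F, E, C, L, P, V. Rounding
#' (B and C to 2 dp; F, E, L, V to integers) is applied here only; the
#' estimates themselves are exact, which is why a rounded row need not
#' satisfy E = D x B x F exactly.
#'
#' @param estimates list of [monthly_estimate()].
#' @param rounded apply display rounding (default `TRUE`).
#' @return data.frame.
#' @export
monthly_report <- function(estimates, rounded = TRUE) {
  df <- do.call(rbind, lapply(estimates, function(e)
    data.frame(month = e$month, D = e$D, n = e$n, B = e$B, F = e$F, E = e$E,
               C = e$C, L = e$L, P = e$P, V = e$V,
               imputed = isTRUE(e$imputed))))
  if (rounded) {
    df$B <- round(df$B, 2); df$C <- round(df$C, 2)
    for (col in c("F", "E", "L", "V")) df[[col]] <- round(df[[col]])
  }
  df
}
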