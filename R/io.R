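# CSV schemas
#
# daily_surveys.csv : date, site, boats_at_sea, boats_inactive
# boat_records.csv  : date, site, activity, n_fishers, n_pots, n_lobsters,
#                     total_weight_kg
# lobsters.csv      : date, species, tl_mm, cl_mm, sex, berried
#
# Dates are ISO-8601 (YYYY-MM-DD). Lines beginning `#` are provenance
# comments and are skipped on read.

LOBSTER_SPECIES <- c("P_homarus", "P_longipes", "P_ornatus",
                     "P_penicillatus", "S_squammosus", "P_antarticus",
                     "A_regalis")
SPINY_SPECIES <- c("P_homarus", "P_longipes", "P_ornatus", "P_penicillatus")
SITES <- c("Main", "Lodge")
ACTIVITIES <- c("lobster_fishing", "other")

.read_csv <- function(path) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  strip.white = TRUE)
}

.check_header <- function(df, expected, path) {
  if (!identical(names(df), expected))
    stop(sprintf("%s: schema mismatch; expected columns %s, found %s",
                 path, paste(expected, collapse = ","),
                 paste(names(df), collapse = ",")), call. = FALSE)
}

.parse_dates <- function(df, path) {
  d <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(d) | df$date != format(d, "%Y-%m-%d"))
  if (length(bad))
    stop(sprintf("%s: unparseable ISO-8601 date at data row(s) %s",
                 path, paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  df$date <- d
  df
}

.reject_rows <- function(bad, path, reason) {
  if (length(bad))
    stop(sprintf("%s: %s at data row(s) %s", path, reason,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
}

#' Read a daily landing-site survey table
#'
#' One row per landing-site visit: the dawn count of boats at sea
#' (drag marks in the sand) and of seaworthy but inactive boats on the
#' beach.
#'
#' @param path CSV path with columns `date,site,boats_at_sea,boats_inactive`.
#' @return data.frame with parsed dates; invalid rows abort with their row
#'   numbers.
#' @export
read_daily_surveys <- function(path) {
  df <- .read_csv(path)
  .check_header(df, c("date", "site", "boats_at_sea", "boats_inactive"), path)
  df <- .parse_dates(df, path)
  .reject_rows(which(!df$site %in% SITES), path, "unknown site")
  for (col in c("boats_at_sea", "boats_inactive"))
    .reject_rows(which(!is.finite(df[[col]]) | df[[col]] < 0 |
                         df[[col]] != floor(df[[col]])),
                 path, sprintf("negative or non-integer %s", col))
  df
}

#' Read a per-boat catch/effort record table
#'
#' One row per sampled returning boat: activity, crew size, pots checked,
#' lobsters caught and total catch weight.
#'
#' @param path CSV path with columns
#'   `date,site,activity,n_fishers,n_pots,n_lobsters,total_weight_kg`.
#' @return validated data.frame.
#' @export
read_boat_records <- function(path) {
  df <- .read_csv(path)
  .check_header(df, c("date", "site", "activity", "n_fishers", "n_pots",
                      "n_lobsters", "total_weight_kg"), path)
  df <- .parse_dates(df, path)
  .reject_rows(which(!df$site %in% SITES), path, "unknown site")
  .reject_rows(which(!df$activity %in% ACTIVITIES), path, "unknown activity")
  for (col in c("n_fishers", "n_pots", "n_lobsters"))
    .reject_rows(which(!is.finite(df[[col]]) | df[[col]] < 0 |
                         df[[col]] != floor(df[[col]])),
                 path, sprintf("negative or non-integer %s", col))
  .reject_rows(which(!is.finite(df$total_weight_kg) | df$total_weight_kg < 0),
               path, "negative total_weight_kg")
  # a boat either landed nothing (count 0, weight 0) or something of both
  .reject_rows(which(xor(df$n_lobsters == 0, df$total_weight_kg == 0)),
               path, "n_lobsters = 0 must coincide with total_weight_kg = 0")
  df
}

#' Read an individual lobster measurement table
#'
#' One row per measured individual from the catch-composition survey.
#'
#' @param path CSV path with columns `date,species,tl_mm,cl_mm,sex,berried`.
#'   `berried` is `true`/`false` and may only be `true` for females.
#' @return validated data.frame with logical `berried`.
#' @export
read_lobsters <- function(path) {
  df <- .read_csv(path)
  .check_header(df, c("date", "species", "tl_mm", "cl_mm", "sex", "berried"),
                path)
  df <- .parse_dates(df, path)
  .reject_rows(which(!df$species %in% LOBSTER_SPECIES), path,
               "unknown species")
  .reject_rows(which(!df$sex %in% c("male", "female")), path, "unknown sex")
  .reject_rows(which(!df$berried %in% c("true", "false")), path,
               "berried must be true/false")
  df$berried <- df$berried == "true"
  .reject_rows(which(df$berried & df$sex == "male"), path,
               "berried = true on a male")
  for (col in c("tl_mm", "cl_mm"))
    .reject_rows(which(!is.finite(df[[col]]) | df[[col]] <= 0), path,
                 sprintf("non-positive %s", col))
  .reject_rows(which(df$tl_mm <= df$cl_mm), path,
               "total length must exceed carapace length")
  df
}

.write_csv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  df2 <- df
  if ("date" %in% names(df2)) df2$date <- format(as.Date(df2$date), "%Y-%m-%d")
  if ("berried" %in% names(df2))
    df2$berried <- ifelse(df2$berried, "true", "false")
  num <- vapply(df2, is.double, logical(1L))
  df2[num] <- lapply(df2[num], function(x) format(x, digits = 17, trim = TRUE,
                                                  scientific = FALSE))
  utils::write.csv(df2, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write survey tables as CSV
#'
#' Lossless round-trip counterparts of [read_daily_surveys()],
#' [read_boat_records()] and [read_lobsters()]. An optional provenance
#' string (version, seed, config hash) is written as a leading `#` comment.
#'
#' @param df the table to write.
#' @param path output path.
#' @param provenance optional single string recorded as a header comment.
#' @return the path, invisibly.
#' @export
write_daily_surveys <- function(df, path, provenance = NULL)
  .write_csv(df[c("date", "site", "boats_at_sea", "boats_inactive")],
             path, provenance)

#' @rdname write_daily_surveys
#' @export
write_boat_records <- function(df, path, provenance = NULL)
  .write_csv(df[c("date", "site", "activity", "n_fishers", "n_pots",
                  "n_lobsters", "total_weight_kg")], path, provenance)

#' @rdname write_daily_surveys
#' @export
write_lobsters <- function(df, path, provenance = NULL)
  .write_csv(df[c("date", "species", "tl_mm", "cl_mm", "sex", "berried")],
             path, provenance)

#' Assemble per-visit survey objects from the two survey tables
#'
#' Joins the daily counts with the boat records sampled on the same date
#' and site, producing one `daily_survey` object per landing-site visit —
#' the unit on which the boat activity coefficient is computed.
#'
#' @param daily data.frame as from [read_daily_surveys()].
#' @param records data.frame as from [read_boat_records()].
#' @return list of `daily_survey` objects (date, site, boats_at_sea,
#'   boats_inactive, records).
#' @export
assemble_surveys <- function(daily, records) {
  lapply(seq_len(nrow(daily)), function(i) {
    row <- daily[i, ]
    sub <- records[records$date == row$date & records$site == row$site, ,
                   drop = FALSE]
    daily_survey(row$date, row$site, row$boats_at_sea, row$boats_inactive,
                 sub)
  })
}

#' Construct a single landing-site survey
#'
#' @param date survey date.
#' @param site `"Main"` or `"Lodge"`.
#' @param boats_at_sea,boats_inactive non-negative counts.
#' @param records data.frame of sampled boat records (may have zero rows).
#' @return object of class `daily_survey`.
#' @export
daily_survey <- function(date, site, boats_at_sea, boats_inactive,
                         records = NULL) {
  if (!site %in% SITES) stop_field("site", "must be Main or Lodge")
  if (!is_count(boats_at_sea)) stop_field("boats_at_sea", "non-negative count")
  if (!is_count(boats_inactive))
    stop_field("boats_inactive", "non-negative count")
  if (is.null(records))
    records <- data.frame(date = as.Date(character()), site = character(),
                          activity = character(), n_fishers = integer(),
                          n_pots = integer(), n_lobsters = integer(),
                          total_weight_kg = numeric())
  if (nrow(records) > boats_at_sea)
    stop_field("records", "more sampled boats than boats at sea")
  structure(list(date = as.Date(date), site = site,
                 boats_at_sea = as.integer(boats_at_sea),
                 boats_inactive = as.integer(boats_inactive),
                 records = records),
            class = "daily_survey")
}

#' @export
print.daily_survey <- function(x, ...) {
  cat(sprintf("<daily_survey> %s %s: %d at sea, %d inactive, %d sampled\n",
              format(x$date), x$site, x$boats_at_sea, x$boats_inactive,
              nrow(x$records)))
  invisible(x)
}
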