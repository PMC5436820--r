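# Catch composition, size structure and compliance statistics

DOMINANT_SPECIES <- c("P_homarus", "P_longipes")

#' Species composition of the catch by month
#'
#' Per-month proportions of the two dominant species, with the remaining
#' spiny lobsters pooled as `other_spiny` and the slipper lobsters as
#' `other_slipper`. Proportions sum to 1 within each month.
#'
#' @param lobsters lobster data.frame (see [read_lobsters()]).
#' @return data.frame `month, group, proportion, n`.
#' @export
composition_by_month <- function(lobsters) {
  if (!nrow(lobsters)) stop("no lobster records", call. = FALSE)
  grp <- ifelse(lobsters$species %in% DOMINANT_SPECIES, lobsters$species,
                ifelse(lobsters$species %in% SPINY_SPECIES, "other_spiny",
                       "other_slipper"))
  mo <- month_key(lobsters$date)
  tab <- as.data.frame(table(month = mo, group = grp),
                       stringsAsFactors = FALSE)
  tab <- tab[order(tab$month, tab$group), ]
  ntot <- tapply(tab$Freq, tab$month, sum)
  tab$proportion <- tab$Freq / ntot[tab$month]
  data.frame(month = tab$month, group = tab$group,
             proportion = tab$proportion, n = tab$Freq, row.names = NULL)
}

#' Proportion of females that are berried
#'
#' @param lobsters lobster data.frame.
#' @param species species code.
#' @param month `"YYYY-MM"`.
#' @return proportion, or `NA` (with attribute `n_females = 0`) when the
#'   month holds no females of the species.
#' @export
berried_proportion <- function(lobsters, species, month) {
  sub <- lobsters[lobsters$species == species &
                    month_key(lobsters$date) == month &
                    lobsters$sex == "female", , drop = FALSE]
  if (!nrow(sub)) {
    out <- NA_real_
    attr(out, "n_females") <- 0L
    return(out)
  }
  out <- mean(sub$berried)
  attr(out, "n_females") <- nrow(sub)
  out
}

#' Proportion of the catch under the minimum landing size
#'
#' Fraction of individuals with total length strictly below the MLS;
#' boundary individuals (TL exactly at the MLS) are legal.
#'
#' @param lobsters lobster data.frame with `tl_mm`.
#' @param mls minimum landing size in mm (default 200).
#' @return proportion.
#' @export
proportion_under_mls <- function(lobsters, mls = 200) {
  if (!nrow(lobsters)) stop("no lobster records", call. = FALSE)
  if (any(!is.finite(lobsters$tl_mm)))
    stop_field("tl_mm", "total length missing on some records")
  mean(lobsters$tl_mm < mls)
}

# asymptotic Kolmogorov distribution: P(sqrt(n) D > lambda)
.kolmogorov_p <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over the pooled sample points of the absolute
#' difference of the two empirical CDFs (evaluating at pooled unique
#' points handles ties in length data). The p-value uses the asymptotic
#' Kolmogorov distribution at effective size `n1 n2 / (n1 + n2)`.
#'
#' @param x,y numeric samples.
#' @return list of class `ks_result`: `D`, `p_value`, `n1`, `n2`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_field("x", "samples must be finite")
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pts)
  Fy <- stats::ecdf(y)(pts)
  D <- max(abs(Fx - Fy))
  ne <- length(x) * length(y) / (length(x) + length(y))
  structure(list(D = D, p_value = .kolmogorov_p(sqrt(ne) * D),
                 n1 = length(x), n2 = length(y)),
            class = "ks_result")
}

#' Size-frequency histogram and Gaussian kernel density
#'
#' Histogram counts in 10 mm bins, left-closed and anchored at 0 mm, plus
#' a Gaussian kernel density estimate evaluated on an explicit grid (the
#' plain average of Gaussian kernels; no boundary correction).
#'
#' @param TLs total lengths (mm), at least two values.
#' @param bandwidth positive kernel standard deviation (mm); figure-style
#'   reproductions pass the caption bandwidth, otherwise Silverman's rule
#'   via [stats::bw.nrd0()] is used.
#' @param bin_width histogram bin width (default 10 mm).
#' @param grid evaluation grid; defaults to 512 points spanning the data
#'   plus three bandwidths.
#' @return list `histogram` (data.frame `bin_left, bin_right, count`) and
#'   `density` (data.frame `x, density`).
#' @export
size_density <- function(TLs, bandwidth = NULL, bin_width = 10,
                         grid = NULL) {
  if (length(TLs) < 2L) stop_field("TLs", "need at least two values")
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(TLs)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop_field("bandwidth", "must be positive")
  lo <- floor(min(TLs) / bin_width) * bin_width
  hi <- ceiling((max(TLs) + 1e-9) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  idx <- findInterval(TLs, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  if (is.null(grid))
    grid <- seq(min(TLs) - 3 * bandwidth, max(TLs) + 3 * bandwidth,
                length.out = 512L)
  dens <- vapply(grid, function(g)
    mean(stats::dnorm(g, mean = TLs, sd = bandwidth)), numeric(1L))
  list(histogram = data.frame(bin_left = breaks[-length(breaks)],
                              bin_right = breaks[-1L], count = counts),
       density = data.frame(x = grid, density = dens))
}

#' Total-length vs carapace-length regression
#'
#' Ordinary least squares of TL on CL within one species-by-sex group,
#' for comparison with management regimes that use carapace length.
#'
#' @param lobsters lobster data.frame.
#' @param species species code.
#' @param sex `"male"` or `"female"`.
#' @return list `slope`, `intercept`, `residual_sd`, `n`.
#' @export
tl_cl_fit <- function(lobsters, species, sex) {
  sub <- lobsters[lobsters$species == species & lobsters$sex == sex, ,
                  drop = FALSE]
  if (nrow(sub) < 3L)
    stop("need at least 3 records for ", species, " ", sex, call. = FALSE)
  if (stats::sd(sub$cl_mm) == 0)
    stop_field("cl_mm", "carapace length is constant; regression degenerate")
  fit <- stats::lm(tl_mm ~ cl_mm, data = sub)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       residual_sd = summary(fit)$sigma, n = nrow(sub))
}

#' Median daily catch and earnings per fisher
#'
#' Each lobster-fishing boat record contributes its catch weight divided
#' by its crew size; the median of these per-fisher daily catches, times
#' the beach price, is the typical fisher's daily earnings.
#'
#' @param records boat-record data.frame.
#' @param price MGA per kg.
#' @return list `median_kg_per_fisher_day`, `earnings_mga_per_fisher_day`,
#'   `n`.
#' @export
median_daily_earnings <- function(records, price) {
  sub <- records[records$activity == "lobster_fishing", , drop = FALSE]
  if (!nrow(sub)) stop("no lobster-fishing records", call. = FALSE)
  if (any(sub$n_fishers < 1))
    stop_field("n_fishers", "every record needs at least one fisher")
  per_fisher <- sub$total_weight_kg / sub$n_fishers
  med <- stats::median(per_fisher)
  list(median_kg_per_fisher_day = med,
       earnings_mga_per_fisher_day = med * price, n = nrow(sub))
}
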