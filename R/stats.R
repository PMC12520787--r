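#' Cooperation frequency
#'
#' Counts of cooperation divided by the total of cooperation and defection.
#'
#' @param actions Character (`"C"`/`"D"`) or logical (TRUE = cooperate)
#'   vector of actions.
#' @return A frequency in `[0, 1]`.
#' @export
cooperation_frequency <- function(actions) {
  if (length(actions) == 0L) stop("no actions", call. = FALSE)
  if (is.character(actions)) actions <- actions == "C"
  mean(actions)
}

#' Connected correlation of perception and sociality
#'
#' The population covariance `<(b - c) s> - <s> <(b - c)>` between the
#' perceived net benefit of the public good and sociality; nonzero values
#' indicate consistent personalities across the two behavioural dimensions.
#'
#' @param net Per-agent perceived net benefit `b_hat - c_hat`.
#' @param s Per-agent sociality.
#' @return The connected correlation (population covariance).
#' @export
connected_correlation <- function(net, s) {
  if (length(net) != length(s))
    stop("net and s must have equal length", call. = FALSE)
  if (length(net) < 2L) stop("need at least two agents", call. = FALSE)
  mean(net * s) - mean(net) * mean(s)
}

#' Logarithmically binned density estimate
#'
#' Bins positive values into multiplicative bins of ratio `base` and
#' normalizes counts by sample size and bin width, so the result estimates
#' the probability density at the (geometric) bin centres.
#'
#' @param values Positive values.
#' @param base Bin ratio (> 1), default 1.3.
#' @return A data.frame with `center`, `density`, `count`, `width` and the
#'   bin edges as attributes; rows with zero counts are kept.
#' @export
log_binned_density <- function(values, base = 1.3) {
  if (base <= 1) stop("base must exceed 1", call. = FALSE)
  values <- values[is.finite(values)]
  if (any(values <= 0)) stop("values must be positive", call. = FALSE)
  if (!length(values)) stop("no values", call. = FALSE)
  lo <- floor(log(min(values)) / log(base))
  hi <- ceiling(log(max(values)) / log(base))
  if (hi == lo) hi <- lo + 1L
  edges <- base^(lo:hi)
  k <- pmin(pmax(floor(log(values) / log(base)) - lo + 1, 1), length(edges) - 1)
  counts <- tabulate(k, nbins = length(edges) - 1L)
  width <- diff(edges)
  centers <- sqrt(edges[-length(edges)] * edges[-1L])
  out <- data.frame(center = centers, density = counts / (length(values) * width),
                    count = counts, width = width)
  attr(out, "edges") <- edges
  attr(out, "base") <- base
  attr(out, "n") <- length(values)
  out
}

#' Least-squares power-law fit of a log-binned tail
#'
#' Ordinary least squares of `log(density)` on `log(center)` over the
#' selected bins. By default the fit uses bins with at least `min_count`
#' observations, drops the top half-decade of the value range (where
#' log-binned histograms are noisiest), and, for `tail = "right"`
#' (`"left"`), keeps only bins above (below) the modal bin.
#'
#' @param density A data.frame from [log_binned_density()], or a numeric
#'   vector of positive values (binned on the fly).
#' @param tail `"right"`, `"left"`, or `"all"`.
#' @param split Value separating the two tails; defaults to the modal bin
#'   centre. The fit additionally excludes half a decade around the split,
#'   where the density has not yet reached its asymptotic behaviour.
#' @param range Optional numeric `c(lo, hi)` restricting bin centres.
#' @param min_count Minimum bin count for inclusion (default 10).
#' @param drop_top_halfdecade Drop bins within a factor `10^0.5` of the
#'   extreme populated centre (the noisiest end of a log-binned
#'   histogram).
#' @param base Binning base when `density` is raw values.
#' @param alt_bases When raw values are given, additional binning bases
#'   used to widen the confidence interval by the systematic sensitivity
#'   of the slope to the binning (set to `NULL` to disable).
#' @return An object of class `powerlaw_fit` with `exponent` (the slope),
#'   `ci` (95% confidence interval), `r_squared`, `fit_range`, `n_bins`
#'   and `base`.
#' @export
fit_powerlaw_tail <- function(density, tail = c("right", "left", "all"),
                              split = NULL, range = NULL, min_count = 10,
                              drop_top_halfdecade = TRUE, base = 1.3,
                              alt_bases = c(1.2, 1.5)) {
  tail <- match.arg(tail)
  values <- NULL
  if (is.numeric(density)) {
    values <- density
    density <- log_binned_density(values, base)
  }
  d <- density
  if (!any(d$count > 0)) stop("empty density", call. = FALSE)
  if (is.null(split)) split <- d$center[which.max(d$density)]
  pop_centers <- d$center[d$count > 0]
  keep <- d$count >= min_count
  if (tail == "right") keep <- keep & d$center > split * sqrt(10)
  if (tail == "left") keep <- keep & d$center < split / sqrt(10)
  if (drop_top_halfdecade && tail != "left")
    keep <- keep & d$center <= max(pop_centers) / sqrt(10)
  if (drop_top_halfdecade && tail == "left")
    keep <- keep & d$center >= min(pop_centers) * sqrt(10)
  if (!is.null(range)) keep <- keep & d$center >= range[1] & d$center <= range[2]
  # keep only the contiguous well-populated run nearest the split:
  # isolated far bins that clear the count threshold by upward
  # fluctuation (beyond the depletion point of the sample) would bias
  # the slope toward shallow values
  idx <- which(keep)
  if (length(idx)) {
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    idx <- if (tail == "left") runs[[length(runs)]] else runs[[1L]]
  }
  d <- d[idx, , drop = FALSE]
  if (nrow(d) < 4L)
    stop("need at least 4 populated bins in the fit range", call. = FALSE)
  fit <- suppressWarnings(stats::lm(log(density) ~ log(center), data = d))
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  ci <- tryCatch(suppressWarnings(stats::confint(fit)[2, ]),
                 error = function(e) c(NA, NA))
  # the regression CI reflects bin-count noise only; when raw values are
  # available, widen it by the systematic spread of the slope across
  # alternative binning bases, which dominates at large sample sizes
  if (!is.null(values) && length(alt_bases)) {
    alt <- vapply(alt_bases, function(b) {
      tryCatch(fit_powerlaw_tail(log_binned_density(values, b), tail = tail,
                                 split = split, range = range,
                                 min_count = min_count,
                                 drop_top_halfdecade = drop_top_halfdecade
                                 )$exponent,
               error = function(e) NA_real_)
    }, numeric(1))
    spread <- suppressWarnings(max(c(abs(alt - slope), 0), na.rm = TRUE))
    ci <- c(ci[1] - spread, ci[2] + spread)
  }
  structure(list(exponent = slope, ci = unname(ci),
                 r_squared = sm$r.squared,
                 fit_range = range(d$center), n_bins = nrow(d),
                 base = attr(density, "base")),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("power-law fit: exponent %.3f (95%% CI %.3f..%.3f), R^2 = %.3f, %d bins in [%.3g, %.3g]\n",
              x$exponent, x$ci[1], x$ci[2], x$r_squared,
              x$n_bins, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Two-sided ("tent") power-law fit of a ratio distribution
#'
#' The perceived benefit-to-cost ratio has a tent-shaped density on
#' log-log axes: a rising power law below the split point and a decaying
#' one above it. The natural split for a perception ratio is 1, the
#' boundary between perceiving the public good as beneficial and as
#' costly. This fits both sides separately.
#'
#' @param values Positive values (e.g. `b_hat / c_hat`).
#' @param split Tent apex (default 1).
#' @param base Binning base.
#' @param min_count Minimum bin count.
#' @return A list with elements `left` and `right`, both `powerlaw_fit`.
#' @export
fit_tent_tails <- function(values, split = 1, base = 1.3, min_count = 10) {
  d <- log_binned_density(values, base)
  list(left = fit_powerlaw_tail(d, tail = "left", split = split,
                                min_count = min_count),
       right = fit_powerlaw_tail(d, tail = "right", split = split,
                                 min_count = min_count))
}

#' Perceptual power-law exponents of a trait sample
#'
#' Computes the four tail exponents characterizing perceptual diversity:
#' the decaying (right) tail of the perceived benefit-to-cost ratio, its
#' rising (left) tail, and the tails of the inverse perceived cost and
#' inverse perceived benefit. Small-value tails fluctuate heavily under
#' log binning, so left tails are fitted through the inverse variable: a
#' density exponent `-(2 - tau)` for the inverse corresponds to exponent
#' `tau` for the variable itself, and the rising branch of the ratio tent
#' is reported with a positive sign as `2 - tau`. Exact zeros of the
#' perceived benefit (the initial condition value) are excluded wherever
#' a ratio or inverse is taken.
#'
#' @param c_hat,b_hat Pooled perceived cost and benefit samples.
#' @param base Log-binning base.
#' @param min_count Minimum bin count for the fits.
#' @return A list of four `powerlaw_fit` objects (`ratio_right`,
#'   `ratio_left`, `inv_cost`, `inv_benefit`) and a named `exponents`
#'   vector on the reporting convention above.
#' @export
perception_powerlaws <- function(c_hat, b_hat, base = 1.3, min_count = 10) {
  ok <- b_hat > 0 & c_hat > 0
  ratio <- b_hat[ok] / c_hat[ok]
  right <- fit_powerlaw_tail(ratio, tail = "right", split = 1,
                             base = base, min_count = min_count)
  left_inv <- fit_powerlaw_tail(1 / ratio, tail = "right", split = 1,
                                base = base, min_count = min_count)
  inv_cost <- fit_powerlaw_tail(1 / c_hat[c_hat > 0], tail = "right",
                                base = base, min_count = min_count)
  inv_benefit <- fit_powerlaw_tail(1 / b_hat[b_hat > 0], tail = "right",
                                   base = base, min_count = min_count)
  left <- left_inv
  left$exponent <- -left_inv$exponent
  left$ci <- rev(-left_inv$ci)
  list(ratio_right = right, ratio_left = left,
       inv_cost = inv_cost, inv_benefit = inv_benefit,
       exponents = c(ratio_right = right$exponent,
                     ratio_left = left$exponent,
                     inv_cost = inv_cost$exponent,
                     inv_benefit = inv_benefit$exponent))
}

#' Per-lineage species records
#'
#' Consolidates species ("lineage") bookkeeping into one record per
#' species: birth and death generation, lifespan, and total / mean /
#' variance of population size over the lifespan.
#'
#' @param x Either a `pgg_abm` run with `track_species = TRUE`, or a long
#'   data.frame with columns `generation`, `species_id`, `n`.
#' @param completed_only Keep only species that died before the end of the
#'   observation window.
#' @return A data.frame with one row per species.
#' @export
species_records <- function(x, completed_only = FALSE) {
  if (inherits(x, "pgg_abm")) {
    if (is.null(x$species)) stop("run had track_species = FALSE", call. = FALSE)
    rec <- x$species
  } else {
    if (!all(c("generation", "species_id", "n") %in% names(x)))
      stop("need columns generation, species_id, n", call. = FALSE)
    if (any(x$n < 1)) stop("population sizes must be >= 1", call. = FALSE)
    sp <- split(x, x$species_id)
    rec <- do.call(rbind, lapply(sp, function(d) {
      gens <- sort(d$generation)
      if (length(gens) > 1L && any(diff(gens) != 1L))
        stop("species ", d$species_id[1], " has gaps in its record",
             call. = FALSE)
      last <- max(d$generation)
      data.frame(species_id = d$species_id[1],
                 birth = min(d$generation),
                 death = NA_integer_,   # filled below if window continues
                 lifespan = nrow(d),
                 total_pop = sum(d$n),
                 mean_pop = mean(d$n),
                 var_pop = if (nrow(d) > 1) stats::var(d$n) else NA_real_,
                 last_seen = last)
    }))
    horizon <- max(x$generation)
    rec$death <- ifelse(rec$last_seen < horizon, rec$last_seen + 1L, NA_integer_)
    rec$last_seen <- NULL
    rownames(rec) <- NULL
  }
  if (completed_only) rec <- rec[!is.na(rec$death), , drop = FALSE]
  rec
}

#' Taylor's fluctuation-scaling exponent
#'
#' Fits the temporal fluctuation of species population size against its
#' mean across species, each computed over the species' lifespan. On the
#' default `scale = "sd"` the exponent is `alpha` in
#' `sd(n) ~ mean(n)^alpha`, the convention under which empirical
#' fluctuation scaling lies between 1/2 (Poisson-like, independent
#' individuals) and 1 (fully synchronized, multiplicative fluctuations);
#' `scale = "var"` fits the variance instead, doubling the exponent.
#'
#' @param records Species records (see [species_records()]).
#' @param min_lifespan Minimum lifespan for inclusion (default 2, the
#'   smallest for which a variance exists).
#' @param scale `"sd"` (default) or `"var"`.
#' @return A `powerlaw_fit` whose `exponent` is the Taylor slope.
#' @export
taylor_exponent <- function(records, min_lifespan = 2L,
                            scale = c("sd", "var")) {
  scale <- match.arg(scale)
  d <- records[records$lifespan >= min_lifespan & !is.na(records$var_pop) &
                 records$var_pop > 0, , drop = FALSE]
  if (nrow(d) < 10L)
    stop("need at least 10 species with lifespan >= 2 and positive variance",
         call. = FALSE)
  fit <- if (scale == "sd")
    stats::lm(log(sqrt(var_pop)) ~ log(mean_pop), data = d)
  else stats::lm(log(var_pop) ~ log(mean_pop), data = d)
  sm <- summary(fit)
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 ci = unname(stats::confint(fit)[2, ]),
                 r_squared = sm$r.squared,
                 fit_range = range(d$mean_pop), n_bins = nrow(d),
                 base = NA_real_),
            class = "powerlaw_fit")
}

#' Power spectral density slope of a species-count series
#'
#' Splits the mean-removed series into non-overlapping windows, averages
#' their periodograms, and fits the log-log slope of spectral power
#' against frequency over a configured band.
#'
#' @param series Species count per generation (length >= 256).
#' @param windows Number of non-overlapping windows to average (default 8).
#' @param freq_range Frequency band `c(lo, hi)` (cycles per generation)
#'   used for the fit; the default keeps the lowest 1.5 decades above the
#'   smallest resolvable frequency, where the spectrum is least affected
#'   by the white sampling-noise floor.
#' @param breakpoint Optional frequency at which to fit two separate
#'   slopes (crossover analysis); returns both segments.
#' @return A `powerlaw_fit` (slope of power vs frequency); with
#'   `breakpoint`, a list with `low` and `high` fits.
#' @export
species_count_psd <- function(series, windows = 8L, freq_range = NULL,
                              breakpoint = NULL) {
  series <- as.numeric(series)
  if (length(series) < 256L) stop("series too short (< 256)", call. = FALSE)
  if (stats::sd(series) == 0) stop("constant series", call. = FALSE)
  wl <- length(series) %/% windows
  spec <- 0
  for (w in seq_len(windows)) {
    seg <- series[((w - 1L) * wl + 1L):(w * wl)]
    seg <- seg - mean(seg)
    pg <- Mod(stats::fft(seg))^2 / wl
    spec <- spec + pg
  }
  spec <- spec / windows
  nf <- wl %/% 2L
  freq <- (1:nf) / wl
  pw <- spec[2:(nf + 1L)]
  if (is.null(freq_range)) freq_range <- c(freq[1], freq[1] * 10^1.5)
  psd_fit <- function(fr) {
    keep <- freq >= fr[1] & freq <= fr[2] & pw > 0
    if (sum(keep) < 4L) stop("too few frequencies in band", call. = FALSE)
    fit <- stats::lm(log(pw[keep]) ~ log(freq[keep]))
    sm <- summary(fit)
    structure(list(exponent = unname(stats::coef(fit)[2]),
                   ci = unname(stats::confint(fit)[2, ]),
                   r_squared = sm$r.squared,
                   fit_range = fr, n_bins = sum(keep), base = NA_real_),
              class = "powerlaw_fit")
  }
  if (!is.null(breakpoint))
    return(list(low = psd_fit(c(freq_range[1], breakpoint)),
                high = psd_fit(c(breakpoint, freq_range[2]))))
  psd_fit(freq_range)
}

#' Pareto (pure power-law) sampler
#'
#' Draws from the density `p(x) = (tau - 1) xmin^(tau - 1) x^(-tau)` for
#' `x >= xmin`, by inverse-CDF sampling. Used as a known-exponent input
#' for validating the tail fitter.
#'
#' @param n Number of draws.
#' @param tau Density exponent (> 1).
#' @param xmin Lower cutoff.
#' @return Numeric vector of samples.
#' @export
rpareto <- function(n, tau, xmin = 1) {
  if (tau <= 1) stop("tau must exceed 1", call. = FALSE)
  xmin * stats::runif(n)^(-1 / (tau - 1))
}
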