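# Synthetic pseudo-immunoblot readouts and timing statistics.
#
# Quantified immunoblot band intensities are positive, heteroscedastic and
# sampled at a handful of time points; the generator emulates this with
# multiplicative log-normal noise plus an additive background on model
# trajectory values, normalized to a loading-control analogue.  Default
# channel map (antibody analogue -> model variable):
#   pTyr15  -> preMPF   (inhibitory Cdk1 phosphorylation)
#   pThr194 -> Gwl      (activating Greatwall phosphorylation)
#   pSer67  -> ENSAPt   (Gwl site on ENSA/ARPP19)
#   pSP     -> MPFa     (phospho-SP Cdk substrate signal)

.default_channels <- c(pTyr15 = "preMPF", pThr194 = "Gwl",
                       pSer67 = "ENSAPt", pSP = "MPFa")

# run expr with a private RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a noisy sampled readout from a trajectory
#'
#' Each channel signal is the linearly interpolated trajectory value at
#' the sampling times, multiplied by log-normal noise
#' `exp(N(0, sigma^2))`, plus an additive `background`, divided by the
#' `normalization` constant (the loading-control analogue, 1 by
#' default).  With `sigma = 0` and `background = 0` the signals equal the
#' trajectory values exactly; identical seeds give identical series.
#'
#' @param traj a `"mito_trajectory"`.
#' @param times sampling times, inside the trajectory span.
#' @param sigma log-normal noise scale (sd of log intensity).
#' @param background additive background level.
#' @param seed integer seed; all randomness is drawn from a private
#'   generator so the global RNG state is untouched.
#' @param channels named character vector mapping channel names to
#'   trajectory variables.
#' @param normalization loading-control normalization constant.
#' @return A `"mito_readout"`: list with `times`, `signals` (matrix,
#'   channels in columns), `truth` (noiseless values), `channels`,
#'   `sigma`, `background`, `normalization`, `seed`.
#' @examples
#' traj <- run_protocol("pp2a_b55", "exit")
#' rd <- generate_readout(traj, times = 0:10 * 3, sigma = 0.1, seed = 17)
#' rd$signals[, "pThr194"]
#' @export
generate_readout <- function(traj, times, sigma = 0.1, background = 0,
                             seed = 1, channels = .default_channels,
                             normalization = 1) {
  stopifnot(inherits(traj, "mito_trajectory"))
  if (sigma < 0 || background < 0 || normalization <= 0)
    stop("'sigma' and 'background' must be >= 0, 'normalization' > 0")
  span <- range(traj$times)
  if (any(times < span[1] - 1e-12) || any(times > span[2] + 1e-12))
    stop("sampling times outside the trajectory span [",
         span[1], ", ", span[2], "]")
  if (is.unsorted(times, strictly = TRUE))
    stop("sampling times must be strictly increasing")
  truth <- sapply(names(channels), function(ch) {
    v <- trajectory_variable(traj, channels[[ch]])
    approx(traj$times, v, xout = times)$y
  })
  truth <- matrix(truth, nrow = length(times),
                  dimnames = list(NULL, names(channels)))
  noise <- with_seed(seed,
    matrix(rlnorm(length(truth), meanlog = 0, sdlog = sigma),
           nrow = nrow(truth)))
  signals <- (truth * noise + background) / normalization
  structure(list(times = times, signals = signals, truth = truth,
                 channels = channels, sigma = sigma,
                 background = background,
                 normalization = normalization, seed = seed),
            class = "mito_readout")
}

#' @export
print.mito_readout <- function(x, ...) {
  cat(sprintf(
    "Pseudo-immunoblot readout: %d time points, %d channels, sigma=%g, seed=%d\n",
    length(x$times), ncol(x$signals), x$sigma, x$seed))
  print(round(cbind(time = x$times, x$signals), 4))
  invisible(x)
}

# monotone (isotonic) fit of a sampled channel in the stated direction;
# returns fitted values on the sampling grid
monotone_fit <- function(times, y, direction) {
  if (direction == "up") isoreg(times, y)$yf else -isoreg(times, -y)$yf
}

# t50 of a monotone fitted series: first linear-interpolated crossing of
# the mid-excursion level; NA if the series does not cross
sampled_t50 <- function(times, yf, direction, fraction = 0.5,
                        min_excursion = 1e-3) {
  y0 <- yf[1]; yf_end <- yf[length(yf)]
  if (abs(yf_end - y0) < min_excursion) return(NA_real_)
  if ((direction == "up") != (yf_end > y0)) return(NA_real_)
  th <- y0 + fraction * (yf_end - y0)
  hit <- if (direction == "up") yf >= th else yf <= th
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(times[1])
  if (yf[i] == yf[i - 1]) return(times[i])
  times[i - 1] + (th - yf[i - 1]) / (yf[i] - yf[i - 1]) *
    (times[i] - times[i - 1])
}

# draw n_boot bootstrap t50 replicates by resampling residuals around the
# monotone fit (assumes RNG state already seeded by the caller)
boot_t50 <- function(times, y, direction, n_boot, fraction = 0.5) {
  fit <- monotone_fit(times, y, direction)
  resid <- y - fit
  vapply(seq_len(n_boot), function(b) {
    yb <- pmax(fit + sample(resid, length(resid), replace = TRUE), 0)
    sampled_t50(times, monotone_fit(times, yb, direction), direction,
                fraction)
  }, numeric(1))
}

#' Estimate t50 from a noisy readout
#'
#' The half-transition time of a channel, estimated by monotone
#' (isotonic) regression of the sampled signal followed by linear
#' interpolation of the mid-excursion crossing.  Uncertainty comes from
#' resampling the residuals around the monotone fit (`n_boot`
#' replicates, fixed seed).
#'
#' At least four sampling times are required; a channel that never
#' crosses its mid-excursion level yields `t50 = NA`.
#'
#' @param readout a `"mito_readout"`.
#' @param channel channel name.
#' @param direction `"up"` or `"down"`.
#' @param fraction excursion fraction (default 0.5).
#' @param n_boot bootstrap replicates.
#' @param seed seed of the bootstrap generator.
#' @param level confidence level of the percentile interval.
#' @return List with `t50`, `ci` (percentile interval), `boot`
#'   (bootstrap draws).
#' @export
estimate_t50 <- function(readout, channel, direction = c("up", "down"),
                         fraction = 0.5, n_boot = 200, seed = 1,
                         level = 0.95) {
  direction <- match.arg(direction)
  stopifnot(inherits(readout, "mito_readout"))
  if (length(readout$times) < 4)
    stop("at least 4 sampling times are required to estimate t50")
  if (!channel %in% colnames(readout$signals))
    stop("unknown channel '", channel, "'")
  y <- readout$signals[, channel]
  tt <- readout$times
  point <- sampled_t50(tt, monotone_fit(tt, y, direction), direction,
                       fraction)
  if (n_boot == 0)
    return(list(t50 = point, ci = c(NA_real_, NA_real_), boot = numeric()))
  boot <- with_seed(seed, boot_t50(tt, y, direction, n_boot, fraction))
  ok <- boot[!is.na(boot)]
  ci <- if (length(ok) >= 2)
    unname(stats::quantile(ok, c((1 - level) / 2, 1 - (1 - level) / 2)))
  else c(NA_real_, NA_real_)
  list(t50 = point, ci = ci, boot = boot)
}

#' Bootstrap ordering test between two transitions
#'
#' Estimates the probability that the transition of `channel_a` precedes
#' that of `channel_b`, as the fraction of paired bootstrap replicates
#' (residual resampling, fixed seed) in which `t50(a) < t50(b)`.  Exact
#' ties contribute 1/2, so two identical channels give a fraction near
#' 0.5 and swapping the channels maps the fraction to its complement.
#' Replicates in which either t50 is undefined are dropped (an error is
#' raised if fewer than half survive).
#'
#' Channels may come from two different readouts (e.g. the same antibody
#' channel under two protocols or scenarios) via `readout_b`.
#'
#' @param readout a `"mito_readout"` providing `channel_a`.
#' @param channel_a,channel_b channel names.
#' @param directions length-2 character, transition direction of each
#'   channel.
#' @param n_boot bootstrap replicates.
#' @param seed seed of the bootstrap generator.
#' @param readout_b optional second `"mito_readout"` providing
#'   `channel_b` (defaults to `readout`).
#' @return Fraction in `[0, 1]`.
#' @examples
#' traj <- run_protocol("pp2a_b55", "entry_oa")
#' rd <- generate_readout(traj, times = 0:10 * 3, sigma = 0.05, seed = 7)
#' ordering_test(rd, "pThr194", "pTyr15", c("up", "down"))
#' @export
ordering_test <- function(readout, channel_a, channel_b,
                          directions = c("up", "down"), n_boot = 200,
                          seed = 1, readout_b = NULL) {
  if (is.null(readout_b)) readout_b <- readout
  stopifnot(inherits(readout, "mito_readout"),
            inherits(readout_b, "mito_readout"))
  if (length(readout$times) < 4 || length(readout_b$times) < 4)
    stop("at least 4 sampling times are required")
  ya <- readout$signals[, channel_a]
  yb <- readout_b$signals[, channel_b]
  point_a <- sampled_t50(readout$times,
                         monotone_fit(readout$times, ya, directions[1]),
                         directions[1])
  point_b <- sampled_t50(readout_b$times,
                         monotone_fit(readout_b$times, yb, directions[2]),
                         directions[2])
  if (is.na(point_a) || is.na(point_b))
    stop("a channel never crosses its mid-excursion level; ",
         "ordering is undefined")
  # draw the two channels in a canonical order so that swapping the
  # arguments reuses the same paired replicates (exact antisymmetry)
  key_a <- paste(channel_a, directions[1], readout$seed)
  key_b <- paste(channel_b, directions[2], readout_b$seed)
  draws <- with_seed(seed, {
    if (key_a <= key_b) {
      a <- boot_t50(readout$times, ya, directions[1], n_boot)
      b <- boot_t50(readout_b$times, yb, directions[2], n_boot)
    } else {
      b <- boot_t50(readout_b$times, yb, directions[2], n_boot)
      a <- boot_t50(readout$times, ya, directions[1], n_boot)
    }
    cbind(a, b)
  })
  ok <- stats::complete.cases(draws)
  if (sum(ok) < n_boot / 2)
    stop("too many bootstrap replicates without a defined t50")
  a <- draws[ok, 1]; b <- draws[ok, 2]
  mean((a < b) + 0.5 * (a == b))
}

#' Write a readout as tidy CSV
#'
#' Long format (`time`, `channel`, `value`) with `#`-prefixed header
#' lines echoing the generation parameters.
#'
#' @param readout a `"mito_readout"`.
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_readout <- function(readout, path) {
  stopifnot(inherits(readout, "mito_readout"))
  hdr <- c("# mitoswitch pseudo-immunoblot readout",
           sprintf("# sigma=%g background=%g normalization=%g seed=%d",
                   readout$sigma, readout$background,
                   readout$normalization, readout$seed),
           paste0("# channels: ",
                  paste0(names(readout$channels), "=", readout$channels,
                         collapse = " ")))
  long <- data.frame(
    time = rep(readout$times, times = ncol(readout$signals)),
    channel = rep(colnames(readout$signals), each = length(readout$times)),
    value = as.vector(readout$signals))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(long, digits = 15, trim = TRUE), con, sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
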