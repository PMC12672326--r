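# Method-of-moments fits for the PSA distribution families. Each family is
# parameterized so its mean equals the base-case value and its spread matches
# the printed 95% interval: sd = (high - low) / (2 * 1.96) for normal, gamma
# and beta; lognormal is centred on the base value with
# sdlog = (log(high) - log(low)) / (2 * 1.96).

.fit_sd <- function(low, high) (high - low) / (2 * stats::qnorm(0.975))

.draw_one <- function(d, name) {
  sd <- .fit_sd(d$low, d$high)
  if (sd <= 0) return(d$base)  # zero-width interval: degenerate draw
  switch(d$family,
    normal = stats::rnorm(1L, mean = d$base, sd = sd),
    lognormal = {
      if (d$base <= 0 || d$low <= 0)
        stop("distribution '", name, "': lognormal requires positive base and bounds")
      sdlog <- (log(d$high) - log(d$low)) / (2 * stats::qnorm(0.975))
      stats::rlnorm(1L, meanlog = log(d$base), sdlog = sdlog)
    },
    gamma = {
      # disutilities are negative: fit the magnitude, restore the sign
      sgn <- if (d$base < 0) -1 else 1
      m <- abs(d$base)
      if (m <= 0)
        stop("distribution '", name, "': gamma requires a non-zero base value")
      shape <- m^2 / sd^2
      sgn * stats::rgamma(1L, shape = shape, rate = shape / m)
    },
    beta = {
      m <- d$base
      if (m <= 0 || m >= 1)
        stop("distribution '", name, "': beta requires base in (0, 1)")
      v <- sd^2
      if (v >= m * (1 - m))
        stop("distribution '", name, "': interval too wide for a beta fit")
      k <- m * (1 - m) / v - 1
      stats::rbeta(1L, shape1 = m * k, shape2 = (1 - m) * k)
    },
    stop("distribution '", name, "': unknown family ", d$family))
}

#' Draw one probabilistic parameter set
#'
#' Produces a new parameter set in which every non-fixed parameter is drawn
#' from its registered distribution family, centred on the base-case value
#' with spread matched to the printed 95\% interval by the method of moments.
#' Parameters registered as `fixed` (the baseline event rates) are never
#' varied. Distributions that drive several fields (e.g. a per-pen price
#' shared by all dose regimens of one agent) are drawn once and written to
#' every field, preserving the within-agent price coherence. Parameters are
#' sampled independently of one another.
#'
#' @param base A validated `cua_parameters` object.
#' @param seed Non-negative integer seed; the same seed always reproduces
#'   the identical draw.
#' @return A new `cua_parameters` object with sampled values.
#' @seealso [run_psa()]
#' @export
sample_parameters <- function(base, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  validate_parameters(base)
  out <- base
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  for (nm in names(base$distributions)) {
    d <- base$distributions[[nm]]
    if (d$family == "fixed") next
    v <- .draw_one(d, nm)
    # keep draws inside the parameter's hard support
    if (d$family == "beta") v <- min(max(v, 0), 1)
    for (path in d$paths) out[[path]] <- v
  }
  out
}
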