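# Density specifications used inside two-groups models.
#
# A spec is a plain list with a `kind` field so fitted models can be written
# to / read from text. Supported kinds:
#   halfnorm : half normal on [0, Inf) with scale s (s = 1 is |N(0,1)|)
#   folded   : folded normal |N(mu, sd)| on [0, Inf)
#   norm     : normal on the real line
#   unif     : Uniform(0,1)
#   grid     : tabulated density, linearly interpolated, 0 outside range

dens_halfnorm <- function(s = 1) {
  stopifnot(s > 0)
  list(kind = "halfnorm", s = s)
}

dens_folded <- function(mu, sd = 1) {
  stopifnot(sd > 0)
  list(kind = "folded", mu = mu, sd = sd)
}

dens_norm <- function(mean = 0, sd = 1) {
  stopifnot(sd > 0)
  list(kind = "norm", mean = mean, sd = sd)
}

dens_unif <- function() list(kind = "unif")

dens_grid <- function(x, y) {
  stopifnot(length(x) == length(y), !is.unsorted(x), all(y >= 0))
  list(kind = "grid", x = x, y = y)
}

dens_eval <- function(spec, z) {
  switch(spec$kind,
    halfnorm = ifelse(z < 0, 0, 2 * stats::dnorm(z / spec$s) / spec$s),
    folded = ifelse(z < 0, 0,
      stats::dnorm(z, spec$mu, spec$sd) + stats::dnorm(z, -spec$mu, spec$sd)),
    norm = stats::dnorm(z, spec$mean, spec$sd),
    unif = stats::dunif(z),
    grid = {
      v <- stats::approx(spec$x, spec$y, xout = z, yleft = 0, yright = 0)$y
      v[is.na(v)] <- 0
      v
    },
    stop("unknown density kind: ", spec$kind)
  )
}

# numeric integral over the spec's domain (used by validity checks)
dens_integral <- function(spec, lower = NULL, upper = NULL) {
  if (spec$kind == "grid") {
    return(sum(diff(spec$x) * (utils::head(spec$y, -1) + utils::tail(spec$y, -1)) / 2))
  }
  lo <- if (!is.null(lower)) lower else if (spec$kind %in% c("halfnorm", "folded")) 0 else -Inf
  hi <- if (!is.null(upper)) upper else Inf
  stats::integrate(function(x) dens_eval(spec, x), lo, hi,
                   rel.tol = 1e-9, abs.tol = 1e-10)$value
}
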