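# Single-study two-groups model: null prior pi0, null density f0, non-null
# density f1, with a power-based shrinkage factor applied to f1.

#' Construct a two-groups model
#'
#' @param pi0 prior null probability in [0,1].
#' @param f0,f1 density specs (see internals in densities.R); callers normally
#'   obtain models from \code{\link{fit_normix}} or
#'   \code{\link{fit_locfdr_style}} rather than building them by hand.
#' @param domain \code{"absolute_z"} if the model lives on |z|,
#'   \code{"signed_z"} otherwise.
#' @param power estimated study power in [0,1] (\code{NA} until computed).
#' @param shrink multiplicative factor applied to f1 in all likelihoods
#'   (1 = unshrunk; set by \code{\link{shrink_f1}}).
#' @param details free-form list (fit diagnostics, branch taken, ...).
#' @return an object of class \code{two_groups_model}.
#' @export
two_groups_model <- function(pi0, f0, f1, domain = c("absolute_z", "signed_z"),
                             power = NA_real_, shrink = 1, details = list()) {
  domain <- match.arg(domain)
  stopifnot(pi0 >= 0, pi0 <= 1, shrink >= 0, shrink <= 1)
  structure(list(pi0 = pi0, f0 = f0, f1 = f1, domain = domain,
                 power = power, shrink = shrink, details = details),
            class = "two_groups_model")
}

#' @export
print.two_groups_model <- function(x, ...) {
  cat(sprintf("two_groups_model (%s): pi0 = %.4f, f0 = %s, f1 = %s",
              x$domain, x$pi0, x$f0$kind, x$f1$kind))
  if (!is.na(x$power)) cat(sprintf(", power = %.3f", x$power))
  if (x$shrink < 1) cat(sprintf(", shrink = %.3f", x$shrink))
  cat("\n")
  invisible(x)
}

# put z on the model's domain
model_domain_z <- function(model, z) {
  if (model$domain == "absolute_z") abs(z) else z
}

# f0(z) and (shrunken) f1(z) evaluated on the model's domain
model_f0 <- function(model, z) dens_eval(model$f0, model_domain_z(model, z))
model_f1 <- function(model, z) {
  model$shrink * dens_eval(model$f1, model_domain_z(model, z))
}

#' Local false discovery rate under a fitted two-groups model
#'
#' Returns \code{pi0 f0(z) / (pi0 f0(z) + (1 - pi0) f1(z))}, the posterior
#' probability that the observation is null. The true discovery rate is
#' \code{1 - local_fdr}. Where the mixture density vanishes the fdr is 1
#' (with a warning).
#'
#' @param model a \code{two_groups_model}.
#' @param z numeric vector of statistics (absolute value is taken for
#'   absolute-scale models).
#' @return numeric vector of local fdr values in [0,1].
#' @export
local_fdr <- function(model, z) {
  g0 <- model$pi0 * model_f0(model, z)
  g1 <- (1 - model$pi0) * model_f1(model, z)
  f <- g0 + g1
  out <- rep(1, length(z))
  ok <- f > 0
  if (!all(ok)) warning("mixture density is zero at some z; local fdr set to 1")
  out[ok] <- g0[ok] / f[ok]
  out
}

#' Fit the normix two-groups model to absolute z-scores
#'
#' EM fit on |z| of the mixture pi0 * halfnormal(s) + (1 - pi0) * |N(mu, 1)|
#' with the constraints s >= 1 and mu > 0 enforced by projection at every
#' M-step. The non-null component is the folded normal, handled with a
#' latent-sign augmentation so every M-step is closed form; the projected
#' updates still maximize the constrained Q function, hence the observed
#' log-likelihood is non-decreasing across iterations.
#'
#' @param z numeric vector of z-scores (absolute values are taken).
#' @param fix_null_scale if \code{TRUE}, the null scale is pinned at the
#'   theoretical value s = 1 and only pi0 and mu are estimated. This is the
#'   recommended setting for dense-effect data.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations; non-convergence warns and returns
#'   the best iterate.
#' @param min_n minimum number of observations required.
#' @return a fitted \code{two_groups_model} on the absolute-z domain, with
#'   \code{details$loglik} holding the log-likelihood trace.
#' @export
fit_normix <- function(z, fix_null_scale = FALSE, tol = 1e-6,
                       max_iter = 1000L, min_n = 100L) {
  a <- abs(as.numeric(z))
  if (length(a) < min_n) {
    stop("fit_normix needs at least ", min_n, " observations")
  }
  if (stats::sd(a) == 0) stop("degenerate input: all |z| equal")

  pi0 <- 0.9
  s <- 1
  mu <- max(stats::quantile(a, 0.75), 1e-3)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d0 <- pi0 * 2 * stats::dnorm(a / s) / s
    d1 <- (1 - pi0) * (stats::dnorm(a - mu) + stats::dnorm(a + mu))
    f <- d0 + d1
    f <- pmax(f, 1e-300)
    ll <- sum(log(f))
    ll_trace <- c(ll_trace, ll)
    w1 <- d1 / f
    w0 <- 1 - w1
    # latent sign of the folded non-null component
    dp <- stats::dnorm(a - mu)
    dm <- stats::dnorm(a + mu)
    gp <- dp / pmax(dp + dm, 1e-300)
    pi0 <- mean(w0)
    if (!fix_null_scale) {
      sw0 <- sum(w0)
      s <- if (sw0 > 0) sqrt(sum(w0 * a^2) / sw0) else 1
      s <- max(1, s)  # projection: null scale cannot fall below theoretical
    }
    sw1 <- sum(w1)
    mu_new <- if (sw1 > 0) sum(w1 * a * (2 * gp - 1)) / sw1 else mu
    mu <- max(mu_new, 1e-3)  # projection: non-null location stays positive
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) warning("normix EM did not converge within max_iter; returning best iterate")
  two_groups_model(
    pi0 = min(max(pi0, 0), 1),
    f0 = dens_halfnorm(s),
    f1 = dens_folded(mu, 1),
    domain = "absolute_z",
    details = list(method = "normix", loglik = ll_trace,
                   converged = converged, iterations = length(ll_trace))
  )
}

#' Fit a simplified locfdr-style two-groups model to signed z-scores
#'
#' Tries, in order: (1) maximum-likelihood fit of an empirical null
#' N(delta, sigma) to the central region |z| <= 2 (truncated-sample MLE),
#' (2) central matching (quadratic fit to the log central histogram), and
#' (3) the theoretical N(0,1) null with pi0 from the fraction of central
#' z-scores. Each fall-back triggers when the previous branch estimates
#' pi0 > 1. The mixture density f is a kernel estimate; f1 is derived as
#' (f - pi0 f0)/(1 - pi0), floored at zero and renormalized. This is a
#' spline-free re-implementation; exact agreement with the published locfdr
#' package is not a goal.
#'
#' @param z numeric vector of signed z-scores.
#' @param central half-width of the central (null-dominated) region.
#' @return a \code{two_groups_model} on the signed-z domain;
#'   \code{details$branch} is one of \code{"mle"}, \code{"central_matching"},
#'   \code{"theoretical"}.
#' @export
fit_locfdr_style <- function(z, central = 2) {
  z <- as.numeric(z)
  n <- length(z)
  branch <- NULL
  delta <- 0; sigma <- 1; pi0 <- NA_real_

  in_central <- abs(z) <= central
  n_central <- sum(in_central)

  if (n >= 200L) {
    # --- MLE empirical null on the central region (truncated normal) ---
    zc <- z[in_central]
    nll <- function(par) {
      d <- par[1]; s <- exp(par[2])
      pa <- stats::pnorm((central - d) / s) - stats::pnorm((-central - d) / s)
      if (pa <= 0) return(1e10)
      sum(log(s) + (zc - d)^2 / (2 * s^2)) + length(zc) * log(pa)
    }
    fit <- stats::optim(c(mean(zc), log(stats::sd(zc))), nll, method = "Nelder-Mead")
    d_hat <- fit$par[1]; s_hat <- exp(fit$par[2])
    pa <- stats::pnorm((central - d_hat) / s_hat) -
      stats::pnorm((-central - d_hat) / s_hat)
    pi0_hat <- (n_central / n) / pa
    if (pi0_hat <= 1) {
      branch <- "mle"; delta <- d_hat; sigma <- s_hat; pi0 <- pi0_hat
    } else {
      # --- central matching: quadratic fit to log density on central bins ---
      h <- graphics::hist(zc, breaks = seq(-central, central, length.out = 25L),
                          plot = FALSE)
      keep <- h$counts > 0
      x <- h$mids[keep]
      y <- log(h$counts[keep] / (n * diff(h$breaks)[1]))
      cf <- stats::coef(stats::lm(y ~ x + I(x^2)))
      if (is.finite(cf[3]) && cf[3] < 0) {
        s_cm <- sqrt(-1 / (2 * cf[3]))
        d_cm <- cf[2] * s_cm^2
        pi0_cm <- exp(cf[1] + d_cm^2 / (2 * s_cm^2)) * s_cm * sqrt(2 * pi)
        if (pi0_cm <= 1) {
          branch <- "central_matching"; delta <- d_cm; sigma <- s_cm; pi0 <- pi0_cm
        }
      }
    }
  }
  if (is.null(branch)) {
    branch <- "theoretical"
    delta <- 0; sigma <- 1
    pa <- stats::pnorm(central) - stats::pnorm(-central)
    pi0 <- min(1, (n_central / n) / pa)
  }
  pi0 <- min(max(pi0, 0), 1)

  # mixture density via kernel estimate; f1 by subtraction
  de <- stats::density(z, n = 1024L)
  f0_spec <- dens_norm(delta, sigma)
  f1y <- pmax(0, de$y - pi0 * dens_eval(f0_spec, de$x))
  if (pi0 < 1 && sum(f1y) > 0) {
    f1y <- f1y / (sum(f1y) * mean(diff(de$x)))  # renormalize to a density
  } else {
    f1y <- rep(0, length(de$x))
  }
  two_groups_model(
    pi0 = pi0,
    f0 = f0_spec,
    f1 = dens_grid(de$x, f1y),
    domain = "signed_z",
    details = list(method = "locfdr_style", branch = branch,
                   null_mean = delta, null_sd = sigma)
  )
}

#' Estimate the power of a study from its two-groups model
#'
#' Power is defined as the expected true discovery rate under the non-null
#' density, \code{E_f1[1 - fdr(z)]}: a measure of how separated the null and
#' non-null groups are. Computed by trapezoidal integration on a fixed grid
#' of 2001 points spanning the model's support.
#'
#' @param model a fitted \code{two_groups_model}.
#' @param grid_max upper end of the integration grid; defaults to a range
#'   wide enough for the fitted densities.
#' @return a number in [0,1]; defined as 0 when \code{pi0 = 1}.
#' @export
estimate_power <- function(model, grid_max = NULL) {
  if (model$pi0 >= 1) return(0)
  if (is.null(grid_max)) {
    grid_max <- switch(model$f1$kind,
      folded = model$f1$mu + 8 * model$f1$sd,
      norm = abs(model$f1$mean) + 8 * model$f1$sd,
      grid = max(abs(model$f1$x)),
      10)
    grid_max <- max(grid_max, 10) + 5
  }
  lo <- if (model$domain == "absolute_z") 0 else -grid_max
  g <- seq(lo, grid_max, length.out = 2001L)
  f1v <- dens_eval(model$f1, g)  # unshrunk f1: power is a property of the fit
  tdr <- 1 - local_fdr_raw(model, g)
  val <- sum(diff(g) * (utils::head(f1v * tdr, -1) + utils::tail(f1v * tdr, -1)) / 2)
  # normalize by the f1 mass actually on the grid (guards truncation error)
  mass <- sum(diff(g) * (utils::head(f1v, -1) + utils::tail(f1v, -1)) / 2)
  if (mass > 0) val <- val / mass
  min(max(val, 0), 1)
}

# local fdr without the shrink factor (power must not depend on shrinkage)
local_fdr_raw <- function(model, z) {
  g0 <- model$pi0 * dens_eval(model$f0, model_domain_z(model, z))
  g1 <- (1 - model$pi0) * dens_eval(model$f1, model_domain_z(model, z))
  f <- g0 + g1
  ifelse(f > 0, g0 / f, 1)
}

#' Shrink the non-null density by the estimated study power
#'
#' Multiplies f1(z) by the study's estimated power, computing the power first
#' if needed. The shrunken f1 is deliberately not renormalized: it enters all
#' downstream likelihoods as is, so low-power studies contribute less
#' non-null evidence.
#'
#' @param model a fitted \code{two_groups_model}.
#' @return the model with its \code{shrink} factor set to the power.
#' @export
shrink_f1 <- function(model) {
  if (is.na(model$power)) model$power <- estimate_power(model)
  model$shrink <- model$power
  model
}

#' Fit two-groups models to every study of a matrix
#'
#' Converts p-values to z-scores if needed, fits the chosen estimator per
#' study column, and (optionally) applies power shrinkage to f1.
#'
#' @param x a \code{study_matrix} on either scale.
#' @param estimator \code{"normix"} (absolute-z half-normal/normal mixture)
#'   or \code{"locfdr"} (signed-z empirical-null fit).
#' @param null \code{"theoretical"} fixes the normix null scale at 1;
#'   \code{"empirical"} estimates it (s >= 1).
#' @param shrink apply power shrinkage to f1 (default \code{TRUE}).
#' @return a list of \code{two_groups_model}, one per study.
#' @export
fit_study_models <- function(x, estimator = c("normix", "locfdr"),
                             null = c("theoretical", "empirical"),
                             shrink = TRUE) {
  estimator <- match.arg(estimator)
  null <- match.arg(null)
  Z <- as_zscores(x)
  models <- lapply(seq_len(ncol(Z$values)), function(j) {
    zj <- Z$values[, j]
    m <- if (estimator == "normix") {
      fit_normix(zj, fix_null_scale = (null == "theoretical"))
    } else {
      fit_locfdr_style(zj)
    }
    m$power <- estimate_power(m)
    if (shrink) m <- shrink_f1(m)
    m
  })
  names(models) <- colnames(Z$values)
  models
}

#' Write a fitted two-groups model as plain-text key/value pairs
#' @param model a \code{two_groups_model}.
#' @param path output path.
#' @export
write_two_groups_model <- function(model, path) {
  num <- function(v) paste(format(v, digits = 17), collapse = ",")
  lines <- c(
    paste0("pi0\t", num(model$pi0)),
    paste0("domain\t", model$domain),
    paste0("power\t", num(model$power)),
    paste0("shrink\t", num(model$shrink)),
    paste0("f0.kind\t", model$f0$kind),
    paste0("f1.kind\t", model$f1$kind)
  )
  for (nm in setdiff(names(model$f0), "kind")) {
    lines <- c(lines, paste0("f0.", nm, "\t", num(model$f0[[nm]])))
  }
  for (nm in setdiff(names(model$f1), "kind")) {
    lines <- c(lines, paste0("f1.", nm, "\t", num(model$f1[[nm]])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-groups model written by \code{write_two_groups_model}
#' @param path input path.
#' @return a \code{two_groups_model}.
#' @export
read_two_groups_model <- function(path) {
  kv <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  vals <- stats::setNames(kv[[2]], kv[[1]])
  getnum <- function(key) as.numeric(strsplit(vals[[key]], ",")[[1]])
  spec <- function(prefix) {
    kind <- vals[[paste0(prefix, ".kind")]]
    keys <- grep(paste0("^", prefix, "\\.(?!kind)"), names(vals),
                 value = TRUE, perl = TRUE)
    params <- lapply(keys, getnum)
    names(params) <- sub(paste0(prefix, "."), "", keys, fixed = TRUE)
    c(list(kind = kind), params)
  }
  two_groups_model(
    pi0 = getnum("pi0"), f0 = spec("f0"), f1 = spec("f1"),
    domain = vals[["domain"]],
    power = getnum("power"), shrink = getnum("shrink")
  )
}

# per-study likelihood pieces for a z-scale matrix:
#   F0[i,j] = f0_j(z_ij), F1[i,j] = shrink_j * f1_j(z_ij), pi0 vector
lik_components <- function(x, models) {
  Z <- as_zscores(x)
  m <- ncol(Z$values)
  stopifnot(length(models) == m)
  F0 <- matrix(0, nrow(Z$values), m)
  F1 <- matrix(0, nrow(Z$values), m)
  for (j in seq_len(m)) {
    F0[, j] <- model_f0(models[[j]], Z$values[, j])
    F1[, j] <- model_f1(models[[j]], Z$values[, j])
  }
  list(F0 = F0, F1 = F1,
       pi0 = vapply(models, function(mo) mo$pi0, numeric(1)),
       gene_ids = rownames(Z$values), study_ids = colnames(Z$values))
}
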