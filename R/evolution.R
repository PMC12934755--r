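#' Drift-diffusion model of pairwise RNA similarity
#'
#' The density `f(s, t)` of pairwise similarity scores `s` evolves under a
#' Fokker-Planck equation `df/dt = -d/ds[A(s) f] + D d2f/ds2`: the drift
#' `A(s)` captures systematic similarity change (motif swapping), the
#' diffusion `D` random change (mutation). The domain is truncated to
#' `[s_min, 1]` with reflecting boundaries because the reference drift
#' `A(s) = -D/(2s)` diverges at 0 while its stationary density `s^(-1/2)`
#' stays integrable; the default grid is logarithmically spaced, matching
#' the power-law geometry of that solution.
#'
#' Built-in drifts: `"sqrt_inverse"` is `A(s) = -D/(2 s)` (stationary
#' density proportional to `s^(-1/2)`), `"zero"` pure diffusion (uniform
#' steady state), `"const"` is `A(s) = const_k`.
#'
#' @param drift a function `A(s)`, or one of `"sqrt_inverse"`, `"zero"`,
#'   `"const"`
#' @param D diffusion coefficient (similarity^2 per unit time), > 0
#' @param s_min lower domain boundary in (0, 1)
#' @param n_grid number of grid points when `grid` is not given
#' @param grid optional strictly increasing grid in `[s_min, 1]`
#' @param const_k drift value for `drift = "const"`
#' @return an `evolution_model`
#' @export
evolution_model <- function(drift = "sqrt_inverse", D = 1, s_min = 0.01,
                            n_grid = 400L, grid = NULL, const_k = -1) {
  stopifnot(D > 0, s_min > 0, s_min < 1)
  if (is.null(grid)) {
    grid <- exp(seq(log(s_min), log(1), length.out = n_grid))
  }
  stopifnot(all(diff(grid) > 0), min(grid) > 0, max(grid) <= 1)
  drift_name <- NULL
  if (is.character(drift)) {
    drift_name <- match.arg(drift, c("sqrt_inverse", "zero", "const"))
    drift <- switch(drift_name,
                    sqrt_inverse = function(s) -D / (2 * s),
                    zero = function(s) rep(0, length(s)),
                    const = function(s) rep(const_k, length(s)))
  }
  structure(list(drift = drift, drift_name = drift_name, D = D,
                 s_min = s_min, grid = grid, const_k = const_k),
            class = "evolution_model")
}

gauss_legendre_7 <- list(
  x = c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0,
        0.4058451513773972, 0.7415311855993945, 0.9491079123427585),
  w = c(0.1294849661688697, 0.2797053914892766, 0.3818300505051189,
        0.4179591836734694, 0.3818300505051189, 0.2797053914892766,
        0.1294849661688697))

cum_integral <- function(f, grid) {
  # cumulative integral of f from grid[1], per-interval 7-point
  # Gauss-Legendre (machine-precision for smooth drifts)
  n <- length(grid)
  inc <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- grid[[i]]; b <- grid[[i + 1L]]
    x <- (a + b) / 2 + (b - a) / 2 * gauss_legendre_7$x
    inc[[i]] <- (b - a) / 2 * sum(gauss_legendre_7$w * f(x))
  }
  c(0, cumsum(inc))
}

trapz_w <- function(grid) {
  n <- length(grid)
  w <- numeric(n)
  d <- diff(grid)
  w[1L] <- d[[1L]] / 2
  w[n] <- d[[n - 1L]] / 2
  if (n > 2L) w[2:(n - 1L)] <- (d[-(n - 1L)] + d[-1L]) / 2
  w
}

#' Stationary density of the drift-diffusion model
#'
#' Zero-flux steady state `f(s) = C exp((1/D) integral A(s) ds)`, evaluated
#' by per-interval Gauss quadrature of the drift and normalized to unit mass
#' on the grid (trapezoidal weights).
#'
#' @param model an `evolution_model`
#' @return a `density_estimate` with fields `s` and `f`
#' @export
stationary_density <- function(model) {
  phi <- cum_integral(model$drift, model$grid) / model$D
  phi <- phi - max(phi)
  f <- exp(phi)
  mass <- sum(trapz_w(model$grid) * f)
  if (!is.finite(mass) || mass <= 0) {
    stop("stationary density is not normalizable on the grid")
  }
  structure(list(s = model$grid, f = f / mass), class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("density estimate on [%.4g, %.4g], %d grid points\n",
              min(x$s), max(x$s), length(x$s)))
  invisible(x)
}

#' Fit a power-law exponent to a density or a sample
#'
#' Least-squares slope of `log f` against `log s`. For a density table the
#' lowest and highest 5% of support points are excluded (boundary layers of
#' the truncated domain bias the tails); samples are trimmed at their 5%/95%
#' quantiles and binned into log-spaced histogram bins first.
#'
#' @param x a `density_estimate`, a list with `s` and `f`, or a numeric
#'   sample of similarity scores
#' @param trim tail fraction excluded on each side (default 0.05)
#' @param bins histogram bin count for samples
#' @return list with `alpha` (exponent), `se` (standard error), `n_points`
#' @export
fit_power_law <- function(x, trim = 0.05, bins = 40L) {
  if (is.list(x)) {
    s <- x$s; f <- x$f
  } else {
    smp <- x[x > 0]
    q <- quantile(smp, c(trim, 1 - trim))
    smp <- smp[smp >= q[[1L]] & smp <= q[[2L]]]
    br <- exp(seq(log(min(smp)), log(max(smp)), length.out = bins + 1L))
    h <- graphics::hist(smp, breaks = br, plot = FALSE)
    keep <- h$counts > 0
    return(fit_loglog(h$mids[keep], h$density[keep], trim = 0))
  }
  if (length(s) < 10L) stop("need at least 10 support points")
  fit_loglog(s, f, trim)
}

fit_loglog <- function(s, f, trim) {
  n <- length(s)
  if (trim > 0) {
    lo <- ceiling(n * trim); hi <- n - lo
    idx <- (lo + 1L):hi
    s <- s[idx]; f <- f[idx]
  }
  if (any(f <= 0)) stop("nonpositive density in fit range")
  fit <- lm(log(f) ~ log(s))
  # noiseless tables trigger lm's perfect-fit note; the zero se is the answer
  se <- suppressWarnings(unname(summary(fit)$coefficients[2L, 2L]))
  list(alpha = unname(coef(fit)[[2L]]), se = se, n_points = length(s))
}

#' Recover the drift from a stationary density
#'
#' Inverts the zero-flux stationary condition `A(s) = D f'(s) / f(s)` with
#' central differences on the (possibly nonuniform) grid; one-sided at the
#' ends.
#'
#' @param dens `density_estimate` (or list with `s`, `f`; `f > 0`)
#' @param D diffusion coefficient
#' @return numeric drift values `A(s)` on the grid
#' @export
drift_from_density <- function(dens, D = 1) {
  s <- dens$s; f <- dens$f
  if (any(f <= 0)) stop("density must be strictly positive")
  n <- length(s)
  dlf <- numeric(n)
  lf <- log(f)
  for (i in 2:(n - 1L)) {
    hp <- s[[i + 1L]] - s[[i]]
    hm <- s[[i]] - s[[i - 1L]]
    dlf[[i]] <- (hm^2 * lf[[i + 1L]] - hp^2 * lf[[i - 1L]] +
                   (hp^2 - hm^2) * lf[[i]]) / (hp * hm * (hp + hm))
  }
  dlf[[1L]] <- (lf[[2L]] - lf[[1L]]) / (s[[2L]] - s[[1L]])
  dlf[[n]] <- (lf[[n]] - lf[[n - 1L]]) / (s[[n]] - s[[n - 1L]])
  D * dlf
}

#' Euler-Maruyama simulation of similarity evolution
#'
#' `s <- s + A(s) dt + sqrt(2 D dt) xi` with reflecting boundaries at
#' `s_min` and 1. Uses R's RNG (so `set.seed()`/`seed` governs the draw);
#' built-in drifts run in compiled code.
#'
#' @param model an `evolution_model`
#' @param n_walkers number of walkers
#' @param n_steps number of time steps
#' @param dt time step; must satisfy `max |A| * dt` below the domain width
#' @param seed optional RNG seed
#' @param init optional initial positions (default uniform on the domain)
#' @return numeric vector of final positions
#' @export
simulate_similarity <- function(model, n_walkers, n_steps, dt, seed = NULL,
                                init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  smin <- model$s_min
  if (is.null(init)) init <- runif(n_walkers, smin, 1)
  amax <- max(abs(model$drift(c(smin, model$grid, 1))))
  if (!is.finite(amax) || amax * dt >= (1 - smin)) {
    stop("step size too large: |A|*dt = ", signif(amax * dt, 3),
         " exceeds the domain width")
  }
  if (!is.null(model$drift_name)) {
    type <- match(model$drift_name, c("sqrt_inverse", "zero", "const"))
    return(sim_em_cpp(init, n_steps, dt, model$D, smin, type,
                      model$const_k))
  }
  s <- init
  sig <- sqrt(2 * model$D * dt)
  for (step in seq_len(n_steps)) {
    s <- s + model$drift(s) * dt + sig * rnorm(length(s))
    repeat {
      below <- s < smin; above <- s > 1
      if (!any(below) && !any(above)) break
      s[below] <- 2 * smin - s[below]
      s[above] <- 2 - s[above]
    }
  }
  s
}
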