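# Sampling uncertain parameters: generic inverse-transform sampling from a
# symbolic p.d.f. via numerical CDF inversion, and uniform index selection
# from realisation vectors.

#' Quadrature and inversion settings
#'
#' @param rel_tol Relative tolerance passed to the adaptive quadrature rule.
#' @param abs_tol Absolute tolerance for the quadrature rule.
#' @param max_subdivisions Subdivision limit for the quadrature rule.
#' @param normalization_tol Maximum allowed `|F(Inf) - 1|`; densities that
#'   integrate further from 1 are rejected, never silently renormalized.
#' @param inversion_tol Tolerance on `|F(x) - z|` for CDF inversion.
#' @param grid_points Number of cache-grid nodes in the substituted variable.
#' @return A list of settings with class `quadrature_settings`.
#' @export
quadrature_settings <- function(rel_tol = 1e-8, abs_tol = 1e-10,
                                max_subdivisions = 200L,
                                normalization_tol = 1e-3,
                                inversion_tol = 1e-9,
                                grid_points = 65L) {
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 max_subdivisions = as.integer(max_subdivisions),
                 normalization_tol = normalization_tol,
                 inversion_tol = inversion_tol,
                 grid_points = as.integer(grid_points)),
            class = "quadrature_settings")
}

# Integrate the substituted integrand over [lo, hi] in u-space.
quad_piece <- function(g, lo, hi, settings) {
  if (hi <= lo) return(0)
  res <- stats::integrate(g, lo, hi,
                          rel.tol = settings$rel_tol, abs.tol = settings$abs_tol,
                          subdivisions = settings$max_subdivisions,
                          stop.on.error = FALSE)
  ok <- res$message == "OK" ||
    res$abs.error <= 10 * max(settings$abs_tol, settings$rel_tol * abs(res$value)) ||
    abs(res$value) < settings$abs_tol
  if (!ok) {
    stop("integration error: quadrature did not converge on [", lo, ", ", hi,
         "] (estimate ", res$value, ", abs.error ", res$abs.error, ", '",
         res$message, "')", call. = FALSE)
  }
  res$value
}

#' Build a numeric CDF from a symbolic probability density
#'
#' The density is a single-argument lambda \eqn{f}.  Its CDF
#' \eqn{F(y) = \int_{-\infty}^{y} f(w)\,dw} is made numerically tractable by
#' the change of variable \eqn{w = \tan(u)}: the integral runs over
#' \eqn{(-\pi/2, \arctan y]} with integrand \eqn{f(\tan u)\,\sec^2 u}, which
#' has finite limits.  At construction the integrand is accumulated over a
#' fixed grid in \eqn{u}; the cached partial sums make later point evaluations
#' cheap and provide the monotonicity spot-check and the normalization test
#' \eqn{|F(\infty)-1| \le} `normalization_tol`.
#'
#' @param pdf A `mathml_expr` lambda with exactly one bound variable, or a
#'   `density_spec`.
#' @param env Evaluation environment for free symbols of the density.
#' @param settings A [quadrature_settings()] object.
#' @return An object of class `numeric_cdf`.
#' @export
numeric_cdf <- function(pdf, env = env_new(), settings = quadrature_settings()) {
  if (inherits(pdf, "density_spec")) pdf <- pdf$pdf
  stopifnot(is_expr(pdf), pdf$kind == "lambda")
  if (length(pdf$bound_vars) != 1L) {
    stop("density lambda must have exactly one bound variable", call. = FALSE)
  }
  f <- function(w) vapply(w, function(wi) apply_lambda(pdf, wi, env), 0)
  g <- function(u) {
    w <- tan(u)
    sec2 <- 1 / cos(u)^2
    val <- ifelse(is.finite(w), f(ifelse(is.finite(w), w, 0)) * sec2, 0)
    val[!is.finite(val)] <- 0
    val
  }
  u_grid <- seq(-pi / 2, pi / 2, length.out = settings$grid_points)
  pieces <- vapply(seq_len(length(u_grid) - 1L), function(j)
    quad_piece(g, u_grid[j], u_grid[j + 1L], settings), 0)
  if (any(pieces < -1e-10)) {
    stop("invalid density: negative mass on a subinterval (pdf takes negative values)",
         call. = FALSE)
  }
  F_grid <- c(0, cumsum(pieces))
  norm <- F_grid[length(F_grid)]
  if (abs(norm - 1) > settings$normalization_tol) {
    stop("invalid density: integral over the real line is ", fmt_num(norm),
         ", outside the normalization tolerance ", settings$normalization_tol,
         call. = FALSE)
  }
  structure(list(pdf = pdf, env = env, f = f, g = g,
                 u_grid = u_grid, F_grid = F_grid,
                 normalization = norm, settings = settings),
            class = "numeric_cdf")
}

# F in u-space, normalized to [0,1].
cdf_value_u <- function(cdf, u) {
  u <- max(-pi / 2, min(pi / 2, u))
  j <- findInterval(u, cdf$u_grid, rightmost.closed = TRUE)
  j <- max(1L, min(j, length(cdf$u_grid)))
  val <- cdf$F_grid[j] + quad_piece(cdf$g, cdf$u_grid[j], u, cdf$settings)
  max(0, min(1, val / cdf$normalization))
}

#' Evaluate a numeric CDF
#'
#' @param cdf A [numeric_cdf()].
#' @param y Point of evaluation; may be `-Inf` or `Inf`.
#' @return `F(y)` in `[0, 1]`.
#' @export
cdf_value <- function(cdf, y) {
  stopifnot(inherits(cdf, "numeric_cdf"))
  cdf_value_u(cdf, atan(y))
}

#' Invert a numeric CDF
#'
#' Finds the smallest `x` with `|F(x) - z|` within the inversion tolerance.
#' The root is bracketed from the construction-time grid, refined by a
#' safeguarded Newton iteration on `F(x) - z` (the damped least-squares view
#' of minimising `(F(x) - z)^2`; the density is the exact derivative), and —
#' when the density vanishes at the solution, i.e. `F` has a flat plateau —
#' pushed to the left edge of the plateau by bisection, so that the smallest
#' minimiser is returned.
#'
#' @param cdf A [numeric_cdf()].
#' @param z A probability; clamped to `[1e-12, 1 - 1e-12]` before inversion.
#' @return The quantile `x`.
#' @export
invert_cdf <- function(cdf, z) {
  stopifnot(inherits(cdf, "numeric_cdf"))
  eps <- 1e-12
  z <- max(eps, min(1 - eps, z))
  tol <- cdf$settings$inversion_tol
  Fn <- cdf$F_grid / cdf$normalization
  n <- length(cdf$u_grid)

  lo_i <- max(which(Fn <= z))
  hi_i <- min(which(Fn >= z))
  if (lo_i == hi_i) {
    # z hit a grid value exactly; widen by one cell where possible.
    lo_i <- max(1L, lo_i - 1L)
    hi_i <- min(n, hi_i + 1L)
  }
  lo <- cdf$u_grid[lo_i]
  hi <- cdf$u_grid[hi_i]

  # Safeguarded Newton in u-space; all quantities finite there.
  u <- (lo + hi) / 2
  Fu <- cdf_value_u(cdf, u)
  for (iter in seq_len(100L)) {
    if (abs(Fu - z) <= tol) break
    if (Fu < z) lo <- u else hi <- u
    du <- cdf$g(u) / cdf$normalization
    u_new <- if (is.finite(du) && du > 0) u - (Fu - z) / du else NA_real_
    if (!is.finite(u_new) || u_new <= lo || u_new >= hi) u_new <- (lo + hi) / 2
    u <- u_new
    Fu <- cdf_value_u(cdf, u)
    if (hi - lo < 1e-13) break
  }
  if (abs(Fu - z) > sqrt(tol)) {
    stop("inversion error: |F(x) - z| = ", fmt_num(abs(Fu - z)),
         " after bracketing and refinement (best iterate x = ",
         fmt_num(tan(u)), ")", call. = FALSE)
  }

  # Flat-plateau tie-break: walk to the left edge of {u : F(u) >= z - tol}.
  if (cdf$g(u) / cdf$normalization < tol) {
    left <- cdf$u_grid[lo_i]
    right <- u
    if (cdf_value_u(cdf, left) < z - tol) {
      for (iter in seq_len(60L)) {
        mid <- (left + right) / 2
        if (cdf_value_u(cdf, mid) >= z - tol) right <- mid else left <- mid
        if (right - left < 1e-12) break
      }
    } else {
      right <- left
    }
    u <- right
  }
  tan(u)
}

#' Sample from a symbolic density by CDF inversion
#'
#' The generic inverse-transform sampler: each draw consumes exactly one
#' uniform deviate `z` from the stream and returns `invert_cdf(F, z)`.
#'
#' @param spec A `density_spec` (or bare density lambda).
#' @param env Evaluation environment for free symbols.
#' @param rng An [rng_stream()].
#' @param settings A [quadrature_settings()].
#' @param n Number of draws (the CDF is constructed once).
#' @return Numeric vector of `n` draws.
#' @export
sample_density <- function(spec, env = env_new(), rng,
                           settings = quadrature_settings(), n = 1L) {
  cdf <- numeric_cdf(spec, env, settings)
  z <- rng_uniform(rng, n)
  vapply(z, function(zi) invert_cdf(cdf, zi), 0)
}

#' Sample from a realisation vector
#'
#' Draws one uniform deviate `z` per sample and returns the realisation at
#' index `floor(z * n) + 1`, so every index is equally likely.  Multivariate
#' realisations are returned whole: tuple components are never decoupled.
#'
#' @param spec A `realisations_spec`.
#' @param rng An [rng_stream()].
#' @param n Number of draws.
#' @return For scalar realisations a numeric vector of length `n`; for
#'   `k`-tuples an `n x k` matrix.  The chosen indices are attached as
#'   attribute `"index"`.
#' @export
sample_realisations <- function(spec, rng, n = 1L) {
  stopifnot(inherits(spec, "realisations_spec"))
  m <- nrow(spec$values)
  z <- rng_uniform(rng, n)
  idx <- pmin(m, floor(z * m) + 1L)
  out <- spec$values[idx, , drop = FALSE]
  if (ncol(out) == 1L) {
    out <- as.numeric(out)
  }
  attr(out, "index") <- idx
  out
}

#' Draw one full parameter set
#'
#' Samples every uncertainty assertion independently, in document order, from
#' the single supplied stream, recording per-assertion provenance (the
#' realisation index, or the fact that a density inversion was used).
#'
#' @param assertions List of `uncertainty_assertion` objects with pairwise
#'   disjoint targets.
#' @param env Evaluation environment for density free symbols.
#' @param rng An [rng_stream()].
#' @param settings A [quadrature_settings()].
#' @return An object of class `parameter_draw` with fields `values` (named
#'   numeric, one entry per target) and `provenance` (per-assertion list).
#' @export
draw_parameter_set <- function(assertions, env = env_new(), rng,
                               settings = quadrature_settings()) {
  values <- numeric()
  provenance <- list()
  for (a in assertions) {
    tnames <- vapply(a$targets, function(t) t$variable, "")
    res <- tryCatch({
      if (inherits(a$spec, "density_spec")) {
        x <- sample_density(a$spec, env, rng, settings, n = 1L)
        list(vals = stats::setNames(x, tnames),
             prov = list(kind = "density", targets = tnames))
      } else {
        x <- sample_realisations(a$spec, rng, n = 1L)
        idx <- attr(x, "index")
        vals <- if (is.matrix(x)) stats::setNames(as.numeric(x[1L, ]), tnames)
                else stats::setNames(as.numeric(x), tnames)
        list(vals = vals,
             prov = list(kind = "realisations", targets = tnames, index = idx))
      }
    }, error = function(e) {
      stop("sampling failed for uncertain parameter(s) ",
           paste(tnames, collapse = ", "), ": ", conditionMessage(e),
           call. = FALSE)
    })
    values <- c(values, res$vals)
    provenance <- c(provenance, list(res$prov))
  }
  structure(list(values = values, provenance = provenance),
            class = "parameter_draw")
}

#' @export
print.parameter_draw <- function(x, ...) {
  cat("<parameter_draw>\n")
  print(x$values)
  invisible(x)
}
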