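#' Conway-Maxwell-Poisson normalizing constant
#'
#' Computes `log Z(lambda, nu)` where `Z = sum_{n>=0} lambda^n / (n!)^nu`,
#' entirely in log space. The series is summed past its largest term (at
#' roughly `n = lambda^(1/nu)`) and truncated once the next term falls below
#' `tol` times the partial sum. Parameter regions whose largest term lies
#' beyond `max_terms` (tiny `nu` with `lambda >= 1`, where the series is
#' effectively divergent at this precision) are rejected.
#'
#' @param lam,nu distribution parameters, both `> 0`.
#' @param tol relative truncation tolerance.
#' @param max_terms hard cap on the number of series terms.
#' @param min_terms force summation through at least this support point.
#' @return a list with `log_z` and `truncation_n` (the largest support point
#'   included in the sum).
#' @export
cmp_normalizer <- function(lam, nu, tol = 1e-12, max_terms = 1e5,
                           min_terms = 0L) {
  if (!is.finite(lam) || lam <= 0) stop("lam must be > 0")
  if (!is.finite(nu) || nu <= 0) stop("nu must be > 0")
  mode_n <- lam^(1 / nu)
  if (mode_n > max_terms) {
    stop(sprintf(
      "normalizer series for (lam = %g, nu = %g) peaks near n = %.3g, beyond the %g-term cap; this parameter region is numerically divergent",
      lam, nu, mode_n, max_terms))
  }
  log_lam <- log(lam)
  lt <- 0           # log term at n = 0
  log_z <- 0        # log partial sum
  n <- 0L
  repeat {
    n <- n + 1L
    lt <- lt + log_lam - nu * log(n)
    log_z <- max(log_z, lt) + log1p(exp(-abs(log_z - lt)))
    if (n >= max_terms) break
    if (n > mode_n && n >= min_terms && lt < log(tol) + log_z) break
  }
  list(log_z = log_z, truncation_n = n)
}

#' Conway-Maxwell-Poisson parameter object
#'
#' Bundles the parameters `(lambda, nu)` of the CMP PMF
#' `P(n) = lambda^n / (n!)^nu / Z(lambda, nu)` with its precomputed
#' log-normalizer. `nu = 1` recovers the Poisson distribution; `nu > 1` is
#' under-dispersed, `nu < 1` over-dispersed.
#'
#' @inheritParams cmp_normalizer
#' @return an object of class `cmp_params` with elements `lam`, `nu`,
#'   `log_z`, `truncation_n`, `tol`.
#' @export
cmp_params <- function(lam, nu, tol = 1e-12, max_terms = 1e5,
                       min_terms = 0L) {
  z <- cmp_normalizer(lam, nu, tol = tol, max_terms = max_terms,
                      min_terms = min_terms)
  structure(list(lam = lam, nu = nu, log_z = z$log_z,
                 truncation_n = z$truncation_n, tol = tol),
            class = "cmp_params")
}

#' @export
print.cmp_params <- function(x, ...) {
  cat(sprintf("<cmp_params> lambda = %.6g, nu = %.6g (log Z = %.6g, %d terms)\n",
              x$lam, x$nu, x$log_z, x$truncation_n))
  if (!is.null(x$loglik)) {
    cat(sprintf("  fitted: logLik = %.4f on %d observations%s\n", x$loglik,
                x$n_obs, if (isTRUE(x$converged)) "" else " (NOT converged)"))
  }
  invisible(x)
}

#' CMP log probability mass
#'
#' `log P(n) = n log(lambda) - nu log(n!) - log Z`, evaluated in log space.
#' If a requested support point lies beyond the truncation used for the
#' normalizer, the normalizer is recomputed with extended truncation.
#'
#' @param n vector of non-negative integers.
#' @param params a [cmp_params()] object.
#' @return vector of log-probabilities.
#' @export
cmp_log_pmf <- function(n, params) {
  stopifnot(inherits(params, "cmp_params"))
  if (any(n < 0) || any(n != floor(n))) stop("support is the non-negative integers")
  if (length(n) && max(n) > params$truncation_n) {
    params <- cmp_params(params$lam, params$nu, tol = params$tol,
                         min_terms = max(n))
  }
  n * log(params$lam) - params$nu * lgamma(n + 1) - params$log_z
}

# negative log-likelihood on the (log lam, log nu) scale; large finite value
# in numerically divergent regions so the optimizer backs off
.cmp_nll <- function(par, x) {
  lam <- exp(par[1]); nu <- exp(par[2])
  if (!is.finite(lam) || !is.finite(nu) || lam <= 0 || nu <= 0) return(1e12)
  if (lam^(1 / nu) > 1e5) return(1e12)
  z <- cmp_normalizer(lam, nu)
  -(sum(x) * log(lam) - nu * sum(lgamma(x + 1)) - length(x) * z$log_z)
}

#' Maximum-likelihood fit of a CMP distribution
#'
#' Fits `(lambda, nu)` to a set of non-negative integers by direct
#' log-likelihood maximization over `(log lambda, log nu)`. Two deterministic
#' starts are used -- a moment-matched point (`nu0` from the mean/variance
#' ratio, `lambda0` from the mean through the CMP mean approximation
#' `mean ~ lambda^(1/nu) - (nu - 1) / (2 nu)`) and the Poisson point
#' `(mean, 1)` -- and the better optimum is kept, so the fit is a pure
#' function of the data. With `fix_nu = 1` the fit reduces to the closed-form
#' Poisson MLE (`lambda = sample mean`), a useful cross-check.
#'
#' @param values vector of at least two non-negative integers, not all equal.
#' @param fix_nu optionally hold `nu` fixed and optimize `lambda` alone.
#' @param max_iter optimizer iteration cap per start.
#' @return a [cmp_params()] object with extra fields `loglik`, `converged`,
#'   and `n_obs`.
#' @export
fit_cmp <- function(values, fix_nu = NULL, max_iter = 500L) {
  x <- as.numeric(values)
  if (length(x) < 2L) stop("need at least 2 values to fit")
  if (any(x < 0) || any(x != floor(x))) stop("values must be non-negative integers")
  if (all(x == 0)) stop("cannot fit: all values are zero")
  if (length(unique(x)) < 2L) {
    stop("degenerate input: a single distinct value cannot identify (lambda, nu)")
  }
  m <- mean(x); v <- stats::var(x)
  nu0 <- min(max(m / v, 0.05), 20)
  mean_adj <- m + (nu0 - 1) / (2 * nu0)
  lam0 <- if (mean_adj > 0) mean_adj^nu0 else m
  if (!is.finite(lam0) || lam0 <= 0 || lam0^(1 / nu0) > 1e5) lam0 <- m

  if (!is.null(fix_nu)) {
    stopifnot(is.numeric(fix_nu), fix_nu > 0)
    obj <- function(ll) .cmp_nll(c(ll, log(fix_nu)), x)
    o <- stats::optimize(obj, interval = log(c(max(m, 1e-6) * 1e-3,
                                               max(m, 1e-6) * 1e3)),
                         tol = 1e-10)
    fit <- cmp_params(exp(o$minimum), fix_nu)
    fit$loglik <- -o$objective
    fit$converged <- TRUE
    fit$n_obs <- length(x)
    return(fit)
  }

  starts <- list(c(log(lam0), log(nu0)), c(log(m), 0))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, .cmp_nll, x = x, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$convergence != 0) {
    # for strongly under-dispersed small samples the likelihood increases
    # monotonically along a ridge towards nu = Inf (the distribution
    # degenerates to a point mass) and the simplex runs out of iterations;
    # finish with a box-constrained quasi-Newton step whose nu bounds
    # [1e-4, 100] make the maximizer well-defined
    o2 <- tryCatch(
      stats::optim(best$par, .cmp_nll, x = x, method = "L-BFGS-B",
                   lower = c(-700, log(1e-4)), upper = c(700, log(100)),
                   control = list(maxit = max_iter)),
      error = function(e) NULL)
    if (!is.null(o2) && o2$convergence == 0 && o2$value <= best$value) {
      best <- o2
    }
  }
  if (best$convergence != 0) {
    stop(sprintf(
      "CMP fit did not converge within %d iterations; best point lambda = %g, nu = %g, logLik = %g",
      max_iter, exp(best$par[1]), exp(best$par[2]), -best$value))
  }
  fit <- cmp_params(exp(best$par[1]), exp(best$par[2]))
  fit$loglik <- -best$value
  fit$converged <- TRUE
  fit$n_obs <- length(x)
  fit
}

# log pmf floored at exp(-700) to keep code lengths finite under gross
# model mismatch; warns when the floor engages
.floored_log_pmf <- function(n, params) {
  lp <- cmp_log_pmf(n, params)
  if (any(lp < -700)) {
    warning("probability underflow: flooring log-PMF at -700 for ",
            sum(lp < -700), " value(s)")
    lp <- pmax(lp, -700)
  }
  lp
}

#' Code distance between two integer sets
#'
#' The excess number of bits needed to encode each set under the CMP model
#' fitted (by maximum likelihood) to the *other* set rather than its own:
#' `D = sum_{n in Ci} log2(Pi(n)/Pj(n)) + sum_{m in Cj} log2(Pj(m)/Pi(m))`.
#' This excess-bits orientation is non-negative in expectation and symmetric
#' by construction; `as_printed = TRUE` flips the ratio orientation (giving
#' `-D`), matching the sign convention sometimes written with the roles of the
#' two models exchanged.
#'
#' @param ci,cj integer vectors (each must be fittable by [fit_cmp()]).
#' @param as_printed flip to the reversed-ratio sign convention.
#' @param fit_i,fit_j optional prefitted [cmp_params()] for `ci`/`cj`, to
#'   avoid refitting.
#' @return code distance in bits.
#' @export
code_distance <- function(ci, cj, as_printed = FALSE,
                          fit_i = NULL, fit_j = NULL) {
  if (is.null(fit_i)) fit_i <- fit_cmp(ci)
  if (is.null(fit_j)) fit_j <- fit_cmp(cj)
  d <- sum(.floored_log_pmf(ci, fit_i) - .floored_log_pmf(ci, fit_j)) +
    sum(.floored_log_pmf(cj, fit_j) - .floored_log_pmf(cj, fit_i))
  d <- d / log(2)
  if (as_printed) -d else d
}

#' Pairwise code-distance matrix
#'
#' Fits each set once, then fills the symmetric matrix of pairwise
#' [code_distance()] values (zero diagonal). Pairs whose fit fails are marked
#' `NA` with a warning rather than aborting the whole matrix.
#'
#' @param sets named list of integer vectors (length >= 2).
#' @param as_printed passed to [code_distance()].
#' @return a symmetric numeric matrix of class `code_distance_matrix`, in
#'   bits.
#' @export
distance_matrix <- function(sets, as_printed = FALSE) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  labels <- names(sets) %||% paste0("set", seq_along(sets))
  k <- length(sets)
  fits <- lapply(seq_len(k), function(i) {
    tryCatch(fit_cmp(sets[[i]]), error = function(e) {
      warning("fit failed for set '", labels[i], "': ", conditionMessage(e))
      NULL
    })
  })
  D <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (is.null(fits[[i]]) || is.null(fits[[j]])) {
        D[i, j] <- D[j, i] <- NA_real_
      } else {
        d <- code_distance(sets[[i]], sets[[j]], as_printed = as_printed,
                           fit_i = fits[[i]], fit_j = fits[[j]])
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  class(D) <- c("code_distance_matrix", class(D))
  D
}

#' @export
print.code_distance_matrix <- function(x, digits = 1, ...) {
  m <- unclass(x)
  up <- format(round(m, digits))
  up[lower.tri(m)] <- ""
  cat("code distance (bits), upper triangle:\n")
  print(as.data.frame(up), ...)
  invisible(x)
}
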