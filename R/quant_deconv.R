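# Quantitative deconvolution from scaled peak heights.
#
# For a two-contributor mixture with haploid variant indicators x1, x2 at
# each site and scaled variant peak height y (y0 + y1 = 1), the expected
# height is beta * x1 + (1 - beta) * x2 where beta is the fraction
# contributed by contributor 1. Rewriting,
#
#     y_i - x2_i = beta * (x1_i - x2_i) + eps_i,
#
# a one-parameter no-intercept regression whose least-squares solution is
#
#     beta_hat = sum((y - x2) * (x1 - x2)) / sum((x1 - x2)^2).
#
# Competing contributor pairs are ranked by the conventional R^2 of this
# model; the pair with the larger R^2 is the better-supported hypothesis.

#' Two-contributor mixture model design
#'
#' Assembles the per-site binary variant indicators for an ordered pair of
#' candidate contributors over a common set of sites.
#'
#' @param pair List of two `mt_profile` objects (contributor 1, contributor
#'   2); `beta` refers to the fraction from the first.
#' @param sites Ordered positions to model; defaults to the union of the
#'   pair's variant positions. Sites where the indicators agree carry no
#'   information about the fraction but are retained: they enter the
#'   residual variance and keep the design aligned with tabulated data.
#' @param rcrs_row Prepend the reference pseudo-site row (see
#'   [design_matrix()]).
#' @return An object of class `two_contributor_model` with elements
#'   `pair`, `sites` (character labels), `x1`, `x2`.
#' @export
two_contributor_model <- function(pair, sites = NULL, rcrs_row = FALSE) {
  stopifnot(length(pair) == 2L)
  X <- design_matrix(pair, sites = sites, rcrs_row = rcrs_row)
  structure(list(pair = pair, sites = rownames(X),
                 x1 = X[, 1L], x2 = X[, 2L]),
            class = "two_contributor_model")
}

# peaks aligned to model sites, from an mt_mixture or a named vector
model_peaks <- function(obs, model) {
  y <- if (inherits(obs, "mt_mixture")) obs$peaks else obs
  if (is.null(y)) stop("observation carries no peak heights")
  if (is.null(names(y))) {
    if (length(y) != length(model$sites))
      stop("unnamed peak vector length does not match model sites")
    names(y) <- model$sites
  }
  missing <- setdiff(model$sites, names(y))
  if (length(missing))
    stop("peak heights missing for model site(s): ",
         paste(missing, collapse = ", "))
  as.numeric(y[model$sites])
}

#' Fit the two-contributor peak-height regression
#'
#' Estimates the fraction contributed by the first haplotype of a candidate
#' pair from scaled variant peak heights, by ordinary least squares on the
#' one-parameter rewritten model (see the package vignette). This is the
#' central fitting function; [estimate_fraction()], [model_fit()],
#' [test_no_contribution()] and [rank_hypotheses()] are thin wrappers.
#'
#' @param obs An `mt_mixture` with peak heights, or a named numeric vector
#'   of scaled y1 values (names matching the model's site labels).
#' @param model A `two_contributor_model`, or a list of two `mt_profile`s
#'   (converted with default sites).
#' @return An object of class `mixture_fit` with components `beta_hat`
#'   (least-squares fraction for contributor 1, unclamped), `se`,
#'   `p_value_beta0` (two-sided t-test of no contribution from
#'   contributor 1), `p_value_beta1` (same for contributor 2),
#'   `r_squared` (centered, clipped to \code{[0, 1]}), `flags`, and the
#'   usual model ingredients. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `simulate`, `plot`, `confint`.
#' @examples
#' tab2 <- mtmix_fixture("table2_quant")
#' db <- mtmix_fixture("table1_excerpt")
#' m <- two_contributor_model(db$profiles[c("16093 16189 16293",
#'                                          "16093 16224 16311")],
#'                            sites = tab2$sites, rcrs_row = TRUE)
#' fit_mixture(tab2$y1, m)
#' @export
fit_mixture <- function(obs, model) {
  if (!inherits(model, "two_contributor_model"))
    model <- two_contributor_model(model)
  d <- model$x1 - model$x2
  denom <- sum(d^2)
  if (denom == 0)
    stop("degenerate model: the candidate pair is identical at every ",
         "modelled site, so the fraction is unidentifiable")
  y <- model_peaks(obs, model)
  n <- length(y)
  z <- y - model$x2
  beta_hat <- sum(z * d) / denom
  fitted <- model$x2 + beta_hat * d
  res <- y - fitted
  ss_res <- sum(res^2)
  df <- n - 1L
  sigma2 <- if (df > 0) ss_res / df else NaN
  se <- sqrt(sigma2 / denom)
  tstat <- function(b0) {
    if (se == 0) {
      if (isTRUE(all.equal(beta_hat, b0))) 0 else Inf
    } else (beta_hat - b0) / se
  }
  pval <- function(t) if (df > 0) 2 * stats::pt(-abs(t), df) else NaN
  ss_tot <- sum((y - mean(y))^2)
  flags <- character(0)
  if (beta_hat < 0 || beta_hat > 1)
    flags <- c(flags, "beta_out_of_range")
  if (ss_tot == 0) {
    flags <- c(flags, "constant_response")
    r2 <- 0
  } else {
    r2 <- 1 - ss_res / ss_tot
    if (r2 < 0) flags <- c(flags, "fit_worse_than_mean")
    r2 <- min(max(r2, 0), 1)
  }
  structure(list(beta_hat = beta_hat, se = se,
                 t_beta0 = tstat(0), p_value_beta0 = pval(tstat(0)),
                 t_beta1 = tstat(1), p_value_beta1 = pval(tstat(1)),
                 r_squared = r2, ss_res = ss_res, ss_tot = ss_tot,
                 sigma = sqrt(sigma2), n_sites = n, df = df,
                 y = stats::setNames(y, model$sites),
                 fitted_values = stats::setNames(fitted, model$sites),
                 residuals = stats::setNames(res, model$sites),
                 model = model, flags = flags,
                 call = match.call()),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, digits = 4, ...) {
  cat("Two-contributor mixture fit (", x$n_sites, " sites)\n", sep = "")
  cat("  contributor 1: ", profile_key(x$model$pair[[1]]), "\n",
      "  contributor 2: ", profile_key(x$model$pair[[2]]), "\n", sep = "")
  cat(sprintf("  beta_hat = %.*g (se %.*g), R^2 = %.*g\n",
              digits, x$beta_hat, digits, x$se, digits, x$r_squared))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mixture_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mixture_fit")
}

#' @export
print.summary.mixture_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("  H0 'contributor 1 absent' (beta = 0): t = %.*g, p = %.*g\n",
              digits, f$t_beta0, digits, f$p_value_beta0))
  cat(sprintf("  H0 'contributor 2 absent' (beta = 1): t = %.*g, p = %.*g\n",
              digits, f$t_beta1, digits, f$p_value_beta1))
  cat(sprintf("  residual sd %.*g on %d degrees of freedom\n",
              digits, f$sigma, f$df))
  invisible(x)
}

#' @export
coef.mixture_fit <- function(object, ...) {
  c(beta = object$beta_hat)
}

#' @export
fitted.mixture_fit <- function(object, ...) object$fitted_values

#' @export
residuals.mixture_fit <- function(object, ...) object$residuals

#' @export
predict.mixture_fit <- function(object, newmodel = NULL, ...) {
  if (is.null(newmodel)) return(object$fitted_values)
  if (!inherits(newmodel, "two_contributor_model"))
    newmodel <- two_contributor_model(newmodel)
  b <- object$beta_hat
  stats::setNames(b * newmodel$x1 + (1 - b) * newmodel$x2, newmodel$sites)
}

#' @export
confint.mixture_fit <- function(object, parm = "beta", level = 0.95, ...) {
  a <- (1 - level) / 2
  q <- stats::qt(1 - a, object$df)
  m <- matrix(object$beta_hat + c(-1, 1) * q * object$se, nrow = 1,
              dimnames = list("beta",
                              sprintf("%.1f %%", 100 * c(a, 1 - a))))
  m
}

#' @export
simulate.mixture_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  b <- min(max(object$beta_hat, 0), 1)
  reps <- replicate(nsim,
                    simulate_peaks(object$model, beta = b,
                                   sigma = object$sigma)$peaks)
  as.data.frame(reps, row.names = object$model$sites)
}

#' @export
plot.mixture_fit <- function(x, ...) {
  graphics::plot(x$fitted_values, x$y,
                 xlab = "fitted peak height", ylab = "observed y1",
                 main = "Two-contributor mixture fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

# ---- spec-level wrappers ----------------------------------------------------

#' Least-squares mixture-fraction estimate
#'
#' @inheritParams fit_mixture
#' @return A list with `beta_hat`, `se`, `r_squared`, `p_value_beta0`,
#'   `n_sites` and `flags` (out-of-range estimates are flagged, never
#'   clamped).
#' @export
estimate_fraction <- function(obs, model) {
  f <- fit_mixture(obs, model)
  f[c("beta_hat", "se", "r_squared", "p_value_beta0", "n_sites", "flags")]
}

#' Model fit (R-squared) of a candidate pair
#'
#' @inheritParams fit_mixture
#' @return The centered R^2, clipped to \code{[0, 1]}.
#' @export
model_fit <- function(obs, model) fit_mixture(obs, model)$r_squared

#' Test that a candidate contributor did not contribute
#'
#' Two-sided t-test of beta = 0 (contributor 1 absent) or beta = 1
#' (contributor 2 absent) in the one-parameter regression, on
#' `n_sites - 1` degrees of freedom.
#'
#' @inheritParams fit_mixture
#' @param contributor 1 or 2.
#' @return Two-sided p-value.
#' @export
test_no_contribution <- function(obs, model, contributor = 1) {
  stopifnot(contributor %in% c(1, 2))
  f <- fit_mixture(obs, model)
  if (contributor == 1) f$p_value_beta0 else f$p_value_beta1
}

#' Rank competing contributor pairs by model fit
#'
#' Fits every candidate pair and orders them by decreasing R^2; the
#' best-fitting pair is the better-supported hypothesis. Near-ties
#' (difference below `tolerance`) are reported as unresolved rather than
#' broken arbitrarily.
#'
#' @param obs Peak-height observation as in [fit_mixture()].
#' @param candidate_solutions List of candidate pairs (each a list of two
#'   `mt_profile`s or a `two_contributor_model`).
#' @param sites,rcrs_row Passed to [two_contributor_model()] for candidates
#'   given as profile pairs; all candidates should be modelled over the
#'   same sites for their R^2 values to be comparable.
#' @param tolerance Tie tolerance on R^2 differences.
#' @return A list of class `mixture_ranking`: `order` (indices into the
#'   candidate list, best first), `fits` (the `mixture_fit`s in ranked
#'   order), `tied` (logical: best R^2 not separated from the runner-up).
#' @export
rank_hypotheses <- function(obs, candidate_solutions, sites = NULL,
                            rcrs_row = FALSE, tolerance = 1e-9) {
  if (!length(candidate_solutions)) stop("no candidate pairs supplied")
  fits <- lapply(candidate_solutions, function(cand) {
    if (!inherits(cand, "two_contributor_model"))
      cand <- two_contributor_model(cand, sites = sites,
                                    rcrs_row = rcrs_row)
    fit_mixture(obs, cand)
  })
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  ord <- order(r2, decreasing = TRUE)
  tied <- length(r2) > 1 && abs(r2[ord[1]] - r2[ord[2]]) < tolerance
  structure(list(order = ord, fits = fits[ord], r_squared = r2[ord],
                 tied = tied),
            class = "mixture_ranking")
}

#' @export
print.mixture_ranking <- function(x, digits = 4, ...) {
  cat("Candidate pairs ranked by R^2",
      if (x$tied) "(top candidates tied)" else "", "\n")
  for (i in seq_along(x$fits)) {
    f <- x$fits[[i]]
    cat(sprintf("  %d. {%s | %s}  R^2 = %.*g  beta_hat = %.*g\n", i,
                profile_key(f$model$pair[[1]]),
                profile_key(f$model$pair[[2]]),
                digits, f$r_squared, digits, f$beta_hat))
  }
  invisible(x)
}
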