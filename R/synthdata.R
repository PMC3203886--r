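# Generative simulator for quantitative mixture data.
#
# Per site, the theoretical scaled variant height is
# t_i = beta * x1_i + (1 - beta) * x2_i; observed heights add a normal
# error truncated so the final value stays in [0, 1] (truncation by
# rejection, preserving the truncated distribution; clipping available).
# The extended generator adds per-contributor allele dropout (a
# contributor's variant contribution is zeroed with probability d) and
# drop-in (a small spurious height appears at a reference-only site with
# probability c), mirroring amplification failure and sporadic artifacts.

.sigma_default <- 0.075

draw_truncated <- function(t, sigma, truncation = c("reject", "clip",
                                                    "none")) {
  truncation <- match.arg(truncation)
  y <- t + stats::rnorm(length(t), 0, sigma)
  if (truncation == "reject") {
    bad <- which(y < 0 | y > 1)
    while (length(bad)) {
      y[bad] <- t[bad] + stats::rnorm(length(bad), 0, sigma)
      bad <- bad[y[bad] < 0 | y[bad] > 1]
    }
  } else if (truncation == "clip") {
    y <- pmin(pmax(y, 0), 1)
  }
  y
}

#' Simulate scaled peak heights for a two-contributor mixture
#'
#' @param model A `two_contributor_model` (or a list of two `mt_profile`s).
#' @param beta Fraction contributed by contributor 1, in \code{[0, 1]}.
#' @param sigma Standard deviation of the per-site error (default 0.075,
#'   calibrated in the package vignette; `sigma = 0` reproduces the exact
#'   theoretical heights).
#' @param truncation `"reject"` (resample until the height lies in
#'   \code{[0, 1]}; the default, preserving the truncated-normal law),
#'   `"clip"`, or `"none"` (unbounded errors, for inference diagnostics).
#' @param seed Optional RNG seed; `NULL` continues the current stream.
#' @return An `mt_mixture` whose `peaks` are the simulated y1 values named
#'   by the model's site labels and whose categorical status is the one a
#'   noise-free assay of the pair would report.
#' @examples
#' db <- mtmix_fixture("table1_excerpt")
#' m <- two_contributor_model(db$profiles[c("16093 16189 16293",
#'                                          "16093 16224 16311")])
#' simulate_peaks(m, beta = 0.3, seed = 1)
#' @export
simulate_peaks <- function(model, beta, sigma = .sigma_default,
                           truncation = "reject", seed = NULL) {
  if (!inherits(model, "two_contributor_model"))
    model <- two_contributor_model(model)
  stopifnot(beta >= 0, beta <= 1, sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  t <- beta * model$x1 + (1 - beta) * model$x2
  y <- if (sigma == 0) t else draw_truncated(t, sigma, truncation)
  obs <- observe_mixture(model$pair,
                         range = range(c(.default_range,
                                         vapply(model$pair, function(p)
                                           p$range, integer(2)))))
  obs$peaks <- stats::setNames(y, model$sites)
  obs
}

#' Simulate peak heights with allele dropout and drop-in
#'
#' Extends [simulate_peaks()]: independently per site and contributor, a
#' carried variant fails to contribute with probability `d` (dropout);
#' with probability `c` a spurious variant height appears at a site where
#' neither contributor carries the variant (drop-in). The total signal is
#' not renormalized after dropout -- a failed allele simply amplifies
#' nothing. With `d = c = 0` the generator consumes the identical random
#' stream as [simulate_peaks()], so equal seeds give identical output.
#'
#' @inheritParams simulate_peaks
#' @param d Per-site, per-contributor dropout probability.
#' @param c_in Per-site drop-in probability.
#' @param drop_in_height Function drawing one spurious height given
#'   `sigma`; default the absolute value of a N(0, sigma) draw.
#' @return An `mt_mixture` with simulated peaks; attributes `dropped`
#'   (matrix of dropout indicators) and `dropin` (logical per site) record
#'   the realized events.
#' @export
simulate_with_dropout <- function(model, beta, sigma = .sigma_default,
                                  d = 0, c_in = 0,
                                  drop_in_height = function(sigma)
                                    abs(stats::rnorm(1, 0, sigma)),
                                  truncation = "reject", seed = NULL) {
  if (!inherits(model, "two_contributor_model"))
    model <- two_contributor_model(model)
  stopifnot(beta >= 0, beta <= 1, d >= 0, d <= 1, c_in >= 0, c_in <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(model$sites)
  keep1 <- rep(1, n); keep2 <- rep(1, n)
  if (d > 0) {
    keep1 <- ifelse(model$x1 == 1,
                    stats::rbinom(n, 1, 1 - d), 1)
    keep2 <- ifelse(model$x2 == 1,
                    stats::rbinom(n, 1, 1 - d), 1)
  }
  t <- beta * model$x1 * keep1 + (1 - beta) * model$x2 * keep2
  dropin <- rep(FALSE, n)
  if (c_in > 0) {
    open <- model$x1 == 0 & model$x2 == 0
    dropin <- open & stats::runif(n) < c_in
    for (i in which(dropin)) t[i] <- min(t[i] + drop_in_height(sigma), 1)
  }
  y <- if (sigma == 0) t else draw_truncated(t, sigma, truncation)
  obs <- observe_mixture(model$pair)
  obs$peaks <- stats::setNames(y, model$sites)
  attr(obs, "dropped") <- cbind(c1 = model$x1 * (1 - keep1),
                                c2 = model$x2 * (1 - keep2))
  attr(obs, "dropin") <- dropin
  obs
}

#' Draw random contributors from a haplotype database
#'
#' @param db An `mt_db`.
#' @param m Number of contributors to draw.
#' @param seed Optional RNG seed.
#' @return List of `m` `mt_profile`s drawn iid from the database frequency
#'   distribution.
#' @export
sample_contributors <- function(db, m, seed = NULL) {
  if (!length(db$profiles)) stop("empty database")
  if (!is.null(seed)) set.seed(seed)
  freqs <- db_frequencies(db)
  idx <- sample.int(length(freqs), m, replace = TRUE, prob = freqs)
  db$profiles[idx]
}

#' Simulation study: fraction recovery and model identification
#'
#' Replicates the package's validation design: for each of `n_sims`
#' replicates, peak heights are simulated from the true contributor pair
#' (optionally with dropout/drop-in), every candidate pair is then fitted
#' with the plain no-dropout regression -- deliberately ignoring any
#' dropout in estimation, as an analyst without knowledge of the dropout
#' probability would -- and the replicate is scored correct when the true
#' pair attains the strictly largest R-squared.
#'
#' @param true_pair List of two `mt_profile`s generating the data.
#' @param competing_pairs List of alternative pairs (each a list of two
#'   profiles).
#' @param beta True fraction from contributor 1.
#' @param sigma Noise standard deviation.
#' @param d,c_in Dropout and drop-in probabilities (0 = plain generator).
#' @param n_sims Number of replicates.
#' @param seed RNG seed (one root seed; replicates consume one common
#'   stream, so results are fully reproducible).
#' @param sites,rcrs_row Site set over which all pairs are modelled;
#'   defaults to the union of all pairs' variant positions.
#' @param truncation Passed to the generator.
#' @return Object of class `mixture_study`: `n_sims`, `correct_rate`,
#'   `beta_mean`, `beta_q025`, `beta_q975`, `seed`, plus the per-replicate
#'   `beta_hat` and R-squared draws.
#' @examples
#' db <- mtmix_fixture("table1_excerpt")
#' run_study(db$profiles[c("16093 16189 16293", "16093 16224 16311")],
#'           list(db$profiles[c("16093 16293",
#'                              "16093 16189 16224 16311")]),
#'           beta = 0.3, n_sims = 50, seed = 1)
#' @export
run_study <- function(true_pair, competing_pairs, beta = 0.3,
                      sigma = .sigma_default, d = 0, c_in = 0,
                      n_sims = 1000, seed = 1, sites = NULL,
                      rcrs_row = FALSE, truncation = "reject") {
  stopifnot(n_sims >= 1)
  all_pairs <- c(list(true_pair), competing_pairs)
  if (is.null(sites))
    sites <- sort(unique(unlist(lapply(all_pairs, function(pr)
      c(pr[[1]]$positions, pr[[2]]$positions)))))
  models <- lapply(all_pairs, two_contributor_model, sites = sites,
                   rcrs_row = rcrs_row)
  set.seed(seed)
  beta_hat <- numeric(n_sims)
  r2 <- matrix(NA_real_, n_sims, length(models))
  for (s in seq_len(n_sims)) {
    obs <- if (d > 0 || c_in > 0)
      simulate_with_dropout(models[[1]], beta, sigma, d = d, c_in = c_in,
                            truncation = truncation)
    else simulate_peaks(models[[1]], beta, sigma, truncation = truncation)
    fits <- lapply(models, function(m) fit_mixture(obs$peaks, m))
    beta_hat[s] <- fits[[1]]$beta_hat
    r2[s, ] <- vapply(fits, `[[`, numeric(1), "r_squared")
  }
  correct <- if (length(models) > 1L)
    r2[, 1] > apply(r2[, -1, drop = FALSE], 1, max)
  else rep(TRUE, n_sims)
  q <- stats::quantile(beta_hat, c(0.025, 0.975), names = FALSE)
  structure(list(n_sims = n_sims, correct_rate = mean(correct),
                 beta_mean = mean(beta_hat),
                 beta_q025 = q[1], beta_q975 = q[2], seed = seed,
                 beta = beta, sigma = sigma, d = d, c_in = c_in,
                 beta_hat = beta_hat, r_squared = r2,
                 correct = correct),
            class = "mixture_study")
}

#' @export
print.mixture_study <- function(x, digits = 4, ...) {
  cat("Mixture simulation study (", x$n_sims, " replicates, sigma = ",
      x$sigma, if (x$d > 0) paste0(", dropout d = ", x$d) else "",
      ", seed = ", x$seed, ")\n", sep = "")
  cat(sprintf("  correct model identified: %.*g%%\n",
              digits, 100 * x$correct_rate))
  cat(sprintf("  beta_hat: mean %.*g, central 95%% [%.*g, %.*g] (true %.*g)\n",
              digits, x$beta_mean, digits, x$beta_q025, digits, x$beta_q975,
              digits, x$beta))
  invisible(x)
}
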