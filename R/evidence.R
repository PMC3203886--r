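# Likelihood-ratio calculus for mtDNA mixture evidence.
#
# Evidence attaches to maternal lineages, not individuals: everyone in a
# matriline shares the haplotype, so an LR quantifies support for "a
# lineage matching X contributed" against an alternative. Haplotype
# probabilities are plain counting estimates from a database.

new_lr <- function(lr, num, den, label_num, label_den, detail = list()) {
  if (!is.finite(den) || den <= 0) stop("denominator likelihood must be > 0")
  structure(list(lr = lr, likelihood_num = num, likelihood_den = den,
                 label_num = label_num, label_den = label_den,
                 detail = detail),
            class = "mt_lr")
}

#' @export
print.mt_lr <- function(x, digits = 6, ...) {
  cat("Likelihood ratio\n")
  cat("  H_num:", x$label_num, "\n")
  cat("  H_den:", x$label_den, "\n")
  cat(sprintf("  P(E|H_num) = %.*g, P(E|H_den) = %.*g\n",
              digits, x$likelihood_num, digits, x$likelihood_den))
  cat(sprintf("  LR = %.*g, log10(LR) = %s\n", digits, x$lr,
              if (x$lr > 0) sprintf("%.*g", digits, log10(x$lr)) else "-Inf"))
  invisible(x)
}

#' LR for a mixture with one known and one queried contributor
#'
#' Hypothesis pair of the usual casework form -- numerator: the mixture
#' comes from the known lineage (e.g. the victim's) and the suspect's
#' lineage; denominator: the known lineage and an unknown lineage. The LR
#' reduces to 1/p with p the frequency estimate of the suspect haplotype.
#' Arithmetic is carried out on the integer counts so that e.g. a count of
#' 1 in an add-one-augmented database of 2575 gives exactly 2576.
#'
#' @param db An `mt_db` (may be `NULL` when `freq` is given).
#' @param suspect The suspect's `mt_profile` (ignored when `freq` given).
#' @param unseen_policy Passed to [haplotype_frequency()]; `"add_one"` is
#'   the conventional, defendant-favorable treatment of an unseen
#'   haplotype.
#' @param freq Optional externally supplied frequency estimate of the
#'   suspect haplotype, overriding the database lookup (for published
#'   summary figures where the full database is unavailable).
#' @return An `mt_lr`.
#' @examples
#' lr_known_contributor(freq = 1 / 11)  # LR = 11
#' @export
lr_known_contributor <- function(db = NULL, suspect = NULL,
                                 unseen_policy = c("add_one", "error"),
                                 freq = NULL) {
  if (is.null(freq)) {
    p <- haplotype_frequency(db, suspect, unseen_policy)
    lr <- attr(p, "total") / attr(p, "count")
    detail <- list(count = attr(p, "count"), total = attr(p, "total"),
                   freq = as.numeric(p))
  } else {
    p <- freq
    lr <- 1 / freq
    detail <- list(freq = freq)
  }
  new_lr(lr, num = 1, den = as.numeric(p),
         label_num = "known lineage + queried lineage contributed",
         label_den = "known lineage + unknown lineage contributed",
         detail = detail)
}

#' LR for a specific pair of unknown contributors
#'
#' Numerator: the mixture comes from the two named lineages (likelihood 1,
#' the pair explaining the stain exactly). Denominator: two lineages drawn
#' independently from the database frequencies form the same unordered
#' pair -- 2 p1 p2 for distinct profiles (both orderings of an iid draw),
#' p^2 for an identical pair. The factor-2 convention can be disabled.
#'
#' @param db An `mt_db` (may be `NULL` when `freqs` is given).
#' @param pair List of two `mt_profile`s.
#' @param unseen_policy Passed to [haplotype_frequency()].
#' @param freqs Optional numeric length-2 vector of the two haplotype
#'   frequencies, overriding database lookup; use equal values for an
#'   identical pair.
#' @param ordered_factor Multiply distinct-pair denominators by 2
#'   (default TRUE).
#' @return An `mt_lr`.
#' @examples
#' lr_two_unknown(freqs = c(1 / 11, 1 / 11))  # LR = 60.5
#' @export
lr_two_unknown <- function(db = NULL, pair = NULL,
                           unseen_policy = c("add_one", "error"),
                           freqs = NULL, ordered_factor = TRUE) {
  if (is.null(freqs)) {
    stopifnot(length(pair) == 2L)
    distinct <- !same_profile(pair[[1]], pair[[2]])
    p1 <- haplotype_frequency(db, pair[[1]], unseen_policy)
    p2 <- haplotype_frequency(db, pair[[2]], unseen_policy)
    freqs <- c(as.numeric(p1), as.numeric(p2))
  } else {
    stopifnot(length(freqs) == 2L)
    # raw frequencies carry no profile identity: pairs are taken as
    # distinct unless the caller marks them identical
    distinct <- !isTRUE(attr(freqs, "identical_pair"))
  }
  den <- if (distinct && ordered_factor) 2 * freqs[1] * freqs[2]
         else freqs[1] * freqs[2]
  new_lr(1 / den, num = 1, den = den,
         label_num = "the two named lineages formed the mixture",
         label_den = "two random lineages formed the mixture",
         detail = list(freqs = as.numeric(freqs), distinct = distinct,
                       ordered_factor = ordered_factor))
}

#' Probability that an m-contributor mixture is informative
#'
#' A mixture of identical haplotypes is unidentifiable; with k distinct
#' profiles at frequencies p1..pk, the probability that m iid draws are
#' not all identical is 1 - sum(p_j^m).
#'
#' @param freqs Numeric vector of distinct-profile frequencies (summing to
#'   1 within 1e-9), or an `mt_db` from which they are taken.
#' @param m Number of contributors (>= 2).
#' @return Probability in \code{[0, 1]}.
#' @examples
#' prob_informative(rep(1 / 11, 11), m = 2)  # 10/11
#' @export
prob_informative <- function(freqs, m) {
  if (inherits(freqs, "mt_db")) freqs <- db_frequencies(freqs)
  stopifnot(m >= 2, m == round(m))
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", format(sum(freqs)), ")")
  1 - sum(freqs^m)
}

#' Monte-Carlo estimate of the informative-mixture probability
#'
#' Simulation counterpart of [prob_informative()]: draws m contributors
#' iid from the database frequencies `n_sims` times and reports the
#' fraction of draws that are not all identical, with its binomial
#' standard error.
#'
#' @param db An `mt_db`.
#' @param m Number of contributors (>= 2).
#' @param n_sims Number of simulated mixtures.
#' @param seed Optional RNG seed.
#' @return List with `estimate`, `se`, `n_sims`.
#' @export
prob_informative_mc <- function(db, m, n_sims = 10000, seed = NULL) {
  stopifnot(n_sims >= 1, m >= 2)
  if (!is.null(seed)) set.seed(seed)
  freqs <- db_frequencies(db)
  k <- length(freqs)
  draws <- matrix(sample.int(k, n_sims * m, replace = TRUE, prob = freqs),
                  nrow = n_sims)
  informative <- rowSums(draws != draws[, 1L]) > 0L
  est <- mean(informative)
  list(estimate = est, se = sqrt(est * (1 - est) / n_sims), n_sims = n_sims)
}

# ---- clinical contamination-vs-instability ----------------------------------

#' Likelihood of x mutations under the instability hypothesis
#'
#' Likelihood of observing x different mutated/heteroplasmic positions out
#' of S phylogenetic sites under the hypothesis that the tumor added
#' mutations. With mutations striking independently and uniformly over the
#' S sites (the default reading), the likelihood is (1/S)^x; the
#' `"distinct_sites"` alternative conditions on the x sites being distinct
#' and gives 1/choose(S, x). S must be supplied by the caller: a
#' conservative analysis assigns a lower limit rather than defaulting.
#'
#' @param S Number of phylogenetic sites considered (>= 1).
#' @param x Number of observed mutated positions (1 <= x <= S).
#' @param site_model `"independent_uniform"` or `"distinct_sites"`.
#' @return Probability.
#' @examples
#' mutation_likelihood(S = 100, x = 8)  # 1e-16
#' @export
mutation_likelihood <- function(S, x,
                                site_model = c("independent_uniform",
                                               "distinct_sites")) {
  site_model <- match.arg(site_model)
  stopifnot(S >= 1, x >= 1, 0 < S)
  if (site_model == "distinct_sites") {
    if (x > S) stop("x > S impossible when the x sites must be distinct")
    1 / choose(S, x)
  } else {
    if (x > S) stop("x must not exceed S")
    (1 / S)^x
  }
}

#' LR of contamination versus tumor instability
#'
#' For a clinical sample whose apparent instabilities exactly reproduce a
#' known haplotype's variant pattern, compares H2 "the data result from
#' contamination by that haplotype" against H1 "the tumor added x
#' independent mutations". The numerator is the contaminating haplotype's
#' frequency (summed over candidates when deconvolution leaves several);
#' the denominator is [mutation_likelihood()]. With no consistent
#' contaminating haplotype the contamination hypothesis is dismissed
#' outright (LR = 0, no calculation needed).
#'
#' @param S,x,site_model As in [mutation_likelihood()].
#' @param p_c Numeric vector of candidate contaminating-haplotype
#'   frequencies (length 0 = no consistent candidate).
#' @return An `mt_lr` (numerator = contamination); `detail$status` is
#'   `"dismissed"` when `p_c` is empty.
#' @examples
#' contamination_lr(S = 100, x = 8, p_c = 0.01)  # LR = 1e14
#' @export
contamination_lr <- function(S, x, p_c,
                             site_model = c("independent_uniform",
                                            "distinct_sites")) {
  site_model <- match.arg(site_model)
  lab_num <- "contamination by a known lineage"
  lab_den <- "mutations/heteroplasmies added by the tumor"
  if (!length(p_c)) {
    out <- structure(list(lr = 0, likelihood_num = 0,
                          likelihood_den = mutation_likelihood(S, x,
                                                               site_model),
                          label_num = lab_num, label_den = lab_den,
                          detail = list(status = "dismissed",
                                        note = paste("no haplotype",
                                                     "combination consistent",
                                                     "with the data"))),
                     class = "mt_lr")
    return(out)
  }
  stopifnot(all(p_c > 0), all(p_c <= 1))
  den <- mutation_likelihood(S, x, site_model)
  num <- sum(p_c)
  new_lr(num / den, num = num, den = den, label_num = lab_num,
         label_den = lab_den,
         detail = list(S = S, x = x, p_c = p_c, site_model = site_model))
}
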