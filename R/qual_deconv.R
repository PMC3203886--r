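# Categorical (qualitative) deconvolution: exhaustive search for the
# contributor combinations from a haplotype database that are consistent
# with a mixed stain, assuming no dropout and no drop-in. The search result
# has three possible outcomes: no solution, a unique solution, or several.

#' Consistency of a contributor set with a mixture observation
#'
#' A set of haplotypes explains a stain (under the no-dropout, no-drop-in
#' assumption) iff at every position: a MIXED call requires at least one
#' contributor carrying the variant and at least one carrying the
#' reference; a VARIANT_ONLY call requires every contributor to carry the
#' variant; a REF_ONLY call requires that no contributor carries it.
#'
#' @param contributors List of `mt_profile` objects (repeats allowed; an
#'   identical pair can only explain a stain with no MIXED position).
#' @param obs An `mt_mixture`.
#' @param known Optional list of profiles that must be members of
#'   `contributors` (e.g. a typed victim); an error is raised otherwise.
#' @return Logical scalar.
#' @examples
#' db <- mtmix_fixture("table1_excerpt")
#' obs <- parse_mixture("16093 16189Y 16293R")
#' is_consistent(list(db$profiles[["16093"]],
#'                    db$profiles[["16093 16189 16293"]]), obs)
#' @export
is_consistent <- function(contributors, obs, known = NULL) {
  stopifnot(length(contributors) >= 1L)
  if (!is.null(known)) {
    keys <- vapply(contributors, profile_key, character(1))
    for (kp in known)
      if (!profile_key(kp) %in% keys)
        stop("known contributor '", format(kp),
             "' is not in the candidate set")
  }
  carried <- lapply(contributors, `[[`, "positions")
  union_pos <- sort(unique(c(unlist(carried),
                             as.integer(names(obs$status)))))
  for (p in union_pos) {
    n_carry <- sum(vapply(carried, function(v) p %in% v, logical(1)))
    st <- mixture_status(obs, p)
    ok <- switch(st,
                 REF_ONLY     = n_carry == 0L,
                 VARIANT_ONLY = n_carry == length(contributors),
                 MIXED        = n_carry >= 1L &&
                                n_carry < length(contributors))
    if (!ok) return(FALSE)
  }
  TRUE
}

# all m-multisets of 1..k as an iterator-free list of integer vectors
multiset_index <- function(k, m) {
  if (m == 0L) return(list(integer(0)))
  if (k == 0L) return(list())
  out <- list()
  rec <- function(prefix, start, left) {
    if (left == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (j in start:k) rec(c(prefix, j), j, left - 1L)
  }
  rec(integer(0), 1L, m)
  out
}

new_search_outcome <- function(solutions, m, obs) {
  status <- if (!length(solutions)) "NO_SOLUTION"
            else if (length(solutions) == 1L) "UNIQUE" else "MULTIPLE"
  structure(list(status = status, solutions = solutions, m = m, obs = obs),
            class = "mt_search")
}

#' Enumerate contributor combinations consistent with a stain
#'
#' Exhaustively searches the unordered m-multisets of distinct database
#' profiles (repetition of a profile is only ever consistent when the stain
#' has no MIXED position) and returns every combination satisfying
#' [is_consistent()]. The search is deliberately unoptimized exhaustive
#' enumeration; a guard refuses m > 4 or more than 10,000 distinct profiles
#' unless `force = TRUE`.
#'
#' Candidate sets are only combinatorially consistent; they should still be
#' reviewed for phylogenetic plausibility (haplotype combinations that make
#' no evolutionary sense point to artifacts), which this function does not
#' attempt.
#'
#' @param db An `mt_db`.
#' @param obs An `mt_mixture`.
#' @param m Number of contributors (>= 1).
#' @param known Optional list of `mt_profile`s fixed as members of every
#'   candidate set (constraining the search, not subtracting signal).
#' @param force Override the combinatorial-size guard.
#' @return An `mt_search` object with `status` in NO_SOLUTION / UNIQUE /
#'   MULTIPLE and `solutions`, a list of contributor lists in deterministic
#'   (lexicographic) order.
#' @examples
#' db <- mtmix_fixture("table1_excerpt")
#' enumerate_contributors(db, parse_mixture("16093 16189Y 16293R"), m = 2)
#' @export
enumerate_contributors <- function(db, obs, m, known = NULL, force = FALSE) {
  if (!is.numeric(m) || length(m) != 1L || m < 1L || m != round(m))
    stop("m must be a single integer >= 1")
  m <- as.integer(m)
  profiles <- db$profiles
  k <- length(profiles)
  if (!force && (m > 4L || k > 10000L))
    stop("refusing exhaustive search with m = ", m, " over ", k,
         " distinct profiles; pass force = TRUE to override")
  known_keys <- vapply(known %||% list(), profile_key, character(1))
  if (length(known_keys) > m)
    stop("more known contributors than m")
  # prefilter: a candidate may not carry any REF_ONLY variant, and must
  # carry every VARIANT_ONLY position (that status requires all carriers)
  var_only <- as.integer(names(obs$status)[obs$status == "VARIANT_ONLY"])
  allowed <- as.integer(names(obs$status))  # MIXED or VARIANT_ONLY
  ok <- vapply(profiles, function(p)
    all(p$positions %in% allowed) && all(var_only %in% p$positions),
    logical(1))
  cand_keys <- names(profiles)[ok]
  if (any(!known_keys %in% cand_keys))
    return(new_search_outcome(list(), m, obs))
  free_keys <- setdiff(cand_keys, known_keys)
  m_free <- m - length(known_keys)
  solutions <- list()
  for (idx in multiset_index(length(free_keys), m_free)) {
    keys <- c(known_keys, free_keys[idx])
    contribs <- profiles[keys]
    if (is_consistent(contribs, obs))
      solutions[[length(solutions) + 1L]] <- contribs
  }
  # deterministic lexicographic order on the sorted contributor keys
  if (length(solutions)) {
    sols_sorted <- lapply(solutions, function(s)
      s[order(vapply(s, profile_key, character(1)))])
    lab <- vapply(sols_sorted, function(s)
      paste(vapply(s, profile_key, character(1)), collapse = " | "),
      character(1))
    solutions <- sols_sorted[order(lab)]
  }
  new_search_outcome(solutions, m, obs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enlarged contributor sets consistent with the same stain
#'
#' Given a consistent base solution, enumerates every enlarged set formed
#' by adding up to `m_extra` database profiles that remains consistent with
#' the observation. Any haplotype whose variants coincide with the base
#' contributors' outside the mixed positions can be added without changing
#' the categorical data, so a unique m-person solution does not rule out
#' larger mixtures -- this function documents that ambiguity.
#'
#' @param db An `mt_db`.
#' @param obs An `mt_mixture`.
#' @param base_solution List of `mt_profile`s consistent with `obs`.
#' @param m_extra Maximum number of added contributors (>= 0).
#' @return List of contributor lists, including `base_solution` itself
#'   (the zero-additions case), in deterministic order.
#' @export
superset_solutions <- function(db, obs, base_solution, m_extra) {
  stopifnot(m_extra >= 0)
  if (!is_consistent(base_solution, obs))
    stop("base_solution is not consistent with the observation")
  keys <- names(db$profiles)
  out <- list()
  for (extra in 0:m_extra) {
    for (idx in multiset_index(length(keys), extra)) {
      contribs <- c(base_solution, db$profiles[keys[idx]])
      if (is_consistent(contribs, obs))
        out[[length(out) + 1L]] <- contribs
    }
  }
  lab <- vapply(out, function(s)
    paste(sort(vapply(s, profile_key, character(1))), collapse = " | "),
    character(1))
  out[order(lengths(out), lab)]
}

#' @export
print.mt_search <- function(x, ...) {
  cat("Deconvolution search (m = ", x$m, "): ", x$status, "\n", sep = "")
  if (x$status == "NO_SOLUTION") {
    cat("  No consistent combination; consider contamination or an",
        "incomplete database.\n")
  } else {
    for (i in seq_along(x$solutions))
      cat(sprintf("  [%d] %s\n", i,
                  paste(vapply(x$solutions[[i]], profile_key, character(1)),
                        collapse = "  |  ")))
    cat("  Note: candidate sets warrant phylogenetic review;",
        "larger mixtures may also be consistent (see superset_solutions).\n")
  }
  invisible(x)
}
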