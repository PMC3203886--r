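# Shared generators and brute-force oracles, independent of the package's
# search/closed-form code paths.

table1_db <- function() mtmix_fixture("table1_excerpt")
table2 <- function() mtmix_fixture("table2_quant")

h <- function(db, key) db$profiles[[key]]
H21 <- "16093"
H22 <- "16093 16189 16293"
H23 <- "16093 16224 16311"
H1263 <- "16093 16293"
H2135 <- "16093 16189 16224 16311"

# random transition-only profile over a small site pool
random_profile <- function(pool = c(16069, 16093, 16126, 16189, 16224,
                                    16293, 16294, 16304, 16311)) {
  n <- sample(0:length(pool), 1)
  txt <- if (n == 0) "rCRS" else
    paste(sort(sample(pool, n)), collapse = " ")
  parse_profile(txt)
}

random_db <- function(n_entries, pool) {
  profs <- replicate(max(2, ceiling(n_entries / 2)),
                     format(random_profile(pool)))
  haplotype_db(sample(profs, n_entries, replace = TRUE))
}

# direct set-logic consistency check (independent of is_consistent's code)
oracle_consistent <- function(profiles, obs) {
  pos_sets <- lapply(profiles, `[[`, "positions")
  all_pos <- sort(unique(c(unlist(pos_sets),
                           as.integer(names(obs$status)))))
  for (p in all_pos) {
    n <- sum(vapply(pos_sets, function(v) p %in% v, logical(1)))
    st <- obs$status[as.character(p)]
    if (is.na(st)) st <- "REF_ONLY"
    if (st == "REF_ONLY" && n != 0) return(FALSE)
    if (st == "VARIANT_ONLY" && n != length(profiles)) return(FALSE)
    if (st == "MIXED" && (n == 0 || n == length(profiles))) return(FALSE)
  }
  TRUE
}

# brute force over all unordered pairs of distinct profiles (incl. identical
# pairs), returning sorted "key | key" labels of consistent pairs
oracle_pairs <- function(db, obs) {
  keys <- names(db$profiles)
  out <- character(0)
  for (i in seq_along(keys)) for (j in i:length(keys)) {
    pr <- db$profiles[c(keys[i], keys[j])]
    if (oracle_consistent(pr, obs))
      out <- c(out, paste(sort(c(keys[i], keys[j])), collapse = " | "))
  }
  sort(out)
}

solution_labels <- function(outcome) {
  sort(vapply(outcome$solutions, function(s)
    paste(sort(vapply(s, format, character(1))), collapse = " | "),
    character(1)))
}

# exhaustive informative-mixture probability over all k^m ordered draws
oracle_prob_informative <- function(freqs, m) {
  k <- length(freqs)
  draws <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  p <- apply(draws, 1, function(ix) prod(freqs[ix]))
  sum(p[apply(draws, 1, function(ix) length(unique(ix)) > 1)])
}

study_pairs <- function(db = table1_db()) {
  list(true = db$profiles[c(H22, H23)],
       false = db$profiles[c(H1263, H2135)])
}
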