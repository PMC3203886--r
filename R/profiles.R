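# Profile and mixture-observation data model.
#
# A haplotype is represented by the set of positions, relative to the rCRS,
# at which it differs from the reference over a declared HVS-I range
# (default 16024-16365). Bare positions denote transitions; explicit
# "T16304C"-style tokens carry ref/alt bases and permit transversions.

.mtmix_env <- new.env(parent = emptyenv())

.default_range <- c(16024L, 16365L)

# two-base IUPAC ambiguity codes; B/D/H/V/N are accepted but flagged
.iupac2 <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))
.iupac_multi <- c("B", "D", "H", "V", "N")

.transition_partner <- c(A = "G", G = "A", C = "T", T = "C")

#' Reference bases at curated control-region sites
#'
#' Returns the bundled lookup table of rCRS reference bases at commonly
#' reported control-region polymorphic sites. The table is used to resolve
#' the implied alternate base of a bare transition token and to validate
#' IUPAC ambiguity codes against the reference; positions absent from the
#' table are handled with bases left unresolved (the deconvolution and
#' likelihood machinery only ever uses variant positions, never bases).
#'
#' @return A data frame with columns `position` and `ref`.
#' @export
rcrs_sites <- function() {
  if (is.null(.mtmix_env$rcrs)) {
    path <- system.file("extdata", "rcrs_sites.tsv", package = "mtmix")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    .mtmix_env$rcrs <- stats::setNames(tab$ref, as.character(tab$position))
  }
  data.frame(position = as.integer(names(.mtmix_env$rcrs)),
             ref = unname(.mtmix_env$rcrs), stringsAsFactors = FALSE)
}

rcrs_base <- function(position) {
  rcrs_sites()  # ensure cache
  unname(.mtmix_env$rcrs[as.character(position)])
}

new_profile <- function(positions = integer(), ref = NULL, alt = NULL,
                        range = .default_range) {
  positions <- as.integer(positions)
  if (anyDuplicated(positions))
    stop("duplicate variant position(s): ",
         paste(unique(positions[duplicated(positions)]), collapse = ", "))
  if (length(positions) &&
      any(positions < range[1] | positions > range[2]))
    stop("position(s) outside range [", range[1], ", ", range[2], "]: ",
         paste(positions[positions < range[1] | positions > range[2]],
               collapse = ", "))
  ord <- order(positions)
  if (is.null(ref)) ref <- rep(NA_character_, length(positions))
  if (is.null(alt)) alt <- rep(NA_character_, length(positions))
  structure(list(positions = positions[ord],
                 ref = as.character(ref)[ord],
                 alt = as.character(alt)[ord],
                 range = as.integer(range)),
            class = "mt_profile")
}

#' Parse an rCRS-relative haplotype profile string
#'
#' Profile strings follow the usual forensic convention: whitespace-separated
#' tokens, each either the literal `"rCRS"` (the profile identical to the
#' reference), a bare position such as `"16093"` (a transition at that
#' position), or an explicit `"T16304C"` token naming ref and alt bases.
#'
#' @param text Profile string, e.g. `"16093 16189 16293"` or `"rCRS"`.
#' @param range Length-2 integer vector, the typed sequence range
#'   (1-based rCRS coordinates, inclusive). Defaults to HVS-I 16024-16365.
#' @return An object of class `mt_profile`.
#' @examples
#' parse_profile("16093 16189 16293")
#' parse_profile("T16126C C16292T C16294T A16399G", range = c(16024, 16569))
#' @export
parse_profile <- function(text, range = .default_range) {
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 1L && toupper(tokens) == "RCRS")
    return(new_profile(range = range))
  pos <- integer(length(tokens))
  ref <- alt <- character(length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (grepl("^[0-9]+$", tok)) {
      pos[i] <- as.integer(tok)
      rb <- rcrs_base(pos[i])
      ref[i] <- if (is.na(rb)) NA_character_ else rb
      alt[i] <- if (is.na(rb)) NA_character_ else .transition_partner[[rb]]
    } else if (grepl("^[ACGTacgt][0-9]+[ACGTacgt]$", tok)) {
      pos[i] <- as.integer(gsub("[^0-9]", "", tok))
      ref[i] <- toupper(substr(tok, 1L, 1L))
      alt[i] <- toupper(substr(tok, nchar(tok), nchar(tok)))
      if (ref[i] == alt[i])
        stop("ref and alt base identical in token '", tok, "'")
      rb <- rcrs_base(pos[i])
      if (!is.na(rb) && rb != ref[i])
        warning("token '", tok, "': stated reference base ", ref[i],
                " differs from rCRS base ", rb, " at ", pos[i])
    } else {
      stop("unparseable profile token '", tok, "'")
    }
  }
  new_profile(pos, ref, alt, range = range)
}

#' @export
format.mt_profile <- function(x, ...) {
  if (!length(x$positions)) return("rCRS")
  tok <- character(length(x$positions))
  for (i in seq_along(x$positions)) {
    implied <- !is.na(x$ref[i]) && !is.na(x$alt[i]) &&
      identical(unname(.transition_partner[[x$ref[i]]]), x$alt[i])
    tok[i] <- if (is.na(x$alt[i]) || implied)
      as.character(x$positions[i])
    else
      paste0(x$ref[i], x$positions[i], x$alt[i])
  }
  paste(tok, collapse = " ")
}

#' @export
print.mt_profile <- function(x, ...) {
  cat("mtDNA profile [", x$range[1], "-", x$range[2], "]: ",
      format(x), "\n", sep = "")
  invisible(x)
}

profile_key <- function(profile) format(profile)

#' Test two profiles for identity
#'
#' Profiles are compared on their canonical representation (sorted variant
#' positions with resolved bases); sample ids play no role.
#'
#' @param a,b `mt_profile` objects.
#' @return Logical scalar.
#' @export
same_profile <- function(a, b) identical(profile_key(a), profile_key(b))

carries <- function(profile, position) position %in% profile$positions

# ---- mixture observations ---------------------------------------------------

new_mixture <- function(status = character(), peaks = NULL,
                        range = .default_range, flagged = integer()) {
  # status: named character vector, names = positions, values in
  # MIXED / VARIANT_ONLY; everything else in range is implicitly REF_ONLY
  stopifnot(all(status %in% c("MIXED", "VARIANT_ONLY")))
  if (!is.null(peaks)) {
    bad <- peaks < 0 | peaks > 1
    if (any(bad, na.rm = TRUE))
      stop("peak heights must lie in [0, 1] (scaled so y0 + y1 = 1)")
  }
  structure(list(status = status, peaks = peaks,
                 range = as.integer(range), flagged = as.integer(flagged)),
            class = "mt_mixture")
}

#' Parse an IUPAC-coded stain (mixture) observation
#'
#' Each whitespace-separated token is a position, optionally suffixed with a
#' single IUPAC ambiguity letter. A suffixed token (e.g. `"16126Y"`) marks
#' the position MIXED (both bases observed); an unsuffixed token marks it
#' VARIANT_ONLY (only the variant base observed); every other position in
#' range is implicitly REF_ONLY. Two-base codes (R, Y, S, W, K, M) are
#' decoded and, where the reference base at the position is known, checked
#' for consistency with the rCRS (a mismatch raises a warning: the observed
#' base pair should include the reference base unless the mixture involves
#' two non-reference variants). Codes denoting more than two bases
#' (B, D, H, V, N) are accepted and flagged.
#'
#' @param text Stain string, e.g. `"16126Y 16292Y 16294Y 16304Y 16399R"`;
#'   the empty string denotes a stain that is reference-only everywhere.
#' @param mixed Optional integer vector of positions to force to MIXED
#'   status (for data reported as plain transitions "displaying a mixture").
#' @param peaks Optional named numeric vector of scaled variant peak
#'   heights y1 (names are positions, values in `[0, 1]`).
#' @inheritParams parse_profile
#' @return An object of class `mt_mixture`.
#' @examples
#' parse_mixture("16126Y 16292Y 16294Y 16304Y 16399R", range = c(16024, 16569))
#' parse_mixture("16093 16189 16293", mixed = c(16189, 16293))
#' @export
parse_mixture <- function(text, mixed = NULL, peaks = NULL,
                          range = .default_range) {
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  status <- character(0)
  flagged <- integer(0)
  for (tok in tokens) {
    if (grepl("^[0-9]+$", tok)) {
      pos <- as.integer(tok)
      st <- "VARIANT_ONLY"
    } else if (grepl("^[0-9]+[A-Za-z]$", tok)) {
      pos <- as.integer(substr(tok, 1L, nchar(tok) - 1L))
      code <- toupper(substr(tok, nchar(tok), nchar(tok)))
      st <- "MIXED"
      if (code %in% names(.iupac2)) {
        rb <- rcrs_base(pos)
        if (!is.na(rb) && !(rb %in% .iupac2[[code]]))
          warning("IUPAC code ", code, " at ", pos, " decodes to {",
                  paste(.iupac2[[code]], collapse = ","),
                  "}, which does not include the rCRS base ", rb)
      } else if (code %in% .iupac_multi) {
        flagged <- c(flagged, pos)
      } else if (code != "X") {
        # "X" appears in the clinical literature for an unspecified mixture
        stop("unknown IUPAC ambiguity code '", code, "' in token '", tok, "'")
      }
    } else {
      stop("unparseable stain token '", tok, "'")
    }
    if (pos < range[1] || pos > range[2])
      stop("position ", pos, " outside range [", range[1], ", ",
           range[2], "]")
    if (as.character(pos) %in% names(status))
      stop("duplicate position ", pos, " in stain")
    status[as.character(pos)] <- st
  }
  if (!is.null(mixed)) status[as.character(as.integer(mixed))] <- "MIXED"
  new_mixture(status, peaks = peaks, range = range, flagged = flagged)
}

#' Noise-free mixture observation from known contributors
#'
#' Builds the categorical observation an ideal assay would report for a
#' mixture of the given haplotypes: positions carried by every contributor
#' are VARIANT_ONLY, positions carried by some but not all are MIXED, and
#' all remaining positions are REF_ONLY.
#'
#' @param profiles List of `mt_profile` contributors.
#' @inheritParams parse_profile
#' @return An `mt_mixture`.
#' @export
observe_mixture <- function(profiles, range = .default_range) {
  all_pos <- sort(unique(unlist(lapply(profiles, `[[`, "positions"))))
  status <- character(0)
  for (p in all_pos) {
    n_carry <- sum(vapply(profiles, carries, logical(1), position = p))
    status[as.character(p)] <-
      if (n_carry == length(profiles)) "VARIANT_ONLY" else "MIXED"
  }
  new_mixture(status, range = range)
}

#' @export
print.mt_mixture <- function(x, ...) {
  cat("mtDNA mixture observation [", x$range[1], "-", x$range[2], "]\n",
      sep = "")
  if (!length(x$status)) {
    cat("  reference-only at every position\n")
  } else {
    for (st in c("VARIANT_ONLY", "MIXED"))
      if (any(x$status == st))
        cat(sprintf("  %-12s %s\n", st,
                    paste(names(x$status)[x$status == st], collapse = " ")))
  }
  if (!is.null(x$peaks))
    cat("  peak heights at", length(x$peaks), "site(s)\n")
  invisible(x)
}

mixture_status <- function(obs, position) {
  st <- unname(obs$status[as.character(position)])
  ifelse(is.na(st), "REF_ONLY", st)
}

# ---- haplotype database -----------------------------------------------------

new_db <- function(entries, range = .default_range) {
  # entries: data.frame(region, sample_id, profile_string)
  profiles <- lapply(entries$profile, parse_profile, range = range)
  keys <- vapply(profiles, profile_key, character(1))
  entries$key <- keys
  distinct <- !duplicated(keys)
  structure(list(entries = entries,
                 profiles = stats::setNames(profiles[distinct],
                                            keys[distinct]),
                 counts = table(factor(keys, levels = keys[distinct])),
                 total = nrow(entries),
                 range = as.integer(range)),
            class = "mt_db")
}

#' Build a haplotype database from sample/profile pairs
#'
#' @param profile Character vector of profile strings.
#' @param sample_id Optional sample identifiers (defaults to row numbers).
#' @param region Optional region labels.
#' @inheritParams parse_profile
#' @return An object of class `mt_db`. Identical profiles under different
#'   sample ids collapse to one distinct profile whose count is the number
#'   of carrying samples; frequency arithmetic is count-based.
#' @export
haplotype_db <- function(profile, sample_id = seq_along(profile),
                         region = "NA", range = .default_range) {
  if (!length(profile)) stop("empty database")
  new_db(data.frame(region = region, sample_id = as.character(sample_id),
                    profile = as.character(profile),
                    stringsAsFactors = FALSE), range = range)
}

#' Load a haplotype database from a delimited file
#'
#' Expects three columns: region, sample id, profile string (profile
#' grammar as in [parse_profile()]). Tab-separated by default.
#'
#' @param path File path.
#' @param sep Field separator (`"\t"` or `","`).
#' @param header Logical; does the first line carry column names?
#' @inheritParams parse_profile
#' @return An `mt_db`.
#' @export
load_database <- function(path, sep = "\t", header = TRUE,
                          range = .default_range) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (header && length(lines)) lines <- lines[-1]
  if (!length(lines)) stop("empty database file: ", path)
  offset <- if (header) 1L else 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], sep, fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed database row at line ", i + offset, ": '",
           lines[i], "'")
    rows[[i]] <- data.frame(region = fields[1], sample_id = fields[2],
                            profile = trimws(paste(fields[-(1:2)],
                                                   collapse = " ")),
                            stringsAsFactors = FALSE)
  }
  db <- tryCatch(new_db(do.call(rbind, rows), range = range),
                 error = function(e) stop("while parsing ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  db
}

#' @export
print.mt_db <- function(x, ...) {
  cat("mtDNA haplotype database: ", x$total, " samples, ",
      length(x$profiles), " distinct profiles\n", sep = "")
  invisible(x)
}

db_count <- function(db, profile) {
  key <- profile_key(profile)
  if (key %in% names(db$counts)) as.integer(db$counts[[key]]) else 0L
}

#' Haplotype frequency estimate from a database
#'
#' Plain counting estimate count/total. For a profile absent from the
#' database the `"add_one"` policy (the conventional approach, favorable to
#' the defendant) adds the query profile once before estimating, giving
#' 1/(total + 1); under `"error"` an unseen profile is an error.
#'
#' @param db An `mt_db`.
#' @param profile An `mt_profile`.
#' @param unseen_policy `"add_one"` or `"error"`.
#' @return Numeric frequency, with attributes `count` and `total` carrying
#'   the exact integer arithmetic.
#' @export
haplotype_frequency <- function(db, profile,
                                unseen_policy = c("add_one", "error")) {
  unseen_policy <- match.arg(unseen_policy)
  n <- db_count(db, profile)
  total <- db$total
  if (n == 0L) {
    if (unseen_policy == "error")
      stop("profile '", format(profile), "' not found in database")
    n <- 1L
    total <- total + 1L
  }
  structure(n / total, count = n, total = total)
}

#' Frequencies of all distinct profiles
#'
#' @param db An `mt_db`.
#' @return Named numeric vector summing to 1, one element per distinct
#'   profile (names are canonical profile strings).
#' @export
db_frequencies <- function(db) {
  f <- as.numeric(db$counts) / db$total
  stats::setNames(f, names(db$counts))
}

# ---- design matrix ----------------------------------------------------------

#' Binary variant design matrix
#'
#' Builds the site-by-profile 0/1 matrix used throughout the quantitative
#' model: entry (i, j) is 1 iff profile j carries the variant at site i.
#'
#' @param profiles List of `mt_profile` objects (optionally named).
#' @param sites Ordered integer vector of positions; defaults to the sorted
#'   union of variant positions across `profiles`.
#' @param rcrs_row If `TRUE`, prepend a pseudo-site row labelled `"rCRS"`
#'   whose entry is 1 iff the profile equals the reference (no variants) --
#'   the convention used when a reference haplotype is tabulated alongside
#'   variant sites.
#' @return Integer matrix with one row per site and one column per profile.
#' @export
design_matrix <- function(profiles, sites = NULL, rcrs_row = FALSE) {
  if (is.null(sites))
    sites <- sort(unique(unlist(lapply(profiles, `[[`, "positions"))))
  sites <- as.integer(sites)
  m <- vapply(profiles,
              function(p) as.integer(sites %in% p$positions),
              integer(length(sites)))
  m <- matrix(m, nrow = length(sites),
              dimnames = list(as.character(sites), names(profiles)))
  if (rcrs_row) {
    top <- vapply(profiles,
                  function(p) as.integer(length(p$positions) == 0L),
                  integer(1))
    m <- rbind(rCRS = top, m)
  }
  m
}
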