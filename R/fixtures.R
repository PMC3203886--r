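# Packaged fixtures: the HVS-I database excerpt, its quantitative
# (peak-height) rendering, and the cigarette-butt casework profiles.

.fixture_names <- c("table1_excerpt", "table2_quant", "example3_case")

#' List the packaged datasets
#'
#' @return Character vector of fixture names usable with
#'   [mtmix_fixture()]: `table1_excerpt` (an excerpt of an Iberian HVS-I
#'   haplotype database, 9 samples / 8 distinct profiles),
#'   `table2_quant` (the same data as a site-by-haplotype 0/1 matrix with
#'   a simulated scaled peak-height column for an H22+H23 mixture at
#'   fraction 0.3), and `example3_case` (victim/suspect/stain profiles
#'   from a murder case in which mtDNA was the only usable evidence).
#' @export
mtmix_fixtures <- function() .fixture_names

#' Load a packaged dataset
#'
#' @param name One of [mtmix_fixtures()].
#' @return `table1_excerpt`: an `mt_db`. `table2_quant`: a list with
#'   `matrix` (the 11-row 0/1 design, haplotype columns), `sites` (the 10
#'   variant positions), `y1` (named peak-height vector incl. the `rCRS`
#'   pseudo-row). `example3_case`: a list with `victim` and `suspect`
#'   profiles and the IUPAC-coded `stain` (`mt_mixture`), typed over the
#'   extended range 16024-16569 (the case profiles include position
#'   16399, beyond HVS-I).
#' @examples
#' mtmix_fixture("table1_excerpt")
#' @export
mtmix_fixture <- function(name = .fixture_names) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "mtmix")
  switch(name,
    table1_excerpt = load_database(path("table1_excerpt.tsv")),
    table2_quant = {
      tab <- utils::read.delim(path("table2_quant.tsv"),
                               check.names = FALSE)
      mat <- as.matrix(tab[, !(names(tab) %in% c("polymorphism", "y1"))])
      rownames(mat) <- tab$polymorphism
      list(matrix = mat,
           sites = as.integer(tab$polymorphism[tab$polymorphism != "rCRS"]),
           y1 = stats::setNames(tab$y1, tab$polymorphism))
    },
    example3_case = {
      tab <- utils::read.delim(path("example3_case.tsv"),
                               stringsAsFactors = FALSE)
      rng <- c(16024L, 16569L)
      get <- function(role) tab$profile[tab$role == role]
      list(victim = parse_profile(get("victim"), range = rng),
           suspect = parse_profile(get("suspect"), range = rng),
           stain = parse_mixture(get("stain"), range = rng))
    })
}
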