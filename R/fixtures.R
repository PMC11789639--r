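#' Bundled synthetic X-Y pair fixture
#'
#' Loads the synthetic 14-species tree and the accompanying 17-pair
#' presence/absence, stratum and Xi-expression tables shipped with the
#' package. These are constructed data (the real species tree and per-gene
#' strata are not published), with stratum maxima and retention patterns on
#' the scale seen for the human X-Y pairs; they exercise [survival_table()]
#' end to end.
#'
#' @return list with `tree` (`phylo`), `presence` (long data.frame: gene,
#'   species, present), `strata` (named list gene -> species subset) and
#'   `xi_expression` (named logical).
#' @examples
#' fx <- xy_pair_fixture()
#' tab <- survival_table(fx$tree, fx$presence, fx$strata, fx$xi_expression)
#' @export
xy_pair_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "xybuffer",
                                  mustWork = TRUE)
  tree <- read_species_tree(path("synthetic_therian_tree.nwk"))
  presence <- utils::read.delim(path("synthetic_presence.tsv"),
                                stringsAsFactors = FALSE)
  strata_long <- utils::read.delim(path("synthetic_strata.tsv"),
                                   stringsAsFactors = FALSE)
  xi <- utils::read.delim(path("synthetic_xi_expression.tsv"),
                          stringsAsFactors = FALSE)
  list(tree = tree,
       presence = presence,
       strata = split(strata_long$species, strata_long$gene),
       xi_expression = stats::setNames(as.logical(xi$xi_expression), xi$gene))
}
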