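#' Read and validate a species tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the requirements of
#' the survival-fraction analysis: a single rooted tree with branch lengths
#' (millions of years), nonnegative lengths, and unique leaf labels.
#'
#' @param file path to a newick file, or
#' @param text newick text (exactly one of the two).
#' @return A validated `phylo` object.
#' @examples
#' tr <- read_species_tree(text = "((A:1,B:1):1,C:2):0;")
#' sum(tr$edge.length)
#' @export
read_species_tree <- function(file = NULL, text = NULL) {
  if (is.null(file) == is.null(text))
    stop("supply exactly one of 'file' or 'text'", call. = FALSE)
  # ape warns (and returns NULL) on malformed input; validation below turns
  # any structural problem into one consistent parse error
  tr <- tryCatch(
    suppressWarnings(
      if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file)
    ),
    error = function(e) stop("newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("newick parse error: input did not yield a single tree",
         call. = FALSE)
  validate_species_tree(tr)
}

#' @rdname read_species_tree
#' @param tree a `phylo` object to validate in place.
#' @export
validate_species_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(is.na(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be nonnegative and non-missing", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("leaf labels must be unique: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted", call. = FALSE)
  tree
}

# tip indices below each node, computed once per tree by postorder
# accumulation (children are visited before their parent)
.node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]
    child <- po$edge[e, 2L]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  desc
}

#' Observed phylogenetic branch length for a set of species
#'
#' Sums the branch lengths of the union of all branches lying on the
#' root-to-leaf paths of the given species — the spanning subtree, rooted at
#' the tree's root, over which a gene is observed to have survived. A branch
#' is counted once no matter how many present species lie below it. The
#' empty set gives 0; the full leaf set gives the total tree length.
#'
#' @param tree a rooted `phylo` with branch lengths (see
#'   [read_species_tree()]).
#' @param present_species character vector of leaf labels in which the gene
#'   is present.
#' @return Total branch length (same units as the tree, typically MY).
#' @examples
#' tr <- read_species_tree(text = "((A:1,B:1):1,C:2):0;")
#' observed_branch_length(tr, c("A", "C"))  # 1 + 1 + 2 = 4
#' @export
observed_branch_length <- function(tree, present_species) {
  validate_species_tree(tree)
  present_species <- unique(as.character(present_species))
  if (length(present_species) == 0L) return(0)
  unknown <- setdiff(present_species, tree$tip.label)
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  target <- match(present_species, tree$tip.label)
  in_set <- logical(length(tree$tip.label))
  in_set[target] <- TRUE
  desc <- .node_tip_sets(tree)
  on_path <- vapply(tree$edge[, 2L],
                    function(child) any(in_set[desc[[child]]]),
                    logical(1L))
  sum(tree$edge.length[on_path])
}

#' Survival fraction of a Y-linked gene
#'
#' Ratio of the observed phylogenetic branch length (branches over which the
#' gene is retained) to the maximum possible branch length for the species
#' set examined. Ranges from 0 (lost in all lineages) to 1 (retained in
#' every lineage). Full precision is returned; round to 3 decimals for
#' table-style reports (see [format_survival_table()]).
#'
#' @param observed observed branch length (MY), `0 <= observed <= maximum`.
#' @param maximum maximum possible branch length (MY), `> 0`.
#' @return `observed / maximum`, vectorized over both arguments.
#' @examples
#' survival_fraction(552, 663)  # 0.833 at 3 decimals
#' @export
survival_fraction <- function(observed, maximum) {
  if (!is.numeric(observed) || !is.numeric(maximum))
    stop("observed and maximum must be numeric", call. = FALSE)
  if (any(is.na(observed)) || any(is.na(maximum)))
    stop("missing branch lengths", call. = FALSE)
  if (any(maximum <= 0))
    stop("maximum branch length must be positive", call. = FALSE)
  if (any(observed < 0) || any(observed > maximum))
    stop("observed branch length must lie in [0, maximum]", call. = FALSE)
  observed / maximum
}

# coerce a long (gene, species, present) data.frame to a logical matrix
.presence_matrix <- function(presence) {
  if (is.data.frame(presence) &&
      all(c("gene", "species", "present") %in% names(presence))) {
    genes <- unique(presence$gene)
    species <- unique(presence$species)
    m <- matrix(FALSE, length(genes), length(species),
                dimnames = list(genes, species))
    m[cbind(match(presence$gene, genes), match(presence$species, species))] <-
      as.logical(as.numeric(presence$present))
    return(m)
  }
  if (is.matrix(presence)) {
    if (is.null(rownames(presence)) || is.null(colnames(presence)))
      stop("presence matrix needs gene rownames and species colnames",
           call. = FALSE)
    storage.mode(presence) <- "logical"
    return(presence)
  }
  stop("presence must be a gene x species matrix or a long data.frame ",
       "with columns gene, species, present", call. = FALSE)
}

#' Survival table for a set of Y-linked genes
#'
#' For each gene, prunes the tree to the gene's stratum (the species subset
#' over which retention can be assessed, i.e. the clade that carried the
#' gene), computes the maximum possible branch length (total length of the
#' pruned tree), the observed branch length over the species retaining the
#' gene, and their ratio, the survival fraction. Genes that arose in
#' different evolutionary strata have different maxima, which is why the
#' stratum map is an explicit input.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param presence gene x species logical/0-1 matrix (rownames = genes), or
#'   a long data.frame with columns `gene`, `species`, `present`.
#' @param stratum_map named list mapping gene id to its stratum species
#'   subset (each of size `>= 2`); genes absent from the map use all leaves.
#' @param xi_expression optional named logical vector: is the X-homolog
#'   expressed from Xi? Used only for the report sort order.
#' @return data.frame with columns `gene`, `xi_expression`, `n_species`,
#'   `n_present`, `observed_bl`, `max_bl`, `survival_fraction`, sorted by
#'   Xi expression (yes first), then survival fraction, then branch length,
#'   all descending.
#' @seealso [format_survival_table()] for Table-style rounding.
#' @export
survival_table <- function(tree, presence, stratum_map = list(),
                           xi_expression = NULL) {
  validate_species_tree(tree)
  pm <- .presence_matrix(presence)
  unknown <- setdiff(colnames(pm), tree$tip.label)
  if (length(unknown))
    stop("presence species not in tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  genes <- rownames(pm)

  rows <- lapply(genes, function(g) {
    stratum <- stratum_map[[g]]
    if (is.null(stratum)) stratum <- tree$tip.label
    stratum <- unique(as.character(stratum))
    if (length(stratum) < 2L)
      stop("gene ", g, ": stratum must contain at least two species",
           call. = FALSE)
    bad <- setdiff(stratum, tree$tip.label)
    if (length(bad))
      stop("gene ", g, ": stratum species not in tree: ",
           paste(bad, collapse = ", "), call. = FALSE)
    sub <- ape::keep.tip(tree, stratum)
    max_bl <- sum(sub$edge.length)
    present <- intersect(stratum, colnames(pm)[pm[g, ]])
    obs <- observed_branch_length(sub, present)
    data.frame(gene = g,
               xi_expression = if (is.null(xi_expression)) NA else
                 isTRUE(xi_expression[[g]]),
               n_species = length(stratum), n_present = length(present),
               observed_bl = obs, max_bl = max_bl,
               survival_fraction = survival_fraction(obs, max_bl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-xtfrm(out$xi_expression), -out$survival_fraction,
               -out$observed_bl)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Format a survival table for reporting
#'
#' Rounds survival fractions to 3 decimals and branch lengths to integer MY,
#' the precision used in published summaries; the unrounded table keeps full
#' precision.
#'
#' @param x a data.frame from [survival_table()].
#' @return The same data.frame with rounded report columns.
#' @export
format_survival_table <- function(x) {
  stopifnot(is.data.frame(x))
  x$observed_bl <- round(x$observed_bl)
  x$max_bl <- round(x$max_bl)
  x$survival_fraction <- round(x$survival_fraction, 3)
  x
}
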