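test_that("newick parsing validates structure and branch lengths", {
  tr <- read_species_tree(text = "(A:1,B:1):0;")
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(sum(tr$edge.length), 2)
  tr3 <- read_species_tree(text = "((A:1,B:1):1,C:2):0;")
  expect_equal(sum(tr3$edge.length), 5)
  expect_error(read_species_tree(text = "((A:1,B:1):1,C:2"), "parse")
  expect_error(read_species_tree(text = "((A,B),C);"), "branch lengths")
  expect_error(read_species_tree(text = "((A:1,A:1):1,C:2):0;"), "unique")
  # round-trips through serialization
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tr3, f)
  expect_equal(sum(read_species_tree(f)$edge.length), 5)
})

test_that("observed branch length covers the trivial unions", {
  tr <- read_species_tree(
    text = "(((A:1,B:2):3,C:4):5,(D:6,E:7):8):0;")
  expect_equal(observed_branch_length(tr, tr$tip.label),
               sum(tr$edge.length))
  expect_equal(observed_branch_length(tr, "A"), 1 + 3 + 5)
  expect_equal(observed_branch_length(tr, character(0)), 0)
  # two non-sister leaves: union of the two root paths
  expect_equal(observed_branch_length(tr, c("A", "D")),
               (1 + 3 + 5) + (6 + 8))
  expect_equal(observed_branch_length(tr, c("A", "D")),
               bf_branch_length(tr, c("A", "D")))
  expect_error(observed_branch_length(tr, "Z"), "Z")
})

test_that("observed branch length is monotone in the present set", {
  set.seed(71)
  for (i in 1:20) {
    tr <- ape::rtree(sample(3:8, 1))
    tips <- sample(tr$tip.label)
    lens <- vapply(seq_along(tips), function(k)
      observed_branch_length(tr, tips[seq_len(k)]), 0)
    expect_true(all(diff(lens) >= -1e-12))
  }
})

test_that("observed branch length equals the union oracle on random trees", {
  set.seed(72)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    tr <- ape::rtree(n)
    for (mask in seq_len(2^n - 1)) {
      present <- tr$tip.label[as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))]
      expect_equal(observed_branch_length(tr, present),
                   bf_branch_length(tr, present))
    }
  }
})

test_that("survival fraction is a guarded ratio", {
  expect_equal(survival_fraction(5, 5), 1)
  expect_equal(round(survival_fraction(343, 967), 3), 0.355)
  expect_error(survival_fraction(1, 0), "positive")
  expect_error(survival_fraction(2, 1), "\\[0, maximum\\]")
  expect_error(survival_fraction(-1, 1), "\\[0, maximum\\]")
})

test_that("survival table recomputes per-gene fractions over strata", {
  fx <- xy_pair_fixture()
  tab <- survival_table(fx$tree, fx$presence, fx$strata, fx$xi_expression)

  # genes retained in every stratum species have fraction exactly 1
  full <- tab$n_present == tab$n_species
  expect_true(all(tab$survival_fraction[full] == 1))
  expect_true(all(tab$survival_fraction >= 0 & tab$survival_fraction <= 1))

  # gene-by-gene agreement with the brute-force oracle on the pruned tree
  pm <- with(fx$presence, {
    m <- matrix(FALSE, length(unique(gene)), length(unique(species)),
                dimnames = list(unique(gene), unique(species)))
    m[cbind(gene, species)] <- present == 1
    m
  })
  for (g in rownames(pm)) {
    sub <- ape::keep.tip(fx$tree, fx$strata[[g]])
    present <- intersect(fx$strata[[g]], colnames(pm)[pm[g, ]])
    expect_equal(tab$observed_bl[tab$gene == g],
                 bf_branch_length(sub, present))
    expect_equal(tab$max_bl[tab$gene == g], sum(sub$edge.length))
  }

  # sorted by Xi expression, then survival fraction, then branch length
  expect_false(is.unsorted(rev(tab$xi_expression)))
  for (grp in split(tab, tab$xi_expression))
    expect_false(is.unsorted(rev(grp$survival_fraction)))
})

test_that("nested presence sets give ordered fractions and rescaling is neutral", {
  tr <- ape::rtree(7)
  tr$edge.length <- tr$edge.length + 0.1
  tips <- tr$tip.label
  pm <- rbind(sub = tips %in% tips[1:3], sup = tips %in% tips[1:5])
  colnames(pm) <- tips
  tab <- survival_table(tr, pm)
  expect_gte(tab$survival_fraction[tab$gene == "sup"],
             tab$survival_fraction[tab$gene == "sub"])

  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 7.3
  tab2 <- survival_table(tr2, pm)
  expect_equal(tab2$survival_fraction, tab$survival_fraction)

  expect_error(survival_table(tr, pm, stratum_map = list(sub = tips[1])),
               "at least two")
})
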