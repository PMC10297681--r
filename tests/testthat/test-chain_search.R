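test_that("head pathways are exactly the pathways containing the head gene", {
  acc <- acc_pathway()
  expect_identical(head_pathways(acc, "FOXP2"), "ACC")
  expect_identical(head_pathways(acc, "NOTAGENE"), character())

  ens <- pathway_ensemble(list(
    P1 = c("FOXP2", "A"), P2 = c("B"), P3 = c("FOXP2", "C"),
    P4 = c("D"), P5 = c("FOXP2")
  ))
  expect_identical(head_pathways(ens, "FOXP2"), c("P1", "P3", "P5"))
})

test_that("level-1 and level-2 chainlink sets follow the chain definitions", {
  # reachable only through an intermediate pathway
  r <- find_chainlinks(two_hop_ensemble(), terminal_set("S", c("G1", "G3")))
  expect_identical(r$levels[["1"]]$genes, character())
  expect_identical(r$levels[["2"]]$genes, "G3")
  expect_identical(r$levels[["1"]]$connectivity, 0L)

  # gene directly on the head pathway
  ens1 <- pathway_ensemble(list(BV = c("FOXP2", "G1")))
  r1 <- find_chainlinks(ens1, terminal_set("S", "G1"))
  expect_identical(r1$levels[["1"]]$genes, "G1")
  expect_identical(r1$levels[["2"]]$genes, character())

  # terminal disjoint from every pathway
  r0 <- find_chainlinks(two_hop_ensemble(), terminal_set("S", c("Z1", "Z2")))
  expect_identical(chainlink_genes(r0), character())
  expect_identical(r0$levels[["1"]]$connectivity, 0L)
  expect_identical(r0$levels[["2"]]$connectivity, 0L)
})

test_that("exclusive and inclusive level conventions differ only on level-1 genes", {
  # G1 is on the head pathway AND on a linked pathway
  r_ex <- find_chainlinks(direct_link_ensemble(), terminal_set("S", c("G1", "G4")))
  r_in <- find_chainlinks(direct_link_ensemble(), terminal_set("S", c("G1", "G4")),
                          inclusive = TRUE)
  expect_identical(r_ex$levels[["1"]]$genes, "G1")
  expect_identical(r_ex$levels[["2"]]$genes, "G4")
  expect_identical(r_in$levels[["2"]]$genes, c("G1", "G4"))
  # exclusive convention keeps levels disjoint
  expect_length(intersect(r_ex$levels[["1"]]$genes, r_ex$levels[["2"]]$genes), 0)
})

test_that("chain search rejects invalid inputs with clear errors", {
  ens <- two_hop_ensemble()
  expect_error(find_chainlinks(ens, terminal_set("S", "G3"), head_gene = "ZZZ"),
               "no head pathway")
  expect_error(find_chainlinks(ens, terminal_set("S", "G3"), max_level = 3),
               "disambiguated")
  expect_error(find_chainlinks(ens, terminal_set("S", "G3"), max_level = 0),
               "max_level")
})

test_that("level-1 set is exactly the terminal intersected with head pathways", {
  for (seed in 1:25) {
    ens <- sweep_ensemble(seed)
    genes <- ensemble_genes(ens)
    set.seed(seed)
    region <- terminal_set("r", sample(genes, 12))
    r <- find_chainlinks(ens, region)
    heads <- head_pathways(ens, "FOXP2")
    head_genes <- unique(unlist(ens$pathways[heads]))
    expect_identical(r$levels[["1"]]$genes,
                     sort(intersect(region$genes, head_genes)))
  }
})

test_that("adding a pathway never shrinks the inclusive chainlink union", {
  set.seed(5)
  for (rep in 1:15) {
    ens <- generate_ensemble(10, 200, c(4, 8), 0.3, seed = rep)
    genes <- ensemble_genes(ens)
    region <- terminal_set("r", sample(genes, 10))
    before <- chainlink_genes(
      find_chainlinks(ens, region, inclusive = TRUE))
    bigger <- ens$pathways
    bigger[["EXTRA"]] <- sample(genes, 6)
    ens2 <- pathway_ensemble(bigger)
    after <- chainlink_genes(
      find_chainlinks(ens2, region, inclusive = TRUE))
    expect_true(all(before %in% after))
  }
})

test_that("connectivity counts pathways collectively (union) or per gene (sum)", {
  ens <- pathway_ensemble(list(
    P1 = c("A", "B"), P2 = c("A", "B", "X"), P3 = c("A", "B"),
    P4 = c("C"), P5 = c("D"), P6 = c("E"), P7 = c("F")
  ))
  expect_identical(connectivity(ens, character()), 0L)
  expect_identical(connectivity(ens, c("A", "B"), mode = "union"), 3L)
  expect_identical(connectivity(ens, c("A", "B"), mode = "sum"), 6L)
  expect_identical(connectivity(ens, "A", mode = "union"), 3L)
  expect_identical(connectivity(ens, c("A", "B"), exclude = "P1"), 2L)
})

test_that("union connectivity <= sum connectivity <= genes x pathways", {
  for (seed in 1:10) {
    ens <- generate_ensemble(12, 150, c(4, 8), 0.4, seed = seed)
    genes <- sample(ensemble_genes(ens), 8)
    u <- connectivity(ens, genes, "union")
    s <- connectivity(ens, genes, "sum")
    expect_lte(u, s)
    expect_lte(s, length(genes) * length(ens$pathways))
  }
})

test_that("chain witnesses enumerate the distinct chains through a gene", {
  # level 1, gene on two head pathways
  ens <- pathway_ensemble(list(
    H1 = c("FOXP2", "G1"), H2 = c("FOXP2", "G1", "G9")
  ))
  w <- chain_witnesses(ens, terminal_set("S", "G1"), "FOXP2", "G1", level = 1)
  expect_identical(nrow(w), 2L)
  expect_identical(w$head_pathway, c("H1", "H2"))
  expect_true(all(is.na(w$intermediate)))

  # non-chainlink gene yields no chains
  w0 <- chain_witnesses(ens, terminal_set("S", "G1"), "FOXP2", "G7", level = 1)
  expect_identical(nrow(w0), 0L)

  # the single level-1 edge of the minimal linked topology
  w1 <- chain_witnesses(direct_link_ensemble(), terminal_set("S", "G2"),
                        "FOXP2", "G2", level = 1)
  expect_identical(nrow(w1), 1L)
  expect_identical(w1$head_pathway, "BV")

  # level 2: (head, intermediate) pairs ordered by ids
  w2 <- chain_witnesses(two_hop_ensemble(), terminal_set("S", "G3"),
                        "FOXP2", "G3", level = 2)
  expect_identical(nrow(w2), 1L)
  expect_identical(w2$head_pathway, "BV")
  expect_identical(w2$intermediate, "B1")
  expect_identical(w2$level, 2L)
})

test_that("reports carry per-gene pathway counts for their chainlink genes", {
  r <- find_chainlinks(direct_link_ensemble(), terminal_set("S", c("G1", "G4")))
  expect_identical(r$per_gene_pathway_counts[["G1"]], 2L)
  expect_identical(r$per_gene_pathway_counts[["G4"]], 1L)
})
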