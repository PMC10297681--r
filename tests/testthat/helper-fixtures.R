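# in-code fixtures shared across test files

# the two-pathway topology where the terminal set reaches the head pathway
# only through an intermediate: head {FOXP2, g2}, intermediate {g2, g3}
two_hop_ensemble <- function() {
  pathway_ensemble(list(BV = c("FOXP2", "G2"), B1 = c("G2", "G3")))
}

# one head pathway linked to one non-head pathway through a shared gene,
# with the terminal set touching the head directly through G2
direct_link_ensemble <- function() {
  pathway_ensemble(list(
    BV = c("FOXP2", "G1", "G2"),
    B2 = c("G1", "G4")
  ))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# frozen generator settings under which every planting seed 1:100 is feasible
sweep_ensemble <- function(seed) {
  generate_ensemble(20, 250, c(4, 8), 0.4, seed = seed)
}

expect_same_chainlinks <- function(a, b) {
  expect_identical(a$levels[["1"]]$genes, b$levels[["1"]]$genes)
  expect_identical(a$levels[["2"]]$genes, b$levels[["2"]]$genes)
  expect_identical(a$levels[["1"]]$connectivity, b$levels[["1"]]$connectivity)
  expect_identical(a$levels[["2"]]$connectivity, b$levels[["2"]]$connectivity)
}
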