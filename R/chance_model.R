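#' Per-gene probability of being a level-2 chainlink gene
#'
#' Under the null model, a gene drawn uniformly from the full symbol universe
#' is a level-2 chainlink gene exactly when it lies on a pathway linked to a
#' head pathway, so the probability is simply the linked-gene fraction
#' `n_linked_genes / n_universe`. In the motivating ensemble 11,746 of the
#' 42,764 HGNC symbols lie on pathways linked to the FOXP2-containing pathway,
#' giving 27.5%.
#'
#' @param n_linked_genes number of distinct genes on linked pathways.
#' @param n_universe total size of the gene-symbol universe (`> 0`).
#' @return probability in `[0, 1]`.
#' @export
per_gene_probability <- function(n_linked_genes, n_universe) {
  stopifnot(length(n_linked_genes) == 1L, length(n_universe) == 1L)
  if (n_universe <= 0) stop("n_universe must be > 0")
  if (n_linked_genes < 0) stop("n_linked_genes must be >= 0")
  if (n_linked_genes > n_universe) {
    stop("n_linked_genes exceeds the gene universe")
  }
  n_linked_genes / n_universe
}

#' Chance of a region having at least one level-2 chain
#'
#' Treats the `k` genes of a region as independent uniform draws from the
#' symbol universe, each a level-2 chainlink gene with probability `p`; the
#' region then carries a level-2 chain with probability `1 - (1 - p)^k`.
#' Monotone non-decreasing in both arguments. For the motivating ensemble the
#' shortest region considered (9 genes) already reaches 94.44% and a 26-gene
#' region 99.98%, which is why chains are never missing in practice.
#'
#' @param p per-gene probability in `[0, 1]`.
#' @param k region size in genes (vectorized, `>= 0`).
#' @return probability (vectorized over `k`).
#' @export
region_chain_probability <- function(p, k) {
  stopifnot(length(p) == 1L, p >= 0, p <= 1, all(k >= 0))
  1 - (1 - p)^k
}

#' Census of pathways and genes linked to the head pathway(s)
#'
#' Counts the ensemble pathways that share at least one gene with a head
#' pathway (the head pathways themselves are not counted) and the distinct
#' genes those linked pathways collectively contain -- the level-2 material of
#' the chance model. By default genes that occur only in head pathways are
#' excluded (they are level-1, not level-2, material); set
#' `include_head_genes = TRUE` to add the head pathways' genes to the census.
#' The symbol-universe size is an explicit input because the ensemble covers
#' only pathway genes, not the whole genome.
#'
#' @inheritParams find_chainlinks
#' @param universe_size total gene-symbol universe size (default 42764, the
#'   HGNC symbol count used in the motivating analysis).
#' @param include_head_genes include head-pathway genes in the linked-gene
#'   count.
#' @return an object of class `chance_inputs`: a list with
#'   `n_linked_pathways`, `n_linked_genes`, `n_universe`, `per_gene_p`.
#' @export
linked_gene_census <- function(ensemble, head_gene = "FOXP2",
                               universe_size = 42764,
                               include_head_genes = FALSE) {
  stopifnot(inherits(ensemble, "pathway_ensemble"))
  heads <- head_pathways(ensemble, head_gene)
  if (length(heads) == 0L) {
    stop("head gene ", head_gene, " absent from the ensemble")
  }
  linked <- linked_pathway_ids(ensemble, heads)
  genes <- unique(unlist(ensemble$pathways[linked], use.names = FALSE))
  if (include_head_genes) {
    genes <- unique(c(genes, unlist(ensemble$pathways[heads], use.names = FALSE)))
  }
  n_linked_genes <- length(genes)
  structure(
    list(n_linked_pathways = length(linked),
         n_linked_genes = n_linked_genes,
         n_universe = universe_size,
         per_gene_p = per_gene_probability(min(n_linked_genes, universe_size),
                                           universe_size)),
    class = "chance_inputs"
  )
}

#' @export
print.chance_inputs <- function(x, ...) {
  cat(sprintf(
    "<chance_inputs> %d linked pathways carrying %d distinct genes of a %d-symbol universe (per-gene p = %.4f)\n",
    x$n_linked_pathways, x$n_linked_genes, x$n_universe, x$per_gene_p))
  invisible(x)
}

#' Fraction of a region's genes that sit on any voice chain
#'
#' `|V1 union V2| / |region|` for a computed chainlink report. Under the
#' randomness null, the mean of this fraction across regions should match the
#' ensemble's per-gene chainlink probability.
#'
#' @param report a `chainlink_report` from [find_chainlinks()] computed for
#'   `region`.
#' @param region the [terminal_set()] the report was computed for.
#' @return fraction in `[0, 1]`.
#' @export
chain_fraction <- function(report, region) {
  stopifnot(inherits(report, "chainlink_report"),
            inherits(region, "terminal_set"))
  if (length(region$genes) == 0L) stop("empty region")
  length(chainlink_genes(report)) / length(region$genes)
}
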