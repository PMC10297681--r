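# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded synthetic pathway ensemble
#'
#' Emulates a pathway collection with tunable overlap density. Pathways are
#' built sequentially: for every earlier pathway, with probability
#' `overlap_density` one of its genes is copied into the new pathway (so
#' `overlap_density` is approximately the probability that any given pair of
#' pathways is linked), and the remaining slots are filled with fresh genes
#' from the universe. The head gene is planted in the first pathway, so at
#' density 0 the head pathway exists and no two pathways share a gene. The
#' generator is a pure function of its arguments: identical spec and seed give
#' identical ensembles.
#'
#' @param n_pathways number of pathways (`>= 1`).
#' @param gene_universe_size number of distinct background gene symbols
#'   available.
#' @param size_range length-2 integer range of pathway sizes.
#' @param overlap_density probability in `[0, 1]` that a pathway inherits a
#'   gene from any given earlier pathway.
#' @param head_gene symbol planted in the first pathway.
#' @param seed RNG seed.
#' @return a [pathway_ensemble()] with pathways `P001`, `P002`, ...
#' @export
generate_ensemble <- function(n_pathways, gene_universe_size,
                              size_range = c(5, 10), overlap_density = 0.1,
                              head_gene = "FOXP2", seed = 1) {
  stopifnot(n_pathways >= 1, gene_universe_size >= 1,
            length(size_range) == 2, size_range[1] >= 1,
            size_range[1] <= size_range[2],
            overlap_density >= 0, overlap_density <= 1)
  head_gene <- normalize_symbol(head_gene)
  if (size_range[2] > gene_universe_size) {
    stop("infeasible spec: pathway size range exceeds the gene universe")
  }
  with_seed(seed, {
    universe <- sprintf("G%05d", seq_len(gene_universe_size))
    unused <- sample(universe)  # draw order fixed by the seed
    sizes <- sample(seq(size_range[1], size_range[2]), n_pathways,
                    replace = TRUE)
    paths <- vector("list", n_pathways)
    for (i in seq_len(n_pathways)) {
      shared <- character()
      if (i > 1 && overlap_density > 0) {
        inherit <- stats::runif(i - 1) < overlap_density
        shared <- unique(vapply(which(inherit), function(j) {
          sample(paths[[j]], 1)
        }, character(1)))
      }
      n_fresh <- max(sizes[i] - length(shared), 0L)
      if (n_fresh > length(unused)) {
        stop("infeasible spec: gene universe exhausted at pathway ", i)
      }
      fresh <- unused[seq_len(n_fresh)]
      if (n_fresh > 0) unused <- unused[-seq_len(n_fresh)]
      paths[[i]] <- c(shared, fresh)
    }
    # plant the head gene in pathway 1, replacing one fresh gene so the
    # size stays in range and density-0 ensembles stay pairwise disjoint
    paths[[1]][1] <- head_gene
    names(paths) <- sprintf("P%03d", seq_len(n_pathways))
    pathway_ensemble(paths)
  })
}

#' Plant a terminal region with known ground truth
#'
#' Builds a terminal set containing exactly `n_level1` genes drawn from head
#' pathways, `n_level2` genes drawn from linked non-head pathways (and not on
#' any head pathway -- the exclusive-level truth labels; inclusive labels
#' follow by union), and `n_background` inert genes that belong to no ensemble
#' pathway. The returned truth labels are what [find_chainlinks()] must
#' recover.
#'
#' @param ensemble a [pathway_ensemble()].
#' @param n_level1,n_level2,n_background how many genes of each class to
#'   plant.
#' @param head_gene the head gene (never planted itself).
#' @param seed RNG seed.
#' @param name region name.
#' @return a list with `region` (a [terminal_set()]) and `truth` (list of
#'   `level1`, `level2`, `background` gene vectors).
#' @export
plant_region <- function(ensemble, n_level1, n_level2, n_background,
                         head_gene = "FOXP2", seed = 1, name = "planted") {
  stopifnot(inherits(ensemble, "pathway_ensemble"),
            n_level1 >= 0, n_level2 >= 0, n_background >= 0)
  if (n_level1 + n_level2 + n_background == 0L) {
    stop("cannot plant an empty region")
  }
  heads <- head_pathways(ensemble, head_gene)
  if (length(heads) == 0L) stop("head gene absent from the ensemble")
  head_genes <- setdiff(
    unique(unlist(ensemble$pathways[heads], use.names = FALSE)),
    normalize_symbol(head_gene))
  linked <- linked_pathway_ids(ensemble, heads)
  level2_pool <- setdiff(
    unique(unlist(ensemble$pathways[linked], use.names = FALSE)),
    c(head_genes, normalize_symbol(head_gene)))
  if (length(head_genes) < n_level1) {
    stop("insufficient genes of class level1: pool has ", length(head_genes))
  }
  if (length(level2_pool) < n_level2) {
    stop("insufficient genes of class level2: pool has ", length(level2_pool))
  }
  with_seed(seed, {
    l1 <- if (n_level1 > 0) sample(sort(head_genes), n_level1) else character()
    l2 <- if (n_level2 > 0) sample(sort(level2_pool), n_level2) else character()
    bg <- if (n_background > 0) sprintf("XBG%04d", sample.int(9999, n_background))
          else character()
    list(
      region = terminal_set(name, c(l1, l2, bg)),
      truth = list(level1 = sort(l1), level2 = sort(l2), background = sort(bg))
    )
  })
}

#' Brute-force chainlink oracle
#'
#' Recomputes the chainlink sets by exhaustively applying the definitions with
#' nested loops over pathway pairs -- no gene index, no shared code with
#' [find_chainlinks()] -- so it can serve as an independent oracle on small
#' instances (at most 50 pathways). A gene is level-1 if some head pathway
#' contains it; level-2 if some chain (head, intermediate) exists where the
#' intermediate is a distinct non-head pathway containing the gene and
#' overlapping the head.
#'
#' @inheritParams find_chainlinks
#' @return a `chainlink_report` shaped like the [find_chainlinks()] result.
#' @export
brute_force_chainlinks <- function(ensemble, terminal, head_gene = "FOXP2",
                                   max_level = 2, inclusive = FALSE) {
  stopifnot(inherits(ensemble, "pathway_ensemble"))
  if (length(ensemble$pathways) > 50L) {
    stop("brute-force oracle is restricted to instances of <= 50 pathways")
  }
  if (is.character(terminal)) terminal <- terminal_set("terminal", terminal)
  if (length(terminal$genes) == 0L) stop("empty terminal set")
  if (!max_level %in% 1:2) stop("max_level must be 1 or 2")
  hg <- normalize_symbol(head_gene)
  ids <- names(ensemble$pathways)
  is_head <- vapply(ids, function(id) hg %in% ensemble$pathways[[id]],
                    logical(1))
  if (!any(is_head)) stop("no head pathway: gene ", hg,
                          " occurs in no pathway of the ensemble")
  v1 <- character()
  for (g in terminal$genes) {
    for (h in ids[is_head]) {
      if (g %in% ensemble$pathways[[h]]) { v1 <- c(v1, g); break }
    }
  }
  v1 <- sort(unique(v1))
  levels <- list(`1` = list(genes = v1, count = length(v1),
                            connectivity = .bf_connectivity(ensemble, v1)))
  if (max_level >= 2) {
    v2 <- character()
    for (g in terminal$genes) {
      found <- FALSE
      for (h in ids[is_head]) {
        for (b in ids[!is_head]) {
          if (g %in% ensemble$pathways[[b]] &&
              length(intersect(ensemble$pathways[[b]],
                               ensemble$pathways[[h]])) > 0) {
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (found) v2 <- c(v2, g)
    }
    v2 <- sort(unique(v2))
    if (!inclusive) v2 <- setdiff(v2, v1)
    levels[["2"]] <- list(genes = v2, count = length(v2),
                          connectivity = .bf_connectivity(ensemble, v2))
  }
  all_genes <- sort(unique(as.character(
    unlist(lapply(levels, `[[`, "genes")))))
  per_gene <- vapply(all_genes, function(g) {
    sum(vapply(ensemble$pathways, function(p) g %in% p, logical(1)))
  }, integer(1))
  structure(
    list(terminal = terminal$name, head_gene = hg,
         head_pathways = sort(ids[is_head]), levels = levels,
         per_gene_pathway_counts = per_gene,
         inclusive = inclusive, connectivity_mode = "union",
         exclude_head = FALSE),
    class = "chainlink_report"
  )
}

# union-mode connectivity by direct scan (oracle-side, index-free)
.bf_connectivity <- function(ensemble, genes) {
  if (length(genes) == 0L) return(0L)
  sum(vapply(ensemble$pathways, function(p) any(genes %in% p), logical(1)))
}

#' Draw samples from a CMP distribution
#'
#' Inverse-CDF sampling over the truncated support of the distribution,
#' reproducible by seed.
#'
#' @param params a [cmp_params()] object.
#' @param n number of draws (`>= 1`).
#' @param seed RNG seed.
#' @return integer vector of length `n`.
#' @export
sample_cmp <- function(params, n, seed = 1) {
  stopifnot(inherits(params, "cmp_params"), n >= 1)
  support <- 0:params$truncation_n
  pmf <- exp(cmp_log_pmf(support, params))
  with_seed(seed, {
    cdf <- cumsum(pmf)
    support[findInterval(stats::runif(n) * cdf[length(cdf)], cdf) + 1L]
  })
}
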