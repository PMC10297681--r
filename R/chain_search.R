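#' Pathways containing a head gene
#'
#' The head pathways are the pathways whose gene set contains the designated
#' voice-related head gene (FOXP2 in the motivating analysis). An empty result
#' is valid; callers that require a head pathway raise their own error.
#'
#' @param ensemble a [pathway_ensemble()].
#' @param head_gene a single gene symbol.
#' @return sorted character vector of pathway ids (possibly empty).
#' @export
head_pathways <- function(ensemble, head_gene) {
  stopifnot(inherits(ensemble, "pathway_ensemble"))
  head_gene <- normalize_symbol(head_gene)
  if (length(head_gene) != 1L) stop("exactly one head gene expected")
  sort(ensemble$gene_index[[head_gene]] %||% character())
}

# ids of non-head pathways sharing at least one gene with some head pathway
linked_pathway_ids <- function(ensemble, head_ids) {
  head_genes <- unique(unlist(ensemble$pathways[head_ids], use.names = FALSE))
  linked <- unique(unlist(ensemble$gene_index[head_genes], use.names = FALSE))
  sort(setdiff(linked, head_ids))
}

#' Chainlink connectivity of a gene set
#'
#' Counts the pathways of the ensemble that contain the given genes. In
#' `"union"` mode (the default, and the convention of the reported
#' parenthesized connectivities) pathways containing at least one of the genes
#' are counted once -- the number of pathways the genes collectively touch. In
#' `"sum"` mode per-gene pathway counts are added, counting shared pathways
#' once per gene.
#'
#' @param ensemble a [pathway_ensemble()].
#' @param genes character vector of gene symbols (empty set gives 0).
#' @param mode `"union"` or `"sum"`.
#' @param exclude pathway ids to leave out of the count (e.g. head pathways).
#' @return a non-negative integer.
#' @export
connectivity <- function(ensemble, genes, mode = c("union", "sum"),
                         exclude = character()) {
  stopifnot(inherits(ensemble, "pathway_ensemble"))
  mode <- match.arg(mode)
  if (length(genes) == 0L) return(0L)
  genes <- normalize_symbol(genes)
  hits <- lapply(ensemble$gene_index[genes], function(ids) {
    setdiff(ids %||% character(), exclude)
  })
  if (mode == "union") {
    length(unique(unlist(hits, use.names = FALSE)))
  } else {
    sum(lengths(hits))
  }
}

#' Find level-1 and level-2 chainlink genes for a terminal set
#'
#' Implements the breadth-first chain search over the pathway-overlap graph.
#' A level-1 chainlink gene of terminal set `S` lies directly on a head
#' pathway (a pathway containing `head_gene`); a level-2 chainlink gene lies
#' on a non-head pathway that shares at least one gene with a head pathway.
#' Chains never reuse a pathway, which for levels up to 2 is enforced by
#' construction (the intermediate pathway of a level-2 chain is never a head
#' pathway, because the head node alone may contain the head gene).
#'
#' Under the default *exclusive* convention a gene already reported at level 1
#' is not re-reported at level 2; `inclusive = TRUE` keeps it in both sets.
#'
#' @param ensemble a [pathway_ensemble()].
#' @param terminal a [terminal_set()] (or a character vector of gene symbols,
#'   which is wrapped into one).
#' @param head_gene the head gene symbol; must occur in at least one pathway.
#' @param max_level 1 or 2. Deeper chains are rejected: beyond level 2 the
#'   chained influences cannot be disambiguated, and self-loops would be
#'   needed to extend them.
#' @param inclusive logical; keep level-1 genes in the level-2 set.
#' @param connectivity_mode passed to [connectivity()].
#' @param exclude_head logical; drop head pathways from connectivity counts
#'   (the "additional pathways" reading of the reported numbers).
#' @return an object of class `chainlink_report`: a list with `terminal`,
#'   `head_gene`, `head_pathways`, `levels` (per level: `genes`, `count`,
#'   `connectivity`), and `per_gene_pathway_counts`.
#' @export
find_chainlinks <- function(ensemble, terminal, head_gene = "FOXP2",
                            max_level = 2, inclusive = FALSE,
                            connectivity_mode = c("union", "sum"),
                            exclude_head = FALSE) {
  stopifnot(inherits(ensemble, "pathway_ensemble"))
  connectivity_mode <- match.arg(connectivity_mode)
  if (is.character(terminal)) terminal <- terminal_set("terminal", terminal)
  stopifnot(inherits(terminal, "terminal_set"))
  if (length(terminal$genes) == 0L) stop("empty terminal set")
  if (!max_level %in% 1:2) {
    stop("max_level must be 1 or 2: at greater lengths the chained pathway ",
         "influences cannot be disambiguated")
  }
  heads <- head_pathways(ensemble, head_gene)
  if (length(heads) == 0L) stop("no head pathway: gene ", head_gene,
                                " occurs in no pathway of the ensemble")
  excl <- if (exclude_head) heads else character()

  head_genes <- as.character(unlist(ensemble$pathways[heads], use.names = FALSE))
  v1 <- sort(intersect(terminal$genes, head_genes))
  levels <- list()
  levels[["1"]] <- list(
    genes = v1, count = length(v1),
    connectivity = connectivity(ensemble, v1, connectivity_mode, excl)
  )
  if (max_level >= 2) {
    linked <- linked_pathway_ids(ensemble, heads)
    linked_genes <- as.character(unlist(ensemble$pathways[linked],
                                        use.names = FALSE))
    v2 <- sort(intersect(terminal$genes, linked_genes))
    if (!inclusive) v2 <- setdiff(v2, v1)
    levels[["2"]] <- list(
      genes = v2, count = length(v2),
      connectivity = connectivity(ensemble, v2, connectivity_mode, excl)
    )
  }
  all_genes <- sort(unique(as.character(
    unlist(lapply(levels, `[[`, "genes")))))
  per_gene <- vapply(all_genes, function(g) {
    length(setdiff(ensemble$gene_index[[g]], excl))
  }, integer(1))
  structure(
    list(terminal = terminal$name, head_gene = normalize_symbol(head_gene),
         head_pathways = heads, levels = levels,
         per_gene_pathway_counts = per_gene,
         inclusive = inclusive, connectivity_mode = connectivity_mode,
         exclude_head = exclude_head),
    class = "chainlink_report"
  )
}

#' @export
print.chainlink_report <- function(x, ...) {
  cat(sprintf("<chainlink_report> terminal %s, head gene %s (%d head pathway%s)\n",
              x$terminal, x$head_gene, length(x$head_pathways),
              if (length(x$head_pathways) == 1) "" else "s"))
  for (lv in names(x$levels)) {
    l <- x$levels[[lv]]
    cat(sprintf("  level %s: %d chainlink gene%s (connectivity %d)%s\n",
                lv, l$count, if (l$count == 1) "" else "s", l$connectivity,
                if (l$count > 0 && l$count <= 12)
                  paste0(": ", paste(l$genes, collapse = " ")) else ""))
  }
  invisible(x)
}

#' Chainlink genes of a report
#' @param report a `chainlink_report`.
#' @param level 1, 2, or `NULL` for the union across levels.
#' @return character vector of gene symbols.
#' @export
chainlink_genes <- function(report, level = NULL) {
  stopifnot(inherits(report, "chainlink_report"))
  if (is.null(level)) {
    return(sort(unique(as.character(
      unlist(lapply(report$levels, `[[`, "genes"))))))
  }
  report$levels[[as.character(level)]]$genes
}

#' Enumerate the voice chains through one chainlink gene
#'
#' Lists every distinct chain of the requested level that reaches the terminal
#' set through `gene`: at level 1, one chain per head pathway containing the
#' gene; at level 2, one chain per (head pathway, intermediate pathway) pair
#' where the intermediate is a non-head pathway that contains the gene and
#' shares at least one gene with the head. Rows are ordered by
#' (head pathway id, intermediate id). A gene that is not a chainlink gene at
#' the requested level yields zero rows.
#'
#' @inheritParams find_chainlinks
#' @param gene the chainlink gene to trace.
#' @param level chain level, 1 or 2.
#' @return a data frame with columns `head_pathway`, `intermediate` (`NA` at
#'   level 1), `terminal`, `level`, `gene`.
#' @export
chain_witnesses <- function(ensemble, terminal, head_gene, gene, level) {
  stopifnot(inherits(ensemble, "pathway_ensemble"), level %in% 1:2)
  if (is.character(terminal)) terminal <- terminal_set("terminal", terminal)
  gene <- normalize_symbol(gene)
  heads <- head_pathways(ensemble, head_gene)
  empty <- data.frame(head_pathway = character(), intermediate = character(),
                      terminal = character(), level = integer(),
                      gene = character(), stringsAsFactors = FALSE)
  if (!gene %in% terminal$genes || length(heads) == 0L) return(empty)
  in_gene <- ensemble$gene_index[[gene]] %||% character()
  if (level == 1) {
    h <- sort(intersect(heads, in_gene))
    if (length(h) == 0L) return(empty)
    return(data.frame(head_pathway = h, intermediate = NA_character_,
                      terminal = terminal$name, level = 1L, gene = gene,
                      stringsAsFactors = FALSE))
  }
  mids <- sort(setdiff(in_gene, heads))
  rows <- empty
  for (h in sort(heads)) {
    hg <- ensemble$pathways[[h]]
    ok <- mids[vapply(mids, function(b) {
      length(intersect(ensemble$pathways[[b]], hg)) > 0
    }, logical(1))]
    if (length(ok)) {
      rows <- rbind(rows, data.frame(head_pathway = h, intermediate = ok,
                                     terminal = terminal$name, level = 2L,
                                     gene = gene, stringsAsFactors = FALSE))
    }
  }
  rows
}
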