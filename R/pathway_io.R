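#' Normalize gene symbol tokens
#'
#' Gene symbols are handled as HGNC-style tokens: trimmed of surrounding
#' whitespace and upper-cased, nothing more (no alias resolution). The
#' operation is idempotent, so already-canonical symbols pass through
#' unchanged and hyphenated symbols such as `"H1-4"` are preserved.
#'
#' @param tokens character vector of raw symbol tokens.
#' @return character vector of normalized symbols.
#' @examples
#' normalize_symbol(c(" foxp2 ", "TP53", "H1-4"))
#' @export
normalize_symbol <- function(tokens) {
  if (!is.character(tokens)) stop("gene symbols must be character")
  out <- toupper(trimws(tokens))
  if (length(out) == 0L) return(out)
  if (any(is.na(out) | !nzchar(out))) {
    stop("empty or missing gene symbol token")
  }
  bad <- grepl("[[:space:]]", out)
  if (any(bad)) {
    stop("gene symbol contains internal whitespace: ",
         paste(out[bad], collapse = ", "))
  }
  out
}

#' Construct a pathway ensemble
#'
#' A pathway ensemble is the collection of named gene sets together with its
#' inverted gene index (gene -> pathway ids). The pathway-overlap graph in
#' which two pathways are linked when they share at least one gene is implicit
#' in the index and never materialized.
#'
#' @param genes named list of character vectors, one per pathway. Names are the
#'   pathway ids and must be unique.
#' @param descriptions optional character vector of display descriptions,
#'   recycled to one per pathway.
#' @return an object of class `pathway_ensemble` with elements `pathways`
#'   (named list of sorted unique normalized symbols), `descriptions`, and
#'   `gene_index` (named list mapping each gene to the pathway ids containing
#'   it).
#' @export
pathway_ensemble <- function(genes, descriptions = NULL) {
  if (!is.list(genes) || length(genes) == 0L) {
    stop("'genes' must be a non-empty named list of gene vectors")
  }
  ids <- names(genes)
  if (is.null(ids) || any(!nzchar(ids))) stop("every pathway needs an id")
  if (anyDuplicated(ids)) stop("duplicate pathway ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  pathways <- lapply(genes, function(g) {
    g <- unique(normalize_symbol(g))
    if (length(g) == 0L) stop("pathway with empty gene set")
    sort(g)
  })
  if (is.null(descriptions)) descriptions <- rep("", length(pathways))
  descriptions <- rep_len(as.character(descriptions), length(pathways))
  names(descriptions) <- ids
  all_genes <- unlist(pathways, use.names = FALSE)
  owner <- rep(ids, lengths(pathways))
  gene_index <- split(owner, all_genes)
  structure(
    list(pathways = pathways, descriptions = descriptions,
         gene_index = gene_index),
    class = "pathway_ensemble"
  )
}

#' @export
print.pathway_ensemble <- function(x, ...) {
  cat(sprintf("<pathway_ensemble> %d pathways, %d distinct genes\n",
              length(x$pathways), length(x$gene_index)))
  sizes <- lengths(x$pathways)
  cat(sprintf("  pathway sizes: min %d, median %g, max %d\n",
              min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

#' Number of pathways / genes in an ensemble
#' @param ensemble a `pathway_ensemble`.
#' @return integer count.
#' @export
n_pathways <- function(ensemble) length(ensemble$pathways)

#' @rdname n_pathways
#' @export
ensemble_genes <- function(ensemble) names(ensemble$gene_index)

#' Read a GMT gene-set file
#'
#' GMT dialect: one pathway per line; tab-separated fields `name`,
#' `description`, then one or more gene symbols. Blank trailing fields are
#' ignored. Duplicate pathway names are disambiguated by appending an ordinal
#' suffix (with a warning); duplicate genes within a line are collapsed to a
#' set (with a warning).
#'
#' @param path path to a GMT file.
#' @return a [pathway_ensemble()].
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- character(length(fields))
  desc <- character(length(fields))
  genes <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    f <- f[!(seq_along(f) > 2 & !nzchar(trimws(f)))]  # drop blank trailing gene fields
    if (length(f) < 3L) {
      stop(sprintf("malformed GMT line %d in %s: fewer than 3 tab-separated fields",
                   i, path))
    }
    nm[i] <- trimws(f[1])
    desc[i] <- f[2]
    g <- normalize_symbol(f[-(1:2)])
    if (anyDuplicated(g)) {
      warning(sprintf("duplicate gene symbols in pathway '%s' (line %d); keeping the set",
                      nm[i], i))
      g <- unique(g)
    }
    genes[[i]] <- g
  }
  if (anyDuplicated(nm)) {
    dup <- unique(nm[duplicated(nm)])
    warning("duplicate pathway names disambiguated with ordinal suffixes: ",
            paste(dup, collapse = ", "))
    nm <- make.unique(nm, sep = "#")
  }
  names(genes) <- nm
  pathway_ensemble(genes, descriptions = desc)
}

#' Write a pathway ensemble to GMT
#'
#' @param ensemble a `pathway_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "pathway_ensemble"))
  lines <- vapply(names(ensemble$pathways), function(id) {
    paste(c(id, ensemble$descriptions[[id]], ensemble$pathways[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a terminal gene set
#'
#' A terminal set is the gene set a chain terminates in -- here, the set of
#' genes lying in a microdeletion region, labelled by its cytoband. Implicated
#' genes (reported in the literature as driving the phenotype) are tracked
#' separately and are not required to be a subset of `genes`.
#'
#' @param name region label, e.g. `"17p13.1"`.
#' @param genes character vector of gene symbols in the region (non-empty).
#' @param implicated optional character vector of implicated gene symbols.
#' @param effects_text optional free-text description of reported speech
#'   effects.
#' @return an object of class `terminal_set`.
#' @export
terminal_set <- function(name, genes, implicated = character(),
                         effects_text = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("terminal set needs a single non-empty name")
  }
  genes <- unique(normalize_symbol(genes))
  if (length(genes) == 0L) stop("terminal set '", name, "' has an empty gene list")
  implicated <- if (length(implicated)) unique(normalize_symbol(implicated)) else character()
  structure(
    list(name = name, genes = sort(genes), implicated = sort(implicated),
         effects_text = as.character(effects_text)[1]),
    class = "terminal_set"
  )
}

#' @export
print.terminal_set <- function(x, ...) {
  cat(sprintf("<terminal_set> %s: %d genes", x$name, length(x$genes)))
  if (length(x$implicated)) {
    cat(sprintf(" (implicated: %s)", paste(x$implicated, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Read terminal-set definitions
#'
#' Accepts either a TSV with columns `name`, `genes`, and optionally
#' `implicated` and `effects` (gene lists separated by commas or semicolons),
#' or a YAML file holding a list of records with the same fields. Record order
#' is preserved.
#'
#' @param path path to a `.tsv`/`.txt` or `.yml`/`.yaml` file.
#' @param on_duplicate what to do when two records share a name: `"error"`
#'   (default) or `"merge"` (union of genes/implicated, first effects text
#'   kept, with a message).
#' @return a list of [terminal_set()] objects.
#' @export
read_terminal_sets <- function(path, on_duplicate = c("error", "merge")) {
  on_duplicate <- match.arg(on_duplicate)
  if (!file.exists(path)) stop("terminal-set file not found: ", path)
  split_genes <- function(x) {
    if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(character())
    trimws(strsplit(x, "[,;]")[[1]])
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    records <- lapply(recs, function(r) {
      genes <- if (is.character(r$genes) && length(r$genes) == 1L) {
        split_genes(r$genes)
      } else {
        as.character(r$genes)
      }
      list(name = r$name, genes = genes,
           implicated = as.character(r$implicated %||% character()),
           effects = as.character(r$effects %||% ""))
    })
  } else {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             check.names = FALSE, colClasses = "character")
    if (!all(c("name", "genes") %in% names(tab))) {
      stop("terminal-set TSV needs 'name' and 'genes' columns")
    }
    records <- lapply(seq_len(nrow(tab)), function(i) {
      list(name = tab$name[i], genes = split_genes(tab$genes[i]),
           implicated = split_genes(tab$implicated[i] %||% ""),
           effects = if ("effects" %in% names(tab)) tab$effects[i] else "")
    })
  }
  out <- list()
  for (r in records) {
    if (length(r$genes) == 0L) {
      stop("terminal set '", r$name, "' has an empty gene list")
    }
    if (!is.null(out[[r$name]])) {
      if (on_duplicate == "error") {
        stop("duplicate terminal set name: ", r$name,
             " (use on_duplicate = \"merge\" to combine)")
      }
      message("merging duplicate terminal set: ", r$name)
      prev <- out[[r$name]]
      out[[r$name]] <- terminal_set(
        r$name, c(prev$genes, r$genes), c(prev$implicated, r$implicated),
        if (nzchar(prev$effects_text)) prev$effects_text else r$effects
      )
    } else {
      out[[r$name]] <- terminal_set(r$name, r$genes, r$implicated, r$effects)
    }
  }
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to a packaged data file
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path (or a vector of file names).
#' @export
voicechain_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "voicechain")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no packaged file: ", file)
  path
}

#' The packaged ACC pathway fixture
#'
#' The 63-gene Adenoid Cystic Carcinoma (ACC) pathway -- the unique
#' FOXP2-containing pathway of the CPDB human pathway collection -- shipped as
#' a one-line GMT file.
#'
#' @return a single-pathway [pathway_ensemble()].
#' @export
acc_pathway <- function() {
  read_gmt(voicechain_extdata("acc_pathway.gmt"))
}
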