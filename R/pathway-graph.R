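#' @importFrom rlang %||% .data :=
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n desc distinct count rename
#' @importFrom tibble tibble as_tibble
NULL

# Entry types defined by KGML; anything else is kept verbatim with a warning
# at parse time.
KGML_ENTRY_TYPES <- c("gene", "compound", "map", "group", "ortholog", "enzyme",
                      "reaction", "brite", "other")

#' Construct a pathway graph
#'
#' A `pathway_graph` is the in-memory model of one KGML pathway map: entries
#' (gene, compound, map, group nodes with their graphics), reactions
#' (substrate/product edges catalysed by a gene entry) and relations
#' (entry-entry links).  Multi-gene entries may carry expanded per-gene
#' children created by [expand_nodes()].
#'
#' @param pathway_id KEGG pathway identifier, e.g. `"hsa00020"`.
#' @param title Pathway title.
#' @param entries Named list of entry records (named by entry id).
#' @param reactions List of reaction records.
#' @param relations List of relation records.
#' @param attrs Named character vector of the raw `<pathway>` attributes;
#'   unknown attributes are preserved verbatim on write.
#'
#' @return An object of class `pathway_graph`.
#' @export
pathway_graph <- function(pathway_id = "", title = "", entries = list(),
                          reactions = list(), relations = list(),
                          attrs = character()) {
  g <- structure(
    list(pathway_id = pathway_id, title = title, entries = entries,
         reactions = reactions, relations = relations, attrs = attrs),
    class = "pathway_graph"
  )
  validate_pathway_graph(g)
}

validate_pathway_graph <- function(g) {
  ids <- names(g$entries)
  if (anyDuplicated(ids)) {
    stop("duplicate entry ids in pathway: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  endpoints <- c(
    unlist(lapply(g$relations, function(r) c(r$entry1, r$entry2))),
    vapply(g$reactions, function(r) r$entry_id, character(1))
  )
  missing <- setdiff(endpoints, ids)
  if (length(missing)) {
    stop("reaction/relation endpoints reference unknown entry ids: ",
         paste(missing, collapse = ", "))
  }
  g
}

new_entry <- function(id, type, name = "", gene_ids = character(),
                      graphics = list(), link = NULL, reaction = NULL,
                      components = character(), extra = character(),
                      parent = NULL, children = character(),
                      annotation = NULL) {
  list(id = id, type = type, name = name, gene_ids = gene_ids,
       graphics = graphics, link = link, reaction = reaction,
       components = components, extra = extra, parent = parent,
       children = children, annotation = annotation)
}

new_reaction <- function(reaction_id, entry_id, substrates, products,
                         reversible = FALSE, attrs = character()) {
  stopifnot(length(substrates) > 0, length(products) > 0)
  list(reaction_id = reaction_id, entry_id = entry_id,
       substrates = substrates, products = products,
       reversible = reversible, attrs = attrs)
}

new_relation <- function(entry1, entry2, relation_type,
                         subtypes = list(), attrs = character()) {
  list(entry1 = entry1, entry2 = entry2, relation_type = relation_type,
       subtypes = subtypes, attrs = attrs)
}

#' @export
print.pathway_graph <- function(x, ...) {
  n_gene <- sum(vapply(x$entries, function(e)
    e$type %in% c("gene", "ortholog") && is.null(e$parent), logical(1)))
  cat("<pathway_graph> ", x$pathway_id,
      if (nzchar(x$title)) paste0(" (", x$title, ")"), "\n",
      "  entries:   ", length(x$entries), " (", n_gene, " gene)\n",
      "  reactions: ", length(x$reactions), "\n",
      "  relations: ", length(x$relations), "\n", sep = "")
  if (is_expanded(x)) cat("  expanded: yes\n")
  invisible(x)
}

#' Is the graph node-expanded?
#'
#' @param graph A [pathway_graph()].
#' @return `TRUE` when no multi-gene entry lacks expanded children.
#' @export
is_expanded <- function(graph) {
  for (e in graph$entries) {
    if (e$type %in% c("gene", "ortholog") && is.null(e$parent) &&
        length(e$gene_ids) > 1 && length(e$children) == 0) {
      return(FALSE)
    }
    if (e$type == "group") return(FALSE)
  }
  TRUE
}

# Structural (non-child) entries: the nodes reactions and relations attach to.
structural_entries <- function(graph) {
  graph$entries[vapply(graph$entries, function(e) is.null(e$parent),
                       logical(1))]
}

#' Per-gene display nodes of a pathway
#'
#' After expansion every gene of a multi-gene entry owns one display row.
#' This enumerates those rows: the expanded children where present, otherwise
#' the single-gene entry itself.
#'
#' @param graph A [pathway_graph()].
#' @return A tibble with columns `node_id`, `entry_id` (owning structural
#'   entry), `gene_id`.
#' @export
gene_nodes <- function(graph) {
  rows <- list()
  for (e in structural_entries(graph)) {
    if (!e$type %in% c("gene", "ortholog")) next
    if (length(e$children)) {
      for (cid in e$children) {
        ch <- graph$entries[[cid]]
        rows[[length(rows) + 1L]] <-
          tibble(node_id = ch$id, entry_id = e$id, gene_id = ch$gene_ids[1])
      }
    } else if (length(e$gene_ids) == 1) {
      rows[[length(rows) + 1L]] <-
        tibble(node_id = e$id, entry_id = e$id, gene_id = e$gene_ids[1])
    } else {
      for (gid in e$gene_ids) {
        rows[[length(rows) + 1L]] <-
          tibble(node_id = e$id, entry_id = e$id, gene_id = gid)
      }
    }
  }
  if (!length(rows)) {
    return(tibble(node_id = character(), entry_id = character(),
                  gene_id = character()))
  }
  bind_rows(rows)
}

#' Multiset of gene identifiers in a pathway
#'
#' @param graph A [pathway_graph()].
#' @return Sorted character vector (with repeats) of KEGG gene ids over all
#'   structural gene entries.
#' @export
pathway_genes <- function(graph) {
  sort(unname(unlist(lapply(structural_entries(graph), function(e)
    if (e$type %in% c("gene", "ortholog")) e$gene_ids else character()))))
}

#' Undirected igraph view of a pathway
#'
#' Vertices are the structural entries; edges connect each reaction's
#' catalysing entry to its substrates and products, plus relation endpoints.
#' Used for connected-component diagnostics.
#'
#' @param graph A [pathway_graph()].
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(graph) {
  ids <- names(structural_entries(graph))
  edges <- character()
  for (r in graph$reactions) {
    for (s in r$substrates) edges <- c(edges, r$entry_id, s)
    for (p in r$products) edges <- c(edges, r$entry_id, p)
  }
  for (rel in graph$relations) {
    edges <- c(edges, rel$entry1, rel$entry2)
  }
  keep <- if (length(edges)) {
    m <- matrix(edges, ncol = 2, byrow = TRUE)
    m[m[, 1] %in% ids & m[, 2] %in% ids, , drop = FALSE]
  } else {
    matrix(character(), ncol = 2)
  }
  igraph::graph_from_data_frame(
    as.data.frame(keep, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
}

#' Number of weakly connected components of the pathway skeleton
#'
#' @param graph A [pathway_graph()].
#' @return Integer component count.
#' @export
component_count <- function(graph) {
  if (!length(graph$entries)) return(0L)
  igraph::components(as_igraph(graph))$no
}

# Structural comparison used by round-trip tests: entry core fields, gene
# lists, reaction and relation content; graphics compared on the core box.
#' Compare two pathway graphs structurally
#'
#' @param a,b [pathway_graph()] objects.
#' @return `TRUE` if ids, types, gene lists, graphics boxes, reactions and
#'   relations all match.
#' @export
pathway_equal <- function(a, b) {
  norm_entry <- function(e) {
    gfx <- lapply(e$graphics, function(g)
      g[intersect(c("name", "x", "y", "width", "height", "type"), names(g))])
    list(e$id, e$type, sort(e$gene_ids), gfx, e$parent %||% "",
         sort(e$children), sort(e$components))
  }
  norm <- function(g) {
    ord <- order(names(g$entries))
    list(
      entries = lapply(g$entries[ord], norm_entry),
      reactions = lapply(g$reactions, function(r)
        list(r$reaction_id, r$entry_id, sort(r$substrates), sort(r$products),
             r$reversible)),
      relations = lapply(g$relations, function(r)
        list(r$entry1, r$entry2, r$relation_type, r$subtypes))
    )
  }
  identical(norm(a), norm(b))
}
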