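#' Expand multi-gene pathway nodes
#'
#' KEGG pathway maps collapse alternative enzymes (functional homologs) into a
#' single node and display only the first gene.  `expand_nodes()` gives every
#' gene entry with more than one gene id one child node per gene, so all
#' homologs can be displayed and styled individually.  Children inherit the
#' parent's graphics and, through the parent, its incident reactions and
#' relations.  Group entries are first flattened into their member entries.
#' The operation is idempotent and preserves the gene multiset, the
#' compound/map entry set and the reaction substrate/product structure.
#'
#' @param graph A [pathway_graph()].
#' @return The expanded [pathway_graph()].
#' @export
#' @examples
#' g <- read_kgml(system.file("extdata", "toy_pathway.xml", package = "funhop"))
#' expand_nodes(g)
expand_nodes <- function(graph) {
  graph <- flatten_groups(graph)
  for (id in names(graph$entries)) {
    e <- graph$entries[[id]]
    if (!e$type %in% c("gene", "ortholog") || !is.null(e$parent)) next
    if (length(e$gene_ids) <= 1 || length(e$children)) next
    child_ids <- paste0(id, "_", seq_along(e$gene_ids))
    for (i in seq_along(e$gene_ids)) {
      graph$entries[[child_ids[i]]] <- new_entry(
        id = child_ids[i], type = e$type, name = e$gene_ids[i],
        gene_ids = e$gene_ids[i], graphics = e$graphics, parent = id
      )
    }
    graph$entries[[id]]$children <- child_ids
  }
  validate_pathway_graph(graph)
}

# Replace each group entry by its member entries: relations touching the
# group are re-targeted to every member; the group entry is then dropped.
flatten_groups <- function(graph) {
  group_ids <- names(graph$entries)[vapply(graph$entries, function(e)
    identical(e$type, "group"), logical(1))]
  if (!length(group_ids)) return(graph)
  members <- lapply(graph$entries[group_ids], function(e) e$components)
  names(members) <- group_ids

  relations <- list()
  for (rel in graph$relations) {
    e1 <- if (rel$entry1 %in% group_ids) members[[rel$entry1]] else rel$entry1
    e2 <- if (rel$entry2 %in% group_ids) members[[rel$entry2]] else rel$entry2
    for (a in e1) for (b in e2) {
      r2 <- rel; r2$entry1 <- a; r2$entry2 <- b
      relations[[length(relations) + 1L]] <- r2
    }
  }
  reactions <- list()
  for (r in graph$reactions) {
    targets <- if (r$entry_id %in% group_ids) members[[r$entry_id]]
               else r$entry_id
    for (t in targets) {
      r2 <- r; r2$entry_id <- t
      reactions[[length(reactions) + 1L]] <- r2
    }
  }
  graph$entries[group_ids] <- NULL
  graph$relations <- relations
  graph$reactions <- reactions
  graph
}

#' Stack expanded children vertically under their parent node
#'
#' Children of each expanded entry get the parent's box width and height and
#' are stacked downward from the parent's (x, y) in input order, so no two
#' children of one entry overlap.  Deterministic given the input graph.
#'
#' @param graph An expanded [pathway_graph()].
#' @return The graph with per-child graphics boxes set.
#' @export
layout_expanded <- function(graph) {
  for (id in names(graph$entries)) {
    e <- graph$entries[[id]]
    if (!length(e$children)) next
    box <- graphics_box(e)
    for (i in seq_along(e$children)) {
      cid <- e$children[i]
      ch <- graph$entries[[cid]]
      gfx <- if (length(ch$graphics)) ch$graphics[[1]] else character()
      gfx["x"] <- format_num(box["x"])
      gfx["y"] <- format_num(box["y"] + (i - 1) * box["height"])
      gfx["width"] <- format_num(box["width"])
      gfx["height"] <- format_num(box["height"])
      if (is.na(gfx["name"]) || !nzchar(gfx["name"])) {
        gfx["name"] <- ch$gene_ids[1]
      }
      graph$entries[[cid]]$graphics <- list(gfx)
    }
  }
  graph
}

# Default KGML gene box is 46x17 pixels.
graphics_box <- function(entry) {
  gfx <- if (length(entry$graphics)) entry$graphics[[1]] else character()
  num <- function(key, default) {
    v <- suppressWarnings(as.numeric(gfx[key]))
    if (is.na(v)) default else v
  }
  c(x = num("x", 0), y = num("y", 0),
    width = num("width", 46), height = num("height", 17))
}

format_num <- function(x) {
  format(unname(x), trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}
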