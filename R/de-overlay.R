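#' Signed transformed differential-expression score
#'
#' Maps a p-value and regulation direction to the display score
#' `log2(p) * (-10) * regulation`, where regulation is +1 for upregulated
#' (positive fold-change) and -1 for downregulated genes.  The score is
#' positive for upregulated genes, negative for downregulated ones, and its
#' magnitude grows as the p-value shrinks (p = 0.5 gives magnitude 10,
#' p = 1 gives 0).
#'
#' @param p_value Numeric vector in (0, 1].
#' @param regulation Integer vector of +1 / -1 (recycled).
#' @return Numeric score vector.
#' @export
#' @examples
#' transform_pvalue(0.5, -1)   # -10
#' transform_pvalue(0.05, +1)  # ~43.22
transform_pvalue <- function(p_value, regulation) {
  if (any(p_value <= 0)) stop("p_value must be > 0")
  if (any(p_value > 1)) stop("p_value must be <= 1")
  if (!all(regulation %in% c(-1, 1))) stop("regulation must be +1 or -1")
  log2(p_value) * (-10) * regulation
}

#' Build differential-expression records
#'
#' @param gene Gene symbols.
#' @param fold_change Signed log fold-changes; their sign defines the
#'   regulation direction (a fold-change of exactly 0 counts as upregulated).
#' @param p_value P-values in (0, 1].
#' @return Tibble with columns `gene`, `fold_change`, `p_value`,
#'   `regulation`, `score`.
#' @export
de_records <- function(gene, fold_change, p_value) {
  regulation <- ifelse(fold_change < 0, -1L, 1L)
  tibble(
    gene = normalize_gene(gene),
    fold_change = fold_change,
    p_value = p_value,
    regulation = regulation,
    score = transform_pvalue(p_value, regulation)
  )
}

#' Filter differential-expression records on significance
#'
#' Keeps records with `p_value` strictly below `alpha` (so records at exactly
#' the threshold are dropped) and reports how many were removed.
#'
#' @param de Tibble from [de_records()] / [read_de_table()].
#' @param alpha Significance threshold in (0, 1]; default 0.05.
#' @return The filtered tibble.
#' @export
filter_de <- function(de, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  kept <- de[de$p_value < alpha, , drop = FALSE]
  message(nrow(de) - nrow(kept), " of ", nrow(de),
          " records removed at alpha = ", alpha)
  kept
}

#' Map a score to a display color
#'
#' Upregulated (positive) scores map into a green range, downregulated
#' (negative) scores into a red range, with intensity monotone in the score
#' magnitude; zero or missing scores get a neutral gray.  Magnitudes are
#' clamped at `cap` before linear interpolation.
#'
#' @param score Numeric vector (NA allowed for genes without a DE record).
#' @param cap Magnitude at which the color saturates.
#' @param up,down Light-to-dark hex endpoints of the two ranges.
#' @param neutral Hex color for zero/missing scores.
#' @return Character vector of hex colors.
#' @export
colorize <- function(score, cap = 100,
                     up = c("#E5F5E0", "#00441B"),
                     down = c("#FEE0D2", "#67000D"),
                     neutral = "#C8C8C8") {
  stopifnot(cap > 0)
  ramp_up <- grDevices::colorRamp(up)
  ramp_down <- grDevices::colorRamp(down)
  vapply(score, function(s) {
    if (is.na(s) || s == 0) return(neutral)
    frac <- min(abs(s), cap) / cap
    rgb <- if (s > 0) ramp_up(frac) else ramp_down(frac)
    grDevices::rgb(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
  }, character(1))
}

#' Attach differential-expression scores and colors to pathway gene nodes
#'
#' Joins the (already filtered) DE table onto every per-gene node of an
#' expanded pathway via the KEGG-id/symbol mapping and stores the symbol,
#' score and color on each node.  Genes without a significant DE record (or
#' without a mapping, which is warned about) get a neutral color.  Topology
#' (entries, reactions, relations) is never altered.
#'
#' @param graph An expanded [pathway_graph()].
#' @param de Filtered DE tibble (see [filter_de()]).
#' @param idmap Tibble with columns `kegg_id`, `symbol`.
#' @param cap,up,down,neutral Passed to [colorize()].
#' @return The annotated [pathway_graph()].
#' @export
annotate_graph <- function(graph, de, idmap, cap = 100,
                           up = c("#E5F5E0", "#00441B"),
                           down = c("#FEE0D2", "#67000D"),
                           neutral = "#C8C8C8") {
  if (!is_expanded(graph)) graph <- expand_nodes(graph)
  sym <- stats::setNames(idmap$symbol, idmap$kegg_id)
  scores <- stats::setNames(de$score, de$gene)
  nodes <- gene_nodes(graph)
  unmapped <- setdiff(unique(nodes$gene_id), names(sym))
  if (length(unmapped)) {
    warning(length(unmapped), " pathway gene id(s) missing from idmap: ",
            paste(utils::head(unmapped, 5), collapse = ", "),
            if (length(unmapped) > 5) ", ...", call. = FALSE)
  }
  for (i in seq_len(nrow(nodes))) {
    gid <- nodes$gene_id[i]
    symbol <- unname(sym[gid])
    score <- if (!is.na(symbol)) unname(scores[symbol]) else NA_real_
    graph$entries[[nodes$node_id[i]]]$annotation <- list(
      symbol = if (is.na(symbol)) NA_character_ else symbol,
      score = score,
      color = colorize(score, cap = cap, up = up, down = down,
                       neutral = neutral)
    )
  }
  graph
}

#' Export a Cytoscape node-attribute table
#'
#' One row per node of the pathway (per-gene rows for expanded entries,
#' one row per compound/map entry) with the attributes Cytoscape styles map
#' onto: gene symbol, localization, DE score and color.
#'
#' @param graph An (optionally annotated) [pathway_graph()].
#' @param consensus Optional consensus tibble from [build_consensus()].
#' @param idmap Optional `kegg_id`/`symbol` mapping (needed to attach
#'   localization when nodes are not annotated).
#' @param path Optional output TSV path.
#' @return The attribute tibble (written to `path` when given), with columns
#'   `node_id`, `entry_type`, `gene_id`, `symbol`, `localization`, `score`,
#'   `color`.
#' @export
node_attributes <- function(graph, consensus = NULL, idmap = NULL,
                            path = NULL) {
  loc <- if (!is.null(consensus)) {
    stats::setNames(consensus$consensus, consensus$gene)
  } else {
    character()
  }
  sym <- if (!is.null(idmap)) stats::setNames(idmap$symbol, idmap$kegg_id)
         else character()
  rows <- lapply(names(graph$entries), function(id) {
    e <- graph$entries[[id]]
    if (length(e$children)) return(NULL)      # children carry the gene rows
    gid <- if (length(e$gene_ids) == 1) e$gene_ids else NA_character_
    symbol <- e$annotation$symbol %||%
      (if (!is.na(gid) && gid %in% names(sym)) unname(sym[gid])
       else NA_character_)
    tibble(
      node_id = id,
      entry_type = e$type,
      gene_id = gid %||% NA_character_,
      symbol = symbol %||% NA_character_,
      localization = if (!is.null(symbol) && !is.na(symbol) &&
                         symbol %in% names(loc)) unname(loc[symbol])
                     else NA_character_,
      score = e$annotation$score %||% NA_real_,
      color = e$annotation$color %||% NA_character_
    )
  })
  out <- bind_rows(rows)
  if (!is.null(path)) readr::write_tsv(out, path)
  out
}

#' Export a pathway as GraphML
#'
#' Builds the undirected entry graph (see [as_igraph()]), attaches node
#' attributes, and writes GraphML for import into Cytoscape.
#'
#' @param graph A [pathway_graph()].
#' @param path Output file path.
#' @param consensus,idmap Passed to [node_attributes()].
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path, consensus = NULL, idmap = NULL) {
  ig <- as_igraph(graph)
  attrs <- node_attributes(graph, consensus = consensus, idmap = idmap)
  attrs <- attrs[match(igraph::V(ig)$name, attrs$node_id), ]
  for (col in c("entry_type", "gene_id", "symbol", "localization", "color")) {
    v <- attrs[[col]]
    v[is.na(v)] <- ""
    ig <- igraph::set_vertex_attr(ig, col, value = v)
  }
  sc <- attrs$score
  sc[is.na(sc)] <- 0
  ig <- igraph::set_vertex_attr(ig, "score", value = sc)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Write a Cytoscape style description for the DE color gradient
#'
#' Emits a small JSON style mapping the `score` node attribute onto the
#' red/neutral/green gradient used by [colorize()], for manual import.
#'
#' @param path Output JSON path.
#' @param cap,up,down,neutral Gradient parameters as in [colorize()].
#' @return `path`, invisibly.
#' @export
write_cytoscape_style <- function(path, cap = 100,
                                  up = c("#E5F5E0", "#00441B"),
                                  down = c("#FEE0D2", "#67000D"),
                                  neutral = "#C8C8C8") {
  style <- list(
    title = "funhop-de-overlay",
    mapping = list(
      attribute = "score", type = "continuous",
      points = list(
        list(value = -cap, color = down[2]),
        list(value = 0, color = neutral),
        list(value = cap, color = up[2])
      )
    )
  )
  jsonlite::write_json(style, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
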