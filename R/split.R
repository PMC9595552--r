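#' Split a pathway into mitochondrial and non-mitochondrial variants
#'
#' Using the consensus localization, every per-gene node is assigned to the
#' mitochondrial variant (consensus `mitochondria`) or the non-mitochondrial
#' variant (any other known category, pooled).  Entries emptied of all their
#' genes are deleted together with their incident relations; reactions whose
#' catalysing entry vanished are flagged as broken links and removed.
#' Compound and map entries are kept in both variants.  Genes with no known
#' consensus are, by default, retained in both variants and flagged, so that
#' missing localization data never silently breaks a path; set
#' `unknown_policy = "drop"` to remove them instead.
#'
#' @param graph An expanded [pathway_graph()] (expanded on the fly if not).
#' @param consensus Tibble from [build_consensus()] (columns `gene`,
#'   `consensus`); must be non-empty.
#' @param idmap Tibble with columns `kegg_id`, `symbol`.
#' @param unknown_policy `"both"` (default) or `"drop"`.
#' @return A list of class `split_result`: `mito_variant` and
#'   `nonmito_variant` ([pathway_graph()]s), `removed_genes`,
#'   `orphaned_entries`, `broken_links` (tibbles), `unknown_genes`, and
#'   `component_counts`.
#' @export
split_pathway <- function(graph, consensus, idmap,
                          unknown_policy = c("both", "drop")) {
  unknown_policy <- match.arg(unknown_policy)
  if (is.null(consensus) || !nrow(consensus)) stop("consensus table is empty")
  if (!is_expanded(graph)) graph <- expand_nodes(graph)

  cat_of <- gene_categories(graph, consensus, idmap)
  keep_in <- function(category, variant) {
    if (is.na(category) || category == "unknown") {
      return(unknown_policy == "both")
    }
    if (variant == "mito") category == "mitochondria"
    else category != "mitochondria"
  }

  build_variant <- function(variant) {
    g <- graph
    removed <- list()
    orphaned <- character()
    for (id in names(structural_entries(graph))) {
      e <- graph$entries[[id]]
      if (!e$type %in% c("gene", "ortholog")) next
      node_ids <- if (length(e$children)) e$children else id
      kept_genes <- character()
      for (nid in node_ids) {
        node <- graph$entries[[nid]]
        gid <- node$gene_ids[1]
        category <- unname(cat_of[gid])
        if (keep_in(category, variant)) {
          kept_genes <- c(kept_genes, gid)
        } else {
          removed[[length(removed) + 1L]] <- tibble(
            variant = variant, entry_id = id, gene_id = gid,
            reason = if (is.na(category)) "unknown" else category)
          if (nid != id) g$entries[[nid]] <- NULL
        }
      }
      if (!length(kept_genes)) {
        orphaned <- c(orphaned, id)
        g$entries[c(id, e$children)] <- NULL
      } else {
        g$entries[[id]]$gene_ids <- kept_genes
        g$entries[[id]]$name <- paste(kept_genes, collapse = " ")
        g$entries[[id]]$children <-
          intersect(e$children, names(g$entries))
      }
    }
    ids <- names(g$entries)
    broken <- list()
    g$reactions <- Filter(function(r) {
      ok <- r$entry_id %in% ids
      if (!ok) broken[[length(broken) + 1L]] <<- tibble(
        variant = variant, reaction_id = r$reaction_id, entry_id = r$entry_id)
      ok
    }, g$reactions)
    g$relations <- Filter(function(rel)
      rel$entry1 %in% ids && rel$entry2 %in% ids, g$relations)
    list(graph = validate_pathway_graph(g),
         removed = bind_rows(removed), orphaned = orphaned,
         broken = bind_rows(broken))
  }

  mito <- build_variant("mito")
  nonmito <- build_variant("nonmito")
  unknown_genes <- names(cat_of)[is.na(cat_of) | cat_of == "unknown"]

  structure(list(
    mito_variant = mito$graph,
    nonmito_variant = nonmito$graph,
    removed_genes = bind_rows(mito$removed, nonmito$removed),
    orphaned_entries = tibble(
      variant = c(rep("mito", length(mito$orphaned)),
                  rep("nonmito", length(nonmito$orphaned))),
      entry_id = c(mito$orphaned, nonmito$orphaned)),
    broken_links = bind_rows(mito$broken, nonmito$broken),
    unknown_genes = unknown_genes,
    component_counts = c(original = component_count(graph),
                         mito = component_count(mito$graph),
                         nonmito = component_count(nonmito$graph))
  ), class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result>\n",
      "  mito variant:    ", length(x$mito_variant$entries), " entries, ",
      length(x$mito_variant$reactions), " reactions\n",
      "  nonmito variant: ", length(x$nonmito_variant$entries), " entries, ",
      length(x$nonmito_variant$reactions), " reactions\n",
      "  broken links: ", nrow(x$broken_links),
      "; unknown-localization genes: ", length(x$unknown_genes), "\n",
      "  components (original/mito/nonmito): ",
      paste(x$component_counts, collapse = "/"), "\n", sep = "")
  invisible(x)
}

# Per KEGG gene id, the consensus category (NA when the gene is missing from
# the idmap or the consensus).
gene_categories <- function(graph, consensus, idmap) {
  sym <- stats::setNames(idmap$symbol, idmap$kegg_id)
  loc <- stats::setNames(consensus$consensus, consensus$gene)
  gids <- unique(gene_nodes(graph)$gene_id)
  out <- stats::setNames(rep(NA_character_, length(gids)), gids)
  mapped <- gids[gids %in% names(sym)]
  if (length(mapped) < length(gids)) {
    message(length(gids) - length(mapped),
            " pathway gene id(s) missing from idmap")
  }
  hit <- mapped[sym[mapped] %in% names(loc)]
  out[hit] <- unname(loc[sym[hit]])
  out
}

#' Connectivity diagnostics for a pathway split
#'
#' Reports the weakly-connected-component count of the undirected
#' reaction/relation graph for the original pathway and each variant, plus
#' the compound pairs that were connected in the original but are
#' disconnected in a variant (broken paths).
#'
#' @param result A `split_result` from [split_pathway()].
#' @param original The original expanded [pathway_graph()] (used for the
#'   broken-pair diagnostics); optional.
#' @return A list with `components` (tibble: graph, n_components) and
#'   `disconnected_pairs` (tibble: variant, compound1, compound2).
#' @export
connectivity_report <- function(result, original = NULL) {
  components <- tibble(
    graph = c("original", "mito", "nonmito"),
    n_components = as.integer(result$component_counts[
      c("original", "mito", "nonmito")])
  )
  pairs <- tibble(variant = character(), compound1 = character(),
                  compound2 = character())
  if (!is.null(original)) {
    pairs <- bind_rows(
      disconnected_compound_pairs(original, result$mito_variant, "mito"),
      disconnected_compound_pairs(original, result$nonmito_variant, "nonmito")
    )
  }
  list(components = components, disconnected_pairs = pairs)
}

disconnected_compound_pairs <- function(original, variant, label) {
  compounds <- names(original$entries)[vapply(original$entries, function(e)
    identical(e$type, "compound"), logical(1))]
  compounds <- intersect(compounds, names(variant$entries))
  if (length(compounds) < 2) {
    return(tibble(variant = character(), compound1 = character(),
                  compound2 = character()))
  }
  mem_o <- igraph::components(as_igraph(original))$membership
  mem_v <- igraph::components(as_igraph(variant))$membership
  combos <- utils::combn(compounds, 2)
  keep <- apply(combos, 2, function(p)
    mem_o[p[1]] == mem_o[p[2]] && mem_v[p[1]] != mem_v[p[2]])
  tibble(variant = label, compound1 = combos[1, keep],
         compound2 = combos[2, keep])
}

#' Mitochondrial / non-mitochondrial gene fractions of a pathway
#'
#' Counts the unique pathway genes with a known consensus localization and
#' reports how many are mitochondrial vs non-mitochondrial, with percentages
#' rounded to integers under round-half-to-even (so a 47.5% / 52.5% pair
#' prints as 48% / 52% and the two always sum to 100).  Genes without a
#' known consensus are counted separately and excluded from the denominator.
#'
#' @param graph An expanded [pathway_graph()].
#' @param consensus Tibble from [build_consensus()].
#' @param idmap Tibble with columns `kegg_id`, `symbol`.
#' @return One-row tibble: `pathway_id`, `n_known`, `n_mito`, `n_nonmito`,
#'   `pct_mito`, `pct_nonmito`, `n_unknown`, plus the per-category
#'   non-mitochondrial breakdown `n_cytoplasm`, `n_nucleus`, `n_secretory`.
#' @export
compartment_fractions <- function(graph, consensus, idmap) {
  if (!is_expanded(graph)) graph <- expand_nodes(graph)
  cats <- gene_categories(graph, consensus, idmap)
  sym <- stats::setNames(idmap$symbol, idmap$kegg_id)
  # count unique genes (by symbol where mapped), not display nodes
  key <- ifelse(names(cats) %in% names(sym),
                unname(sym[names(cats)]), names(cats))
  cats <- cats[!duplicated(key)]
  known <- cats[!is.na(cats) & cats != "unknown"]
  n_mito <- sum(known == "mitochondria")
  n_known <- length(known)
  tibble(
    pathway_id = graph$pathway_id,
    n_known = n_known,
    n_mito = n_mito,
    n_nonmito = n_known - n_mito,
    pct_mito = if (n_known) round(100 * n_mito / n_known) else NA_real_,
    pct_nonmito = if (n_known)
      round(100 * (n_known - n_mito) / n_known) else NA_real_,
    n_unknown = length(cats) - n_known,
    n_cytoplasm = sum(known == "cytoplasm"),
    n_nucleus = sum(known == "nucleus"),
    n_secretory = sum(known == "secretory")
  )
}
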