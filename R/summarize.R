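#' Up/down regulation counts per subcellular compartment
#'
#' Tallies the significantly regulated genes (an already filtered DE table)
#' by their localization category and regulation direction, one count per
#' gene.  Genes without a localization fall into the `unknown` bucket.
#'
#' @param de Filtered DE tibble (see [filter_de()]).
#' @param loc Tibble with columns `gene`, `category` (one source's reduced
#'   calls, or the consensus renamed accordingly).
#' @return Tibble with one row per compartment: `category`, `n_up`, `n_down`.
#' @export
regulation_by_compartment <- function(de, loc) {
  levels <- c(LOC_CATEGORIES, "unknown")
  base <- tibble(category = levels, n_up = 0L, n_down = 0L)
  if (!nrow(de)) return(base)
  loc <- loc |>
    mutate(gene = normalize_gene(.data$gene)) |>
    distinct(.data$gene, .keep_all = TRUE)
  tallied <- de |>
    distinct(.data$gene, .keep_all = TRUE) |>
    left_join(select(loc, "gene", "category"), by = "gene") |>
    mutate(category = ifelse(is.na(.data$category) |
                               !usable(.data$category),
                             "unknown", .data$category)) |>
    group_by(.data$category) |>
    summarise(n_up = sum(.data$regulation > 0),
              n_down = sum(.data$regulation < 0), .groups = "drop")
  base |>
    rows_update_counts(tallied)
}

rows_update_counts <- function(base, tallied) {
  i <- match(tallied$category, base$category)
  base$n_up[i] <- tallied$n_up
  base$n_down[i] <- tallied$n_down
  base
}

#' Per-source localization summary
#'
#' For each localization source, counts the genes with a usable (neither
#' unassigned nor uncertain) localization, how many of those are
#' mitochondrial, the overlap with a reference KEGG gene list, and the
#' mitochondrial count within that overlap.  Percentages are reported to one
#' decimal; the KEGG percentage is the share of the KEGG list covered by the
#' source.
#'
#' @param sources Named list of tibbles with columns `gene`, `category`.
#' @param kegg_genes Character vector of KEGG pathway gene symbols (non-empty).
#' @return Tibble with one row per source: `source`, `n_genes`, `n_mito`,
#'   `pct_mito`, `n_kegg`, `pct_kegg`, `n_kegg_mito`, `pct_kegg_mito`.
#' @export
source_summary <- function(sources, kegg_genes) {
  stopifnot(length(kegg_genes) > 0)
  kegg_genes <- unique(normalize_gene(kegg_genes))
  pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else NA_real_
  rows <- lapply(names(sources), function(nm) {
    s <- sources[[nm]] |>
      mutate(gene = normalize_gene(.data$gene)) |>
      filter(usable(.data$category)) |>
      distinct(.data$gene, .keep_all = TRUE)
    in_kegg <- s$gene %in% kegg_genes
    tibble(
      source = nm,
      n_genes = nrow(s),
      n_mito = sum(s$category == "mitochondria"),
      pct_mito = pct(sum(s$category == "mitochondria"), nrow(s)),
      n_kegg = sum(in_kegg),
      pct_kegg = pct(sum(in_kegg), length(kegg_genes)),
      n_kegg_mito = sum(in_kegg & s$category == "mitochondria"),
      pct_kegg_mito = pct(sum(in_kegg & s$category == "mitochondria"),
                          sum(in_kegg))
    )
  })
  bind_rows(rows)
}

#' Rank pathways by mitochondrial gene fraction
#'
#' Computes [compartment_fractions()] for each pathway and sorts descending
#' by the mitochondrial fraction, breaking ties by gene count (descending)
#' and then pathway id.  Pathways with no known-localization gene are
#' excluded with a warning.
#'
#' @param pathways List of (expanded) [pathway_graph()]s.
#' @param consensus Tibble from [build_consensus()].
#' @param idmap Tibble with columns `kegg_id`, `symbol`.
#' @return Tibble: `pathway_id`, `n_genes`, `n_mito`, `mito_fraction`,
#'   sorted as described.
#' @export
rank_pathways <- function(pathways, consensus, idmap) {
  rows <- lapply(pathways, function(g) {
    f <- compartment_fractions(g, consensus, idmap)
    if (f$n_known == 0) {
      warning("pathway ", f$pathway_id,
              " has no genes with known localization; excluded",
              call. = FALSE)
      return(NULL)
    }
    tibble(pathway_id = f$pathway_id, n_genes = f$n_known,
           n_mito = f$n_mito, mito_fraction = f$n_mito / f$n_known)
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(pathway_id = character(), n_genes = integer(),
                  n_mito = integer(), mito_fraction = numeric()))
  }
  arrange(out, desc(.data$mito_fraction), desc(.data$n_genes),
          .data$pathway_id)
}
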