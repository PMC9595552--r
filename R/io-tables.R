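# Readers for the tabular dialects the pipeline consumes.  All readers accept
# TSV or CSV (sniffed from the extension), normalize gene symbols, and return
# tibbles; column names are configurable because public exports of these
# resources have changed header spelling over time.

read_table_auto <- function(path, ...) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, progress = FALSE, show_col_types = FALSE, ...)
  } else {
    readr::read_tsv(path, progress = FALSE, show_col_types = FALSE, ...)
  }
}

require_cols <- function(tbl, cols, path) {
  miss <- setdiff(cols, names(tbl))
  if (length(miss)) {
    stop("missing column(s) ", paste(miss, collapse = ", "), " in ", path)
  }
}

#' Read a SubCellBarCode-style localization table
#'
#' Long format: one row per gene and cell line with that line's localization
#' neighborhood (`Mitochondria`, `Cytosol`, `Nuclear`, `Secretory`,
#' `Unassign`).
#'
#' @param path TSV/CSV file.
#' @param gene_col,cell_line_col,label_col Column names.
#' @return Tibble with columns `gene`, `cell_line`, `label`.
#' @export
read_subcell <- function(path, gene_col = "gene", cell_line_col = "cell_line",
                         label_col = "neighborhood") {
  tbl <- read_table_auto(path)
  require_cols(tbl, c(gene_col, cell_line_col, label_col), path)
  tibble(gene = normalize_gene(tbl[[gene_col]]),
         cell_line = tbl[[cell_line_col]],
         label = tbl[[label_col]])
}

#' Read a Human Protein Atlas subcellular-location export
#'
#' One row per gene; the location column holds semicolon-separated labels
#' from HPA's 35-location vocabulary.
#'
#' @param path TSV/CSV file.
#' @param gene_col,locations_col,reliability_col Column names (reliability is
#'   carried through but never used as a weight).
#' @return Tibble with columns `gene`, `locations`, `reliability`.
#' @export
read_hpa <- function(path, gene_col = "gene", locations_col = "locations",
                     reliability_col = "reliability") {
  tbl <- read_table_auto(path)
  require_cols(tbl, c(gene_col, locations_col), path)
  tibble(gene = normalize_gene(tbl[[gene_col]]),
         locations = tbl[[locations_col]],
         reliability = if (reliability_col %in% names(tbl))
           tbl[[reliability_col]] else NA_character_)
}

#' Read a BUSCA prediction output table
#'
#' One row per protein sequence with the single predicted compartment.
#'
#' @param path TSV/CSV file.
#' @param id_col,class_col,score_col Column names; the sequence id is taken
#'   as the gene symbol.
#' @return Tibble with columns `gene`, `label`, `score`.
#' @export
read_busca <- function(path, id_col = "sequence_id",
                       class_col = "predicted_class", score_col = "score") {
  tbl <- read_table_auto(path)
  require_cols(tbl, c(id_col, class_col), path)
  tibble(gene = normalize_gene(tbl[[id_col]]),
         label = tbl[[class_col]],
         score = if (score_col %in% names(tbl)) tbl[[score_col]] else NA_real_)
}

# Tolerant normalizer for already-reduced per-source categories as they
# appear in combined assignment tables.
normalize_category <- function(x) {
  key <- tolower(trimws(x))
  map <- c(mitochondria = "mitochondria", mitochondrion = "mitochondria",
           cytoplasm = "cytoplasm", cytosol = "cytoplasm",
           nucleus = "nucleus", nuclear = "nucleus",
           secretory = "secretory", secreted = "secretory",
           uncertain = "uncertain", unknown = "unknown",
           unassign = "unknown", unassigned = "unknown")
  out <- unname(map[key])
  out[is.na(key) | key == ""] <- "unknown"
  if (anyNA(out)) {
    warning("unrecognized localization categories -> unknown: ",
            paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
    out[is.na(out)] <- "unknown"
  }
  out
}

#' Read a combined per-source localization assignment table
#'
#' One row per gene with the already-reduced localization from each source
#' (columns `gene`, `subcell`, `hpa`, `busca`), the layout of a combined
#' supplementary assignment export.
#'
#' @param path TSV/CSV file.
#' @return List of three tibbles (`subcell`, `hpa`, `busca`), each with
#'   columns `gene`, `category`, ready for [build_consensus()].
#' @export
read_combined_loc <- function(path) {
  tbl <- read_table_auto(path)
  require_cols(tbl, c("gene", "subcell", "hpa", "busca"), path)
  one <- function(col) tibble(gene = normalize_gene(tbl$gene),
                              category = normalize_category(tbl[[col]]))
  list(subcell = one("subcell"), hpa = one("hpa"), busca = one("busca"))
}

#' Read a differential-expression result table
#'
#' @param path TSV/CSV file.
#' @param gene_col,lfc_col,p_col Column names for the gene symbol, signed log
#'   fold-change and p-value (set `p_col` to an adjusted-p column to filter
#'   on adjusted values).
#' @return Tibble with columns `gene`, `fold_change`, `p_value`,
#'   `regulation`, `score` (see [transform_pvalue()]).
#' @export
read_de_table <- function(path, gene_col = "gene", lfc_col = "logFC",
                          p_col = "p_value") {
  tbl <- read_table_auto(path)
  require_cols(tbl, c(gene_col, lfc_col, p_col), path)
  de_records(gene = tbl[[gene_col]], fold_change = tbl[[lfc_col]],
             p_value = tbl[[p_col]])
}

#' Read a KEGG-id / gene-symbol mapping table
#'
#' Two columns: `kegg_id` (e.g. `"hsa:50"`) and `symbol` (HGNC).  Pathways
#' carry KEGG ids while localization and expression tables carry symbols, so
#' this mapping is required to join them.
#'
#' @param path TSV/CSV file.
#' @return Tibble with columns `kegg_id`, `symbol`.
#' @export
read_idmap <- function(path) {
  tbl <- read_table_auto(path)
  require_cols(tbl, c("kegg_id", "symbol"), path)
  tibble(kegg_id = trimws(tbl$kegg_id), symbol = normalize_gene(tbl$symbol))
}

pick_col <- function(tbl, candidates) {
  hit <- intersect(candidates, names(tbl))
  if (!length(hit)) {
    stop("none of the column(s) ", paste(candidates, collapse = "/"),
         " present")
  }
  tbl[[hit[1]]]
}

empty_loc <- function() tibble(gene = character(), category = character())

#' Reduce a SubCellBarCode table to per-gene preferred localizations
#'
#' @param tbl Output of [read_subcell()] (or a raw-dialect tibble with a
#'   `neighborhood` column).
#' @return Tibble with columns `gene`, `category`.
#' @export
reduce_subcell_table <- function(tbl) {
  if (!nrow(tbl)) return(empty_loc())
  mapping <- loc_mapping("subcell")
  tibble(gene = normalize_gene(tbl$gene),
         label = pick_col(tbl, c("label", "neighborhood"))) |>
    group_by(.data$gene) |>
    summarise(category = reduce_subcell(.data$label, mapping = mapping),
              .groups = "drop")
}

#' Reduce an HPA table to per-gene preferred localizations
#'
#' @param tbl Output of [read_hpa()].
#' @return Tibble with columns `gene`, `category`.
#' @export
reduce_hpa_table <- function(tbl) {
  if (!nrow(tbl)) return(empty_loc())
  mapping <- loc_mapping("hpa")
  tbl |>
    group_by(.data$gene) |>
    summarise(category = reduce_hpa(simplify_hpa(
      unlist(strsplit(.data$locations, ";")), mapping = mapping)),
      .groups = "drop")
}

#' Reduce a BUSCA table to per-gene preferred localizations
#'
#' @param tbl Output of [read_busca()] (or a raw-dialect tibble with
#'   `sequence_id`/`predicted_class` columns).
#' @return Tibble with columns `gene`, `category`.
#' @export
reduce_busca_table <- function(tbl) {
  if (!nrow(tbl)) return(empty_loc())
  mapping <- loc_mapping("busca")
  tibble(gene = normalize_gene(pick_col(tbl, c("gene", "sequence_id"))),
         label = pick_col(tbl, c("label", "predicted_class"))) |>
    group_by(.data$gene) |>
    summarise(category = plurality(
      vapply(.data$label, map_busca, character(1), mapping = mapping)),
      .groups = "drop")
}

#' Write a consensus table as TSV
#'
#' @param consensus Output of [build_consensus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(consensus, path) {
  readr::write_tsv(consensus, path)
  invisible(path)
}
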