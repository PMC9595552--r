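#' Recompute the published-style tables from downloaded inputs
#'
#' Given a combined per-source localization assignment table (the layout of
#' the published per-gene assignment supplement, columns `gene`, `subcell`,
#' `hpa`, `busca`) and a set of KGML pathway files downloaded from KEGG, this
#' recomputes, from scratch: the prediction-vs-experiment and
#' experiment-vs-experiment mitochondrial agreement statistics (sensitivity /
#' specificity, averaged per comparison pair), the cytosol share among
#' non-mitochondrial consensus calls, and the per-pathway mitochondrial /
#' non-mitochondrial fractions.  None of these inputs ship with the package;
#' point the arguments at your local downloads.
#'
#' @param combined_loc Path to the combined assignment table.
#' @param kgml Character vector of KGML file paths (may be empty to skip the
#'   pathway fractions).
#' @param idmap Path or tibble mapping `kegg_id` to `symbol` (required when
#'   `kgml` is non-empty).
#' @return List with `agreement` (tibble of comparisons incl. averages),
#'   `cytosol_share_pct` (percentage of non-mitochondrial consensus calls
#'   that are cytoplasmic), `fractions` (per-pathway tibble or `NULL`) and
#'   `consensus` (the full consensus tibble).
#' @export
reproduce_published_tables <- function(combined_loc, kgml = character(),
                                       idmap = NULL) {
  check_inputs_exist(combined_loc)
  src <- read_combined_loc(combined_loc)
  consensus <- build_consensus(subcell = src$subcell, hpa = src$hpa,
                               busca = src$busca)

  agreement_tbl <- bind_rows(
    agreement(src$busca, src$subcell, "busca_vs_subcell"),
    agreement(src$busca, src$hpa, "busca_vs_hpa"),
    agreement_average(list(agreement(src$busca, src$subcell),
                           agreement(src$busca, src$hpa)),
                      "busca_vs_experimental_avg"),
    agreement(src$hpa, src$subcell, "hpa_vs_subcell"),
    agreement(src$subcell, src$hpa, "subcell_vs_hpa"),
    agreement_average(list(agreement(src$hpa, src$subcell),
                           agreement(src$subcell, src$hpa)),
                      "experimental_avg")
  )

  nonmito <- consensus$consensus[usable(consensus$consensus) &
                                   consensus$consensus != "mitochondria"]
  cytosol_share <- 100 * sum(nonmito == "cytoplasm") / length(nonmito)

  fractions <- NULL
  if (length(kgml)) {
    check_inputs_exist(kgml)
    if (is.character(idmap)) idmap <- read_idmap(idmap)
    if (is.null(idmap)) stop("idmap required when kgml files are given")
    fractions <- bind_rows(lapply(kgml, function(p)
      compartment_fractions(expand_nodes(read_kgml(p)), consensus, idmap)))
  }

  list(agreement = agreement_tbl,
       cytosol_share_pct = cytosol_share,
       fractions = fractions,
       consensus = consensus)
}
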