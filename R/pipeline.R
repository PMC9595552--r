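# High-level pipeline steps.  Each run_* function is a thin composition of
# the module operations, reading files and writing files plus a provenance
# sidecar; the command-line front end adds no computation on top of these.

write_provenance <- function(outdir, step, inputs, params) {
  sidecar <- list(
    step = step,
    inputs = inputs,
    params = params,
    package = as.character(utils::packageVersion("funhop")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(sidecar, file.path(outdir, paste0(step, ".provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

check_inputs_exist <- function(paths) {
  paths <- unlist(paths)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Expand every multi-gene node of one or more KGML files
#'
#' Reads each KGML file, expands multi-gene nodes, lays the children out and
#' writes `<basename>.expanded.xml` into `outdir`.
#'
#' @param kgml Character vector of KGML paths (or a single directory, in
#'   which case all `*.xml` files inside are processed).
#' @param outdir Output directory (created if absent).
#' @return Character vector of output paths, invisibly.
#' @export
run_expand <- function(kgml, outdir) {
  if (length(kgml) == 1 && dir.exists(kgml)) {
    kgml <- list.files(kgml, pattern = "\\.xml$", full.names = TRUE)
  }
  if (!length(kgml)) stop("no KGML inputs given", call. = FALSE)
  check_inputs_exist(kgml)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outs <- vapply(kgml, function(p) {
    g <- read_kgml(p)
    n_multi <- sum(vapply(structural_entries(g), function(e)
      e$type %in% c("gene", "ortholog") && length(e$gene_ids) > 1,
      logical(1)))
    g <- layout_expanded(expand_nodes(g))
    out <- file.path(outdir, sub("\\.xml$", ".expanded.xml", basename(p)))
    write_kgml(g, out)
    message(basename(p), ": ", n_multi, " multi-gene entr",
            if (n_multi == 1) "y" else "ies", " expanded")
    out
  }, character(1))
  write_provenance(outdir, "expand", list(kgml = kgml), list())
  invisible(unname(outs))
}

#' Build the consensus localization table from source files
#'
#' Either three per-source tables (any subset) or one combined per-source
#' assignment table is reduced and merged into the consensus.
#'
#' @param subcell,hpa,busca Paths to the per-source tables (see
#'   [read_subcell()], [read_hpa()], [read_busca()]); `NULL` when absent.
#' @param combined Path to a combined assignment table (see
#'   [read_combined_loc()]); overrides the three per-source paths.
#' @param out Output TSV path.
#' @param prefer Casting-vote policy, see [build_consensus()].
#' @return The consensus tibble, invisibly.
#' @export
run_consensus <- function(subcell = NULL, hpa = NULL, busca = NULL,
                          combined = NULL, out,
                          prefer = c("busca", "experimental")) {
  prefer <- match.arg(prefer)
  if (is.null(combined) && is.null(subcell) && is.null(hpa) &&
      is.null(busca)) {
    stop("no localization source tables given", call. = FALSE)
  }
  if (!is.null(combined)) {
    check_inputs_exist(combined)
    src <- read_combined_loc(combined)
  } else {
    check_inputs_exist(c(subcell, hpa, busca))
    src <- list(
      subcell = if (!is.null(subcell))
        reduce_subcell_table(read_subcell(subcell)) else NULL,
      hpa = if (!is.null(hpa)) reduce_hpa_table(read_hpa(hpa)) else NULL,
      busca = if (!is.null(busca)) reduce_busca_table(read_busca(busca))
              else NULL
    )
  }
  consensus <- build_consensus(subcell = src$subcell, hpa = src$hpa,
                               busca = src$busca, prefer = prefer)
  rule_counts <- table(consensus$rule)
  message("consensus rules: ",
          paste(names(rule_counts), rule_counts, sep = "=", collapse = ", "))
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  write_consensus(consensus, out)
  write_provenance(dirname(out), "consensus",
                   list(subcell = subcell, hpa = hpa, busca = busca,
                        combined = combined),
                   list(prefer = prefer))
  invisible(consensus)
}

#' Split pathways into mitochondrial / non-mitochondrial variants
#'
#' For each KGML file, writes `<base>.mito.xml` and `<base>.nonmito.xml`,
#' a split report TSV (removed genes, broken links, component counts) and a
#' compartment-fraction TSV over all pathways.
#'
#' @param kgml Character vector of KGML paths.
#' @param consensus Path to a consensus TSV (from [run_consensus()]) or a
#'   consensus tibble.
#' @param idmap Path to a `kegg_id`/`symbol` mapping or a tibble.
#' @param outdir Output directory.
#' @param unknown_policy Passed to [split_pathway()].
#' @return Named list of `split_result` objects, invisibly.
#' @export
run_split <- function(kgml, consensus, idmap, outdir,
                      unknown_policy = c("both", "drop")) {
  unknown_policy <- match.arg(unknown_policy)
  check_inputs_exist(kgml)
  if (is.character(consensus)) {
    check_inputs_exist(consensus)
    consensus <- readr::read_tsv(consensus, show_col_types = FALSE,
                                 progress = FALSE)
  }
  if (is.character(idmap)) idmap <- read_idmap(idmap)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  fractions <- list()
  reports <- list()
  for (p in kgml) {
    g <- layout_expanded(expand_nodes(read_kgml(p)))
    res <- split_pathway(g, consensus, idmap, unknown_policy = unknown_policy)
    base <- sub("\\.xml$", "", basename(p))
    write_kgml(res$mito_variant, file.path(outdir, paste0(base, ".mito.xml")))
    write_kgml(res$nonmito_variant,
               file.path(outdir, paste0(base, ".nonmito.xml")))
    fractions[[p]] <- compartment_fractions(g, consensus, idmap)
    conn <- connectivity_report(res, original = g)
    reports[[p]] <- bind_rows(
      res$removed_genes |> mutate(pathway = base, item = "removed_gene",
                                  detail = .data$gene_id),
      res$broken_links |> mutate(pathway = base, item = "broken_link",
                                 detail = .data$reaction_id),
      conn$components |> mutate(pathway = base, item = "component_count",
                                variant = .data$graph,
                                detail = as.character(.data$n_components))
    ) |> select("pathway", "variant", "item", "detail")
    results[[base]] <- res
  }
  readr::write_tsv(bind_rows(fractions),
                   file.path(outdir, "compartment_fractions.tsv"))
  readr::write_tsv(bind_rows(reports), file.path(outdir, "split_report.tsv"))
  write_provenance(outdir, "split", list(kgml = kgml),
                   list(unknown_policy = unknown_policy))
  invisible(results)
}

#' Overlay differential expression onto expanded pathways
#'
#' Filters the DE table at `alpha`, transforms p-values to signed scores,
#' annotates every per-gene node with score and color and writes the
#' annotated KGML, a node-attribute TSV, a GraphML export and a Cytoscape
#' style file.
#'
#' @param kgml Character vector of KGML paths.
#' @param de Path to a DE table (see [read_de_table()]) or a DE tibble.
#' @param idmap Path to a `kegg_id`/`symbol` mapping or a tibble.
#' @param outdir Output directory.
#' @param alpha Significance threshold (strict), default 0.05.
#' @param consensus Optional consensus (path or tibble) to include
#'   localization in the attribute table.
#' @param cap Color saturation cap, see [colorize()].
#' @return Named list of annotated [pathway_graph()]s, invisibly.
#' @export
run_overlay <- function(kgml, de, idmap, outdir, alpha = 0.05,
                        consensus = NULL, cap = 100) {
  check_inputs_exist(kgml)
  if (is.character(de)) {
    check_inputs_exist(de)
    de <- read_de_table(de)
  }
  if (is.character(idmap)) idmap <- read_idmap(idmap)
  if (is.character(consensus)) {
    check_inputs_exist(consensus)
    consensus <- readr::read_tsv(consensus, show_col_types = FALSE,
                                 progress = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  de_sig <- filter_de(de, alpha = alpha)

  out <- list()
  for (p in kgml) {
    g <- layout_expanded(expand_nodes(read_kgml(p)))
    g <- annotate_graph(g, de_sig, idmap, cap = cap)
    base <- sub("\\.xml$", "", basename(p))
    write_kgml(g, file.path(outdir, paste0(base, ".annotated.xml")))
    node_attributes(g, consensus = consensus, idmap = idmap,
                    path = file.path(outdir, paste0(base, ".attrs.tsv")))
    write_graphml(g, file.path(outdir, paste0(base, ".graphml")),
                  consensus = consensus, idmap = idmap)
    out[[base]] <- g
  }
  write_cytoscape_style(file.path(outdir, "de_style.json"), cap = cap)
  write_provenance(outdir, "overlay", list(kgml = kgml),
                   list(alpha = alpha, cap = cap))
  invisible(out)
}

#' Dataset- and pathway-level summaries
#'
#' Writes the per-source localization summary, the per-compartment up/down
#' regulation counts (one block per source and one for the consensus) and
#' the mitochondrial-fraction pathway ranking.
#'
#' @param kgml Character vector of KGML paths.
#' @param sources Named list of per-gene `gene`/`category` tibbles (or paths
#'   to per-source raw tables readable by the matching reader, named
#'   `subcell`, `hpa`, `busca`).
#' @param consensus Consensus tibble or TSV path.
#' @param de DE tibble or path.
#' @param idmap Mapping tibble or path.
#' @param outdir Output directory.
#' @param alpha Significance threshold for the regulation counts.
#' @return List with `source_summary`, `regulation`, `ranking`, invisibly.
#' @export
run_summarize <- function(kgml, sources, consensus, de, idmap, outdir,
                          alpha = 0.05) {
  check_inputs_exist(kgml)
  if (is.character(consensus)) {
    consensus <- readr::read_tsv(consensus, show_col_types = FALSE,
                                 progress = FALSE)
  }
  if (is.character(de)) de <- read_de_table(de)
  if (is.character(idmap)) idmap <- read_idmap(idmap)
  sources <- lapply(stats::setNames(names(sources), names(sources)),
                    function(nm) {
    s <- sources[[nm]]
    if (is.character(s)) {
      s <- switch(nm,
                  subcell = reduce_subcell_table(read_subcell(s)),
                  hpa = reduce_hpa_table(read_hpa(s)),
                  busca = reduce_busca_table(read_busca(s)),
                  stop("unknown source name: ", nm))
    }
    s
  })
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  graphs <- lapply(kgml, function(p) expand_nodes(read_kgml(p)))
  sym <- stats::setNames(idmap$symbol, idmap$kegg_id)
  kegg_genes <- unique(stats::na.omit(unname(
    sym[unlist(lapply(graphs, pathway_genes))])))

  summary <- source_summary(sources, kegg_genes)
  de_sig <- filter_de(de, alpha = alpha)
  regulation <- bind_rows(lapply(names(sources), function(nm)
    regulation_by_compartment(de_sig, sources[[nm]]) |>
      mutate(source = nm)))
  regulation <- bind_rows(
    regulation,
    regulation_by_compartment(
      de_sig, consensus |> select("gene", category = "consensus")) |>
      mutate(source = "consensus"))
  ranking <- rank_pathways(graphs, consensus, idmap)

  readr::write_tsv(summary, file.path(outdir, "source_summary.tsv"))
  readr::write_tsv(regulation, file.path(outdir, "regulation_by_compartment.tsv"))
  readr::write_tsv(ranking, file.path(outdir, "pathway_ranking.tsv"))
  write_provenance(outdir, "summarize", list(kgml = kgml),
                   list(alpha = alpha))
  invisible(list(source_summary = summary, regulation = regulation,
                 ranking = ranking))
}
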