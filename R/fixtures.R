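# Seeded synthetic-data generators.  They emit the same KGML and table
# dialects the ingestion functions read, with a ground-truth table recording
# each gene's true compartment, so every stage of the pipeline can be tested
# offline and end-to-end recovery can be measured against a known answer.

# run code under a fixed seed without disturbing the caller's RNG stream
with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# SubCell / BUSCA spellings of the shared four-category vocabulary
SUBCELL_LABEL_OF <- c(mitochondria = "Mitochondria", cytoplasm = "Cytosol",
                      nucleus = "Nuclear", secretory = "Secretory")
BUSCA_LABEL_OF <- c(mitochondria = "mitochondrion", cytoplasm = "cytoplasm",
                    nucleus = "nucleus", secretory = "extracellular space")
HPA_LABELS_OF <- list(
  mitochondria = "Mitochondria",
  cytoplasm = c("Cytosol", "Microtubules", "Centrosome", "Actin filaments"),
  nucleus = c("Nucleoplasm", "Nucleoli", "Nuclear bodies",
              "Nuclear speckles"),
  secretory = c("Vesicles", "Golgi apparatus", "Endoplasmic reticulum",
                "Plasma membrane")
)

#' Specify a synthetic pathway/localization/expression fixture
#'
#' Central parameter object for the synthetic generators.  Defaults emulate
#' the study conditions of the real analysis: a mixed-localization metabolic
#' pathway (40% mitochondrial genes, with cytosol dominating the
#' non-mitochondrial calls), SubCellBarCode uncertainty around 4% and HPA
#' uncertainty around 15%, experimental coverage of 61% (SubCell) and 53%
#' (HPA) with full BUSCA coverage, and upregulation biased 3:1 towards
#' mitochondrial genes in the differential-expression table.
#'
#' @param n_compounds Number of compound entries (>= n_gene_entries + 1).
#' @param n_gene_entries Number of gene (enzyme) entries along the chain.
#' @param genes_per_entry Integer vector of homolog counts, recycled over the
#'   gene entries (multi-gene entries are what node expansion acts on).
#' @param fraction_mito Probability a gene is truly mitochondrial.
#' @param nonmito_weights Category weights for non-mitochondrial genes
#'   (cytoplasm, nucleus, secretory).
#' @param subcell_coverage,hpa_coverage Fraction of genes present in each
#'   experimental source (BUSCA always covers every gene).
#' @param subcell_unassign_rate Per-cell-line probability of an `Unassign`.
#' @param frac_uncertain_subcell,frac_uncertain_hpa Fraction of covered genes
#'   forced into an exact tie (reducing to `uncertain`).
#' @param busca_disagree_rate Probability BUSCA predicts a wrong category.
#' @param frac_significant Fraction of genes differentially expressed below
#'   the 0.05 threshold.
#' @param up_odds Named numeric: odds of upregulation (p_up) per category.
#' @param seed Integer seed fixing all generator output.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_compounds = 8, n_gene_entries = 6,
                         genes_per_entry = c(1, 2, 3),
                         fraction_mito = 0.4,
                         nonmito_weights = c(cytoplasm = 0.59,
                                             nucleus = 0.25,
                                             secretory = 0.16),
                         subcell_coverage = 0.61, hpa_coverage = 0.53,
                         subcell_unassign_rate = 0.1,
                         frac_uncertain_subcell = 0.04,
                         frac_uncertain_hpa = 0.15,
                         busca_disagree_rate = 0.1,
                         frac_significant = 0.5,
                         up_odds = c(mitochondria = 0.75, cytoplasm = 0.5,
                                     nucleus = 0.5, secretory = 0.5),
                         seed = 1L) {
  stopifnot(n_gene_entries >= 1, n_compounds >= n_gene_entries + 1,
            all(genes_per_entry >= 1),
            fraction_mito >= 0, fraction_mito <= 1,
            subcell_coverage >= 0, subcell_coverage <= 1,
            hpa_coverage >= 0, hpa_coverage <= 1,
            frac_significant >= 0, frac_significant <= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic pathway with ground-truth localizations
#'
#' Builds a linear reaction chain `C1 -[E1]-> C2 -[E2]-> ...` alternating
#' compounds and gene entries, attaching any surplus compounds as branch
#' products of randomly chosen entries, plus map-link relations between
#' consecutive gene entries.  Every gene gets a synthetic KEGG id and symbol
#' and a true compartment drawn from the spec's localization model.
#'
#' @param spec A [fixture_spec()].
#' @return List with `graph` (a [pathway_graph()]) and `truth` (tibble:
#'   `kegg_id`, `symbol`, `entry_id`, `category`).
#' @export
make_pathway <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec$seed, {
    sizes <- rep_len(spec$genes_per_entry, spec$n_gene_entries)
    n_genes <- sum(sizes)
    kegg_ids <- sprintf("hsa:%d", 1000L + seq_len(n_genes))
    symbols <- sprintf("GENE%03d", seq_len(n_genes))
    category <- ifelse(
      stats::runif(n_genes) < spec$fraction_mito, "mitochondria",
      sample(names(spec$nonmito_weights), n_genes, replace = TRUE,
             prob = spec$nonmito_weights))

    entries <- list()
    reactions <- list()
    relations <- list()
    compound_ids <- sprintf("c%d", seq_len(spec$n_compounds))
    for (i in seq_along(compound_ids)) {
      entries[[compound_ids[i]]] <- new_entry(
        id = compound_ids[i], type = "compound",
        name = sprintf("cpd:C%05d", i),
        graphics = list(c(name = sprintf("C%05d", i),
                          x = format_num(60 * i), y = "400",
                          width = "8", height = "8", type = "circle")))
    }
    truth_entry <- character(n_genes)
    g <- 1L
    for (j in seq_len(spec$n_gene_entries)) {
      eid <- sprintf("e%d", j)
      idx <- g:(g + sizes[j] - 1L)
      truth_entry[idx] <- eid
      entries[[eid]] <- new_entry(
        id = eid, type = "gene", name = paste(kegg_ids[idx], collapse = " "),
        gene_ids = kegg_ids[idx], reaction = sprintf("rn:R%05d", j),
        graphics = list(c(name = paste0(symbols[idx[1]], "..."),
                          x = format_num(100 * j), y = "200",
                          width = "46", height = "17", type = "rectangle")))
      reactions[[j]] <- new_reaction(
        reaction_id = sprintf("rn:R%05d", j), entry_id = eid,
        substrates = compound_ids[j], products = compound_ids[j + 1])
      g <- g + sizes[j]
    }
    # surplus compounds become branch products of random entries
    surplus <- setdiff(seq_len(spec$n_compounds),
                       seq_len(spec$n_gene_entries + 1L))
    for (k in surplus) {
      j <- sample.int(spec$n_gene_entries, 1)
      r <- reactions[[j]]
      reactions[[j]]$products <- c(r$products, compound_ids[k])
    }
    if (spec$n_gene_entries > 1) {
      for (j in seq_len(spec$n_gene_entries - 1L)) {
        relations[[j]] <- new_relation(
          entry1 = sprintf("e%d", j), entry2 = sprintf("e%d", j + 1),
          relation_type = "ECrel",
          subtypes = list(list(name = "compound",
                               value = compound_ids[j + 1])))
      }
    }
    graph <- pathway_graph(
      pathway_id = sprintf("path:syn%05d", spec$seed %% 100000L),
      title = "synthetic fixture pathway",
      entries = entries, reactions = reactions, relations = relations,
      attrs = c(name = sprintf("path:syn%05d", spec$seed %% 100000L),
                org = "syn", number = "00000",
                title = "synthetic fixture pathway"))
    list(graph = graph,
         truth = tibble(kegg_id = kegg_ids, symbol = symbols,
                        entry_id = truth_entry, category = category))
  })
}

#' Identifier mapping for a synthetic fixture
#'
#' @param truth Truth tibble from [make_pathway()].
#' @return Tibble with columns `kegg_id`, `symbol`.
#' @export
make_idmap <- function(truth) {
  tibble(kegg_id = truth$kegg_id, symbol = truth$symbol)
}

#' Generate the three localization source tables for a fixture
#'
#' Emits tables in the three ingestion dialects: a long SubCellBarCode table
#' (five cell lines, `Unassign` noise, optional forced ties), an HPA table
#' (semicolon-joined multi-labels drawn from the raw 35-location vocabulary,
#' optional forced ties) and a BUSCA table (one predicted class per gene,
#' wrong with probability `busca_disagree_rate`).  Coverage, noise and tie
#' rates come from the spec; with all noise at zero the consensus recovers
#' the ground truth exactly.
#'
#' @param spec A [fixture_spec()].
#' @param truth Truth tibble from [make_pathway()].
#' @return List of tibbles `subcell`, `hpa`, `busca` (ingestion-dialect
#'   layouts, ready for [reduce_subcell_table()] etc. or to be written with
#'   [readr::write_tsv()] and re-read).
#' @export
make_localization_tables <- function(spec, truth) {
  stopifnot(inherits(spec, "fixture_spec"))
  cell_lines <- c("A431", "MCF7", "H322", "U251", "HCC827")
  with_fixture_seed(spec$seed + 101L, {
    n <- nrow(truth)
    other <- function(cat) sample(setdiff(LOC_CATEGORIES, cat), 1)

    sc_cover <- stats::runif(n) < spec$subcell_coverage
    sc_rows <- list()
    for (i in which(sc_cover)) {
      cat <- truth$category[i]
      if (stats::runif(1) < spec$frac_uncertain_subcell) {
        alt <- other(cat)
        labs <- c(SUBCELL_LABEL_OF[c(cat, cat, alt, alt)], "Unassign")
      } else {
        labs <- rep(SUBCELL_LABEL_OF[cat], 5)
        drop <- stats::runif(5) < spec$subcell_unassign_rate
        labs[drop] <- "Unassign"
      }
      sc_rows[[length(sc_rows) + 1L]] <- tibble(
        gene = truth$symbol[i], cell_line = cell_lines,
        neighborhood = unname(labs))
    }

    hpa_cover <- stats::runif(n) < spec$hpa_coverage
    hpa_rows <- list()
    for (i in which(hpa_cover)) {
      cat <- truth$category[i]
      if (stats::runif(1) < spec$frac_uncertain_hpa) {
        alt <- other(cat)
        labs <- c(sample(HPA_LABELS_OF[[cat]], 1),
                  sample(HPA_LABELS_OF[[alt]], 1))
      } else {
        k <- sample(1:2, 1)
        labs <- sample(HPA_LABELS_OF[[cat]], min(k, length(HPA_LABELS_OF[[cat]])))
      }
      hpa_rows[[length(hpa_rows) + 1L]] <- tibble(
        gene = truth$symbol[i],
        locations = paste(labs, collapse = ";"),
        reliability = sample(c("Enhanced", "Supported", "Approved"), 1))
    }

    busca_cat <- vapply(truth$category, function(cat) {
      if (stats::runif(1) < spec$busca_disagree_rate) other(cat) else cat
    }, character(1))
    busca <- tibble(
      sequence_id = truth$symbol,
      predicted_class = unname(BUSCA_LABEL_OF[busca_cat]),
      score = round(stats::runif(n, 0.6, 1), 3))

    list(
      subcell = if (length(sc_rows)) bind_rows(sc_rows) else
        tibble(gene = character(), cell_line = character(),
               neighborhood = character()),
      hpa = if (length(hpa_rows)) bind_rows(hpa_rows) else
        tibble(gene = character(), locations = character(),
               reliability = character()),
      busca = busca
    )
  })
}

#' Generate a differential-expression table for a fixture
#'
#' Significant genes (fraction `frac_significant`) draw p-values
#' log-uniformly below 0.05 and their regulation sign from the
#' per-compartment upregulation odds; the rest draw null p-values uniformly
#' on [0.05, 1).  Layout matches the DE ingestion dialect (`gene`, `logFC`,
#' `p_value`).
#'
#' @param spec A [fixture_spec()].
#' @param truth Truth tibble from [make_pathway()].
#' @return List with `table` (tibble `gene`, `logFC`, `p_value`) and
#'   `truth_de` (tibble `gene`, `significant`, `regulation`).
#' @export
make_de_table <- function(spec, truth) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec$seed + 202L, {
    n <- nrow(truth)
    significant <- stats::runif(n) < spec$frac_significant
    p_up <- spec$up_odds[truth$category]
    up <- stats::runif(n) < p_up
    p_value <- ifelse(significant,
                      10 ^ stats::runif(n, -6, log10(0.049)),
                      stats::runif(n, 0.05, 0.9999))
    logfc <- ifelse(up, 1, -1) * abs(stats::rnorm(n, 1.5, 0.5))
    list(
      table = tibble(gene = truth$symbol, logFC = logfc, p_value = p_value),
      truth_de = tibble(gene = truth$symbol, significant = significant,
                        regulation = ifelse(up, 1L, -1L),
                        category = truth$category)
    )
  })
}
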