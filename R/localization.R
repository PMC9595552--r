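# Shared localization vocabulary.  Sources are reduced to one of the four
# biological categories plus "uncertain" (conflicting evidence) and "unknown"
# (no usable evidence); the consensus never emits "uncertain".
LOC_CATEGORIES <- c("mitochondria", "cytoplasm", "nucleus", "secretory")
LOC_VOCAB <- c(LOC_CATEGORIES, "uncertain", "unknown")

loc_mapping <- function(which = c("hpa", "busca", "subcell"), path = NULL) {
  which <- match.arg(which)
  if (is.null(path)) {
    path <- system.file("extdata", paste0(which, "_category_map.tsv"),
                        package = "funhop", mustWork = TRUE)
  }
  tab <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  stats::setNames(tab$category, tab$raw_label)
}

usable <- function(category) {
  !is.na(category) & category %in% LOC_CATEGORIES
}

# Strict-plurality vote: the winning label must occur strictly more often
# than the runner-up; an exact tie is "uncertain", an empty ballot "unknown".
plurality <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) return("unknown")
  tab <- sort(table(labels), decreasing = TRUE)
  if (length(tab) == 1 || tab[1] > tab[2]) names(tab)[1] else "uncertain"
}

#' Reduce SubCellBarCode cell-line calls to one preferred localization
#'
#' SubCellBarCode reports one localization neighborhood per cell line (five
#' lines: A431, MCF7, H322, U251, HCC827).  Cell lines with an `Unassign`
#' call are dropped; the remaining calls are harmonized to the shared
#' four-category vocabulary and put to a strict-plurality vote.  A tie gives
#' `uncertain`; all-`Unassign` gives `unknown`.
#'
#' @param labels Character vector of per-cell-line neighborhood labels
#'   (`Mitochondria`, `Cytosol`, `Nuclear`, `Secretory`, `Unassign`).
#' @param mapping Named vector mapping SubCell labels to categories; defaults
#'   to the bundled table.
#' @return A single category string.
#' @export
#' @examples
#' reduce_subcell(c("Mitochondria", "Mitochondria", "Unassign",
#'                  "Cytosol", "Mitochondria"))
reduce_subcell <- function(labels, mapping = loc_mapping("subcell")) {
  stopifnot(length(labels) > 0)
  labels <- trimws(labels)
  labels <- labels[!labels %in% c("Unassign", "unassign", "")]
  if (!length(labels)) return("unknown")
  plurality(unname(mapping[labels]))
}

#' Simplify HPA multi-label annotations to the four-category vocabulary
#'
#' The Human Protein Atlas annotates up to 35 subcellular locations per
#' protein.  Each raw label is mapped through the bundled organelle-grouping
#' table (nucleus / cytoplasm / secretory, with mitochondria kept separate).
#' Unmapped labels are dropped with a warning.
#'
#' @param labels Character vector of HPA location labels (an empty set is an
#'   error).
#' @param mapping Named vector mapping HPA labels to categories.
#' @return Character vector of simplified categories, one per mapped label.
#' @export
simplify_hpa <- function(labels, mapping = loc_mapping("hpa")) {
  if (!length(labels)) stop("empty HPA label set")
  labels <- trimws(labels)
  out <- unname(mapping[labels])
  if (anyNA(out)) {
    warning("unmapped HPA labels dropped: ",
            paste(unique(labels[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out[!is.na(out)]
}

#' Reduce simplified HPA categories to one preferred localization
#'
#' Strict-plurality vote over the output of [simplify_hpa()]: a unanimous or
#' strictly most frequent category wins, a tie gives `uncertain`.
#'
#' @param simplified Character vector of simplified categories.
#' @return A single category string.
#' @export
reduce_hpa <- function(simplified) {
  plurality(simplified)
}

#' Map a BUSCA predicted class to the four-category vocabulary
#'
#' BUSCA emits a single predicted compartment per protein.  Extracellular and
#' membrane classes are grouped with `secretory`; BUSCA has no `uncertain`
#' category.  Unknown labels give `unknown` with a warning.
#'
#' @param label BUSCA class string (e.g. `"mitochondrion"`,
#'   `"extracellular space"`, `"plasma membrane"`).
#' @param mapping Named vector mapping BUSCA labels to categories.
#' @return A single category string.
#' @export
map_busca <- function(label, mapping = loc_mapping("busca")) {
  stopifnot(length(label) == 1)
  out <- unname(mapping[trimws(tolower(label))])
  if (is.na(out)) {
    warning("unknown BUSCA label '", label, "' -> unknown", call. = FALSE)
    out <- "unknown"
  }
  out
}

# Consensus for one gene.  Votes are the three per-source categories;
# uncertain and unknown are absent votes.  Hierarchy: two-of-three agreement
# beats everything (BUSCA included); otherwise BUSCA casts the deciding vote;
# otherwise a lone experimental vote stands; otherwise unknown.
consensus_one <- function(subcell, hpa, busca,
                          prefer = c("busca", "experimental")) {
  prefer <- match.arg(prefer)
  votes <- c(subcell = subcell, hpa = hpa, busca = busca)
  votes[!usable(votes)] <- NA_character_
  ok <- votes[!is.na(votes)]
  if (length(ok) == 0) {
    return(list(category = "unknown", rule = "none"))
  }
  tab <- sort(table(ok), decreasing = TRUE)
  if (tab[1] >= 2) {
    rule <- if (length(ok) == 3 && length(tab) == 1) "unanimous" else "majority"
    return(list(category = names(tab)[1], rule = rule))
  }
  if (length(ok) == 1) {
    return(list(category = unname(ok), rule = "single_source"))
  }
  # >= 2 usable votes, all distinct
  if (!is.na(votes["busca"]) && prefer == "busca") {
    return(list(category = unname(votes["busca"]),
                rule = "busca_casting_vote"))
  }
  exp_votes <- votes[c("subcell", "hpa")]
  exp_votes <- exp_votes[!is.na(exp_votes)]
  if (prefer == "experimental" && length(exp_votes) == 1) {
    return(list(category = unname(exp_votes), rule = "single_source"))
  }
  list(category = "unknown", rule = "none")
}

#' Build the three-way localization consensus
#'
#' Combines per-gene preferred localizations from SubCellBarCode, the Human
#' Protein Atlas and BUSCA into one consensus category per gene.  `uncertain`
#' and `unknown` source calls are treated as absent votes.  When two usable
#' votes agree the consensus goes to them even against BUSCA; when all usable
#' votes differ BUSCA provides the casting vote; a lone usable vote stands;
#' with no usable vote the consensus is `unknown`.
#'
#' @param subcell,hpa,busca Tibbles with columns `gene`, `category` (one row
#'   per gene); any may be `NULL` when a source is unavailable.
#' @param prefer Tie policy when exactly one experimental vote disagrees with
#'   BUSCA: `"busca"` (default, prediction decides) or `"experimental"`.
#' @return A tibble with columns `gene`, `subcell`, `hpa`, `busca`,
#'   `consensus`, `rule`.
#' @export
#' @examples
#' build_consensus(
#'   subcell = tibble::tibble(gene = "ACACA", category = "cytoplasm"),
#'   hpa     = tibble::tibble(gene = "ACACA", category = "cytoplasm"),
#'   busca   = tibble::tibble(gene = "ACACA", category = "mitochondria")
#' )
build_consensus <- function(subcell = NULL, hpa = NULL, busca = NULL,
                            prefer = c("busca", "experimental")) {
  prefer <- match.arg(prefer)
  take <- function(x, nm) {
    if (is.null(x) || !nrow(x)) {
      return(tibble(gene = character(), !!nm := character()))
    }
    x |>
      mutate(gene = normalize_gene(.data$gene)) |>
      group_by(.data$gene) |>
      summarise(!!nm := plurality(.data$category), .groups = "drop")
  }
  tbl <- Reduce(function(a, b) dplyr::full_join(a, b, by = "gene"),
                list(take(subcell, "subcell"), take(hpa, "hpa"),
                     take(busca, "busca")))
  if (!nrow(tbl)) {
    return(tibble(gene = character(), subcell = character(),
                  hpa = character(), busca = character(),
                  consensus = character(), rule = character()))
  }
  tbl[is.na(tbl)] <- "unknown"
  res <- mapply(consensus_one, tbl$subcell, tbl$hpa, tbl$busca,
                MoreArgs = list(prefer = prefer), SIMPLIFY = FALSE,
                USE.NAMES = FALSE)
  tbl$consensus <- vapply(res, `[[`, character(1), "category")
  tbl$rule <- vapply(res, `[[`, character(1), "rule")
  arrange(tbl, .data$gene)
}

normalize_gene <- function(x) toupper(trimws(x))

#' Cross-source agreement on mitochondrial localization
#'
#' Binarizes two per-gene category vectors as mitochondria vs the rest and
#' reports the confusion matrix, sensitivity and specificity over the genes
#' with a usable category in both sources.
#'
#' @param pred,truth Tibbles with columns `gene`, `category`.
#' @param comparison Label for the report row.
#' @return A one-row tibble: `comparison`, `n_shared`, `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`.
#' @export
agreement <- function(pred, truth, comparison = "pred_vs_truth") {
  p <- pred  |> mutate(gene = normalize_gene(.data$gene)) |>
    filter(usable(.data$category)) |> distinct(.data$gene, .data$category)
  t <- truth |> mutate(gene = normalize_gene(.data$gene)) |>
    filter(usable(.data$category)) |> distinct(.data$gene, .data$category)
  m <- dplyr::inner_join(p, t, by = "gene", suffix = c("_pred", "_truth"))
  if (!nrow(m)) stop("no shared genes with usable localization")
  pm <- m$category_pred == "mitochondria"
  tm <- m$category_truth == "mitochondria"
  tp <- sum(pm & tm); fp <- sum(pm & !tm)
  tn <- sum(!pm & !tm); fn <- sum(!pm & tm)
  tibble(
    comparison = comparison, n_shared = nrow(m),
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' Average a list of agreement reports
#'
#' @param reports List of tibbles from [agreement()].
#' @param comparison Label for the averaged row.
#' @return One-row tibble with mean sensitivity and specificity.
#' @export
agreement_average <- function(reports, comparison = "average") {
  all <- bind_rows(reports)
  tibble(comparison = comparison, n_shared = sum(all$n_shared),
         tp = NA_integer_, fp = NA_integer_, tn = NA_integer_,
         fn = NA_integer_,
         sensitivity = mean(all$sensitivity),
         specificity = mean(all$specificity))
}
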