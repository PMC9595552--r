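# In-code fixture builders shared across the suite.

LOC4 <- c("mitochondria", "cytoplasm", "nucleus", "secretory")

# The three-compound / two-gene chain: C1 -[mito gene]-> C2 -[cyto gene]-> C3
toy_graph <- function() {
  entries <- list(
    c1 = funhop:::new_entry("c1", "compound", "cpd:C00022",
      graphics = list(c(name = "C00022", x = "100", y = "200",
                        width = "8", height = "8", type = "circle"))),
    c2 = funhop:::new_entry("c2", "compound", "cpd:C00024",
      graphics = list(c(name = "C00024", x = "200", y = "200",
                        width = "8", height = "8", type = "circle"))),
    c3 = funhop:::new_entry("c3", "compound", "cpd:C00186",
      graphics = list(c(name = "C00186", x = "300", y = "200",
                        width = "8", height = "8", type = "circle"))),
    g1 = funhop:::new_entry("g1", "gene", "hsa:9001",
      gene_ids = "hsa:9001", reaction = "rn:R90001",
      graphics = list(c(name = "TOYM1", x = "150", y = "160",
                        width = "46", height = "17", type = "rectangle"))),
    g2 = funhop:::new_entry("g2", "gene", "hsa:9002",
      gene_ids = "hsa:9002", reaction = "rn:R90002",
      graphics = list(c(name = "TOYC1", x = "250", y = "160",
                        width = "46", height = "17", type = "rectangle")))
  )
  reactions <- list(
    funhop:::new_reaction("rn:R90001", "g1", "c1", "c2"),
    funhop:::new_reaction("rn:R90002", "g2", "c2", "c3")
  )
  pathway_graph("path:toy00001", "toy compartment chain",
                entries = entries, reactions = reactions)
}

toy_idmap <- function() {
  tibble::tibble(kegg_id = c("hsa:9001", "hsa:9002"),
                 symbol = c("TOYM1", "TOYC1"))
}

toy_consensus <- function() {
  tibble::tibble(gene = c("TOYM1", "TOYC1"),
                 consensus = c("mitochondria", "cytoplasm"),
                 rule = "single_source")
}

random_fixture <- function(seed) {
  fixture_spec(
    n_compounds = 5 + seed %% 4,
    n_gene_entries = 3 + seed %% 3,
    genes_per_entry = 1 + (seq_len(3 + seed %% 3) + seed) %% 3,
    fraction_mito = 0.5,
    seed = seed
  )
}

# Independent consensus oracle: a literal tally of the published voting
# rules, kept free of the package's vote bookkeeping.
oracle_consensus <- function(subcell, hpa, busca) {
  v <- c(subcell, hpa, busca)
  v[!v %in% LOC4] <- NA
  counts <- vapply(LOC4, function(cat) sum(v == cat, na.rm = TRUE),
                   integer(1))
  if (max(counts) >= 2) return(LOC4[which.max(counts)])
  if (!is.na(v[3])) return(v[3])
  left <- v[!is.na(v)]
  if (length(left) == 1) return(left)
  "unknown"
}

# Brute-force binary confusion matrix, mitochondria as positive class.
oracle_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] == "mitochondria"
    t <- truth[i] == "mitochondria"
    if (p && t) tp <- tp + 1L
    else if (p && !t) fp <- fp + 1L
    else if (!p && t) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

write_inline_kgml <- function(text) {
  path <- withr::local_tempfile(fileext = ".xml",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}
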