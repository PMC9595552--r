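test_that("the toy chain splits into complementary broken variants", {
  g <- layout_expanded(expand_nodes(toy_graph()))
  res <- split_pathway(g, toy_consensus(), toy_idmap())
  # mito variant keeps only the first reaction, nonmito only the second
  expect_equal(vapply(res$mito_variant$reactions, function(r) r$reaction_id,
                      character(1)), "rn:R90001")
  expect_equal(vapply(res$nonmito_variant$reactions,
                      function(r) r$reaction_id, character(1)), "rn:R90002")
  # one broken link per variant, components go from 1 to 2
  expect_equal(sum(res$broken_links$variant == "mito"), 1)
  expect_equal(sum(res$broken_links$variant == "nonmito"), 1)
  expect_equal(unname(res$component_counts),
               c(1L, 2L, 2L))
  conn <- connectivity_report(res, original = g)
  expect_equal(conn$components$n_components, c(1L, 2L, 2L))
  # compounds are retained in both variants
  expect_true(all(c("c1", "c2", "c3") %in% names(res$mito_variant$entries)))
  expect_true(all(c("c1", "c2", "c3") %in%
                    names(res$nonmito_variant$entries)))
})

test_that("an all-mitochondrial pathway keeps its mito variant intact", {
  spec <- fixture_spec(seed = 3, fraction_mito = 1)
  pw <- make_pathway(spec)
  cons <- tibble::tibble(gene = pw$truth$symbol,
                         consensus = pw$truth$category)
  g <- expand_nodes(pw$graph)
  res <- split_pathway(g, cons, make_idmap(pw$truth))
  expect_true(pathway_equal(res$mito_variant, g))
  expect_equal(component_count(res$mito_variant), component_count(g))
  expect_equal(nrow(gene_nodes(res$nonmito_variant)), 0)
  # a variant with no gene entries is edgeless: every compound its own island
  n_compounds <- sum(vapply(res$nonmito_variant$entries, function(e)
    e$type == "compound", logical(1)))
  expect_equal(component_count(res$nonmito_variant), n_compounds)
})

test_that("a two-gene node with mixed localization survives in both variants", {
  entries <- list(
    s = funhop:::new_entry("s", "compound", "cpd:C1"),
    p = funhop:::new_entry("p", "compound", "cpd:C2"),
    mdh = funhop:::new_entry("mdh", "gene", "hsa:4190 hsa:4191",
                             gene_ids = c("hsa:4190", "hsa:4191"))
  )
  g <- pathway_graph("path:mdh", "malate",
                     entries = entries,
                     reactions = list(funhop:::new_reaction(
                       "rn:R00342", "mdh", "s", "p", reversible = TRUE)))
  cons <- tibble::tibble(gene = c("MDH1", "MDH2"),
                         consensus = c("cytoplasm", "mitochondria"))
  idmap <- tibble::tibble(kegg_id = c("hsa:4190", "hsa:4191"),
                          symbol = c("MDH1", "MDH2"))
  res <- split_pathway(g, cons, idmap)
  expect_equal(gene_nodes(res$mito_variant)$gene_id, "hsa:4191")
  expect_equal(gene_nodes(res$nonmito_variant)$gene_id, "hsa:4190")
  # the catalysed reaction survives on both sides
  expect_length(res$mito_variant$reactions, 1)
  expect_length(res$nonmito_variant$reactions, 1)
  expect_equal(nrow(res$broken_links), 0)
})

test_that("variant gene sets partition the known-localization genes", {
  for (seed in 1:200) {
    spec <- fixture_spec(
      n_compounds = 4 + seed %% 3,
      n_gene_entries = 2 + seed %% 3,
      genes_per_entry = 1 + (seq_len(2 + seed %% 3) + seed) %% 3,
      fraction_mito = (seed %% 5) / 4,
      seed = seed)
    pw <- make_pathway(spec)
    # random unknowns in the consensus
    cats <- pw$truth$category
    cats[seq_along(cats) %% 7 == 0] <- "unknown"
    cons <- tibble::tibble(gene = pw$truth$symbol, consensus = cats)
    g <- expand_nodes(pw$graph)
    res <- split_pathway(g, cons, make_idmap(pw$truth),
                         unknown_policy = "drop")
    mito_genes <- unique(gene_nodes(res$mito_variant)$gene_id)
    nonmito_genes <- unique(gene_nodes(res$nonmito_variant)$gene_id)
    known <- pw$truth$kegg_id[cats != "unknown"]
    expect_length(intersect(mito_genes, nonmito_genes), 0)
    expect_setequal(union(mito_genes, nonmito_genes), known)
    # edge subset: variant reactions/relations are subsets of the original
    rid <- function(x) vapply(x$reactions, function(r)
      paste(r$reaction_id, r$entry_id), character(1))
    expect_true(all(rid(res$mito_variant) %in% rid(g)))
    expect_true(all(rid(res$nonmito_variant) %in% rid(g)))
  }
})

test_that("unknown-localization genes follow the chosen policy", {
  pw <- make_pathway(fixture_spec(seed = 77))
  cats <- pw$truth$category
  cats[1] <- "unknown"
  cons <- tibble::tibble(gene = pw$truth$symbol, consensus = cats)
  g <- expand_nodes(pw$graph)
  both <- split_pathway(g, cons, make_idmap(pw$truth),
                        unknown_policy = "both")
  unknown_id <- pw$truth$kegg_id[1]
  expect_true(unknown_id %in% gene_nodes(both$mito_variant)$gene_id)
  expect_true(unknown_id %in% gene_nodes(both$nonmito_variant)$gene_id)
  expect_equal(both$unknown_genes, unknown_id)
  dropped <- split_pathway(g, cons, make_idmap(pw$truth),
                           unknown_policy = "drop")
  expect_false(unknown_id %in% gene_nodes(dropped$mito_variant)$gene_id)
  expect_false(unknown_id %in% gene_nodes(dropped$nonmito_variant)$gene_id)
})

test_that("an empty consensus table is an error", {
  expect_error(split_pathway(toy_graph(), toy_consensus()[0, ], toy_idmap()),
               "empty")
})

test_that("compartment fractions reproduce printed-style percentages", {
  make_counted <- function(n_mito, n_nonmito) {
    n <- n_mito + n_nonmito
    entries <- list()
    for (i in seq_len(n)) {
      id <- paste0("e", i)
      entries[[id]] <- funhop:::new_entry(id, "gene",
                                          sprintf("hsa:%d", i),
                                          gene_ids = sprintf("hsa:%d", i))
    }
    g <- pathway_graph("path:frac", "f", entries = entries)
    cons <- tibble::tibble(
      gene = sprintf("S%d", seq_len(n)),
      consensus = c(rep("mitochondria", n_mito),
                    rep("cytoplasm", n_nonmito)))
    idmap <- tibble::tibble(kegg_id = sprintf("hsa:%d", seq_len(n)),
                            symbol = sprintf("S%d", seq_len(n)))
    compartment_fractions(g, cons, idmap)
  }
  tca <- make_counted(23, 6)
  expect_equal(c(tca$pct_mito, tca$pct_nonmito), c(79, 21))
  expect_equal(c(tca$n_mito, tca$n_nonmito), c(23, 6))
  pyr <- make_counted(19, 21)     # 47.5/52.5 round half-to-even: 48/52
  expect_equal(c(pyr$pct_mito, pyr$pct_nonmito), c(48, 52))
  onesided <- make_counted(0, 10)
  expect_equal(c(onesided$pct_mito, onesided$pct_nonmito), c(0, 100))
})

test_that("fraction percentages stay within rounding bounds", {
  for (seed in c(4L, 40L, 400L)) {
    pw <- make_pathway(random_fixture(seed))
    cons <- tibble::tibble(gene = pw$truth$symbol,
                           consensus = pw$truth$category)
    f <- compartment_fractions(pw$graph, cons, make_idmap(pw$truth))
    expect_true(f$pct_mito + f$pct_nonmito >= 99)
    expect_true(f$pct_mito + f$pct_nonmito <= 101)
    # pre-rounding fractions sum exactly to one
    expect_equal(f$n_mito / f$n_known + f$n_nonmito / f$n_known, 1)
    expect_equal(f$n_mito + f$n_nonmito, f$n_known)
  }
})

test_that("genes absent from idmap or consensus count as unknown", {
  g <- toy_graph()
  cons <- toy_consensus()[1, ]             # TOYC1 missing from consensus
  f <- compartment_fractions(g, cons, toy_idmap())
  expect_equal(f$n_known, 1)
  expect_equal(f$n_unknown, 1)
})

test_that("merging the variants recovers the known-localization subgraph", {
  pw <- make_pathway(fixture_spec(seed = 55))
  cons <- tibble::tibble(gene = pw$truth$symbol,
                         consensus = pw$truth$category)
  g <- expand_nodes(pw$graph)
  res <- split_pathway(g, cons, make_idmap(pw$truth), unknown_policy = "drop")
  merged <- sort(c(unique(gene_nodes(res$mito_variant)$gene_id),
                   unique(gene_nodes(res$nonmito_variant)$gene_id)))
  expect_equal(merged, sort(unique(gene_nodes(g)$gene_id)))
  ents <- union(names(res$mito_variant$entries),
                names(res$nonmito_variant$entries))
  expect_setequal(ents, names(g$entries))
})
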