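test_that("SubCell cell-line reduction follows drop-Unassign plus plurality", {
  expect_equal(reduce_subcell(c("Mitochondria", "Mitochondria", "Unassign",
                                "Cytosol", "Mitochondria")),
               "mitochondria")
  expect_equal(reduce_subcell(c("Mitochondria", "Cytosol")), "uncertain")
  expect_equal(reduce_subcell(rep("Unassign", 5)), "unknown")
  expect_equal(reduce_subcell(c("Nuclear", "Nuclear", "Unassign")), "nucleus")
})

test_that("HPA labels simplify through the bundled 35-to-4 grouping", {
  expect_equal(simplify_hpa(c("Nucleoplasm", "Nucleoli")),
               c("nucleus", "nucleus"))
  expect_equal(simplify_hpa("Mitochondria"), "mitochondria")
  expect_equal(simplify_hpa(c("Cytosol", "Mitochondria")),
               c("cytoplasm", "mitochondria"))
  expect_error(simplify_hpa(character()), "empty")
  expect_warning(out <- simplify_hpa(c("Cytosol", "Flagellum")), "unmapped")
  expect_equal(out, "cytoplasm")
  # every one of the 35 bundled labels maps into the four categories
  mapping <- funhop:::loc_mapping("hpa")
  expect_length(mapping, 35)
  expect_true(all(mapping %in% LOC4))
})

test_that("HPA reduction is a strict-plurality vote", {
  expect_equal(reduce_hpa(c("nucleus", "nucleus", "cytoplasm")), "nucleus")
  expect_equal(reduce_hpa(c("mitochondria", "cytoplasm")), "uncertain")
  expect_equal(reduce_hpa("secretory"), "secretory")
})

test_that("BUSCA classes map onto the four categories", {
  expect_equal(map_busca("mitochondrion"), "mitochondria")
  expect_equal(map_busca("extracellular space"), "secretory")
  expect_equal(map_busca("plasma membrane"), "secretory")
  expect_equal(map_busca("endomembrane system"), "secretory")
  expect_warning(out <- map_busca("flagellum"), "unknown BUSCA label")
  expect_equal(out, "unknown")
})

test_that("reduce operators are invariant under label permutation", {
  set.seed(404)
  for (i in 1:20) {
    labs <- sample(c("Mitochondria", "Cytosol", "Nuclear", "Secretory",
                     "Unassign"), sample(2:6, 1), replace = TRUE)
    expect_equal(reduce_subcell(labs), reduce_subcell(sample(labs)))
    cats <- sample(LOC4, sample(2:6, 1), replace = TRUE)
    expect_equal(reduce_hpa(cats), reduce_hpa(sample(cats)))
  }
})

cons1 <- function(s, h, b, prefer = "busca") {
  tb <- function(cat) tibble::tibble(gene = "G1", category = cat)
  build_consensus(tb(s), tb(h), tb(b), prefer = prefer)
}

test_that("consensus follows the two-of-three / casting-vote hierarchy", {
  r <- cons1("mitochondria", "mitochondria", "cytoplasm")
  expect_equal(r$consensus, "mitochondria")
  expect_equal(r$rule, "majority")
  # experimental agreement beats the prediction (ACACA case)
  r <- cons1("cytoplasm", "cytoplasm", "mitochondria")
  expect_equal(r$consensus, "cytoplasm")
  # all three differ: prediction casts the deciding vote
  r <- cons1("mitochondria", "cytoplasm", "nucleus")
  expect_equal(r$consensus, "nucleus")
  expect_equal(r$rule, "busca_casting_vote")
  # prediction as the only usable source
  r <- cons1("unknown", "unknown", "mitochondria")
  expect_equal(r$consensus, "mitochondria")
  expect_equal(r$rule, "single_source")
  r <- cons1("secretory", "secretory", "secretory")
  expect_equal(r$rule, "unanimous")
  r <- cons1("unknown", "uncertain", "unknown")
  expect_equal(r$consensus, "unknown")
  expect_equal(r$rule, "none")
})

test_that("all 125 vote combinations match the brute-force oracle", {
  vocab <- c(LOC4, "unknown")
  for (s in vocab) for (h in vocab) for (b in vocab) {
    expect_equal(cons1(s, h, b)$consensus, oracle_consensus(s, h, b),
                 label = paste("votes:", s, h, b))
  }
})

test_that("uncertain votes behave exactly like unknown votes", {
  vocab <- c(LOC4, "unknown")
  for (s in vocab) for (h in vocab) {
    swap <- function(x) ifelse(x == "unknown", "uncertain", x)
    expect_equal(cons1(swap(s), h, "uncertain")$consensus,
                 cons1(s, h, "unknown")$consensus)
  }
  # and the consensus itself never emits uncertain
  expect_false("uncertain" %in%
                 cons1("uncertain", "uncertain", "uncertain")$consensus)
})

test_that("two agreeing votes dominate any third vote", {
  vocab <- c(LOC4, "unknown", "uncertain")
  for (cat in LOC4) for (third in vocab) {
    expect_equal(cons1(cat, cat, third)$consensus, cat)
    expect_equal(cons1(cat, third, cat)$consensus, cat)
    expect_equal(cons1(third, cat, cat)$consensus, cat)
  }
})

test_that("the experimental-preference switch only flips one-vs-one conflicts", {
  # one usable experimental vote disagreeing with the prediction
  expect_equal(cons1("cytoplasm", "unknown", "mitochondria")$consensus,
               "mitochondria")
  r <- cons1("cytoplasm", "unknown", "mitochondria", prefer = "experimental")
  expect_equal(r$consensus, "cytoplasm")
  # but two-of-three agreement is untouched by the switch
  expect_equal(
    cons1("cytoplasm", "cytoplasm", "mitochondria",
          prefer = "experimental")$consensus, "cytoplasm")
})

test_that("duplicate gene rows in a source are pooled before voting", {
  sub <- tibble::tibble(gene = c("g1", "g1", "g1"),
                        category = c("mitochondria", "mitochondria",
                                     "cytoplasm"))
  r <- build_consensus(sub, NULL, NULL)
  expect_equal(r$consensus, "mitochondria")
  # gene symbols are case/whitespace normalized on the way in
  r2 <- build_consensus(tibble::tibble(gene = " acaca ",
                                       category = "cytoplasm"),
                        tibble::tibble(gene = "ACACA",
                                       category = "cytoplasm"), NULL)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$gene, "ACACA")
})

test_that("agreement reproduces hand-computed confusion matrices", {
  identical_cats <- tibble::tibble(
    gene = paste0("g", 1:6),
    category = c("mitochondria", "mitochondria", "cytoplasm", "nucleus",
                 "secretory", "mitochondria"))
  r <- agreement(identical_cats, identical_cats)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  truth <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"),
                          category = c("mitochondria", "mitochondria",
                                       "cytoplasm", "nucleus"))
  pred <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"),
                         category = c("mitochondria", "cytoplasm",
                                      "cytoplasm", "nucleus"))
  r <- agreement(pred, truth)
  expect_equal(unlist(r[c("tp", "fn", "tn", "fp")]),
               c(tp = 1, fn = 1, tn = 2, fp = 0))
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$specificity, 1)
  expect_equal(r$n_shared, sum(unlist(r[c("tp", "fp", "tn", "fn")])))

  no_mito_pred <- tibble::tibble(gene = truth$gene, category = "cytoplasm")
  expect_equal(agreement(no_mito_pred, truth)$sensitivity, 0)

  expect_error(agreement(tibble::tibble(gene = "a", category = "cytoplasm"),
                         tibble::tibble(gene = "b", category = "cytoplasm")),
               "no shared genes")
})

test_that("agreement matches the brute-force oracle on random vectors", {
  for (seed in c(5L, 19L)) {
    set.seed(seed)
    n <- 1000
    genes <- paste0("g", 1:n)
    truth <- tibble::tibble(
      gene = genes,
      category = sample(c(LOC4, "unknown", "uncertain"), n, replace = TRUE,
                        prob = c(0.2, 0.35, 0.15, 0.1, 0.1, 0.1)))
    pred <- tibble::tibble(
      gene = genes,
      category = sample(c(LOC4, "unknown"), n, replace = TRUE))
    r <- agreement(pred, truth)
    shared <- merge(subset(pred, category %in% LOC4),
                    subset(truth, category %in% LOC4), by = "gene")
    o <- oracle_confusion(shared$category.x, shared$category.y)
    expect_equal(r$n_shared, nrow(shared))
    expect_equal(unlist(r[c("tp", "fp", "tn", "fn")]),
                 unlist(o[c("tp", "fp", "tn", "fn")]), ignore_attr = TRUE)
    expect_equal(r$sensitivity, o$sensitivity)
    expect_equal(r$specificity, o$specificity)
  }
})

test_that("agreement_average averages sensitivity and specificity", {
  a <- tibble::tibble(comparison = "a", n_shared = 10L, tp = 3L, fp = 1L,
                      tn = 5L, fn = 1L, sensitivity = 0.75,
                      specificity = 5 / 6)
  b <- a
  b$sensitivity <- 0.25
  b$specificity <- 0.5
  avg <- agreement_average(list(a, b))
  expect_equal(avg$sensitivity, 0.5)
  expect_equal(avg$specificity, mean(c(5 / 6, 0.5)))
})

test_that("the bundled synthetic assignment fixture reproduces known calls", {
  path <- system.file("extdata", "synthetic_s2_localizations.tsv",
                      package = "funhop")
  src <- read_combined_loc(path)
  cons <- build_consensus(src$subcell, src$hpa, src$busca)
  pick <- function(g) cons$consensus[cons$gene == g]
  # experimental agreement overrides the prediction
  expect_equal(pick("ACACA"), "cytoplasm")
  expect_equal(pick("MDH1"), "cytoplasm")
  expect_equal(pick("MDH2"), "mitochondria")
  # prediction as lone usable source
  expect_equal(pick("GLS2"), "mitochondria")
  # three-way disagreement: prediction casts the vote
  expect_equal(pick("NIT2"), "nucleus")
  expect_equal(cons$rule[cons$gene == "NIT2"], "busca_casting_vote")
})
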