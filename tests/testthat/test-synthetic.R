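test_that("world parameters are validated", {
  expect_error(world_params(p = 0), "p must")
  expect_error(world_params(coverage = 0), "coverage")
  expect_error(world_params(mu_on = 0, mu_off = 1), "mu_on")
  expect_error(world_params(sigma = 0), "sigma")
})

test_that("simulated worlds honour prevalence, coverage and orthology", {
  # p = 1: every pair expressed
  w <- simulate_world(world_params(organisms = "human", n_genes = 10,
                                   n_tissues = 4, p = 1, seed = 2))
  expect_true(all(w$truth$human))

  # q = 0: no ortholog groups linking organisms, empty 1:1 map
  w <- simulate_world(world_params(organisms = c("human", "mouse"),
                                   q = 0, frac_non121 = 0, seed = 3))
  expect_equal(nrow(one_to_one_pairs(w$groups, "human", "mouse")$pairs), 0)

  # expressed-pair count within 3 binomial sigma of n*p across seeds
  n <- 200 * 10
  for (seed in 1:5) {
    w <- simulate_world(world_params(organisms = "human", n_genes = 200,
                                     n_tissues = 10, p = 0.3,
                                     seed = seed))
    k <- sum(w$truth$human)
    expect_lt(abs(k - n * 0.3), 3 * sqrt(n * 0.3 * 0.7))
  }

  # ortholog-linked genes share truth; groups file exercises 1:1 filters
  w <- simulate_world(world_params(organisms = c("human", "mouse"),
                                   n_genes = 50, n_tissues = 6, q = 0.5,
                                   frac_non121 = 0.2, seed = 4))
  map <- one_to_one_pairs(w$groups, "human", "mouse")
  expect_equal(nrow(map$pairs), 25)
  for (i in seq_len(nrow(map$pairs)))
    expect_equal(unname(w$truth$mouse[map$pairs$gene_b[i], ]),
                 unname(w$truth$human[map$pairs$gene_a[i], ]))
  # non-1:1 groups exist and contribute no pairs
  per_group <- table(w$groups$groups$group)
  expect_true(any(per_group == 3))

  # ontology is a DAG whose major tissues are the dataset tissues
  expect_s3_class(w$ontology, "TissueOntology")
  expect_setequal(w$ontology$major_tissues, w$tissues)
  expect_true(all(lengths(lapply(w$tissues, ancestors,
                                 onto = w$ontology)) >= 1))
})

test_that("datasets are seed-deterministic with controlled separation", {
  w <- simulate_world(world_params(organisms = "human", n_genes = 60,
                                   n_tissues = 8, seed = 5))
  d1 <- simulate_dataset(w, "human", seed = 11)
  d2 <- simulate_dataset(w, "human", seed = 11)
  expect_identical(d1$values, d2$values)
  d3 <- simulate_dataset(w, "human", seed = 12)
  expect_false(identical(d1$values, d3$values))

  # near-zero noise: expressed and silent pairs are perfectly separable
  clean <- simulate_dataset(w, "human", mu_on = 3, mu_off = 0,
                            sigma = 1e-4, seed = 13)
  on_vals <- clean$values[w$truth$human]
  off_vals <- clean$values[!w$truth$human]
  expect_gt(min(on_vals), max(off_vals))
  expect_equal(mean(on_vals), exp(3), tolerance = 1e-3)

  expect_error(simulate_dataset(w, "dog"), "unknown organism")
})

test_that("gold-standard sampling is a binomial subset of the truth", {
  w <- simulate_world(world_params(organisms = "human", n_genes = 200,
                                   n_tissues = 10, p = 0.5, seed = 6))
  truth_pairs <- truth_gold_standard(w, "human")$pairs
  n_true <- nrow(truth_pairs)

  # c = 1 recovers the full truth
  gs_full <- simulate_gold_standard(w, "human", coverage = 1)
  expect_equal(gs_full$pairs, truth_pairs)

  # contamination 0: always a subset of the truth; size ~ Binom(n, c)
  for (seed in 1:5) {
    gs <- simulate_gold_standard(w, "human", coverage = 0.2, seed = seed)
    expect_true(all(paste(gs$pairs$gene, gs$pairs$tissue) %in%
                      paste(truth_pairs$gene, truth_pairs$tissue)))
    expect_lt(abs(nrow(gs$pairs) - 0.2 * n_true),
              3 * sqrt(n_true * 0.2 * 0.8))
  }
  expect_error(simulate_gold_standard(w, "human", coverage = 1.2),
               "coverage")
})

test_that("corpus signal follows the elevation parameter", {
  w <- simulate_world(world_params(organisms = "human", n_genes = 30,
                                   n_tissues = 6, p = 0.3, seed = 7))
  truth <- w$truth$human
  auc_of <- function(elevation, seed) {
    tm <- simulate_corpus(w, "human", n_docs = 200,
                          elevation = elevation, seed = seed)
    counts <- count_comentions(tm$corpus, tm$gene_names, tm$tissue_names)
    ch <- cooccurrence_score(counts, alpha = 0.6)
    roc_against_gold(ch, truth_gold_standard(w, "human"),
                     colnames(truth))$auc
  }
  # same seed -> identical corpus
  t1 <- simulate_corpus(w, "human", n_docs = 20, seed = 8)
  t2 <- simulate_corpus(w, "human", n_docs = 20, seed = 8)
  expect_identical(t1$corpus, t2$corpus)

  # strong elevation separates truth well; zero elevation does not
  expect_gt(auc_of(0.95, 1), 0.9)
  aucs <- vapply(1:5, function(s) auc_of(0, s), numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("pipeline-level recovery: fitted midpoint tracks the truth", {
  # the sigmoid midpoint a3 should sit near the log10 decision boundary
  # between the on- and off-distributions, (mu_on + mu_off) / (2 ln 10)
  mu_on <- 3; mu_off <- 0
  boundary <- ((mu_on + mu_off) / 2) / log(10)
  hits <- 0
  for (seed in 1:10) {
    w <- simulate_world(world_params(organisms = "human", n_genes = 100,
                                     n_tissues = 10, p = 0.3,
                                     coverage = 0.6, seed = seed))
    ds <- simulate_dataset(w, "human", mu_on = mu_on, mu_off = mu_off,
                           sigma = 1, seed = seed + 500)
    gs <- simulate_gold_standard(w, "human", seed = seed)
    fit <- fit_sigmoid(fold_enrichment_curve(ds, gs, window = 50,
                                             step = 50))
    if (abs(fit$a3 - boundary) <= 0.25) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
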