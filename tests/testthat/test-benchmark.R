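test_that("dataset correlation: self, anti, and closed-form oracle", {
  ch <- make_channel(30, seed = 1)
  expect_equal(dataset_correlation(ch, ch), 1.0, tolerance = 1e-12)

  # b = star_max - a over the same pairs -> r = -1
  a <- ch$associations
  flipped <- scored_channel(transform(a, stars = 5 - stars),
                            organism = ch$organism, dataset_id = "flip")
  expect_equal(dataset_correlation(ch, flipped, mode = "co_detected"),
               -1.0, tolerance = 1e-12)

  # 20-pair synthetic channels: r equals the textbook formula
  set.seed(44)
  genes <- sprintf("g%02d", 1:5)
  tissues <- sprintf("t%d", 1:4)
  grid <- expand.grid(gene = genes, tissue = tissues,
                      stringsAsFactors = FALSE)
  c1 <- scored_channel(transform(grid, stars = stats::runif(20, 0, 5)),
                       dataset_id = "c1")
  c2 <- scored_channel(transform(grid, stars = stats::runif(20, 0, 5)),
                       dataset_id = "c2")
  r <- dataset_correlation(c1, c2)
  key <- paste(grid$gene, grid$tissue)
  v1 <- stats::setNames(c1$associations$stars,
                        paste(c1$associations$gene,
                              c1$associations$tissue))[key]
  v2 <- stats::setNames(c2$associations$stars,
                        paste(c2$associations$gene,
                              c2$associations$tissue))[key]
  expect_equal(r, oracle_pearson(v1, v2))

  # zero-fill: a pair absent from one channel contributes a 0
  c3 <- scored_channel(c2$associations[-1, ], dataset_id = "c3")
  v2z <- v2; v2z[1] <- 0
  expect_equal(dataset_correlation(c1, c3), oracle_pearson(v1, v2z))

  # degenerate cases error
  tiny <- scored_channel(data.frame(gene = c("g01", "g02"),
                                    tissue = "t1", stars = 1:2))
  expect_error(dataset_correlation(tiny, tiny), "fewer than 3")
  flat <- scored_channel(transform(grid, stars = 1), dataset_id = "flat")
  expect_error(dataset_correlation(flat, c1), "zero variance")
})

test_that("cross-organism correlation routes genes through the map", {
  set.seed(45)
  genes_h <- sprintf("h%02d", 1:6)
  genes_m <- sprintf("m%02d", 1:6)
  tissues <- sprintf("t%d", 1:3)
  gh <- expand.grid(gene = genes_h, tissue = tissues,
                    stringsAsFactors = FALSE)
  gh$stars <- stats::runif(18, 0, 5)
  gm <- gh
  gm$gene <- sprintf("m%02d", as.integer(sub("h", "", gh$gene)))
  a <- scored_channel(gh, organism = "human", dataset_id = "a")
  b <- scored_channel(gm, organism = "mouse", dataset_id = "b")
  map <- structure(list(org_a = "human", org_b = "mouse",
                        pairs = data.frame(gene_a = genes_h,
                                           gene_b = genes_m),
                        voided = 0L), class = "OrthologMap")
  expect_equal(dataset_correlation(a, b, map = map), 1.0,
               tolerance = 1e-12)
})

test_that("per-tissue correlation is the single-tissue restriction", {
  ch1 <- make_channel(32, seed = 3, genes = sprintf("g%02d", 1:8),
                      tissues = c("t1", "t2"), id = "x")
  ch2 <- make_channel(32, seed = 4, genes = sprintf("g%02d", 1:8),
                      tissues = c("t1", "t2"), id = "y")
  r <- per_tissue_correlation(ch1, ch2, "t1")
  expect_equal(r, dataset_correlation(ch1, ch2, tissues = "t1"))
  expect_error(per_tissue_correlation(ch1, ch2, "t9"), "t9")

  # single-tissue channels: equals the whole-dataset correlation
  a1 <- scored_channel(ch1$associations[ch1$associations$tissue == "t1", ],
                       dataset_id = "x1")
  a2 <- scored_channel(ch2$associations[ch2$associations$tissue == "t1", ],
                       dataset_id = "y1")
  expect_equal(per_tissue_correlation(a1, a2, "t1"),
               dataset_correlation(a1, a2))
})

test_that("correlation matrix is symmetric with unit diagonal", {
  chs <- list(a = make_channel(30, seed = 1, id = "a"),
              b = make_channel(30, seed = 2, id = "b"),
              c = make_channel(30, seed = 3, id = "c"))
  m <- correlation_matrix(chs)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m, t(m))
  expect_equal(m["a", "b"], dataset_correlation(chs$a, chs$b))
  expect_equal(m["b", "c"], dataset_correlation(chs$b, chs$c))

  # identical channels correlate at 1 everywhere
  m2 <- correlation_matrix(list(x = chs$a, y = chs$a))
  expect_equal(unname(m2), matrix(1, 2, 2), ignore_attr = TRUE)

  # independent random channels at n = 2000: off-diagonals near 0
  set.seed(99)
  grid <- expand.grid(gene = sprintf("g%03d", 1:200),
                      tissue = sprintf("t%02d", 1:10),
                      stringsAsFactors = FALSE)
  big <- lapply(1:2, function(i)
    scored_channel(transform(grid, stars = stats::runif(2000, 0, 5)),
                   dataset_id = paste0("r", i)))
  names(big) <- c("r1", "r2")
  m3 <- correlation_matrix(big)
  expect_lt(abs(m3["r1", "r2"]), 0.1)

  p <- withr::local_tempfile(fileext = ".tsv")
  write_correlation_matrix(m, p)
  back <- utils::read.delim(p, row.names = 1)
  expect_equal(as.matrix(back), m, ignore_attr = TRUE)
})

test_that("ROC against the gold standard: indicators and invariance", {
  set.seed(7)
  genes <- sprintf("g%02d", 1:30)
  tissues <- sprintf("t%d", 1:4)
  grid <- expand.grid(gene = genes, tissue = tissues,
                      stringsAsFactors = FALSE)
  pos <- grid[sample(nrow(grid), 25), ]
  gs <- gold_standard(pos)

  # perfect scorer: stars = gold indicator
  grid$stars <- as.numeric(paste(grid$gene, grid$tissue) %in%
                             paste(pos$gene, pos$tissue))
  perfect <- scored_channel(grid, dataset_id = "perfect")
  roc <- roc_against_gold(perfect, gs, tissues)
  expect_equal(roc$auc, 1.0)
  expect_false(is.unsorted(roc$points$tpr))
  expect_false(is.unsorted(roc$points$fpr))
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(roc$points$fpr[nrow(roc$points)], 1)

  # inverted scorer
  inv <- scored_channel(transform(grid, stars = 1 - stars),
                        dataset_id = "inv")
  expect_equal(roc_against_gold(inv, gs, tissues)$auc, 0.0)

  # monotone transform of scores leaves the curve unchanged
  warped <- scored_channel(transform(grid, stars = grid$stars^3 + 1),
                           dataset_id = "w")
  expect_equal(roc_against_gold(warped, gs, tissues)$auc, roc$auc)

  # degenerate gold standards error
  all_gs <- gold_standard(grid[, c("gene", "tissue")])
  expect_error(roc_against_gold(perfect, all_gs, tissues),
               "zero negatives")
  none <- gold_standard(data.frame(gene = "g01", tissue = "zz"))
  expect_error(roc_against_gold(perfect, none, tissues),
               "zero positives")

  p <- withr::local_tempfile(fileext = ".tsv")
  write_roc(roc, p)
  expect_match(readLines(p)[1], "threshold\ttpr\tfpr")
})

test_that("homolog profile correlation over major tissues", {
  prof <- stats::setNames(stats::runif(21, 0, 5), sprintf("T%02d", 1:21))
  expect_equal(homolog_profile_correlation(prof, prof), 1.0)
  expect_error(homolog_profile_correlation(prof[1:2], prof[1:2]),
               "fewer than 3")
  flat <- stats::setNames(rep(2, 21), names(prof))
  expect_error(homolog_profile_correlation(prof, flat), "zero variance")

  other <- stats::setNames(stats::runif(21, 0, 5), names(prof))
  expect_equal(homolog_profile_correlation(prof, other),
               oracle_pearson(unname(prof), unname(other)))

  # missing tissues in one profile are zero-filled
  partial <- other[1:15]
  filled <- c(unname(other[1:15]), rep(0, 6))
  expect_equal(homolog_profile_correlation(prof, partial,
                                           tissues = names(prof)),
               oracle_pearson(unname(prof), filled))
})
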