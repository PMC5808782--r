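test_that("expected fraction is the gs density of the universe", {
  gs <- gold_standard(data.frame(gene = c("g1", "g2", "gX"),
                                 tissue = c("t1", "t2", "tX")))
  expect_equal(expected_fraction(gs, sprintf("g%d", 1:4), c("t1", "t2")),
               2 / 8)  # 2 restricted pairs over 4x2
  full <- gold_standard(expand.grid(gene = c("a", "b"),
                                    tissue = c("x", "y"),
                                    stringsAsFactors = FALSE))
  expect_equal(expected_fraction(full, c("a", "b"), c("x", "y")), 1.0)
  expect_error(expected_fraction(gs, "nope", "t1"), "cannot be benchmarked")

  # enumeration oracle on a random 50x10 universe
  set.seed(12)
  genes <- sprintf("g%02d", 1:50); tissues <- sprintf("t%02d", 1:10)
  gs <- gold_standard(data.frame(
    gene = sample(genes, 120, replace = TRUE),
    tissue = sample(tissues, 120, replace = TRUE)))
  manual <- sum(outer(genes, tissues, paste) %in%
                  paste(gs$pairs$gene, gs$pairs$tissue)) / 500
  expect_equal(expected_fraction(gs, genes, tissues), manual)
})

test_that("fold-enrichment bins match the direct-count oracle", {
  set.seed(17)
  ds <- make_dataset(40, 10, seed = 17)
  genes <- dataset_genes(ds); tissues <- dataset_tissues(ds)

  # gs = all pairs -> e = 1 everywhere
  gs_all <- gold_standard(expand.grid(gene = genes, tissue = tissues,
                                      stringsAsFactors = FALSE))
  cv <- fold_enrichment_curve(ds, gs_all, window = 100, step = 100)
  expect_equal(cv$bins$e, rep(1, 4))
  expect_equal(cv$bins$n, rep(100L, 4))

  # random gs: exact agreement with the oracle, 400 pairs window 100
  gs <- gold_standard(data.frame(
    gene = sample(genes, 80, replace = TRUE),
    tissue = sample(tissues, 80, replace = TRUE)))
  cv <- fold_enrichment_curve(ds, gs, window = 100, step = 100)
  orc <- oracle_curve(ds, gs, 100, 100)
  expect_equal(cv$bins$x, orc$x)
  expect_equal(cv$bins$e, orc$e)

  # sliding stride 1 also matches
  cv <- fold_enrichment_curve(ds, gs, window = 50, step = 1)
  orc <- oracle_curve(ds, gs, 50, 1)
  expect_equal(cv$bins$e, orc$e)

  # row-order invariance (ties broken deterministically)
  perm <- sample(length(genes))
  ds2 <- expression_dataset(ds$values[perm, ], dataset_id = "perm")
  cv2 <- fold_enrichment_curve(ds2, gs, window = 100, step = 100)
  expect_equal(cv2$bins, fold_enrichment_curve(ds, gs, window = 100,
                                               step = 100)$bins)

  # a window with zero gs pairs has e = 0: checkerboard of high/low
  # values with the gs exactly on the high cells (covering every gene and
  # tissue, so nothing is lost to universe restriction)
  high <- outer(1:20, 1:10, function(g, t) (g + t) %% 2 == 0)
  m <- ifelse(high, 100, 1) + matrix(seq(0, 0.199, by = 0.001), 20)
  dimnames(m) <- list(sprintf("g%02d", 1:20), sprintf("t%02d", 1:10))
  ds3 <- expression_dataset(m)
  idx <- which(high, arr.ind = TRUE)
  gs3 <- gold_standard(data.frame(gene = rownames(m)[idx[, 1]],
                                  tissue = colnames(m)[idx[, 2]]))
  cv3 <- fold_enrichment_curve(ds3, gs3, window = 100, step = 100)
  expect_equal(cv3$bins$e, c(2, 0))  # top window all hits, bottom none

  # fewer pairs than the window is an error suggesting a smaller window
  expect_error(fold_enrichment_curve(ds3, gs3, window = 500),
               "smaller window")
})

test_that("non-overlapping bins conserve the overall gs hit fraction", {
  set.seed(23)
  ds <- make_dataset(40, 10, seed = 23)
  # gs touches every gene and tissue so the restricted universe is the
  # full 400-pair grid, which the 4 non-overlapping bins cover exactly
  gs <- gold_standard(data.frame(
    gene = c(dataset_genes(ds),
             sample(dataset_genes(ds), 50, replace = TRUE)),
    tissue = c(rep_len(dataset_tissues(ds), 40),
               sample(dataset_tissues(ds), 50, replace = TRUE))))
  cv <- fold_enrichment_curve(ds, gs, window = 100, step = 100)
  # mean(e) * expected = overall hit fraction over the covered pairs
  overall <- mean(cv$bins$e) * cv$expected
  genes <- intersect(dataset_genes(ds), unique(gs$pairs$gene))
  tissues <- intersect(dataset_tissues(ds), unique(gs$pairs$tissue))
  n_hit <- sum(gs$pairs$gene %in% genes & gs$pairs$tissue %in% tissues)
  expect_equal(overall, n_hit / (length(genes) * length(tissues)))
})

test_that("sigmoid evaluation obeys its closed form", {
  fit <- sigmoid_fit(a0 = 0.5, a1 = 3.5, a2 = 1.7, a3 = 0.8)
  expect_equal(eval_sigmoid(fit, 10^0.8), (0.5 + 3.5) / 2)  # midpoint
  flat <- sigmoid_fit(1, 3, 0, 0)
  expect_equal(eval_sigmoid(flat, c(0.01, 1, 100)), rep(2, 3))  # a2 = 0
  f <- sigmoid_fit(0, 4, 1, 0)
  expect_equal(eval_sigmoid(f, 10), 4 / (1 + exp(-1)))  # ~2.9281
  # monotone and bounded
  xs <- 10^seq(-6, 6, length.out = 200)
  v <- eval_sigmoid(fit, xs)
  expect_false(is.unsorted(v))
  expect_true(all(v >= fit$a0 & v <= fit$a1))
})

test_that("sigmoid fitting recovers parameters", {
  true <- sigmoid_fit(a0 = 0.3, a1 = 3.2, a2 = 1.4, a3 = 0.9)
  x <- 10^seq(-1, 3, length.out = 40)
  curve <- structure(list(
    bins = data.frame(x = x, e = eval_sigmoid(true, x), n = 100L),
    window = 100L, step = 100L, expected = 0.1, n_pairs = 4000L),
    class = "EnrichmentCurve")
  fit <- fit_sigmoid(curve)
  expect_equal(fit$a0, true$a0, tolerance = 1e-3)
  expect_equal(fit$a1, true$a1, tolerance = 1e-3)
  expect_equal(fit$a2, true$a2, tolerance = 1e-3)
  expect_equal(fit$a3, true$a3, tolerance = 1e-3)

  # constant curve accepted as the flat solution a0 ~ a1 ~ c
  flat_curve <- curve
  flat_curve$bins$e <- 2.5
  fit <- fit_sigmoid(flat_curve)
  expect_equal(eval_sigmoid(fit, 1), 2.5, tolerance = 1e-4)
  expect_equal(eval_sigmoid(fit, 1000), 2.5, tolerance = 1e-4)

  expect_error(fit_sigmoid(structure(list(
    bins = data.frame(x = 1:3, e = 1:3, n = 1L)),
    class = "EnrichmentCurve")), "at least 4 bins")

  # fit round-trips through JSON
  p <- withr::local_tempfile(fileext = ".json")
  write_sigmoid_fit(fit, p)
  back <- read_sigmoid_fit(p)
  expect_equal(back$a3, fit$a3)
  expect_equal(back$x_floor, fit$x_floor)
})

test_that("curve TSV round-trips", {
  set.seed(2)
  ds <- make_dataset(40, 10, seed = 2)
  gs <- gold_standard(data.frame(
    gene = sample(dataset_genes(ds), 60, replace = TRUE),
    tissue = sample(dataset_tissues(ds), 60, replace = TRUE)))
  cv <- fold_enrichment_curve(ds, gs, window = 50, step = 50)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_curve(cv, p)
  back <- read_enrichment_curve(p)
  expect_equal(back$bins, cv$bins)
  expect_equal(back$expected, cv$expected)
  expect_equal(back$window, cv$window)
})

test_that("dataset scoring is pointwise sigmoid evaluation", {
  ds <- make_dataset(10, 4, seed = 5)
  fit <- sigmoid_fit(0.2, 3, 1.5, 1)
  ch <- score_dataset(ds, fit)
  a <- ch$associations
  expect_equal(a$confidence, eval_sigmoid(fit, a$raw))
  expect_equal(nrow(a), 40)
  # monotone: higher raw cannot give lower confidence
  ord <- order(a$raw)
  expect_false(is.unsorted(a$confidence[ord]))
  # raw at midpoint -> (a0+a1)/2
  m <- matrix(10, 1, 1, dimnames = list("g", "t"))
  mid <- score_dataset(expression_dataset(m), fit)
  expect_equal(mid$associations$confidence, (0.2 + 3) / 2)
})

test_that("star calibration reproduces anchor quantiles", {
  set.seed(31)
  ref <- scored_channel(data.frame(
    gene = sprintf("g%03d", 1:500),
    tissue = "t1",
    confidence = stats::runif(500, 0, 4)))
  anchors <- data.frame(quantile = c(0.1, 0.4, 0.8, 1.0),
                        stars = c(0, 1.5, 4, 5))
  cal <- calibrate_stars(ref, anchors)
  conf <- ref$associations$confidence
  expect_equal(cal$breakpoints$confidence,
               unname(stats::quantile(conf, anchors$quantile)))
  # the map hits its anchors exactly
  expect_equal(eval_calibration(cal, cal$breakpoints$confidence),
               anchors$stars)

  # two-anchor map on uniform confidences is linear in between
  cal2 <- calibrate_stars(ref, data.frame(quantile = c(0, 1),
                                          stars = c(0, 5)))
  lo <- min(conf); hi <- max(conf)
  mid <- (lo + hi) / 2
  expect_equal(eval_calibration(cal2, mid), 5 * (mid - lo) / (hi - lo))

  # degenerate all-equal reference: step map
  refc <- scored_channel(data.frame(gene = sprintf("g%d", 1:10),
                                    tissue = "t", confidence = 2))
  cal3 <- calibrate_stars(refc)
  expect_equal(eval_calibration(cal3, c(1.9, 2, 2.1)), c(0, 5, 5))

  # non-monotone anchors rejected
  expect_error(calibrate_stars(ref, data.frame(quantile = c(0.2, 0.8),
                                               stars = c(3, 1))),
               "non-decreasing")
})

test_that("apply_stars filters negatives and matches a direct filter", {
  ref <- scored_channel(data.frame(
    gene = sprintf("g%03d", 1:200), tissue = "t1",
    confidence = stats::runif(200, 0, 4)))
  cal <- calibrate_stars(ref)
  set.seed(41)
  ch <- scored_channel(data.frame(
    gene = sprintf("h%03d", 1:300), tissue = "t1",
    confidence = stats::runif(300, -1, 4)))
  out <- apply_stars(ch, cal)
  a <- out$associations
  expect_true(all(a$stars >= 0 & a$stars <= 5))
  # survivor count equals the direct filter on pre-clamp scores
  pre <- eval_calibration(cal, ch$associations$confidence)
  expect_equal(nrow(a), sum(pre >= 0))
  expect_equal(attr(out, "removed"), sum(pre < 0))
  # monotone in confidence; equal confidences get equal stars
  ord <- order(a$confidence)
  expect_false(is.unsorted(a$stars[ord]))
  two <- scored_channel(data.frame(gene = c("a", "b"), tissue = "t",
                                   confidence = c(2, 2)))
  st <- apply_stars(two, cal)$associations$stars
  expect_equal(st[1], st[2])
})

test_that("channel integration takes the per-pair max", {
  k <- scored_channel(data.frame(gene = "g1", tissue = "t1", stars = 4),
                      channel = "knowledge", dataset_id = "k")
  e <- scored_channel(data.frame(gene = c("g1", "g2"),
                                 tissue = c("t1", "t2"),
                                 stars = c(2, 3)),
                      channel = "experiments", dataset_id = "e")
  out <- integrate_channels(list(k, e))
  a <- out$associations
  expect_equal(a$stars[a$gene == "g1"], 4)       # max wins
  expect_equal(a$stars[a$gene == "g2"], 3)       # single-channel passthrough
  contrib <- attr(out, "contributors")
  expect_equal(contrib$channels[contrib$gene == "g1"], "k")

  other <- scored_channel(data.frame(gene = "x", tissue = "t"),
                          organism = "mouse")
  expect_error(integrate_channels(list(k, other)), "multiple organisms")

  # 3 random channels vs brute-force per-pair max
  chs <- lapply(1:3, function(i)
    make_channel(15, seed = i, id = paste0("c", i)))
  out <- integrate_channels(chs)
  all <- do.call(rbind, lapply(chs, function(ch) ch$associations))
  oracle <- tapply(all$stars, paste(all$gene, all$tissue), max)
  got <- stats::setNames(out$associations$stars,
                         paste(out$associations$gene,
                               out$associations$tissue))
  expect_equal(unname(got[names(oracle)]), as.numeric(oracle))
  expect_true(nrow(out$associations) <= nrow(all))
  expect_true(nrow(out$associations) >=
                max(vapply(chs, function(ch)
                  nrow(ch$associations), numeric(1))))
})
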