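# The core scoring scheme: fold-enrichment curves against a gold standard,
# sigmoid fitting on the log10 expression axis, confidence scores, star
# calibration, negative-score filtering, and channel integration.

#' Expected gold-standard fraction under random sampling
#'
#' The fraction of all (gene, tissue) combinations from the given universes
#' that are gold-standard pairs -- the hit rate expected when sampling
#' genes and tissues at random, i.e. the denominator of fold enrichment.
#'
#' @param gs a `GoldStandard`.
#' @param genes,tissues the benchmark universes (normally the dataset /
#'   gold-standard intersections); both non-empty.
#' @return a single fraction in (0, 1].
#' @export
expected_fraction <- function(gs, genes, tissues) {
  if (length(genes) == 0L || length(tissues) == 0L)
    stop("empty gene or tissue universe", call. = FALSE)
  p <- gs$pairs
  n_hit <- sum(p$gene %in% genes & p$tissue %in% tissues)
  if (n_hit == 0L)
    stop("no gold-standard pairs in the benchmark universe; ",
         "dataset cannot be benchmarked", call. = FALSE)
  n_hit / (length(genes) * length(tissues))
}

#' Fold-enrichment curve of a dataset against a gold standard
#'
#' Restricts the dataset to genes shared with the gold standard and to the
#' benchmark tissues, sorts all remaining gene-tissue pairs by descending
#' raw expression (ties broken by gene then tissue id for determinism), and
#' slides a window of `window` pairs with stride `step` along the sorted
#' list.  Each full window becomes one bin with `x` the mean raw value,
#' `e` the fraction of the window's pairs found in the gold standard
#' divided by [expected_fraction()], and `n = window`.
#'
#' @param ds an `ExpressionDataset`.
#' @param gs a `GoldStandard` for the same organism.
#' @param window bin size in pairs (default 100).
#' @param step stride between bin starts; defaults to `window`
#'   (non-overlapping bins); set to 1 for the fully sliding variant.
#' @param tissues benchmark tissue set; default is the tissues common to
#'   the dataset and the gold standard.
#' @return an `EnrichmentCurve`: list with `bins` (data.frame `x`, `e`,
#'   `n`), `window`, `step`, `expected` (the expected fraction) and
#'   `n_pairs`.
#' @export
fold_enrichment_curve <- function(ds, gs, window = 100L, step = window,
                                  tissues = NULL) {
  genes <- intersect(dataset_genes(ds), unique(gs$pairs$gene))
  if (is.null(tissues))
    tissues <- intersect(dataset_tissues(ds), unique(gs$pairs$tissue))
  tissues <- intersect(dataset_tissues(ds), tissues)
  expected <- expected_fraction(gs, genes, tissues)
  m <- ds$values[genes, tissues, drop = FALSE]
  pairs <- data.frame(
    gene = rep(genes, times = length(tissues)),
    tissue = rep(tissues, each = length(genes)),
    raw = as.vector(m), stringsAsFactors = FALSE)
  n <- nrow(pairs)
  if (n < window)
    stop(sprintf(paste0("only %d gene-tissue pairs after restriction; ",
                        "window is %d -- use a smaller window"), n, window),
         call. = FALSE)
  ord <- order(-pairs$raw, pairs$gene, pairs$tissue)
  pairs <- pairs[ord, , drop = FALSE]
  in_gs <- pair_key(pairs$gene, pairs$tissue) %in%
    pair_key(gs$pairs$gene, gs$pairs$tissue)
  starts <- seq.int(1L, n - window + 1L, by = step)
  x <- vapply(starts, function(s) mean(pairs$raw[s:(s + window - 1L)]),
              numeric(1))
  hits <- vapply(starts, function(s) sum(in_gs[s:(s + window - 1L)]),
                 numeric(1))
  e <- (hits / window) / expected
  structure(list(bins = data.frame(x = x, e = e, n = window),
                 window = as.integer(window), step = as.integer(step),
                 expected = expected, n_pairs = n),
            class = "EnrichmentCurve")
}

#' @export
print.EnrichmentCurve <- function(x, ...) {
  cat(sprintf(
    "EnrichmentCurve: %d bins (window %d, step %d) over %d pairs; expected fraction %.4g\n",
    nrow(x$bins), x$window, x$step, x$n_pairs, x$expected))
  invisible(x)
}

#' Construct a sigmoid fit object
#'
#' The confidence-score sigmoid on the log10 expression axis:
#' `score(x) = a0 + (a1 - a0) / (1 + exp(-a2 * (log10(x) - a3)))`,
#' where `a0` is the lower asymptote, `a1` the upper asymptote (both in
#' fold-enrichment units), `a2` the slope and `a3` the midpoint on the
#' log10 axis.
#'
#' @param a0,a1,a2,a3 sigmoid parameters; `a1 >= a0 >= 0`, `a2 >= 0`.
#' @param rss residual sum of squares of the fit (NA if constructed
#'   directly).
#' @param x_floor pseudo-floor substituted for non-positive `x` before
#'   taking log10 (see [eval_sigmoid()]).
#' @return a `SigmoidFit`.
#' @export
sigmoid_fit <- function(a0, a1, a2, a3, rss = NA_real_,
                        x_floor = .Machine$double.xmin) {
  if (a1 < a0) stop("a1 must be >= a0", call. = FALSE)
  if (a0 < 0) stop("a0 must be >= 0", call. = FALSE)
  if (a2 < 0) stop("a2 must be >= 0", call. = FALSE)
  structure(list(a0 = a0, a1 = a1, a2 = a2, a3 = a3, rss = rss,
                 x_floor = x_floor),
            class = "SigmoidFit")
}

#' @export
print.SigmoidFit <- function(x, ...) {
  cat(sprintf(
    "SigmoidFit: a0=%.4g a1=%.4g a2=%.4g a3=%.4g (rss=%.4g)\n",
    x$a0, x$a1, x$a2, x$a3, x$rss))
  invisible(x)
}

#' Evaluate the confidence-score sigmoid
#'
#' @param fit a `SigmoidFit`.
#' @param x raw expression value(s); non-positive values are replaced by
#'   the fit's `x_floor` before taking log10.
#' @return confidence score(s), bounded in `[a0, a1]`.
#' @export
eval_sigmoid <- function(fit, x) {
  x <- pmax(x, fit$x_floor)
  fit$a0 + (fit$a1 - fit$a0) /
    (1 + exp(-fit$a2 * (log10(x) - fit$a3)))
}

# sigmoid on the already-logged axis, used internally by the fitter
sigmoid_log <- function(theta, L) {
  # theta = (a0, d, a2, a3) with a1 = a0 + d
  theta[1] + theta[2] / (1 + exp(-theta[3] * (L - theta[4])))
}

#' Fit the confidence-score sigmoid to an enrichment curve
#'
#' Unweighted least squares of the four-parameter sigmoid to the curve's
#' `(log10 x, e)` bin points, with constraints `a1 >= a0 >= 0`, `a2 >= 0`.
#' Multi-start: the midpoint `a3` is initialised at the deciles of the
#' observed log10-x range and the slope at `a2` in `{0.5, 1, 2}`; the best
#' converged candidate by residual sum of squares wins.
#'
#' @param curve an `EnrichmentCurve` with at least 4 bins.
#' @param x_floor pseudo-floor for non-positive bin means before log10;
#'   default is half the smallest positive bin mean.
#' @return a `SigmoidFit` with `rss` filled in.
#' @export
fit_sigmoid <- function(curve, x_floor = NULL) {
  bins <- curve$bins
  if (nrow(bins) < 4L)
    stop("need at least 4 bins to fit 4 parameters", call. = FALSE)
  pos <- bins$x[bins$x > 0]
  if (is.null(x_floor))
    x_floor <- if (length(pos)) min(pos) * 0.5 else .Machine$double.xmin
  L <- log10(pmax(bins$x, x_floor))
  e <- bins$e
  obj <- function(theta) sum((sigmoid_log(theta, L) - e)^2)
  lo <- c(0, 0, 0, -Inf)
  hi <- c(Inf, Inf, Inf, Inf)
  e_lo <- max(min(e), 0)
  e_hi <- max(e)
  a3_grid <- stats::quantile(L, probs = seq(0.1, 0.9, by = 0.1),
                             names = FALSE)
  starts <- list(c(mean(e), 0, 1, stats::median(L)))  # flat candidate
  for (a3 in unique(a3_grid))
    for (a2 in c(0.5, 1, 2))
      starts[[length(starts) + 1L]] <- c(e_lo, max(e_hi - e_lo, 1e-6),
                                         a2, a3)
  best <- NULL
  any_converged <- FALSE
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0L) any_converged <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("sigmoid fit failed from every start", call. = FALSE)
  fit <- sigmoid_fit(a0 = best$par[1], a1 = best$par[1] + best$par[2],
                     a2 = best$par[3], a3 = best$par[4],
                     rss = best$value, x_floor = x_floor)
  if (!any_converged) {
    cond <- simpleError(
      sprintf("sigmoid fit did not converge (best rss %.4g)", best$value))
    cond$best_fit <- fit
    stop(cond)
  }
  fit
}

#' Score every gene-tissue pair of a dataset with a fitted sigmoid
#'
#' Every (gene, tissue, raw value) cell of the dataset receives
#' `confidence = eval_sigmoid(fit, raw)`.  No filtering happens here; star
#' calibration and negative-score filtering are applied by
#' [apply_stars()].
#'
#' @param ds an `ExpressionDataset`.
#' @param fit a `SigmoidFit`, normally fitted on this dataset's own
#'   enrichment curve.
#' @param channel channel label for the result (default `"experiments"`).
#' @return a `ScoredChannel` with `raw` and `confidence` filled, `stars`
#'   `NA`.
#' @export
score_dataset <- function(ds, fit, channel = "experiments") {
  m <- ds$values
  a <- data.frame(
    gene = rep(rownames(m), times = ncol(m)),
    tissue = rep(colnames(m), each = nrow(m)),
    raw = as.vector(m), stringsAsFactors = FALSE)
  a$confidence <- eval_sigmoid(fit, a$raw)
  scored_channel(a, channel = channel, organism = ds$organism,
                 dataset_id = ds$dataset_id)
}

#' Build the confidence-to-stars calibration function
#'
#' Derives a single monotone piecewise-linear map from confidence scores to
#' the common 0-5 star scale, anchored at stated quantiles of a reference
#' channel's confidence distribution (by convention the human text-mining
#' channel, which is large and available for every related resource).
#'
#' @param reference a non-empty `ScoredChannel` carrying confidences.
#' @param anchors data.frame with columns `quantile` (in `[0, 1]`,
#'   increasing) and `stars` (non-decreasing).  The default places the
#'   reference median at 2 stars and the top of the distribution at the
#'   5-star ceiling.
#' @param star_max scale ceiling, default 5.
#' @return a `CalibrationFunction`: list with `breakpoints` (data.frame
#'   `confidence`, `stars`) and `star_max`.  Confidences below the lowest
#'   anchor extrapolate linearly (and may map below zero -- such
#'   associations are removed by [apply_stars()]); above the highest
#'   anchor the map is clamped at its top star value.
#' @export
calibrate_stars <- function(reference,
                            anchors = data.frame(
                              quantile = c(0.05, 0.5, 0.9, 1.0),
                              stars = c(0, 2, 4, 5)),
                            star_max = 5) {
  conf <- reference$associations$confidence
  conf <- conf[!is.na(conf)]
  if (length(conf) == 0L)
    stop("reference channel has no confidences", call. = FALSE)
  stopifnot(is.data.frame(anchors),
            all(c("quantile", "stars") %in% names(anchors)))
  if (is.unsorted(anchors$quantile, strictly = TRUE))
    stop("anchor quantiles must be strictly increasing", call. = FALSE)
  if (is.unsorted(anchors$stars))
    stop("anchor stars must be non-decreasing", call. = FALSE)
  if (any(anchors$stars < 0 | anchors$stars > star_max))
    stop("anchor stars must lie in [0, star_max]", call. = FALSE)
  bp <- data.frame(
    confidence = unname(stats::quantile(conf, probs = anchors$quantile)),
    stars = anchors$stars)
  structure(list(breakpoints = bp, star_max = star_max),
            class = "CalibrationFunction")
}

#' @export
print.CalibrationFunction <- function(x, ...) {
  cat(sprintf("CalibrationFunction: %d anchors, star_max %g\n",
              nrow(x$breakpoints), x$star_max))
  print(x$breakpoints)
  invisible(x)
}

#' Evaluate a calibration function (pre-clamp)
#'
#' Piecewise-linear interpolation between anchors; linear extrapolation
#' below the lowest anchor (values can go negative); constant at the top
#' star above the highest anchor.  If all anchor confidences coincide the
#' map degenerates to a step at that value.
#'
#' @param cal a `CalibrationFunction`.
#' @param confidence numeric vector of confidence scores.
#' @return numeric vector of un-clamped star values.
#' @export
eval_calibration <- function(cal, confidence) {
  bp <- cal$breakpoints
  cu <- sort(unique(bp$confidence))
  if (length(cu) == 1L)
    return(ifelse(confidence < cu, bp$stars[1],
                  bp$stars[nrow(bp)]))
  # collapse duplicate anchor confidences to their max star
  su <- vapply(cu, function(v) max(bp$stars[bp$confidence == v]),
               numeric(1))
  out <- stats::approx(cu, su, xout = confidence, rule = 2, ties = max)$y
  below <- confidence < cu[1]
  if (any(below)) {
    slope <- (su[2] - su[1]) / (cu[2] - cu[1])
    out[below] <- su[1] + slope * (confidence[below] - cu[1])
  }
  out
}

#' Calibrate stars and filter negative-score associations
#'
#' Applies the calibration function to each association's confidence.
#' Associations whose pre-clamp calibrated score is negative are removed
#' entirely (they are not retained at zero stars); surviving scores are
#' clamped to `[0, star_max]`.
#'
#' @param assocs a `ScoredChannel` carrying confidences.
#' @param cal a `CalibrationFunction`.
#' @return a `ScoredChannel` with `stars` filled and negative-score
#'   associations removed; `attr(, "removed")` is the removal count.
#' @export
apply_stars <- function(assocs, cal) {
  a <- assocs$associations
  raw_star <- eval_calibration(cal, a$confidence)
  keep <- !is.na(raw_star) & raw_star >= 0
  a <- a[keep, , drop = FALSE]
  a$stars <- pmin(pmax(raw_star[keep], 0), cal$star_max)
  out <- scored_channel(a, channel = assocs$channel,
                        organism = assocs$organism,
                        dataset_id = assocs$dataset_id)
  attr(out, "removed") <- sum(!keep)
  out
}

#' Integrate several evidence channels into one
#'
#' Per (gene, tissue) pair the integrated star score is the maximum over
#' the contributing channels, consistent with the max semantics of
#' ontology propagation: the integrated score reflects the single
#' strongest piece of evidence.
#'
#' @param channels list of `ScoredChannel` objects for one organism.
#' @return a `ScoredChannel` with `channel = "integrated"`;
#'   `attr(, "contributors")` maps each pair to the semicolon-joined list
#'   of channels that attained the maximum.
#' @export
integrate_channels <- function(channels) {
  if (length(channels) < 1L) stop("need at least one channel", call. = FALSE)
  orgs <- unique(vapply(channels, function(ch) ch$organism, character(1)))
  if (length(orgs) > 1L)
    stop("channels span multiple organisms: ",
         paste(orgs, collapse = ", "), call. = FALSE)
  tabs <- lapply(channels, function(ch) {
    a <- ch$associations
    a$src <- ch$dataset_id
    a
  })
  all <- do.call(rbind, tabs)
  key <- pair_key(all$gene, all$tissue)
  per <- split(seq_len(nrow(all)), key)
  rows <- lapply(per, function(idx) {
    s <- all$stars[idx]
    best <- if (all(is.na(s))) idx[1] else idx[which.max(s)]
    contributing <- all$src[idx][!is.na(s) & s == max(s, na.rm = TRUE)]
    if (!length(contributing)) contributing <- all$src[idx]
    data.frame(gene = all$gene[best], tissue = all$tissue[best],
               raw = NA_real_,
               confidence = suppressWarnings(
                 if (all(is.na(all$confidence[idx]))) NA_real_
                 else max(all$confidence[idx], na.rm = TRUE)),
               stars = all$stars[best],
               contributors = paste(sort(unique(contributing)),
                                    collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  out <- scored_channel(res[, c("gene", "tissue", "raw", "confidence",
                                "stars")],
                        channel = "integrated", organism = orgs,
                        dataset_id = "integrated")
  ord <- order(res$gene, res$tissue)
  attr(out, "contributors") <- data.frame(
    gene = res$gene[ord], tissue = res$tissue[ord],
    channels = res$contributors[ord], stringsAsFactors = FALSE)
  out
}

#' Write / read an enrichment curve as TSV
#'
#' Columns `x`, `e`, `n`; window, step, expected fraction and pair count
#' are carried in `#`-prefixed header comments so the file round-trips.
#'
#' @param curve an `EnrichmentCurve`.
#' @param path output / input file path.
#' @return `write_enrichment_curve` returns `path` invisibly;
#'   `read_enrichment_curve` returns an `EnrichmentCurve`.
#' @export
write_enrichment_curve <- function(curve, path) {
  meta <- sprintf("# %s\t%.15g",
                  c("window", "step", "expected", "n_pairs"),
                  c(curve$window, curve$step, curve$expected,
                    curve$n_pairs))
  body <- paste(formatC(curve$bins$x, digits = 15, format = "g"),
                formatC(curve$bins$e, digits = 15, format = "g"),
                curve$bins$n, sep = "\t")
  writeLines(c(meta, "x\te\tn", body), path)
  invisible(path)
}

#' @rdname write_enrichment_curve
#' @export
read_enrichment_curve <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- strsplit(sub("^# ", "", meta_lines), "\t", fixed = TRUE)
  vals <- stats::setNames(
    as.numeric(vapply(meta, `[`, character(1), 2L)),
    vapply(meta, `[`, character(1), 1L))
  body <- lines[!grepl("^#", lines)][-1]
  rows <- strsplit(body, "\t", fixed = TRUE)
  bins <- data.frame(
    x = as.numeric(vapply(rows, `[`, character(1), 1L)),
    e = as.numeric(vapply(rows, `[`, character(1), 2L)),
    n = as.integer(vapply(rows, `[`, character(1), 3L)))
  structure(list(bins = bins, window = as.integer(vals[["window"]]),
                 step = as.integer(vals[["step"]]),
                 expected = vals[["expected"]],
                 n_pairs = as.integer(vals[["n_pairs"]])),
            class = "EnrichmentCurve")
}

#' Serialize / read a sigmoid fit as flat JSON
#'
#' @param fit a `SigmoidFit`.
#' @param path output / input file path.
#' @return `write_sigmoid_fit` returns `path` invisibly;
#'   `read_sigmoid_fit` returns a `SigmoidFit`.
#' @export
write_sigmoid_fit <- function(fit, path) {
  jsonlite::write_json(
    list(a0 = fit$a0, a1 = fit$a1, a2 = fit$a2, a3 = fit$a3,
         rss = fit$rss, x_floor = fit$x_floor),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sigmoid_fit
#' @export
read_sigmoid_fit <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sigmoid_fit(j$a0, j$a1, j$a2, j$a3,
              rss = if (is.null(j$rss)) NA_real_ else j$rss,
              x_floor = j$x_floor)
}
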