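# End-to-end demo pipeline: simulate a world, ingest, benchmark, fit,
# score, calibrate, integrate, compare.  Every intermediate is written in
# the documented text dialects so each stage can be re-run from disk.

#' Build a pipeline run configuration
#'
#' @param outdir output directory (created if missing).
#' @param world a `WorldParams` describing the synthetic world.
#' @param datasets list of per-dataset quality specs: each a list with
#'   `organism`, and optionally `mu_on`, `mu_off`, `sigma`, `id`.  The
#'   default gives every organism one clean dataset (separation 3).
#' @param window,step fold-enrichment window and stride.
#' @param anchors calibration anchors, see [calibrate_stars()].
#' @param alpha,w_sentence,w_abstract text-mining parameters.
#' @param n_docs toy-corpus size.
#' @param benchmark_tissues tissue term ids used for the ROC benchmark;
#'   default: the first 4 major tissues (mirroring the convention of
#'   benchmarking on a small set of tissues covered by every dataset).
#' @param seed master seed; per-dataset seeds are derived from it.
#' @return a `RunConfig` list.
#' @export
run_config <- function(outdir,
                       world = world_params(),
                       datasets = NULL,
                       window = 100L, step = window,
                       anchors = data.frame(
                         quantile = c(0.05, 0.5, 0.9, 1.0),
                         stars = c(0, 2, 4, 5)),
                       alpha = 0.6, w_sentence = 1.0, w_abstract = 0.2,
                       n_docs = 200L,
                       benchmark_tissues = NULL,
                       seed = world$seed) {
  if (is.null(datasets))
    datasets <- lapply(world$organisms, function(o) list(organism = o))
  datasets <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    if (is.null(d$mu_on)) d$mu_on <- world$mu_on
    if (is.null(d$mu_off)) d$mu_off <- world$mu_off
    if (is.null(d$sigma)) d$sigma <- world$sigma
    if (is.null(d$id)) d$id <- sprintf("%s_ds%d", d$organism, i)
    d
  })
  structure(list(outdir = outdir, world = world, datasets = datasets,
                 window = as.integer(window), step = as.integer(step),
                 anchors = anchors, alpha = alpha,
                 w_sentence = w_sentence, w_abstract = w_abstract,
                 n_docs = as.integer(n_docs),
                 benchmark_tissues = benchmark_tissues,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full demo pipeline
#'
#' Stages: simulate world -> write fixtures -> build gold standards
#' (reference organism sampled from truth, others orthology-transferred)
#' -> text-mining channel on a toy corpus -> star calibration on the
#' text-mining channel -> per dataset: enrichment curve, sigmoid fit,
#' confidence scoring, star calibration and filtering, propagation to
#' parent terms, restriction to major tissues -> channel integration per
#' organism -> cross-dataset correlation matrix and per-dataset ROC.
#' All intermediates land under `config$outdir`.
#'
#' @param config a `RunConfig`.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory objects of every stage and
#'   a `report` list (also written to `report.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  say("[simulate] world seed %d", config$seed)
  wp <- config$world
  wp$seed <- config$seed
  world <- simulate_world(wp)
  onto <- world$ontology
  write_ontology_obo(onto, file.path(out, "ontology.obo"))
  writeLines(onto$major_tissues, file.path(out, "major_tissues.txt"))
  write_orthogroups(world$groups, file.path(out, "orthogroups.tsv"),
                    organism_taxids = stats::setNames(
                      as.character(seq_along(wp$organisms) + 9000L),
                      wp$organisms))

  ref <- wp$organisms[1]
  say("[gold-standard] sampling %s truth at coverage %.2f", ref,
      wp$coverage)
  gs <- list()
  gs[[ref]] <- simulate_gold_standard(world, ref, seed = config$seed)
  maps <- list()
  for (o in wp$organisms[-1]) {
    maps[[paste(ref, o, sep = "|")]] <-
      one_to_one_pairs(world$groups, ref, o)
    gs[[o]] <- transfer_gold_standard(gs[[ref]],
                                      maps[[paste(ref, o, sep = "|")]])
    say("[gold-standard] %s: %d pairs transferred (%d dropped)", o,
        nrow(gs[[o]]$pairs), attr(gs[[o]], "dropped"))
  }
  for (o in names(gs))
    write_annotation_pairs(gs[[o]],
                           file.path(out, sprintf("gold_%s.tsv", o)))

  say("[textmining] %d toy abstracts (%s)", config$n_docs, ref)
  tm <- simulate_corpus(world, ref, n_docs = config$n_docs,
                        seed = config$seed)
  write_corpus(tm$corpus, file.path(out, "corpus.tsv"))
  counts <- count_comentions(tm$corpus, tm$gene_names, tm$tissue_names,
                             organisms = tm$organisms,
                             w_sentence = config$w_sentence,
                             w_abstract = config$w_abstract)
  tm_channel <- cooccurrence_score(counts, alpha = config$alpha,
                                   organism = ref)
  say("[calibrate] %d text-mining associations anchor the star scale",
      nrow(tm_channel$associations))
  cal <- calibrate_stars(tm_channel, anchors = config$anchors)
  tm_starred <- apply_stars(tm_channel, cal)
  write_channel(tm_starred, file.path(out, "channel_textmining.tsv"),
                onto = onto)

  bench_tissues <- config$benchmark_tissues
  if (is.null(bench_tissues))
    bench_tissues <- utils::head(onto$major_tissues, 4L)

  channels <- list()
  report <- list(seed = config$seed, datasets = list())
  for (i in seq_along(config$datasets)) {
    d <- config$datasets[[i]]
    ds_seed <- config$seed + i * 1009L
    ds <- simulate_dataset(world, d$organism, mu_on = d$mu_on,
                           mu_off = d$mu_off, sigma = d$sigma,
                           seed = ds_seed, dataset_id = d$id)
    write_expression_matrix(ds, file.path(out,
                                          sprintf("matrix_%s.tsv", d$id)))
    curve <- fold_enrichment_curve(ds, gs[[d$organism]],
                                   window = config$window,
                                   step = config$step)
    write_enrichment_curve(curve,
                           file.path(out, sprintf("curve_%s.tsv", d$id)))
    fit <- fit_sigmoid(curve)
    write_sigmoid_fit(fit, file.path(out, sprintf("fit_%s.json", d$id)))
    say("[fit] %s: a0=%.3g a1=%.3g a2=%.3g a3=%.3g (rss=%.3g)",
        d$id, fit$a0, fit$a1, fit$a2, fit$a3, fit$rss)
    scored <- score_dataset(ds, fit)
    scored$dataset_id <- d$id
    starred <- apply_stars(scored, cal)
    propagated <- restrict_to_major(propagate_scores(starred, onto), onto)
    propagated$dataset_id <- d$id
    write_channel(propagated,
                  file.path(out, sprintf("channel_%s.tsv", d$id)),
                  onto = onto)
    roc <- roc_against_gold(propagated, gs[[d$organism]], bench_tissues)
    write_roc(roc, file.path(out, sprintf("roc_%s.tsv", d$id)))
    say("[roc] %s: AUC = %.3f", d$id, roc$auc)
    channels[[d$id]] <- propagated
    report$datasets[[d$id]] <- list(
      organism = d$organism,
      separation = (d$mu_on - d$mu_off) / d$sigma,
      n_associations = nrow(propagated$associations),
      fit = list(a0 = fit$a0, a1 = fit$a1, a2 = fit$a2, a3 = fit$a3,
                 rss = fit$rss),
      auc = roc$auc)
  }

  # integrated channel per organism: its datasets plus (for the reference
  # organism) the text-mining channel, all restricted to major tissues
  for (o in wp$organisms) {
    contrib <- channels[vapply(channels, function(ch)
      identical(ch$organism, o), logical(1))]
    if (identical(o, ref))
      contrib <- c(contrib,
                   list(restrict_to_major(
                     propagate_scores(tm_starred, onto), onto)))
    if (length(contrib)) {
      integrated <- integrate_channels(unname(contrib))
      write_channel(integrated,
                    file.path(out, sprintf("channel_integrated_%s.tsv", o)),
                    onto = onto)
    }
  }

  if (length(channels) >= 2L) {
    cm <- correlation_matrix(channels, maps = maps)
    write_correlation_matrix(cm, file.path(out, "correlations.tsv"))
    report$correlations <- cm
  }
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] outputs in %s", out)
  invisible(list(world = world, gold_standards = gs, maps = maps,
                 calibration = cal, textmining = tm_starred,
                 channels = channels, report = report))
}
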