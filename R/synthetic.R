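# Synthetic worlds: ontology, planted gene-tissue truth shared across
# orthologs, expression datasets of controlled quality, incomplete gold
# standards, ortholog groups, and toy literature corpora.  Everything is
# seed-deterministic so the full pipeline is testable offline.

#' Parameters of a synthetic world
#'
#' The generative model: every (gene, tissue) pair is truly expressed with
#' probability `p`; a fraction `q` of each organism's genes has a 1:1
#' ortholog in every other organism, and orthologous genes share their
#' expression truth (optionally degraded by `divergence`); a gold standard
#' samples true pairs at rate `coverage`; an expression dataset draws
#' log-normal raw values with meanlog `mu_on` for expressed pairs and
#' `mu_off` otherwise, common sdlog `sigma`, so `(mu_on - mu_off) / sigma`
#' is the signal separation.
#'
#' @param organisms organism labels; the first is the reference whose
#'   truth seeds the ortholog-shared truth.
#' @param n_genes genes per organism.
#' @param n_tissues leaf tissue terms (these double as the major-tissue
#'   set).
#' @param depth,branching shape of the random ontology DAG above the
#'   leaves.
#' @param p expression prevalence, in (0, 1].
#' @param q 1:1 ortholog coverage, in \[0, 1\].
#' @param coverage gold-standard coverage of true pairs, in (0, 1].
#' @param contamination probability that a non-true pair enters the gold
#'   standard (default 0: gold standard is reliable).
#' @param divergence probability that a transferred truth value flips.
#' @param frac_non121 fraction of extra ortholog groups made non-1:1 (an
#'   in-paralog added) to exercise the filters.
#' @param mu_on,mu_off,sigma default dataset quality (separation 3).
#' @param seed integer seed.
#' @return a validated `WorldParams` list.
#' @export
world_params <- function(organisms = c("human", "mouse"),
                         n_genes = 200L, n_tissues = 10L,
                         depth = 3L, branching = 2L,
                         p = 0.3, q = 0.6, coverage = 0.5,
                         contamination = 0, divergence = 0,
                         frac_non121 = 0.1,
                         mu_on = 3, mu_off = 0, sigma = 1,
                         seed = 1L) {
  stopifnot(length(organisms) >= 1L, !anyDuplicated(organisms),
            n_genes >= 1L, n_tissues >= 1L, depth >= 1L, branching >= 1L)
  if (!(p > 0 && p <= 1)) stop("p must be in (0, 1]", call. = FALSE)
  if (!(q >= 0 && q <= 1)) stop("q must be in [0, 1]", call. = FALSE)
  if (!(coverage > 0 && coverage <= 1))
    stop("coverage must be in (0, 1]", call. = FALSE)
  if (contamination < 0 || contamination > 1)
    stop("contamination must be in [0, 1]", call. = FALSE)
  if (mu_on <= mu_off) stop("mu_on must exceed mu_off", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  structure(list(organisms = organisms, n_genes = as.integer(n_genes),
                 n_tissues = as.integer(n_tissues),
                 depth = as.integer(depth),
                 branching = as.integer(branching),
                 p = p, q = q, coverage = coverage,
                 contamination = contamination, divergence = divergence,
                 frac_non121 = frac_non121,
                 mu_on = mu_on, mu_off = mu_off, sigma = sigma,
                 seed = as.integer(seed)),
            class = "WorldParams")
}

# random layered DAG: root, `depth` internal layers, then the leaf tissues
simulate_ontology <- function(n_tissues, depth, branching) {
  terms <- c("TS:0000000" = "tissue root")
  layers <- list("TS:0000000")
  parents <- list()
  counter <- 0L
  for (l in seq_len(depth)) {
    n_l <- min(branching^l, max(2L, n_tissues))
    layer <- character(n_l)
    for (i in seq_len(n_l)) {
      counter <- counter + 1L
      id <- sprintf("TS:%07d", counter)
      layer[i] <- id
      terms[[id]] <- sprintf("internal layer %d node %d", l, i)
      par <- sample(layers[[l]], 1L)
      # second parent with some probability: makes it a DAG, not a tree
      if (length(layers[[l]]) > 1L && stats::runif(1) < 0.2)
        par <- unique(c(par, sample(setdiff(layers[[l]], par), 1L)))
      parents[[id]] <- par
    }
    layers[[l + 1L]] <- layer
  }
  leaves <- character(n_tissues)
  leaf_layer <- layers[[depth + 1L]]
  for (i in seq_len(n_tissues)) {
    counter <- counter + 1L
    id <- sprintf("TS:%07d", counter)
    leaves[i] <- id
    terms[[id]] <- sprintf("tissue %d", i)
    parents[[id]] <- sample(leaf_layer, 1L)
  }
  tissue_ontology(terms, parents, major_tissues = leaves)
}

#' Simulate a complete synthetic world
#'
#' Generates the random ontology, the per-organism expression truth (with
#' truth copied across 1:1 orthologs), and the ortholog groups file
#' content, all from one seed.
#'
#' @param params a `WorldParams`.
#' @return a `SyntheticWorld`: list with `params`, `ontology`, per-organism
#'   `genes` and `truth` (logical gene x tissue matrix over the leaf
#'   tissues), `tissues` (the leaf term ids), `tissue_labels` (free-text
#'   label -> term id, for exercising tissue mapping) and `groups` (an
#'   `OrthologGroups`).
#' @export
simulate_world <- function(params) {
  stopifnot(inherits(params, "WorldParams"))
  set.seed(params$seed)
  onto <- simulate_ontology(params$n_tissues, params$depth,
                            params$branching)
  tissues <- onto$major_tissues
  orgs <- params$organisms
  genes <- lapply(orgs, function(o)
    sprintf("%s_g%04d", o, seq_len(params$n_genes)))
  names(genes) <- orgs
  ref <- orgs[1]
  truth <- list()
  truth[[ref]] <- matrix(
    stats::runif(params$n_genes * params$n_tissues) < params$p,
    nrow = params$n_genes,
    dimnames = list(genes[[ref]], tissues))
  n_linked <- round(params$q * params$n_genes)
  linked_idx <- if (n_linked > 0)
    sort(sample.int(params$n_genes, n_linked)) else integer(0)
  for (o in orgs[-1]) {
    m <- matrix(stats::runif(params$n_genes * params$n_tissues) < params$p,
                nrow = params$n_genes,
                dimnames = list(genes[[o]], tissues))
    if (length(linked_idx)) {
      shared <- truth[[ref]][linked_idx, , drop = FALSE]
      if (params$divergence > 0) {
        flip <- matrix(stats::runif(length(shared)) < params$divergence,
                       nrow = nrow(shared))
        shared <- xor(shared, flip)
      }
      m[linked_idx, ] <- shared
    }
    truth[[o]] <- m
  }
  # 1:1 groups for linked genes, singletons elsewhere, plus a fraction of
  # non-1:1 groups built from unlinked genes
  recs <- list()
  gcount <- 0L
  for (i in linked_idx) {
    gcount <- gcount + 1L
    recs[[length(recs) + 1L]] <- data.frame(
      group = sprintf("OG%05d", gcount),
      organism = orgs,
      gene = vapply(orgs, function(o) genes[[o]][i], character(1)),
      stringsAsFactors = FALSE)
  }
  unlinked <- setdiff(seq_len(params$n_genes), linked_idx)
  n_bad <- round(params$frac_non121 * max(length(linked_idx), 1L))
  if (length(orgs) >= 2L && length(unlinked) >= 3L && n_bad > 0) {
    for (k in seq_len(n_bad)) {
      idx <- sample(unlinked, 3L)
      gcount <- gcount + 1L
      recs[[length(recs) + 1L]] <- data.frame(
        group = sprintf("OG%05d", gcount),
        organism = c(orgs[1], orgs[1], orgs[2]),
        gene = c(genes[[orgs[1]]][idx[1]], genes[[orgs[1]]][idx[2]],
                 genes[[orgs[2]]][idx[3]]),
        stringsAsFactors = FALSE)
    }
  }
  groups <- ortholog_groups(
    if (length(recs)) do.call(rbind, recs)
    else data.frame(group = character(), organism = character(),
                    gene = character(), stringsAsFactors = FALSE))
  labels <- stats::setNames(tissues,
                            paste0("tissue label ",
                                   seq_along(tissues)))
  structure(list(params = params, ontology = onto, genes = genes,
                 truth = truth, tissues = tissues,
                 tissue_labels = labels, groups = groups),
            class = "SyntheticWorld")
}

#' @export
print.SyntheticWorld <- function(x, ...) {
  cat(sprintf(
    "SyntheticWorld: %s; %d genes x %d tissues per organism (seed %d)\n",
    paste(x$params$organisms, collapse = ", "),
    x$params$n_genes, x$params$n_tissues, x$params$seed))
  invisible(x)
}

#' Simulate an expression dataset from planted truth
#'
#' Raw values are log-normal: `meanlog = mu_on` where the (gene, tissue)
#' pair is truly expressed, `mu_off` otherwise, common `sdlog = sigma`.
#' `(mu_on - mu_off) / sigma` is the separation; 3 is a clean dataset, 0.5
#' a noisy one.
#'
#' @param world a `SyntheticWorld`.
#' @param organism organism label present in the world.
#' @param mu_on,mu_off,sigma dataset quality; defaults from the world's
#'   params.
#' @param seed integer seed for this dataset's noise.
#' @param dataset_id label; default derived from organism and seed.
#' @param unit expression unit tag.
#' @return an `ExpressionDataset`.
#' @export
simulate_dataset <- function(world, organism,
                             mu_on = world$params$mu_on,
                             mu_off = world$params$mu_off,
                             sigma = world$params$sigma,
                             seed = world$params$seed,
                             dataset_id = sprintf("%s_ds%d", organism, seed),
                             unit = "arbitrary") {
  truth <- world$truth[[organism]]
  if (is.null(truth)) stop("unknown organism: ", organism, call. = FALSE)
  set.seed(seed)
  meanlog <- ifelse(truth, mu_on, mu_off)
  vals <- matrix(stats::rlnorm(length(truth), meanlog = as.vector(meanlog),
                               sdlog = sigma),
                 nrow = nrow(truth), dimnames = dimnames(truth))
  expression_dataset(vals, dataset_id = dataset_id, organism = organism,
                     unit = unit)
}

#' Simulate an incomplete gold standard from planted truth
#'
#' Each true (gene, tissue) pair is annotated independently with
#' probability `coverage`; each false pair enters with probability
#' `contamination` (default 0, so the gold standard is a subset of the
#' truth -- reliable but incomplete).
#'
#' @param world a `SyntheticWorld`.
#' @param organism organism label.
#' @param coverage,contamination sampling rates; defaults from the world's
#'   params.
#' @param seed integer seed.
#' @return a `GoldStandard` with `source = "synthetic"`.
#' @export
simulate_gold_standard <- function(world, organism,
                                   coverage = world$params$coverage,
                                   contamination = world$params$contamination,
                                   seed = world$params$seed) {
  if (!(coverage > 0 && coverage <= 1))
    stop("coverage must be in (0, 1]", call. = FALSE)
  truth <- world$truth[[organism]]
  if (is.null(truth)) stop("unknown organism: ", organism, call. = FALSE)
  set.seed(seed + 104729L)  # offset so gs noise differs from dataset noise
  u <- matrix(stats::runif(length(truth)), nrow = nrow(truth))
  keep <- (truth & u < coverage) | (!truth & u < contamination)
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("gold-standard sampling produced zero pairs", call. = FALSE)
  gold_standard(
    data.frame(gene = rownames(truth)[idx[, 1]],
               tissue = colnames(truth)[idx[, 2]],
               stringsAsFactors = FALSE),
    organism = organism, source = "synthetic")
}

#' Default species-name table for the toy corpus
#'
#' @return data.frame with columns `organism`, `name` (Linnaean and common
#'   names for human, mouse, rat, pig).
#' @export
default_organism_names <- function() {
  data.frame(
    organism = c("human", "human", "mouse", "mouse",
                 "rat", "rat", "pig", "pig"),
    name = c("Homo sapiens", "human", "Mus musculus", "mouse",
             "Rattus norvegicus", "rat", "Sus scrofa", "pig"),
    stringsAsFactors = FALSE)
}

#' Simulate a toy literature corpus from planted truth
#'
#' Each document names its organism and contains a few sentences
#' co-mentioning a gene and a tissue.  With probability `elevation` the
#' co-mentioned pair is drawn from the true pairs, otherwise uniformly
#' from all pairs -- so `elevation = 0` yields a corpus whose
#' co-occurrence scores carry no signal, while strong elevation makes
#' true pairs rank high.
#'
#' @param world a `SyntheticWorld`.
#' @param organism organism label.
#' @param n_docs number of abstracts (default 200).
#' @param elevation probability of drawing a true pair, in `[0, 1]`
#'   (default 0.95).
#' @param mentions_per_doc sentences with a gene-tissue co-mention per
#'   document (default 3).
#' @param seed integer seed.
#' @return list with `corpus` (see [read_corpus()]), `gene_names`,
#'   `tissue_names` and `organisms` dictionaries ready for
#'   [count_comentions()].
#' @export
simulate_corpus <- function(world, organism, n_docs = 200L,
                            elevation = 0.95, mentions_per_doc = 3L,
                            seed = world$params$seed) {
  truth <- world$truth[[organism]]
  if (is.null(truth)) stop("unknown organism: ", organism, call. = FALSE)
  set.seed(seed + 7919L)
  genes <- rownames(truth)
  tissues <- colnames(truth)
  tissue_words <- gsub(" ", "_", world$ontology$terms[tissues])
  true_idx <- which(truth, arr.ind = TRUE)
  all_n <- length(truth)
  org_names <- default_organism_names()
  species <- org_names$name[org_names$organism == organism][1]
  if (is.na(species)) species <- organism
  corpus <- vector("list", n_docs)
  for (d in seq_len(n_docs)) {
    sentences <- sprintf("This study was performed in %s samples.", species)
    for (s in seq_len(mentions_per_doc)) {
      if (nrow(true_idx) > 0 && stats::runif(1) < elevation) {
        k <- sample.int(nrow(true_idx), 1L)
        g <- genes[true_idx[k, 1]]; t <- tissues[true_idx[k, 2]]
      } else {
        k <- sample.int(all_n, 1L)
        g <- genes[(k - 1L) %% nrow(truth) + 1L]
        t <- tissues[(k - 1L) %/% nrow(truth) + 1L]
      }
      sentences <- c(sentences,
                     sprintf("Expression of %s was detected in the %s.",
                             g, tissue_words[t]))
    }
    corpus[[d]] <- list(doc_id = sprintf("doc%05d", d),
                        sentences = sentences)
  }
  list(corpus = corpus,
       gene_names = data.frame(alias = genes, gene = genes,
                               organism = organism,
                               stringsAsFactors = FALSE),
       tissue_names = data.frame(alias = unname(tissue_words),
                                 tissue = tissues,
                                 stringsAsFactors = FALSE),
       organisms = org_names)
}

#' Planted truth as a gold standard (complete reference)
#'
#' Convenience accessor used by benchmarking tests: the full truth of one
#' organism as a `GoldStandard` (coverage 1, no noise).
#'
#' @param world a `SyntheticWorld`.
#' @param organism organism label.
#' @return a `GoldStandard` with `source = "synthetic"`.
#' @export
truth_gold_standard <- function(world, organism) {
  truth <- world$truth[[organism]]
  if (is.null(truth)) stop("unknown organism: ", organism, call. = FALSE)
  idx <- which(truth, arr.ind = TRUE)
  gold_standard(
    data.frame(gene = rownames(truth)[idx[, 1]],
               tissue = colnames(truth)[idx[, 2]],
               stringsAsFactors = FALSE),
    organism = organism, source = "synthetic")
}
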