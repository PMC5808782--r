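# Tissue ontology DAG (BTO-style) and score propagation to parent terms.

#' Construct a tissue ontology
#'
#' Represents a tissue ontology as a directed acyclic graph over `is_a`
#' relations (child -> parent).  Only `is_a` edges are modelled; `part_of`
#' and other relations are out of scope for call propagation.
#'
#' @param terms named character vector: term id -> human-readable name.
#' @param parents named list: term id -> character vector of parent term
#'   ids (may be empty for roots).  Terms absent from the list are roots.
#' @param major_tissues optional character vector of term ids designating
#'   the major-tissue subset used for cross-dataset comparison.
#' @return an object of class `TissueOntology` with fields `terms`,
#'   `parents` (complete: one entry per term) and `major_tissues`.
#' @export
tissue_ontology <- function(terms, parents = list(), major_tissues = character()) {
  if (is.null(names(terms)) || anyDuplicated(names(terms)))
    stop("'terms' must be a uniquely named character vector", call. = FALSE)
  ids <- names(terms)
  full <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) full[[id]] <- character()
  for (child in names(parents)) {
    if (!child %in% ids)
      stop("parent entry for unknown term: ", child, call. = FALSE)
    p <- unique(as.character(parents[[child]]))
    bad <- setdiff(p, ids)
    if (length(bad))
      stop("dangling is_a target(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    full[[child]] <- p
  }
  onto <- structure(list(terms = terms, parents = full,
                         major_tissues = unique(as.character(major_tissues))),
                    class = "TissueOntology")
  bad <- setdiff(onto$major_tissues, ids)
  if (length(bad))
    stop("major tissues not in ontology: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cyc <- find_cycle(onto)
  if (!is.null(cyc))
    stop("is_a graph contains a cycle: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  onto
}

#' @export
print.TissueOntology <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  cat(sprintf("TissueOntology: %d terms, %d is_a edges, %d major tissues\n",
              length(x$terms), n_edges, length(x$major_tissues)))
  invisible(x)
}

# Depth-first search for a cycle in the child->parent graph; returns one
# offending path or NULL.
find_cycle <- function(onto) {
  state <- stats::setNames(integer(length(onto$terms)), names(onto$terms))
  path <- character()
  visit <- function(id) {
    if (state[[id]] == 1L) return(c(path[which(path == id)[1]:length(path)], id))
    if (state[[id]] == 2L) return(NULL)
    state[[id]] <<- 1L
    path <<- c(path, id)
    for (p in onto$parents[[id]]) {
      res <- visit(p)
      if (!is.null(res)) return(res)
    }
    path <<- path[-length(path)]
    state[[id]] <<- 2L
    NULL
  }
  for (id in names(onto$terms)) {
    res <- visit(id)
    if (!is.null(res)) return(res)
  }
  NULL
}

#' Ancestors of an ontology term
#'
#' Transitive closure over `is_a` edges, excluding the term itself.
#'
#' @param onto a `TissueOntology`.
#' @param term a term id present in the ontology.
#' @return character vector of ancestor term ids (possibly empty).
#' @export
ancestors <- function(onto, term) {
  if (!term %in% names(onto$terms))
    stop("unknown term: ", term, call. = FALSE)
  seen <- character()
  frontier <- onto$parents[[term]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(onto$parents[new], use.names = FALSE))
  }
  sort(seen)
}

# Topological order with children before parents (so that pushing a child's
# accumulated score to its direct parents transitively covers all
# descendants).
topo_children_first <- function(onto) {
  ids <- names(onto$terms)
  remaining_counts <- stats::setNames(integer(length(ids)), ids)
  for (child in ids)
    for (p in onto$parents[[child]])
      remaining_counts[[p]] <- remaining_counts[[p]] + 1L
  # Kahn's algorithm starting from leaves (terms with no children).
  queue <- ids[remaining_counts == 0L]
  order <- character(0)
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    order <- c(order, id)
    for (p in onto$parents[[id]]) {
      remaining_counts[[p]] <- remaining_counts[[p]] - 1L
      if (remaining_counts[[p]] == 0L) queue <- c(queue, p)
    }
  }
  order
}

#' Propagate association scores to ancestor tissue terms
#'
#' For every gene and every ontology term, the propagated score is the
#' maximum of the term's own score and the scores of all its descendants.
#' Associations are created for ancestor terms that had none (with `raw`
#' set to `NA`, since raw units are platform-specific and not comparable
#' across terms).  Both `confidence` and `stars` columns are propagated by
#' the same max rule.
#'
#' @param assocs a `ScoredChannel`.
#' @param onto a `TissueOntology`; every tissue in `assocs` must be a term.
#' @return a `ScoredChannel` with propagated scores.
#' @export
propagate_scores <- function(assocs, onto) {
  a <- assocs$associations
  bad <- setdiff(unique(a$tissue), names(onto$terms))
  if (length(bad))
    stop("association references unknown term(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (nrow(a) == 0L) return(assocs)
  order <- topo_children_first(onto)
  out <- lapply(split(a, a$gene), function(g) {
    conf <- stats::setNames(rep(NA_real_, length(onto$terms)),
                            names(onto$terms))
    star <- conf
    raw <- conf
    conf[g$tissue] <- g$confidence
    star[g$tissue] <- g$stars
    raw[g$tissue] <- g$raw
    for (id in order) {
      for (p in onto$parents[[id]]) {
        conf[[p]] <- max_na(conf[[p]], conf[[id]])
        star[[p]] <- max_na(star[[p]], star[[id]])
      }
    }
    keep <- !(is.na(conf) & is.na(star))
    data.frame(gene = g$gene[1], tissue = names(conf)[keep],
               raw = raw[keep], confidence = conf[keep],
               stars = star[keep], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  scored_channel(res, channel = assocs$channel, organism = assocs$organism,
                 dataset_id = assocs$dataset_id)
}

# max treating NA as the identity element
max_na <- function(a, b) {
  if (is.na(a)) return(b)
  if (is.na(b)) return(a)
  max(a, b)
}

#' Propagate gold-standard annotations to ancestor terms
#'
#' A trusted call at a term implies the gene is expressed in every
#' ancestor tissue, so each (gene, term) pair is expanded to
#' (gene, ancestor) for all ancestors.  Used to benchmark datasets whose
#' tissue columns sit higher in the ontology than the annotations.
#'
#' @param gs a `GoldStandard`.
#' @param onto a `TissueOntology` containing every annotated term.
#' @return a `GoldStandard` with the expanded, deduplicated pair set.
#' @export
propagate_gold_standard <- function(gs, onto) {
  bad <- setdiff(unique(gs$pairs$tissue), names(onto$terms))
  if (length(bad))
    stop("gold standard references unknown term(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  anc <- lapply(unique(gs$pairs$tissue), ancestors, onto = onto)
  names(anc) <- unique(gs$pairs$tissue)
  extra <- do.call(rbind, lapply(seq_len(nrow(gs$pairs)), function(i) {
    up <- anc[[gs$pairs$tissue[i]]]
    if (length(up))
      data.frame(gene = gs$pairs$gene[i], tissue = up,
                 stringsAsFactors = FALSE)
  }))
  gold_standard(rbind(gs$pairs, extra), organism = gs$organism,
                source = gs$source)
}

#' Default major-tissue list
#'
#' The package ships a synthetic stand-in for the curated major-tissue
#' configuration: 21 term ids with names, one per line
#' (`inst/extdata/major_tissues_synthetic.txt`).  Rats lack a gall
#' bladder, so the rat list has 20 entries.
#'
#' @param organism taxon label; `"rat"` drops the gall bladder term.
#' @return named character vector: term id -> tissue name.
#' @export
default_major_tissues <- function(organism = "human") {
  path <- system.file("extdata", "major_tissues_synthetic.txt",
                      package = "tissuescore", mustWork = TRUE)
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  out <- stats::setNames(vapply(rows, `[`, character(1), 2L),
                         vapply(rows, `[`, character(1), 1L))
  if (identical(organism, "rat")) out <- out[out != "gall bladder"]
  out
}

#' Restrict a channel to the major-tissue subset
#'
#' Keeps only associations whose tissue term is in the ontology's
#' major-tissue list.  Scores should be propagated first, otherwise calls
#' made at descendant terms of a major tissue are lost.
#'
#' @param assocs a `ScoredChannel` (normally after [propagate_scores()]).
#' @param onto a `TissueOntology` with a non-empty `major_tissues` set.
#' @return a `ScoredChannel` over major tissues only.
#' @export
restrict_to_major <- function(assocs, onto) {
  if (length(onto$major_tissues) == 0L)
    stop("ontology has an empty major-tissue set", call. = FALSE)
  a <- assocs$associations
  a <- a[a$tissue %in% onto$major_tissues, , drop = FALSE]
  scored_channel(a, channel = assocs$channel, organism = assocs$organism,
                 dataset_id = assocs$dataset_id)
}
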