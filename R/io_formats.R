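# Readers/writers for the external file dialects the pipeline touches.
# Universal tabular dialect: TSV, "." decimal, no quoting.  Dropped records
# are never silent: every reader exposes drop counts via the "dropped"
# attribute or an explicit field.

#' Read a gene-by-tissue expression matrix from TSV
#'
#' Expects a header row of tissue/sample labels and a first column of
#' gene/probe identifiers.  Duplicate gene rows are an error: collapsing
#' probe-level rows to genes is the responsibility of [map_identifiers()].
#'
#' @param path TSV file path.
#' @param dataset_id,organism,unit dataset metadata; see
#'   [expression_dataset()].
#' @return an `ExpressionDataset`.
#' @export
read_expression_matrix <- function(path, dataset_id = basename(path),
                                   organism = "human", unit = "arbitrary") {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("expression matrix needs a header and at least one row: ", path,
         call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  tissues <- header[-1]
  ncol_expected <- length(header)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (any(lens != ncol_expected)) {
    bad <- which(lens != ncol_expected)[1]
    stop(sprintf("malformed row at line %d: expected %d fields, found %d",
                 bad + 1L, ncol_expected, lens[bad]), call. = FALSE)
  }
  genes <- vapply(rows, `[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1]), numeric(length(tissues))))
  vals <- matrix(vals, nrow = length(tissues))  # vapply gives tissues x genes
  if (any(is.na(vals))) {
    bad <- which(colSums(is.na(vals)) > 0)[1]
    stop(sprintf("non-numeric value at line %d", bad + 1L), call. = FALSE)
  }
  if (any(vals < 0)) {
    bad <- which(colSums(vals < 0) > 0)[1]
    stop(sprintf("negative expression value at line %d", bad + 1L),
         call. = FALSE)
  }
  m <- t(vals)
  dimnames(m) <- list(genes, tissues)
  expression_dataset(m, dataset_id = dataset_id, organism = organism,
                     unit = unit)
}

#' Write an expression matrix as TSV
#'
#' @param ds an `ExpressionDataset`.
#' @param path output file path.
#' @param digits significant digits used for formatting (default 15,
#'   enough for exact double round-trips in practice).
#' @return invisibly, `path`.
#' @export
write_expression_matrix <- function(ds, path, digits = 15) {
  m <- ds$values
  header <- paste(c("gene", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i],
            formatC(m[i, ], digits = digits, format = "g")),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a tissue ontology from an OBO 1.2-style file
#'
#' Minimal parser: `[Term]` stanzas with `id:`, `name:`, `is_a:` and
#' `is_obsolete:` lines; every other tag is ignored, as are `relationship:`
#' edges -- only the `is_a` DAG drives call propagation.  Obsolete terms
#' are excluded together with edges mentioning them.
#'
#' @param path OBO file path.
#' @param major_tissues optional character vector of term ids to mark as
#'   major tissues.
#' @return a `TissueOntology`.
#' @export
read_ontology_obo <- function(path, major_tissues = character()) {
  lines <- readLines(path)
  terms <- character()
  parents <- list()
  cur_id <- NULL; cur_name <- NA_character_
  cur_parents <- character(); cur_obsolete <- FALSE
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur_id) && !cur_obsolete) {
      terms[[cur_id]] <<- if (is.na(cur_name)) cur_id else cur_name
      parents[[cur_id]] <<- cur_parents
    }
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)        # strip trailing comments
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur_id <- NULL; cur_name <- NA_character_
      cur_parents <- character(); cur_obsolete <- FALSE
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {  # [Typedef] etc.
      flush(); cur_id <- NULL; in_term <- FALSE
    } else if (in_term && grepl("^id:", ln)) {
      cur_id <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^name:", ln)) {
      cur_name <- trimws(sub("^name:", "", ln))
    } else if (in_term && grepl("^is_a:", ln)) {
      cur_parents <- c(cur_parents, trimws(sub("^is_a:", "", ln)))
    } else if (in_term && grepl("^is_obsolete:", ln)) {
      cur_obsolete <- trimws(sub("^is_obsolete:", "", ln)) == "true"
    }
  }
  flush()
  if (length(terms) == 0L)
    stop("no terms found in OBO file: ", path, call. = FALSE)
  # drop edges to obsolete/absent parents only if the parent was declared
  # obsolete; a parent never declared at all is a dangling reference
  parents <- lapply(parents, function(p) p)
  tissue_ontology(terms, parents, major_tissues = major_tissues)
}

#' Write a tissue ontology as a minimal OBO file
#'
#' @param onto a `TissueOntology`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_ontology_obo <- function(onto, path) {
  out <- c("format-version: 1.2", "")
  for (id in names(onto$terms)) {
    p <- onto$parents[[id]]
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", onto$terms[[id]]),
             if (length(p)) paste0("is_a: ", p), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read orthologous groups from an eggNOG-style members TSV
#'
#' Dialect: one group per line; a group-id column and a comma-separated
#' member column of `taxid.protein_id` tokens.  By default the first column
#' is the group id and the last column the member list, which covers both
#' the 2-column toy dialect and the 5-column eggNOG members layout.
#' Members of organisms outside `allowed_organisms` are dropped and
#' counted; groups left empty are omitted.
#'
#' @param path TSV file path.
#' @param allowed_organisms named character vector mapping numeric taxon
#'   prefix to organism label, e.g. `c("9606" = "human", "10090" = "mouse")`.
#' @return an `OrthologGroups` object: a list with `groups` (data.frame of
#'   `group`, `organism`, `gene`) and `dropped_members` count.
#' @export
read_orthogroups <- function(path,
                             allowed_organisms = c("9606" = "human",
                                                   "10090" = "mouse",
                                                   "10116" = "rat",
                                                   "9823" = "pig")) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  dropped <- 0L
  recs <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    gid <- r[1]
    members <- strsplit(r[length(r)], ",", fixed = TRUE)[[1]]
    members <- trimws(members)
    members <- members[nzchar(members)]
    if (any(!grepl(".", members, fixed = TRUE)))
      stop(sprintf(
        "line %d: member token without '.' separator: %s", i,
        members[!grepl(".", members, fixed = TRUE)][1]), call. = FALSE)
    taxid <- sub("\\..*$", "", members)
    gene <- sub("^[^.]*\\.", "", members)
    keep <- taxid %in% names(allowed_organisms)
    dropped <- dropped + sum(!keep)
    if (any(keep))
      recs[[i]] <- data.frame(group = gid,
                              organism = unname(allowed_organisms[taxid[keep]]),
                              gene = gene[keep],
                              stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  groups <- if (length(recs)) do.call(rbind, recs) else
    data.frame(group = character(), organism = character(),
               gene = character(), stringsAsFactors = FALSE)
  ortholog_groups(groups, dropped_members = dropped)
}

#' Write ortholog groups in the members TSV dialect
#'
#' Inverse of [read_orthogroups()]: one line per group, group id then the
#' comma-separated `taxid.gene` member list.
#'
#' @param groups an `OrthologGroups`.
#' @param path output file path.
#' @param organism_taxids named character vector: organism label -> taxon
#'   prefix (defaults mirror the reader's allow-list).
#' @return invisibly, `path`.
#' @export
write_orthogroups <- function(groups, path,
                              organism_taxids = c(human = "9606",
                                                  mouse = "10090",
                                                  rat = "10116",
                                                  pig = "9823")) {
  g <- groups$groups
  lines <- vapply(split(g, g$group), function(gr)
    paste0(gr$group[1], "\t",
           paste(organism_taxids[gr$organism], gr$gene, sep = ".",
                 collapse = ",")),
    character(1))
  writeLines(lines[order(names(lines))], path)
  invisible(path)
}

#' Construct an ortholog-groups object
#'
#' @param groups data.frame with columns `group`, `organism`, `gene`.
#' @param dropped_members count of members dropped by organism filtering.
#' @return an `OrthologGroups` object.
#' @export
ortholog_groups <- function(groups, dropped_members = 0L) {
  stopifnot(is.data.frame(groups),
            all(c("group", "organism", "gene") %in% names(groups)))
  rownames(groups) <- NULL
  structure(list(groups = groups, dropped_members = dropped_members),
            class = "OrthologGroups")
}

#' @export
print.OrthologGroups <- function(x, ...) {
  cat(sprintf("OrthologGroups: %d groups, %d members (%d dropped)\n",
              length(unique(x$groups$group)), nrow(x$groups),
              x$dropped_members))
  invisible(x)
}

#' Read gold-standard annotation pairs from TSV
#'
#' Two dialects are accepted: two columns `gene<TAB>tissue_term`, or three
#' columns `gene<TAB>tissue_label<TAB>...` combined with a `label_to_term`
#' mapping.  When a mapping is supplied the second column is treated as a
#' free-text tissue label; labels without a mapping are dropped and
#' counted.
#'
#' @param path TSV file path (no header).
#' @param organism taxon label.
#' @param source provenance tag, see [gold_standard()].
#' @param label_to_term optional named character vector: tissue label ->
#'   term id.
#' @return a `GoldStandard`; the number of rows dropped for unmappable
#'   labels is in `attr(, "dropped")`.
#' @export
read_annotation_pairs <- function(path, organism = "human",
                                  source = "curated", label_to_term = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("gold standard file is empty: ", path, call. = FALSE)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  gene <- vapply(rows, `[`, character(1), 1L)
  second <- vapply(rows, `[`, character(1), 2L)
  if (any(is.na(second)))
    stop("annotation row without a tissue column at line ",
         which(is.na(second))[1], call. = FALSE)
  dropped <- 0L
  if (!is.null(label_to_term)) {
    mapped <- label_to_term[second]
    keep <- !is.na(mapped)
    dropped <- sum(!keep)
    gene <- gene[keep]
    second <- unname(mapped[keep])
  }
  if (length(gene) == 0L)
    stop("no mappable annotation pairs in: ", path, call. = FALSE)
  gs <- gold_standard(data.frame(gene = gene, tissue = second,
                                 stringsAsFactors = FALSE),
                      organism = organism, source = source)
  attr(gs, "dropped") <- dropped
  gs
}

#' Write gold-standard pairs as TSV
#'
#' @param gs a `GoldStandard`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_annotation_pairs <- function(gs, path) {
  writeLines(paste(gs$pairs$gene, gs$pairs$tissue, sep = "\t"), path)
  invisible(path)
}

#' Write a scored channel as a download-style TSV
#'
#' Columns: gene id, tissue term id, tissue name, channel, raw value
#' (empty when not applicable), confidence, stars.  Rows are sorted by
#' gene, then by descending stars, then tissue id; output is byte-stable
#' for a fixed input.
#'
#' @param assocs a `ScoredChannel`.
#' @param path output file path.
#' @param onto optional `TissueOntology` used to resolve tissue names
#'   (term id is repeated when absent).
#' @return invisibly, `path`.
#' @export
write_channel <- function(assocs, path, onto = NULL) {
  a <- assocs$associations
  name <- if (is.null(onto)) a$tissue else {
    nm <- onto$terms[a$tissue]
    ifelse(is.na(nm), a$tissue, nm)
  }
  ord <- order(a$gene, -ifelse(is.na(a$stars), -Inf, a$stars), a$tissue)
  a <- a[ord, , drop = FALSE]
  name <- name[ord]
  fmt <- function(v) ifelse(is.na(v), "",
                            formatC(v, digits = 15, format = "g"))
  header <- "gene\ttissue\ttissue_name\tchannel\traw\tconfidence\tstars"
  body <- if (nrow(a) == 0L) character(0) else
    paste(a$gene, a$tissue, name, assocs$channel,
          fmt(a$raw), fmt(a$confidence), fmt(a$stars), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a scored channel written by [write_channel()]
#'
#' @param path TSV file path.
#' @param organism taxon label to tag the channel with.
#' @return a `ScoredChannel`.
#' @export
read_channel <- function(path, organism = "human") {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(lines) == 1L)
    return(scored_channel(data.frame(gene = character(),
                                     tissue = character()),
                          channel = "experiments", organism = organism))
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  get <- function(i) vapply(rows, function(r)
    if (length(r) >= i) r[i] else "", character(1))
  num <- function(v) suppressWarnings(
    ifelse(nzchar(v), as.numeric(v), NA_real_))
  channel <- get(4)[1]
  scored_channel(data.frame(gene = get(1), tissue = get(2),
                            raw = num(get(5)), confidence = num(get(6)),
                            stars = num(get(7)), stringsAsFactors = FALSE),
                 channel = channel, organism = organism,
                 dataset_id = basename(path))
}
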