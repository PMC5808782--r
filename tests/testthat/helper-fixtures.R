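# Shared fixture builders.  Everything is built in code; no binary files.

# small expression dataset with reproducible random values
make_dataset <- function(n_genes = 5, n_tissues = 3, seed = 1,
                         organism = "human", genes = NULL, tissues = NULL) {
  set.seed(seed)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(n_genes))
  if (is.null(tissues)) tissues <- sprintf("t%02d", seq_len(n_tissues))
  m <- matrix(round(stats::runif(length(genes) * length(tissues)) * 100, 3),
              nrow = length(genes), dimnames = list(genes, tissues))
  expression_dataset(m, dataset_id = "fix", organism = organism)
}

# chain ontology A -> B -> C (A is the leaf)
chain_ontology <- function() {
  tissue_ontology(c(A = "leaf", B = "middle", C = "root"),
                  list(A = "B", B = "C"))
}

# random DAG over n terms: term i may have parents among terms > i
random_dag <- function(n, seed = 1, p_edge = 0.15) {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  parents <- list()
  for (i in seq_len(n - 1)) {
    cand <- ids[(i + 1):n]
    sel <- cand[stats::runif(length(cand)) < p_edge]
    if (length(sel) == 0 && i < n) sel <- sample(cand, 1)
    parents[[ids[i]]] <- sel
  }
  tissue_ontology(stats::setNames(ids, ids), parents)
}

# brute-force ancestor closure by repeated edge expansion
oracle_ancestors <- function(onto, term) {
  res <- character()
  frontier <- term
  repeat {
    nxt <- unique(unlist(onto$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, res)
    if (length(nxt) == 0) break
    res <- c(res, nxt)
    frontier <- nxt
  }
  sort(res)
}

# random scored channel over given genes/tissues
make_channel <- function(n = 20, seed = 1, organism = "human",
                         genes = sprintf("g%02d", 1:8),
                         tissues = sprintf("t%02d", 1:4),
                         channel = "experiments", id = "chan") {
  set.seed(seed)
  all <- expand.grid(gene = genes, tissue = tissues,
                     stringsAsFactors = FALSE)
  pick <- sample(nrow(all), min(n, nrow(all)))
  a <- all[pick, ]
  a$confidence <- round(stats::runif(nrow(a), 0, 4), 4)
  a$stars <- round(stats::runif(nrow(a), 0, 5), 4)
  scored_channel(a, channel = channel, organism = organism,
                 dataset_id = id)
}

# random ortholog groups over two or more organisms
make_groups <- function(n_groups = 30, orgs = c("human", "mouse"),
                        seed = 1) {
  set.seed(seed)
  recs <- list()
  for (g in seq_len(n_groups)) {
    for (o in orgs) {
      k <- sample(0:2, 1)  # 0, 1 or 2 members of this organism
      if (k > 0)
        recs[[length(recs) + 1]] <- data.frame(
          group = sprintf("OG%03d", g), organism = o,
          gene = sprintf("%s_%03d_%d", o, g, seq_len(k)),
          stringsAsFactors = FALSE)
    }
  }
  ortholog_groups(do.call(rbind, recs))
}

# independent direct-count oracle for fold-enrichment curves
oracle_curve <- function(ds, gs, window, step) {
  genes <- intersect(rownames(ds$values), unique(gs$pairs$gene))
  tissues <- intersect(colnames(ds$values), unique(gs$pairs$tissue))
  grid <- expand.grid(gene = genes, tissue = tissues,
                      stringsAsFactors = FALSE)
  grid$raw <- ds$values[cbind(grid$gene, grid$tissue)]
  grid <- grid[order(-grid$raw, grid$gene, grid$tissue), ]
  gs_key <- paste(gs$pairs$gene, gs$pairs$tissue)
  hit <- paste(grid$gene, grid$tissue) %in% gs_key
  expected <- sum(gs$pairs$gene %in% genes & gs$pairs$tissue %in% tissues) /
    (length(genes) * length(tissues))
  starts <- seq(1, nrow(grid) - window + 1, by = step)
  data.frame(
    x = vapply(starts, function(s)
      mean(grid$raw[s:(s + window - 1)]), numeric(1)),
    e = vapply(starts, function(s)
      (sum(hit[s:(s + window - 1)]) / window) / expected, numeric(1)))
}

# textbook Pearson r, computed from first principles
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
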