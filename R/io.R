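# All on-disk formats are tab-separated UTF-8 text: '#' lines are
# comments, fields are never quoted, gene identifiers key every table
# (integer vertex indices stay internal).

read_tsv_checked <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  fields <- utils::count.fields(path, sep = "\t", comment.char = "#",
                                quote = "")
  fields <- fields[!is.na(fields)]
  if (length(fields) && length(unique(fields)) > 1) {
    bad <- which(fields != fields[1])[1]
    stop("parse error in ", path, ": ragged row at data line ", bad,
         " (", fields[bad], " fields, expected ", fields[1], ")")
  }
  utils::read.delim(path, header = header, sep = "\t", quote = "",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_tsv <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
}

#' Read an expression matrix
#'
#' First column gene id, header row sample ids, numeric expression values.
#'
#' @param path TSV file path.
#' @return list with `values` (genes x samples matrix) and `samples`.
#' @export
read_expression <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2) stop("parse error in ", path, ": need gene id + samples")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric expression values in ", path)
  rownames(values) <- genes
  list(values = values, samples = colnames(values))
}

#' Write an expression matrix
#' @param values genes x samples matrix with dimnames.
#' @param path output TSV path.
#' @export
write_expression <- function(values, path) {
  df <- data.frame(gene = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read per-sample class labels
#'
#' Two-column TSV: sample id, class.
#'
#' @param path TSV file path.
#' @return named character vector (class per sample).
#' @export
read_labels <- function(path) {
  df <- read_tsv_checked(path, header = FALSE)
  if (ncol(df) < 2) stop("parse error in ", path, ": need sample + class")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write per-sample class labels
#' @param labels named character vector (names = sample ids).
#' @param path output TSV path.
#' @export
write_labels <- function(labels, path) {
  write_tsv(data.frame(sample = names(labels), class = unname(labels)),
            path, col.names = FALSE)
}

#' Read a protein-protein interaction edge list
#'
#' TSV with two gene-symbol columns; extra columns are ignored.
#'
#' @param path TSV file path.
#' @param header whether the file carries a header row (default FALSE).
#' @return two-column data frame (`from`, `to`).
#' @export
read_ppin <- function(path, header = FALSE) {
  df <- read_tsv_checked(path, header = header)
  if (ncol(df) < 2) stop("parse error in ", path, ": need two gene columns")
  data.frame(from = as.character(df[[1]]), to = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Read a gene similarity matrix
#'
#' Square TSV, first column and header row both carrying the gene ids.
#' Asymmetries beyond 1e-8 are an error.
#'
#' @param path TSV file path.
#' @return symmetric numeric matrix.
#' @export
read_similarity <- function(path) {
  df <- read_tsv_checked(path)
  genes <- as.character(df[[1]])
  sim <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(sim)) stop("non-numeric similarity values in ", path)
  rownames(sim) <- genes
  validate_similarity(sim)
}

#' Write a gene similarity matrix
#' @param sim symmetric named matrix.
#' @param path output TSV path.
#' @export
write_similarity <- function(sim, path) {
  df <- data.frame(gene = rownames(sim), sim, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write a weighted network as an edge list
#'
#' One row per undirected edge, lexicographically smaller gene first,
#' columns `gene_a`, `gene_b`, `weight`; rows sorted for reproducible
#' output. A companion node-index map (`gene`, `index`) can be written
#' with [write_node_map()].
#'
#' @param net weighted `igraph` network.
#' @param path output TSV path.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  df <- data.frame(gene_a = pmin(el[, 1], el[, 2]),
                   gene_b = pmax(el[, 1], el[, 2]),
                   weight = igraph::E(net)$weight,
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b, method = "radix"), , drop = FALSE]
  write_tsv(df, path)
}

#' Read a weighted edge-list network
#' @param path TSV path with columns `gene_a`, `gene_b`, `weight`.
#' @return weighted `igraph` network.
#' @export
read_network <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 3) stop("parse error in ", path, ": need gene_a/gene_b/weight")
  if (!is.numeric(df[[3]])) stop("non-numeric weights in ", path)
  weighted_network(df)
}

#' Write the node-index map of a network
#' @param net weighted `igraph` network.
#' @param path output TSV path.
#' @export
write_node_map <- function(net, path) {
  write_tsv(data.frame(gene = igraph::V(net)$name,
                       index = seq_len(igraph::vcount(net))), path)
}

#' Write / read the per-node bookkeeping table
#'
#' Columns: `gene`, `lm_id`, `module_id`, `vw`, `va`.
#'
#' @param node_table node table (from [boundary_correction()]).
#' @param path TSV path.
#' @export
write_node_table <- function(node_table, path) {
  write_tsv(node_table[, c("gene", "lm_id", "module_id", "vw", "va")], path)
}

#' @rdname write_node_table
#' @export
read_node_table <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("gene", "lm_id", "module_id", "vw", "va")
  if (!all(need %in% names(df)))
    stop("parse error in ", path, ": missing node-table columns")
  df$node <- seq_len(nrow(df))
  df[, c("node", need)]
}

#' Write a module assignment
#'
#' Two-column TSV (`gene`, `module_id`), sorted by gene for reproducible
#' output.
#'
#' @param assignment named integer vector (names = genes).
#' @param path output TSV path.
#' @export
write_modules <- function(assignment, path) {
  df <- data.frame(gene = names(assignment),
                   module_id = unname(assignment),
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene, method = "radix"), , drop = FALSE]
  write_tsv(df, path)
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then the member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("parse error in ", path, ": GMT line needs name, description, genes")
    gene_set(parts[1], parts[-(1:2)])
  })
}

#' Read a flat one-gene-per-line ground-truth list
#' @param path text file path.
#' @param name label for the resulting set.
#' @return a [gene_set()].
#' @export
read_gene_list <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  genes <- readLines(path, warn = FALSE)
  genes <- trimws(genes)
  gene_set(name, genes[nzchar(genes) & !startsWith(genes, "#")])
}

#' Read ontology tables
#'
#' Three TSVs: term probabilities (`term`, `p`), ancestor closure
#' (`term`, `ancestor`; reflexivity is enforced on load) and annotations
#' (`gene`, `term`).
#'
#' @param term_prob_path,ancestors_path,annotations_path file paths.
#' @return an [ontology_tables()] object.
#' @export
read_ontology <- function(term_prob_path, ancestors_path, annotations_path) {
  tp <- read_tsv_checked(term_prob_path)
  if (ncol(tp) < 2 || !is.numeric(tp[[2]]))
    stop("parse error in ", term_prob_path, ": need term + numeric p")
  term_prob <- stats::setNames(tp[[2]], as.character(tp[[1]]))
  an <- read_tsv_checked(ancestors_path)
  ancestors <- split(as.character(an[[2]]), as.character(an[[1]]))
  ga <- read_tsv_checked(annotations_path)
  annotations <- split(as.character(ga[[2]]), as.character(ga[[1]]))
  ontology_tables(term_prob, ancestors, annotations)
}
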