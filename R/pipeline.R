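#' Pipeline run configuration
#'
#' Bundles file paths and parameters for [run_pipeline()]. Defaults match
#' the method's reference settings: DEG threshold `alpha = 0.05`,
#' population 50, 100 generations, neighbourhood 40, mutation rate 0.1.
#'
#' @param expression path to the expression TSV (gene id + sample
#'   columns).
#' @param labels path to the two-column sample-label TSV.
#' @param ppin path to the interaction edge-list TSV.
#' @param out_dir output directory (created if missing).
#' @param similarity optional path to a precomputed similarity TSV; if
#'   `NULL`, the three ontology paths must be given.
#' @param term_prob,ancestors,annotations ontology table paths (used only
#'   when `similarity` is `NULL`).
#' @param truth optional ground-truth gene file (GMT if it ends in
#'   `.gmt`, otherwise one gene per line) for the enrichment stage.
#' @param alpha DEG adjusted-p threshold.
#' @param universe enrichment universe: `"network"` (default) or `"all"`
#'   (every gene in the expression matrix).
#' @param seed master seed for the run.
#' @param combine gene-level similarity aggregation (see
#'   [simrel_genes()]).
#' @param ... further arguments passed to [moga_config()] (`pop`,
#'   `max_gen`, `nm`, `mutation_rate`, `cc_sign`, `dbi_mode`, ...).
#' @return a `run_config` list.
#' @export
run_config <- function(expression, labels, ppin, out_dir,
                       similarity = NULL, term_prob = NULL,
                       ancestors = NULL, annotations = NULL,
                       truth = NULL, alpha = 0.05,
                       universe = c("network", "all"),
                       seed = 1L, combine = "bma", ...) {
  universe <- match.arg(universe)
  for (p in c(expression, labels, ppin, similarity, term_prob,
              ancestors, annotations, truth)) {
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  }
  if (is.null(similarity) &&
      (is.null(term_prob) || is.null(ancestors) || is.null(annotations)))
    stop("either a similarity matrix or the three ontology tables required")
  structure(list(expression = expression, labels = labels, ppin = ppin,
                 out_dir = out_dir, similarity = similarity,
                 term_prob = term_prob, ancestors = ancestors,
                 annotations = annotations, truth = truth, alpha = alpha,
                 universe = universe, seed = as.integer(seed),
                 combine = combine,
                 moga = moga_config(rng_seed = as.integer(seed), ...)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full module-identification pipeline
#'
#' Executes, in order: DEG selection, co-expression network construction
#' with interaction masking, local-module pre-simplification with
#' boundary correction and triangle contraction, the multi-objective
#' evolutionary search, final-solution selection by the within/between
#' contrast criterion, and (if a ground-truth file is given)
#' hypergeometric enrichment of the largest module. All artifacts are
#' written under `cfg$out_dir`: `network.tsv`, `node_map.tsv`,
#' `node_table.tsv`, `front.tsv`, `modules.tsv`, `core_module.txt`,
#' `enrichment.tsv` and a JSON `report.json` (config, seed, objective
#' table, selection criterion, per-generation reference point).
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the main in-memory results
#'   (`degs`, `network`, `node_table`, `result`, `final`, `enrichment`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  expr <- stage("read-expression", read_expression(cfg$expression))
  labels <- stage("read-labels", read_labels(cfg$labels))
  if (!all(colnames(expr$values) %in% names(labels)))
    stop("stage 'read-labels' failed: unlabeled samples", call. = FALSE)
  labels <- labels[colnames(expr$values)]
  ppin <- stage("read-ppin", read_ppin(cfg$ppin))

  degs <- stage("select-degs",
                select_degs(expr$values, labels, cfg$alpha))
  net <- stage("build-network", build_gcn(expr$values, degs$genes, ppin))
  write_network(net, file.path(cfg$out_dir, "network.tsv"))
  write_node_map(net, file.path(cfg$out_dir, "node_map.tsv"))

  sim <- stage("similarity", {
    if (!is.null(cfg$similarity)) {
      read_similarity(cfg$similarity)
    } else {
      onto <- read_ontology(cfg$term_prob, cfg$ancestors, cfg$annotations)
      simrel_matrix(igraph::V(net)$name, onto, combine = cfg$combine)
    }
  })
  if (!all(igraph::V(net)$name %in% rownames(sim)))
    stop("stage 'similarity' failed: matrix does not cover network genes",
         call. = FALSE)

  red <- stage("presimplify", presimplify(net, rng_seed = cfg$seed))
  node_table <- stage("boundary-correction",
                      boundary_correction(net, red$node_table))
  write_node_table(node_table, file.path(cfg$out_dir, "node_table.tsv"))

  result <- stage("evolve", evolve(red$reduced, sim, cfg$moga))
  final <- stage("select-final", select_final(result, red$reduced))

  front <- data.frame(
    solution = seq_along(result$archive),
    f1 = vapply(result$archive, function(e) e$objectives[["f1"]], numeric(1)),
    f2 = vapply(result$archive, function(e) e$objectives[["f2"]], numeric(1)),
    n_modules = vapply(result$archive,
                       function(e) length(unique(e$assignment)), integer(1)))
  write_tsv(front, file.path(cfg$out_dir, "front.tsv"))
  write_modules(final$assignment, file.path(cfg$out_dir, "modules.tsv"))
  writeLines(sort(final$module, method = "radix"),
             file.path(cfg$out_dir, "core_module.txt"))

  enrichment <- NULL
  if (!is.null(cfg$truth)) {
    enrichment <- stage("enrich", {
      truth <- if (grepl("\\.gmt$", cfg$truth, ignore.case = TRUE)) {
        read_gmt(cfg$truth)[[1]]
      } else {
        read_gene_list(cfg$truth)
      }
      uni <- if (cfg$universe == "network") igraph::V(net)$name
             else rownames(expr$values)
      enrich_module(final$module, truth, uni)
    })
    write_tsv(enrichment, file.path(cfg$out_dir, "enrichment.tsv"))
  }

  report <- list(
    seed = cfg$seed,
    alpha = cfg$alpha,
    universe = cfg$universe,
    moga = unclass(cfg$moga),
    n_degs = length(degs$genes),
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    n_reduced_nodes = igraph::vcount(red$reduced$graph),
    archive_size = length(result$archive),
    w_prime = unname(final$w_prime),
    core_module_size = length(final$module),
    z_history = apply(result$z_history, 1, as.numeric, simplify = FALSE),
    enrichment_p = if (!is.null(enrichment)) enrichment$p else NULL)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(degs = degs, network = net, node_table = node_table,
                 result = result, final = final, enrichment = enrichment))
}

#' Simulate a complete synthetic study on disk
#'
#' Writes every input the pipeline consumes, with known ground truth:
#' a block-structured two-class expression matrix, sample labels, an
#' interaction network wiring the co-expression blocks (plus sparse
#' cross-block contacts), a block-structured similarity matrix over all
#' genes, and the true disease gene list.
#'
#' @param out_dir output directory.
#' @param seed integer seed (all generators derive from it).
#' @param block_sizes,n_disease,n_control,coexpr,effect,noise,n_background
#'   passed to [gen_expression()].
#' @param affected_blocks blocks carrying the disease effect.
#' @param p_within,p_between interaction probabilities inside/between
#'   blocks.
#' @param mu_in,mu_out,sim_sd similarity-matrix parameters (see
#'   [gen_similarity()]).
#' @return invisibly, the named vector of written file paths.
#' @export
simulate_study <- function(out_dir, seed = 1L,
                           block_sizes = c(20L, 20L, 20L, 20L),
                           n_disease = 20L, n_control = 20L,
                           coexpr = 0.8, effect = 2, noise = 1,
                           n_background = 100L,
                           affected_blocks = seq_along(block_sizes),
                           p_within = 0.9, p_between = 0.02,
                           mu_in = 0.8, mu_out = 0.2, sim_sd = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 3L)
  study <- gen_expression(block_sizes, n_disease, n_control, coexpr,
                          effect, noise, n_background, affected_blocks,
                          seed = seeds[1])

  # interaction edges: dense inside blocks, sparse elsewhere
  genes <- rownames(study$values)
  block_of <- stats::setNames(rep(0L, length(genes)), genes)
  for (b in seq_along(study$blocks)) block_of[study$blocks[[b]]] <- b
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seeds[2])
  pairs <- utils::combn(length(genes), 2)
  same <- block_of[pairs[1, ]] > 0 &
    block_of[pairs[1, ]] == block_of[pairs[2, ]]
  present <- stats::runif(ncol(pairs)) < ifelse(same, p_within, p_between)
  ppin <- data.frame(from = genes[pairs[1, present]],
                     to = genes[pairs[2, present]],
                     stringsAsFactors = FALSE)

  # similarity labels: blocks keep their id, background genes are their
  # own one-gene communities
  sim_labels <- block_of
  sim_labels[sim_labels == 0L] <-
    seq_len(sum(sim_labels == 0L)) + length(study$blocks)
  sim <- gen_similarity(sim_labels, mu_in, mu_out, sim_sd, seed = seeds[3])

  paths <- c(expression = file.path(out_dir, "expression.tsv"),
             labels = file.path(out_dir, "labels.tsv"),
             ppin = file.path(out_dir, "ppin.tsv"),
             similarity = file.path(out_dir, "similarity.tsv"),
             truth = file.path(out_dir, "truth_genes.txt"),
             blocks = file.path(out_dir, "block_truth.tsv"))
  write_expression(study$values, paths[["expression"]])
  write_labels(study$labels, paths[["labels"]])
  write_tsv(ppin, paths[["ppin"]], col.names = FALSE)
  write_similarity(sim, paths[["similarity"]])
  writeLines(study$deg_truth, paths[["truth"]])
  write_tsv(data.frame(gene = genes, block = unname(block_of)),
            paths[["blocks"]])
  invisible(paths)
}
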