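#' Planted-partition weighted network
#'
#' Draws a weighted benchmark graph with known community structure:
#' within-community edges appear with probability `p_in` and weights
#' uniform in `w_in`, cross-community edges with probability `p_out` and
#' weights in `w_out`. Nodes left isolated are rewired to one random
#' same-community partner (with a `w_in` weight) so the planted structure
#' stays intact while the search operators always have neighbours to work
#' with.
#'
#' @param n_nodes number of nodes (split as evenly as possible).
#' @param n_communities number of planted communities.
#' @param p_in,p_out edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param w_in,w_out length-2 weight ranges (positive).
#' @param seed integer seed.
#' @return list with `network` (weighted `igraph`, genes named `g001`...)
#'   and `labels` (integer community per node, named by gene).
#' @export
gen_planted_network <- function(n_nodes = 64L, n_communities = 4L,
                                p_in = 0.9, p_out = 0.05,
                                w_in = c(0.5, 1), w_out = c(0.05, 0.2),
                                seed = 1L) {
  stopifnot(n_nodes >= 2, n_communities >= 1,
            p_out >= 0, p_out < p_in, p_in <= 1,
            all(w_in > 0), all(w_out > 0))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  ids <- sprintf("g%03d", seq_len(n_nodes))
  labels <- sort(rep(seq_len(n_communities), length.out = n_nodes))
  pairs <- utils::combn(n_nodes, 2)
  same <- labels[pairs[1, ]] == labels[pairs[2, ]]
  prob <- ifelse(same, p_in, p_out)
  present <- stats::runif(ncol(pairs)) < prob
  w <- numeric(ncol(pairs))
  w[same] <- stats::runif(sum(same), w_in[1], w_in[2])
  w[!same] <- stats::runif(sum(!same), w_out[1], w_out[2])
  edges <- data.frame(from = ids[pairs[1, present]],
                      to = ids[pairs[2, present]],
                      weight = w[present], stringsAsFactors = FALSE)
  deg <- tabulate(c(pairs[1, present], pairs[2, present]), n_nodes)
  for (v in which(deg == 0)) {
    mates <- setdiff(which(labels == labels[v]), v)
    if (!length(mates)) mates <- setdiff(seq_len(n_nodes), v)
    u <- mates[sample.int(length(mates), 1L)]
    edges <- rbind(edges, data.frame(
      from = ids[min(u, v)], to = ids[max(u, v)],
      weight = stats::runif(1, w_in[1], w_in[2]), stringsAsFactors = FALSE))
  }
  net <- weighted_network(edges, vertices = ids)
  list(network = net, labels = stats::setNames(labels, ids))
}

#' Two-class expression matrix with co-expressed gene blocks
#'
#' Genes in each block share a latent sample factor scaled by the block
#' co-expression strength, plus independent Gaussian noise; blocks listed
#' in `affected_blocks` add `effect` to the disease samples, making their
#' genes the true differentially expressed genes. `n_background` pure
#' noise genes are appended.
#'
#' @param block_sizes integer vector of co-expression block sizes (each
#'   >= 2).
#' @param n_disease,n_control sample counts per class (each >= 2).
#' @param coexpr block co-expression strength (latent-factor loading,
#'   >= 0).
#' @param effect disease mean shift added to affected-block genes.
#' @param noise independent noise standard deviation (> 0).
#' @param n_background number of unstructured null genes.
#' @param affected_blocks indices of blocks carrying the disease effect
#'   (default: all blocks).
#' @param seed integer seed.
#' @return list with `values` (genes x samples matrix), `labels`
#'   (per-sample class, `disease`/`control`), `deg_truth` (true DEG ids)
#'   and `blocks` (list of gene-id vectors per block).
#' @export
gen_expression <- function(block_sizes = c(20L, 20L, 20L, 20L),
                           n_disease = 20L, n_control = 20L,
                           coexpr = 0.8, effect = 2, noise = 1,
                           n_background = 100L,
                           affected_blocks = seq_along(block_sizes),
                           seed = 1L) {
  stopifnot(all(block_sizes >= 2), n_disease >= 2, n_control >= 2,
            coexpr >= 0, noise > 0, n_background >= 0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  n_genes <- sum(block_sizes) + n_background
  n_samp <- n_disease + n_control
  genes <- sprintf("gene%04d", seq_len(n_genes))
  samples <- sprintf("s%03d", seq_len(n_samp))
  labels <- stats::setNames(c(rep("disease", n_disease),
                              rep("control", n_control)), samples)

  values <- matrix(stats::rnorm(n_genes * n_samp, sd = noise),
                   n_genes, n_samp, dimnames = list(genes, samples))
  blocks <- list()
  offset <- 0L
  for (b in seq_along(block_sizes)) {
    idx <- offset + seq_len(block_sizes[b])
    offset <- offset + block_sizes[b]
    blocks[[b]] <- genes[idx]
    factor_b <- stats::rnorm(n_samp)
    values[idx, ] <- values[idx, ] +
      coexpr * matrix(factor_b, length(idx), n_samp, byrow = TRUE)
    if (b %in% affected_blocks) {
      values[idx, labels == "disease"] <-
        values[idx, labels == "disease"] + effect
    }
  }
  deg_truth <- unlist(blocks[affected_blocks], use.names = FALSE)
  list(values = values, labels = labels,
       deg_truth = if (is.null(deg_truth)) character(0) else deg_truth,
       blocks = blocks)
}

#' Block-structured similarity matrix
#'
#' Stand-in for a semantic-similarity matrix with known community
#' structure: within-community entries are drawn from a clipped
#' `Normal(mu_in, sd)`, cross-community entries from
#' `Normal(mu_out, sd)`, symmetrised, with unit diagonal.
#'
#' @param labels community label per gene; names (if any) become the
#'   matrix dimnames.
#' @param mu_in,mu_out means, `0 <= mu_out < mu_in <= 1`.
#' @param sd normal spread (>= 0; 0 gives an exact two-valued matrix).
#' @param seed integer seed.
#' @return symmetric similarity matrix with entries in \[0, 1\].
#' @export
gen_similarity <- function(labels, mu_in = 0.8, mu_out = 0.2, sd = 0.05,
                           seed = 1L) {
  stopifnot(mu_out >= 0, mu_out < mu_in, mu_in <= 1, sd >= 0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  n <- length(labels)
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("g%03d", seq_len(n))
  same <- outer(labels, labels, "==")
  mu <- ifelse(same, mu_in, mu_out)
  sim <- matrix(stats::rnorm(n * n, mean = mu, sd = sd), n, n,
                dimnames = list(ids, ids))
  sim[upper.tri(sim)] <- t(sim)[upper.tri(sim)]
  sim <- pmin(pmax(sim, 0), 1)
  diag(sim) <- 1
  sim
}
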