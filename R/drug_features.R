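# Per-drug feature blocks: CHEM, a 256-bit folded circular (Morgan-style)
# fingerprint of the SMILES structure, and DGNet, a per-pathway z-score of
# random-walk-propagated drug-target influence over the PPI graph against a
# permutation null.

# deterministic integer hash of an integer vector, kept < 2^31
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483629)) %% 2147483629
  h
}

# molecular graph (heavy atoms + bond orders) from one SMILES via ChemmineR
smiles_graph <- function(smiles, drug_id = NULL) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e)
                    stop2("invalid SMILES", if (!is.null(drug_id))
                      paste0(" for drug ", drug_id), ": ", smiles))
  ab <- ChemmineR::atomblock(sdf[[1]])
  elements <- sub("_.*$", "", rownames(ab))
  bb <- tryCatch(ChemmineR::bondblock(sdf[[1]]), error = function(e) NULL)
  # bond-free molecules yield a placeholder block without the order column
  bonds <- if (is.null(bb) || nrow(bb) == 0 || ncol(bb) < 3 ||
               all(bb[, 1] == 0)) {
    base::matrix(numeric(0), 0, 3)
  } else {
    cbind(as.numeric(bb[, 1]), as.numeric(bb[, 2]), as.numeric(bb[, 3]))
  }
  list(elements = elements, bonds = bonds)
}

#' Fixed-length circular fingerprint of a molecule
#'
#' Iterative neighborhood hashing over the heavy-atom bond graph (ECFP-style
#' invariants: element, degree, summed bond orders), with every identifier
#' from radius 0 up to `radius` folded into `n_bits` bits.
#'
#' @param smiles SMILES string.
#' @param radius neighborhood radius (2 corresponds to ECFP4).
#' @param n_bits folded length (256 by default).
#' @param drug_id optional id used in error messages.
#' @return integer 0/1 vector of length `n_bits` with attribute `radius`.
#' @export
morgan_fingerprint <- function(smiles, radius = 2, n_bits = 256, drug_id = NULL) {
  g <- smiles_graph(smiles, drug_id)
  n <- length(g$elements)
  nbr <- vector("list", n)
  if (nrow(g$bonds) > 0) {
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds[i, 1]; b <- g$bonds[i, 2]; o <- g$bonds[i, 3]
      nbr[[a]] <- rbind(nbr[[a]], c(b, o))
      nbr[[b]] <- rbind(nbr[[b]], c(a, o))
    }
  }
  deg <- vapply(nbr, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  bond_sum <- vapply(nbr, function(x) if (is.null(x)) 0 else sum(x[, 2]), numeric(1))
  ids <- vapply(seq_len(n), function(i)
    hash_ints(c(utf8ToInt(g$elements[i]), deg[i], round(bond_sum[i] * 10))),
    numeric(1))
  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- ids
    for (i in seq_len(n)) {
      if (deg[i] == 0) { new_ids[i] <- hash_ints(c(ids[i], r)); next }
      env <- nbr[[i]]
      key <- ids[env[, 1]] * 8 + env[, 2]        # neighbor id + bond order
      new_ids[i] <- hash_ints(c(ids[i], sort(key)))
    }
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  bits <- integer(n_bits)
  bits[unique(floor(all_ids %% n_bits)) + 1] <- 1L
  attr(bits, "radius") <- radius
  bits
}

#' CHEM feature matrix for a drug table
#'
#' @param drugs data.frame from [read_drug_table()] or [generate_cohort()].
#' @param radius,n_bits see [morgan_fingerprint()].
#' @return drugs x n_bits binary matrix, rownames = drug ids.
#' @export
chem_matrix <- function(drugs, radius = 2, n_bits = 256) {
  out <- t(vapply(seq_len(nrow(drugs)), function(i)
    morgan_fingerprint(drugs$smiles[i], radius, n_bits, drugs$drug_id[i]),
    integer(n_bits)))
  rownames(out) <- drugs$drug_id
  colnames(out) <- sprintf("CHEM%03d", seq_len(n_bits))
  out
}

#' Random walk with restart over a weighted graph
#'
#' Solves p = r e + (1 - r) W p by power iteration, where W is the
#' column-normalized weighted adjacency (dangling columns teleport to the
#' restart distribution) and e is uniform over the seed genes.
#'
#' @param graph igraph with optional `weight` edge attribute.
#' @param seed_genes character vector; must intersect the graph's nodes.
#' @param restart_prob restart probability in (0, 1].
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return named probability vector over all nodes (sums to 1).
#' @export
rwr_propagate <- function(graph, seed_genes, restart_prob = 0.5,
                          tol = 1e-8, max_iter = 10000) {
  if (restart_prob <= 0 || restart_prob > 1)
    stop2("restart_prob must be in (0, 1]")
  nodes <- igraph::V(graph)$name
  seeds <- intersect(unique(seed_genes), nodes)
  if (length(seeds) == 0) stop2("no seed gene present in the graph")
  A <- as.matrix(igraph::as_adjacency_matrix(graph, attr =
    if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL,
    sparse = FALSE))
  e <- numeric(length(nodes)); names(e) <- nodes
  e[seeds] <- 1 / length(seeds)
  cs <- colSums(A)
  W <- A
  pos <- cs > 0
  W[, pos] <- sweep(A[, pos, drop = FALSE], 2, cs[pos], "/")
  if (any(!pos)) W[, !pos] <- e   # dangling nodes restart
  r <- restart_prob
  p <- e
  for (it in seq_len(max_iter)) {
    p_new <- r * e + (1 - r) * as.numeric(W %*% p)
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < tol) {
      names(p) <- nodes
      return(p)
    }
  }
  stop2("random walk did not converge after ", max_iter,
        " iterations (L1 residual ", signif(res, 3), ")")
}

#' Network-propagated target-to-pathway enrichment (DGNet features)
#'
#' The drug's targets seed a random walk with restart over the PPI graph; a
#' pathway's raw score is the mean stationary probability over its member
#' genes present in the graph. The null distribution comes from `n_perm`
#' uniformly drawn target sets of equal size, and the reported value is the
#' z-score of the raw score against that null.
#'
#' @param graph igraph PPI network.
#' @param drug one-row drug data.frame, or a list with `drug_id` and
#'   `targets`.
#' @param collection `gene_sets` collection (fixes feature order).
#' @param restart_prob restart probability.
#' @param n_perm permutation count for the null.
#' @param seed RNG seed.
#' @param null `"uniform"` (default) or `"degree_matched"` permutation draws.
#' @return named numeric vector of z-scores, one per pathway, with attribute
#'   `no_targets_in_graph` flagging drugs that produced an all-zero vector.
#' @export
netpea_scores <- function(graph, drug, collection, restart_prob = 0.5,
                          n_perm = 100, seed = 1,
                          null = c("uniform", "degree_matched")) {
  null <- match.arg(null)
  targets <- if (is.data.frame(drug)) drug$targets[[1]] else drug$targets
  drug_id <- if (is.data.frame(drug)) drug$drug_id[1] else drug$drug_id
  nodes <- igraph::V(graph)$name
  seeds <- intersect(unique(targets), nodes)
  z <- stats::setNames(numeric(length(collection)), names(collection))
  if (length(seeds) == 0) {
    warning("drug ", drug_id, " has no targets in the graph; DGNet set to 0")
    attr(z, "no_targets_in_graph") <- TRUE
    return(z)
  }
  path_idx <- lapply(collection, function(s) intersect(unique(s), nodes))
  empty <- lengths(path_idx) == 0
  if (any(empty))
    warning(sum(empty), " pathway(s) with zero graph overlap; DGNet imputed to 0")
  p_obs <- rwr_propagate(graph, seeds, restart_prob)
  raw <- vapply(path_idx, function(g) if (length(g)) mean(p_obs[g]) else NA_real_,
                numeric(1))
  k <- length(seeds)
  null_mat <- with_seed(seed, {
    draw <- if (null == "uniform") {
      function() sample(nodes, k)
    } else {
      degs <- igraph::degree(graph)
      bins <- cut(rank(degs, ties.method = "first"), breaks = 10, labels = FALSE)
      seed_bins <- bins[match(seeds, nodes)]
      function() vapply(seed_bins, function(b) sample(nodes[bins == b], 1), character(1))
    }
    t(vapply(seq_len(n_perm), function(i) {
      pp <- rwr_propagate(graph, draw(), restart_prob)
      vapply(path_idx, function(g) if (length(g)) mean(pp[g]) else NA_real_,
             numeric(1))
    }, numeric(length(collection))))
  })
  mu <- colMeans(null_mat)
  sd0 <- apply(null_mat, 2, stats::sd)
  zz <- (raw - mu) / sd0
  zz[!is.finite(zz)] <- 0
  z[] <- zz
  attr(z, "no_targets_in_graph") <- FALSE
  z
}

#' DGNet feature matrix for a drug table
#'
#' @param graph igraph PPI network.
#' @param drugs drug data.frame.
#' @param collection `gene_sets`.
#' @param ... passed to [netpea_scores()]; each drug gets a distinct
#'   deterministic child seed derived from `seed`.
#' @param seed base RNG seed.
#' @return drugs x pathways matrix of z-scores.
#' @export
dgnet_matrix <- function(graph, drugs, collection, seed = 1, ...) {
  out <- t(vapply(seq_len(nrow(drugs)), function(i)
    as.numeric(netpea_scores(graph, drugs[i, ], collection,
                             seed = child_seed(seed, drugs$drug_id[i]), ...)),
    numeric(length(collection))))
  dimnames(out) <- list(drugs$drug_id, paste0("DGNET_", names(collection)))
  out
}
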