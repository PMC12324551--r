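#' Spectral partition of the CNS graph into networks
#'
#' Symmetrises the input-fraction weights into an undirected affinity
#' `a[i, j] = (w[i, j] + w[j, i]) / 2` over the supplied (pruned) cell
#' population, computes the eigenvectors belonging to the k smallest
#' eigenvalues of the graph Laplacian, row-normalises each cell's
#' k-dimensional eigenvector loadings to unit norm, and applies k-means
#' to the resulting feature rows. The default k of 13 is the
#' coarse-grained resolution used for whole-CNS network maps.
#'
#' @param cn A [connectome].
#' @param cells Cell population to partition; should be the output of
#'   [prune_to_reciprocal_core()] so that every cell has both input and
#'   output partners. A cell disconnected from all others within the
#'   population is a contract violation and raises an error.
#' @param k Number of networks (default 13). `k = 1` labels all cells 1.
#' @param rng_seed Integer seed controlling the k-means restarts.
#' @param laplacian `"normalized"` (symmetric normalised Laplacian,
#'   matching the row-normalisation step) or `"unnormalized"`.
#' @param nstart k-means restarts (default 50; best inertia kept).
#' @return Tibble with `id` and integer `network` in 1..k.
#' @export
spectral_partition <- function(cn, cells, k = 13, rng_seed = 1,
                               laplacian = c("normalized", "unnormalized"),
                               nstart = 50) {
  stopifnot(inherits(cn, "connectome"), k >= 1)
  laplacian <- match.arg(laplacian)
  cells <- as.character(cells)
  stopifnot(length(cells) >= k)
  if (k == 1) {
    return(tibble::tibble(id = cells, network = 1L))
  }
  W <- build_weight_matrix(cn)$W
  idx <- match(cells, rownames(W))
  if (anyNA(idx)) stop("cells absent from connectome", call. = FALSE)
  Wsub <- W[idx, idx, drop = FALSE]
  A <- (Wsub + Matrix::t(Wsub)) / 2
  d <- Matrix::rowSums(A)
  if (any(d == 0)) {
    stop("cell(s) with no within-population partners; prune with ",
         "prune_to_reciprocal_core() first", call. = FALSE)
  }
  n <- length(cells)
  if (laplacian == "normalized") {
    Dinv <- Matrix::Diagonal(n, 1 / sqrt(d))
    L <- Matrix::Diagonal(n) - Dinv %*% A %*% Dinv
  } else {
    L <- Matrix::Diagonal(n, d) - A
  }
  L <- Matrix::forceSymmetric(L)
  X <- laplacian_eigenvectors(L, k)
  norms <- sqrt(rowSums(X^2))
  Y <- X
  ok <- norms > 0
  Y[ok, ] <- X[ok, , drop = FALSE] / norms[ok]
  km <- withr::with_seed(rng_seed, stats::kmeans(Y[ok, , drop = FALSE],
                                                 centers = k, nstart = nstart,
                                                 iter.max = 100))
  labels <- integer(n)
  labels[ok] <- km$cluster
  if (any(!ok)) {
    # numerically zero-norm feature rows: assign by nearest centroid in
    # raw eigenvector space rather than dropping the cell
    for (i in which(!ok)) {
      d2 <- colSums((t(km$centers) - X[i, ])^2)
      labels[i] <- which.min(d2)
    }
  }
  tibble::tibble(id = cells, network = as.integer(labels))
}

# Eigenvectors of the k smallest eigenvalues of a symmetric Laplacian.
laplacian_eigenvectors <- function(L, k) {
  n <- nrow(L)
  if (n <= 2000) {
    eig <- eigen(as.matrix(L), symmetric = TRUE)
    ord <- order(eig$values)
    return(eig$vectors[, ord[seq_len(k)], drop = FALSE])
  }
  res <- RSpectra::eigs_sym(L, k = k, sigma = -1e-10,
                            opts = list(maxitr = 5000))
  res$vectors[, order(res$values), drop = FALSE]
}

#' Proportion of synaptic partners outside a cell's own network
#'
#' For each labelled cell, the number of distinct synaptic partners (the
#' union of its presynaptic and postsynaptic partners within the labelled
#' population) assigned to a different network, divided by its total
#' number of distinct partners. Cells with no partners are excluded with
#' a message.
#'
#' @param cn A [connectome].
#' @param labels Tibble with `id`, `network` (e.g. from
#'   [spectral_partition()]).
#' @return Tibble with `id`, `network`, `n_partners`,
#'   `out_of_network_proportion`.
#' @export
out_of_network_proportion <- function(cn, labels) {
  stopifnot(inherits(cn, "connectome"),
            all(c("id", "network") %in% names(labels)))
  labels <- tibble::as_tibble(labels)
  net <- stats::setNames(labels$network, labels$id)
  e <- cn$edges[cn$edges$pre != cn$edges$post, c("pre", "post")]
  e <- e[e$pre %in% labels$id & e$post %in% labels$id, ]
  pairs <- unique(rbind(
    data.frame(cell = e$pre, partner = e$post),
    data.frame(cell = e$post, partner = e$pre)
  ))
  pairs$outside <- net[pairs$partner] != net[pairs$cell]
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(pairs), .data$cell),
    n_partners = dplyr::n_distinct(.data$partner),
    out_of_network_proportion = mean(.data$outside),
    .groups = "drop"
  )
  names(out)[names(out) == "cell"] <- "id"
  skipped <- setdiff(labels$id, out$id)
  if (length(skipped) > 0) {
    message(length(skipped), " labelled cell(s) with no partners excluded")
  }
  out$network <- net[out$id]
  out[, c("id", "network", "n_partners", "out_of_network_proportion")]
}

#' Network-to-network link strength matrix
#'
#' Entry (A, B) counts the distinct cells in network B that receive at
#' least `min_synapses` synapses from at least one cell in network A (the
#' aggregated synapse count of the directed cell pair is compared to the
#' threshold). The diagonal holds within-network counts.
#'
#' @param cn A [connectome].
#' @param labels Tibble with `id`, `network`.
#' @param min_synapses Minimum per-pair synapse count (default 1).
#' @return Integer matrix (#networks squared), dimnames = network labels.
#' @export
network_link_matrix <- function(cn, labels, min_synapses = 1) {
  stopifnot(inherits(cn, "connectome"),
            all(c("id", "network") %in% names(labels)))
  labels <- tibble::as_tibble(labels)
  nets <- sort(unique(labels$network))
  m <- matrix(0L, length(nets), length(nets),
              dimnames = list(as.character(nets), as.character(nets)))
  e <- cn$edges[cn$edges$pre %in% labels$id & cn$edges$post %in% labels$id,
                c("pre", "post", "count")]
  if (nrow(e) == 0) return(m)
  agg <- dplyr::summarise(
    dplyr::group_by(e, .data$pre, .data$post),
    count = sum(.data$count), .groups = "drop"
  )
  agg <- agg[agg$count >= min_synapses, ]
  if (nrow(agg) == 0) return(m)
  net <- stats::setNames(labels$network, labels$id)
  agg$net_pre <- as.character(net[agg$pre])
  agg$net_post <- as.character(net[agg$post])
  counts <- dplyr::summarise(
    dplyr::group_by(agg, .data$net_pre, .data$net_post),
    n_cells = dplyr::n_distinct(.data$post), .groups = "drop"
  )
  for (r in seq_len(nrow(counts))) {
    m[counts$net_pre[r], counts$net_post[r]] <- counts$n_cells[r]
  }
  m
}
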