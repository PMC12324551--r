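#' Direct-connectivity feature vectors
#'
#' For each cell in `cells`, the concatenation of its output synapse
#' counts onto every cell in the connectome and its input synapse counts
#' from every cell (both pre- and postsynaptic connectivity). Cells with
#' no connections at all are excluded (their feature vector would have
#' zero norm) and recorded in the `"excluded"` attribute.
#'
#' @param cn A [connectome].
#' @param cells Character vector of cell ids to featurise.
#' @return Sparse matrix, rows = cells, columns = `out:<id>` then
#'   `in:<id>` over all connectome cells.
#' @export
connectivity_features <- function(cn, cells) {
  stopifnot(inherits(cn, "connectome"))
  cells <- as.character(cells)
  if (length(cells) == 0) stop("cells must be nonempty", call. = FALSE)
  stopifnot(all(cells %in% cn$cells$id))
  ids <- cn$cells$id
  n <- length(ids)
  e <- cn$edges
  C <- Matrix::sparseMatrix(
    i = match(e$pre, ids), j = match(e$post, ids), x = as.numeric(e$count),
    dims = c(n, n), dimnames = list(ids, ids)
  )
  ridx <- match(cells, ids)
  out_block <- C[ridx, , drop = FALSE]            # outputs onto partners
  in_block <- Matrix::t(C)[ridx, , drop = FALSE]  # inputs from partners
  F <- cbind(out_block, in_block)
  colnames(F) <- c(paste0("out:", ids), paste0("in:", ids))
  rownames(F) <- cells
  norms <- sqrt(Matrix::rowSums(F^2))
  excluded <- cells[norms == 0]
  if (length(excluded) > 0) {
    message(length(excluded), " cell(s) with no connections excluded from features")
    F <- F[norms > 0, , drop = FALSE]
  }
  attr(F, "excluded") <- excluded
  F
}

#' Received-influence feature vectors
#'
#' Transposes a seeds-by-targets matrix of adjusted influence scores into
#' a feature matrix whose rows are target (e.g. effector) cells and whose
#' columns are the individual seed cells (e.g. ascending/descending
#' neurons). All-zero rows (targets unreachable from every seed, floored
#' at 0) are retained.
#'
#' @param scores Numeric matrix, rows = seeds, columns = targets, no
#'   missing values.
#' @return Numeric matrix, rows = targets, columns = seeds.
#' @export
influence_features <- function(scores) {
  scores <- as.matrix(scores)
  if (any(is.na(scores))) stop("scores contain missing values", call. = FALSE)
  t(scores)
}

#' Cosine similarity between feature rows
#'
#' `sim(u, v) = <u, v> / (|u| |v|)`; symmetric with unit diagonal. For
#' nonnegative features all entries lie in `[0, 1]`.
#'
#' @param F Feature matrix (rows = cells); no row may have zero norm.
#' @return Dense symmetric similarity matrix.
#' @export
cosine_similarity <- function(F) {
  F <- as.matrix(F)
  norms <- sqrt(rowSums(F^2))
  if (any(norms == 0)) {
    stop("zero-norm feature row(s): ",
         paste(utils::head(rownames(F)[norms == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  Fn <- F / norms
  S <- tcrossprod(Fn)
  S[S > 1] <- 1
  S[S < -1] <- -1
  diag(S) <- 1
  S
}

#' Two-dimensional neighbourhood embedding
#'
#' Embeds cells into 2-D with UMAP, preserving local neighbourhood
#' structure. Input is either a feature matrix (with a cosine metric by
#' default, which induces the same neighbourhoods as the cosine
#' similarity matrix) or a precomputed `dist` object. The random seed is
#' fixed and the embedding is single-threaded, so identical inputs and
#' seed give identical coordinates.
#'
#' @param x Feature matrix (rows = cells) or a `dist` object.
#' @param rng_seed Integer seed.
#' @param n_neighbors UMAP neighbourhood size (default 15; also the
#'   minimum number of cells accepted).
#' @param metric Distance metric for feature-matrix input.
#' @param min_dist UMAP min_dist parameter.
#' @return Numeric matrix (n x 2) with rownames.
#' @export
embed_2d <- function(x, rng_seed = 1, n_neighbors = 15, metric = "cosine",
                     min_dist = 0.1) {
  n <- if (inherits(x, "dist")) attr(x, "Size") else nrow(x)
  if (n < 15) {
    stop("need at least 15 cells to embed; cluster the features directly instead",
         call. = FALSE)
  }
  input <- if (inherits(x, "dist")) x else as.matrix(x)
  coords <- withr::with_seed(
    rng_seed,
    uwot::umap(input, n_neighbors = min(n_neighbors, n - 1), metric = metric,
               min_dist = min_dist, n_threads = 1, n_sgd_threads = 0)
  )
  if (!inherits(x, "dist") && !is.null(rownames(x))) {
    rownames(coords) <- rownames(x)
  }
  colnames(coords) <- c("x", "y")
  coords
}

# Gap-ratio thresholds for the adaptive dendrogram cut; higher deep_split
# splits more aggressively (lower required gap).
deep_split_thresholds <- c(`0` = 8, `1` = 5, `2` = 3.5, `3` = 2.5, `4` = 2)

#' Adaptive cut of a Ward dendrogram in embedding space
#'
#' Builds a Ward-linkage dendrogram on Euclidean distances between 2-D
#' embedding coordinates and cuts it adaptively: the number of clusters is
#' the largest k whose merge-height gap ratio (the ratio between the
#' heights bounding the k-cluster cut) exceeds a threshold controlled by
#' `deep_split` (0 = conservative ... 4 = aggressive). If no gap is large
#' enough the points form a single cluster. Clusters smaller than
#' `min_size` are labelled 0 (unassigned outliers).
#'
#' @param coords Numeric matrix (n x 2) of embedding coordinates with
#'   rownames, e.g. from [embed_2d()].
#' @param deep_split Integer 0-4 (default 4).
#' @param min_size Minimum cluster size (default 5).
#' @param max_k Cap on the number of clusters considered.
#' @return Tibble with `id`, `cluster` (integer; 0 = unassigned); the
#'   number of clusters is in `attr(, "k")`.
#' @export
cut_clusters <- function(coords, deep_split = 4, min_size = 5, max_k = 25) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (min_size > n) stop("min_size exceeds the number of points", call. = FALSE)
  stopifnot(deep_split %in% 0:4)
  ids <- rownames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  hc <- stats::hclust(stats::dist(coords), method = "ward.D2")
  heights <- hc$height  # ascending, length n - 1
  threshold <- deep_split_thresholds[[as.character(deep_split)]]
  kmax <- min(max_k, floor(n / min_size), n - 1)
  k <- 1L
  if (kmax >= 2) {
    for (kk in 2:kmax) {
      upper <- heights[n - kk + 1]
      lower <- heights[n - kk]
      if (lower <= 0) next
      if (upper / lower >= threshold) k <- kk
    }
  }
  labels <- if (k == 1) rep(1L, n) else stats::cutree(hc, k = k)
  sizes <- table(labels)
  small <- as.integer(names(sizes)[sizes < min_size])
  labels[labels %in% small] <- 0L
  # relabel surviving clusters 1..K in order of first appearance
  surviving <- unique(labels[labels != 0])
  relabel <- stats::setNames(seq_along(surviving), surviving)
  labels[labels != 0] <- relabel[as.character(labels[labels != 0])]
  out <- tibble::tibble(id = ids, cluster = as.integer(labels))
  attr(out, "k") <- length(surviving)
  attr(out, "deep_split") <- deep_split
  attr(out, "min_size") <- min_size
  out
}

#' Attach supercluster labels to a cluster assignment
#'
#' Superclusters are a user-supplied many-to-one lumping of clusters
#' (grouping related clusters by shared influence patterns and known
#' cells is a judgement call, not automated here).
#'
#' @param assignment Tibble with `id`, `cluster` (from [cut_clusters()]).
#' @param lookup Tibble with `cluster`, `supercluster`.
#' @return The assignment with a `supercluster` column (NA for clusters
#'   absent from the lookup and for unassigned cells).
#' @export
assign_superclusters <- function(assignment, lookup) {
  stopifnot(all(c("id", "cluster") %in% names(assignment)),
            all(c("cluster", "supercluster") %in% names(lookup)))
  dplyr::left_join(tibble::as_tibble(assignment), tibble::as_tibble(lookup),
                   by = "cluster")
}

cluster_id_sets <- function(assignment) {
  assignment <- tibble::as_tibble(assignment)
  col <- if ("supercluster" %in% names(assignment) &&
             !all(is.na(assignment$supercluster))) "supercluster" else "cluster"
  keep <- !is.na(assignment[[col]]) & assignment[[col]] != 0
  split(assignment$id[keep], as.character(assignment[[col]][keep]))
}

#' Mean adjusted influence between clusters and annotated cell groups
#'
#' Summarises the influence either received by each (super)cluster from
#' named groups of cells (`direction = "onto_clusters"`, e.g. sensor
#' pools) or sent by each (super)cluster onto named groups
#' (`direction = "from_clusters"`, e.g. effector pools). Rows are
#' (super)clusters; columns are groups. Empty groups are dropped with a
#' message. Optionally each row is minmax-normalised to `[0, 1]`.
#'
#' @param wm A (rescaled) `weight_matrix`.
#' @param assignment Tibble with `id`, `cluster` and optionally
#'   `supercluster` (used if present).
#' @param groups Named list of character id vectors.
#' @param direction `"onto_clusters"` or `"from_clusters"`.
#' @param normalize Minmax-normalise rows (default `TRUE`).
#' @return Numeric matrix (#clusters x #groups).
#' @export
group_influence_summary <- function(wm, assignment, groups,
                                    direction = c("onto_clusters", "from_clusters"),
                                    normalize = TRUE) {
  direction <- match.arg(direction)
  clusters <- cluster_id_sets(assignment)
  sizes <- lengths(groups)
  if (any(sizes == 0)) {
    message("dropping empty group(s): ",
            paste(names(groups)[sizes == 0], collapse = ", "))
    groups <- groups[sizes > 0]
  }
  stopifnot(length(groups) > 0, length(clusters) > 0)
  if (direction == "onto_clusters") {
    m <- influence_matrix(wm, seed_groups = groups, target_groups = clusters)
    m <- t(m)
  } else {
    m <- influence_matrix(wm, seed_groups = clusters, target_groups = groups)
  }
  if (normalize) m <- t(apply(m, 1, minmax_scale))
  m
}

#' Supercluster-by-supercluster influence matrix
#'
#' Entry (g, h) is the adjusted pooled influence of supercluster g's
#' cells onto supercluster h's cells, normalised by both pool sizes (the
#' `1/(N*M)` pooled form). The diagonal is self-influence, reported but
#' flagged via the `"self"` attribute.
#'
#' @param wm A (rescaled) `weight_matrix`.
#' @param assignment Tibble with `id` and `cluster`/`supercluster`.
#' @return Numeric matrix (#superclusters squared).
#' @export
cross_cluster_influence <- function(wm, assignment) {
  clusters <- cluster_id_sets(assignment)
  if (length(clusters) < 2) stop("need at least 2 (super)clusters", call. = FALSE)
  m <- influence_matrix(wm, seed_groups = clusters, target_groups = clusters,
                        include_seed_targets = TRUE)
  attr(m, "self") <- diag(m)
  m
}
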