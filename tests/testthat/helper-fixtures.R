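# Fixture builders shared across test files. All fixtures are constructed
# in code; nothing is read from disk except through temp files written
# here.

toy_edges <- function(...) {
  rows <- list(...)
  tibble::tibble(
    pre = vapply(rows, `[[`, "", 1),
    post = vapply(rows, `[[`, "", 2),
    count = as.integer(vapply(rows, `[[`, 0, 3))
  )
}

# A -> C (3), B -> C (1): hand-normalised weights 0.75 / 0.25.
fan_in_connectome <- function() {
  connectome(toy_edges(list("A", "C", 3), list("B", "C", 1)))
}

# Two-cell cycle A <-> B, both weights 1 before rescale.
cycle_connectome <- function(count = 5L) {
  connectome(toy_edges(list("A", "B", count), list("B", "A", count)))
}

write_edge_file <- function(tab, delim = ",") {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_delim(tab, path, delim = delim)
  path
}

# Random sparse nonnegative matrix wrapped as a connectome guaranteed to
# contain a cycle (positive spectral radius).
random_cyclic_connectome <- function(n = 30, p = 0.15, seed = 1) {
  withr::with_seed(seed, {
    grid <- expand.grid(pre = paste0("c", seq_len(n)),
                        post = paste0("c", seq_len(n)),
                        stringsAsFactors = FALSE)
    grid <- grid[grid$pre != grid$post, ]
    grid <- grid[stats::runif(nrow(grid)) < p, ]
    grid$count <- 1L + stats::rpois(nrow(grid), 3)
  })
  # ensure at least one 2-cycle
  grid <- rbind(grid, data.frame(pre = c("c1", "c2"), post = c("c2", "c1"),
                                 count = c(4L, 4L)))
  grid <- grid[!duplicated(grid[, c("pre", "post")]), ]
  connectome(grid)
}

# Gaussian point blobs with known membership (oracle for cut_clusters).
make_blobs <- function(centers, n_each = 20, spread = 0.5, seed = 1) {
  withr::with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      cbind(stats::rnorm(n_each, centers[i, 1], spread),
            stats::rnorm(n_each, centers[i, 2], spread))
    }))
  })
  rownames(pts) <- paste0("p", seq_len(nrow(pts)))
  list(coords = pts, membership = rep(seq_len(nrow(centers)), each = n_each))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
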