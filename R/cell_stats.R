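# Per-cell synapse-site statistics. A site record describes one synaptic
# link from the perspective of one cell: role ("presynaptic" when the
# cell is the transmitting side, "postsynaptic" when it receives), side
# (-1 left / +1 right), region ("brain"/"vnc"), compartment
# ("axon"/"dendrite").

check_sites <- function(sites, need = character(0)) {
  sites <- tibble::as_tibble(sites)
  stopifnot("role" %in% names(sites))
  if (!all(sites$role %in% c("presynaptic", "postsynaptic"))) {
    stop("role must be 'presynaptic' or 'postsynaptic'", call. = FALSE)
  }
  for (col in need) {
    if (!col %in% names(sites) || anyNA(sites[[col]])) {
      stop("site records must carry a complete '", col, "' column",
           call. = FALSE)
    }
  }
  sites
}

#' Laterality index of one cell
#'
#' Each synaptic site is signed by its anatomical side (-1 left, +1
#' right). The index is `1 - |mean postsynaptic side - mean presynaptic
#' side|`: 1 for a cell whose inputs and outputs sit on the same side (or
#' are equally balanced), down to -1 when inputs and outputs lie fully on
#' opposite sides.
#'
#' @param sites Site records for one cell with columns `role` and `side`.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
laterality_index <- function(sites) {
  sites <- check_sites(sites, "side")
  if (!all(sites$side %in% c(-1, 1))) {
    stop("side must be -1 (left) or +1 (right)", call. = FALSE)
  }
  post <- sites$side[sites$role == "postsynaptic"]
  pre <- sites$side[sites$role == "presynaptic"]
  if (length(post) == 0 || length(pre) == 0) {
    stop("need at least one presynaptic and one postsynaptic site",
         call. = FALSE)
  }
  1 - abs(mean(post) - mean(pre))
}

binary_entropy <- function(p) {
  ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
}

#' Axon/dendrite segregation index of one cell
#'
#' Quantifies how cleanly a cell's inputs and outputs separate into its
#' axonal and dendritic compartments, via the entropy of the
#' postsynaptic fraction per compartment: with `p_k` the fraction of
#' compartment k's sites that are postsynaptic,
#' `H = sum_k (n_k / n) h(p_k)` (h = binary entropy) and
#' `H0 = h(overall postsynaptic fraction)`, the index is `1 - H / H0`
#' (0 when `H0 = 0`). 1 means fully polarised (all inputs on the
#' dendrite, all outputs on the axon); 0 means no segregation.
#'
#' @param sites Site records for one cell with columns `role` and
#'   `compartment`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
segregation_index <- function(sites) {
  sites <- check_sites(sites, "compartment")
  n <- nrow(sites)
  if (n == 0) stop("no site records", call. = FALSE)
  p0 <- mean(sites$role == "postsynaptic")
  H0 <- binary_entropy(p0)
  if (H0 == 0) return(0)
  H <- 0
  for (comp in unique(sites$compartment)) {
    sub <- sites[sites$compartment == comp, ]
    H <- H + nrow(sub) / n * binary_entropy(mean(sub$role == "postsynaptic"))
  }
  max(0, min(1, 1 - H / H0))
}

#' Fraction of a cell's output sites located in the nerve cord
#'
#' Over the cell's presynaptic (output) site records, the fraction that
#' lie in the VNC rather than the brain.
#'
#' @param sites Site records for one cell with columns `role` and
#'   `region` ("brain"/"vnc").
#' @return Numeric scalar in `[0, 1]`.
#' @export
region_output_fraction <- function(sites) {
  sites <- check_sites(sites, "region")
  pre <- sites[sites$role == "presynaptic", ]
  if (nrow(pre) == 0) stop("no presynaptic site records", call. = FALSE)
  if (!all(pre$region %in% c("brain", "vnc"))) {
    stop("region must be 'brain' or 'vnc'", call. = FALSE)
  }
  mean(pre$region == "vnc")
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Standard two-sample KS statistic (supremum distance between empirical
#' CDFs) with its asymptotic p-value.
#'
#' @param sample_a,sample_b Nonempty numeric vectors.
#' @return List with `statistic` and `p_value`.
#' @export
compare_distributions <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(sample_a, sample_b))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}
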