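# Input-fraction rows used by both traversal models: W[i, j] = fraction of
# cell i's input synapses arriving from cell j (no stability rescaling).
input_fraction_matrix <- function(cn) {
  build_weight_matrix(cn)$W
}

traversal_result <- function(order, first_round_sum, reached_count, replicates,
                             rng_seed, model) {
  layer <- ifelse(reached_count > 0, first_round_sum / reached_count, NA_real_)
  tibble::tibble(
    id = order,
    layer = layer,
    reached = reached_count > 0,
    reach_frequency = reached_count / replicates
  ) |>
    structure(replicates = replicates, rng_seed = rng_seed, model = model)
}

#' Signal-cascade activation layers
#'
#' Probabilistic traversal in which activity spreads in discrete rounds:
#' in each round, a never-activated cell becomes active with probability
#' `min(1, activation_scale * f)`, where `f` is the fraction of its input
#' synapses arriving from cells active in the previous round. Activated
#' cells transmit for one round and then deactivate permanently (each
#' neuron fires at most once), so the model traces a temporal wave of
#' first activations. Seeds are active in round 0 and carry layer 0.
#'
#' @param cn A [connectome].
#' @param seeds Nonempty character vector of seed ids.
#' @param activation_scale Multiplier on the input fraction (> 0); large
#'   values force deterministic breadth-first spread.
#' @param replicates Number of stochastic replicates to average.
#' @param rng_seed Integer seed; equal seeds give identical results.
#' @param max_rounds Safety cap on rounds per replicate.
#' @return Tibble with `id`, `layer` (mean first-activation round over the
#'   replicates in which the cell activated; NA if never reached),
#'   `reached`, `reach_frequency`.
#' @export
cascade_layers <- function(cn, seeds, activation_scale = 1, replicates = 100,
                           rng_seed = 1, max_rounds = 200) {
  stopifnot(inherits(cn, "connectome"))
  if (activation_scale <= 0) stop("activation_scale must be > 0", call. = FALSE)
  W <- input_fraction_matrix(cn)
  order <- rownames(W)
  seeds <- as.character(seeds)
  if (length(seeds) == 0 || !all(seeds %in% order)) {
    stop("seeds must be a nonempty subset of connectome cells", call. = FALSE)
  }
  seed_idx <- match(seeds, order)
  n <- length(order)
  first_sum <- numeric(n)
  reach_count <- integer(n)

  withr::with_seed(rng_seed, {
    for (rep in seq_len(replicates)) {
      first_round <- rep(NA_integer_, n)
      first_round[seed_idx] <- 0L
      active <- logical(n)
      active[seed_idx] <- TRUE
      round <- 0L
      while (any(active) && round < max_rounds) {
        round <- round + 1L
        f <- as.numeric(W %*% as.numeric(active))
        p <- pmin(1, activation_scale * f)
        candidates <- which(is.na(first_round) & p > 0)
        fired <- candidates[stats::runif(length(candidates)) < p[candidates]]
        active <- logical(n)
        if (length(fired) > 0) {
          first_round[fired] <- round
          active[fired] <- TRUE
        }
      }
      hit <- !is.na(first_round)
      first_sum[hit] <- first_sum[hit] + first_round[hit]
      reach_count <- reach_count + hit
    }
  })
  traversal_result(order, first_sum, reach_count, replicates, rng_seed,
                   model = "cascade")
}

#' Information-flow recruitment ranks
#'
#' Probabilistic traversal with persistent activation: once recruited, a
#' cell keeps contributing ("ongoing activation"). In each round an
#' unrecruited cell is recruited with probability `min(1, f / ramp_cap)`,
#' where `f` is the fraction of its input synapses from already-recruited
#' cells; cells receiving at least `ramp_cap` of their input from the
#' recruited set are recruited with certainty. The mean recruitment round
#' is the cell's rank, reflecting its integration point in the circuit.
#'
#' @param cn A [connectome].
#' @param seeds Nonempty character vector of seed ids (rank 0).
#' @param ramp_cap Input fraction at which recruitment saturates, in
#'   `(0, 1]` (default 0.3).
#' @param replicates Number of stochastic replicates.
#' @param rng_seed Integer seed; equal seeds give identical ranks.
#' @param max_rounds Cap on rounds per replicate.
#' @return Tibble as in [cascade_layers()] (`layer` = mean recruitment
#'   round).
#' @export
info_flow_ranks <- function(cn, seeds, ramp_cap = 0.3, replicates = 100,
                            rng_seed = 1, max_rounds = 200) {
  stopifnot(inherits(cn, "connectome"))
  if (ramp_cap <= 0 || ramp_cap > 1) {
    stop("ramp_cap must be in (0, 1]", call. = FALSE)
  }
  W <- input_fraction_matrix(cn)
  order <- rownames(W)
  seeds <- as.character(seeds)
  if (length(seeds) == 0 || !all(seeds %in% order)) {
    stop("seeds must be a nonempty subset of connectome cells", call. = FALSE)
  }
  seed_idx <- match(seeds, order)
  n <- length(order)
  first_sum <- numeric(n)
  reach_count <- integer(n)

  withr::with_seed(rng_seed, {
    for (rep in seq_len(replicates)) {
      round_recruited <- rep(NA_integer_, n)
      round_recruited[seed_idx] <- 0L
      recruited <- logical(n)
      recruited[seed_idx] <- TRUE
      round <- 0L
      repeat {
        round <- round + 1L
        f <- as.numeric(W %*% as.numeric(recruited))
        p <- pmin(1, f / ramp_cap)
        candidates <- which(!recruited & p > 0)
        if (length(candidates) == 0 || round > max_rounds) break
        joined <- candidates[stats::runif(length(candidates)) < p[candidates]]
        if (length(joined) > 0) {
          round_recruited[joined] <- round
          recruited[joined] <- TRUE
        }
      }
      hit <- !is.na(round_recruited)
      first_sum[hit] <- first_sum[hit] + round_recruited[hit]
      reach_count <- reach_count + hit
    }
  })
  traversal_result(order, first_sum, reach_count, replicates, rng_seed,
                   model = "infoflow")
}

#' Regress adjusted influence on traversal layer
#'
#' Ordinary least squares of adjusted influence against layer/rank; used
#' to check that influence decays (approximately linearly on the log
#' scale) with network distance.
#'
#' @param adjusted Numeric vector of adjusted influence scores.
#' @param layers Numeric vector of layers/ranks (same length).
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
influence_layer_regression <- function(adjusted, layers) {
  keep <- is.finite(adjusted) & is.finite(layers)
  x <- layers[keep]
  y <- adjusted[keep]
  if (length(x) < 3) stop("need at least 3 finite paired points", call. = FALSE)
  if (stats::var(x) == 0) stop("layers have zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    n = length(x)
  )
}
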