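resolve_ids <- function(wm, ids, what) {
  ids <- as.character(ids)
  missing <- setdiff(ids, wm$order)
  if (length(missing) > 0) {
    stop(what, " not in weight matrix order: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ids
}

#' Steady-state activity for a seed set
#'
#' Solves the steady state of the linear rate dynamics
#' `tau * dr/dt = -r + W r + s`, i.e. `(I - W) r = s`, where `s` is 1 on
#' the seed cells and 0 elsewhere. The time constant `tau` sets the speed
#' of approach but not the steady state itself. Seed entries include their
#' own recurrent drive. Solved with a sparse direct factorisation; the
#' residual is checked against `1e-8`.
#'
#' @param wm A (rescaled) `weight_matrix`.
#' @param seeds Character vector of seed cell ids; an empty vector queries
#'   the zero response.
#' @return Named numeric vector of steady-state activity per cell.
#' @export
steady_state_activity <- function(wm, seeds) {
  stopifnot(inherits(wm, "weight_matrix"))
  seeds <- resolve_ids(wm, seeds, "seed id(s)")
  n <- length(wm$order)
  s <- numeric(n)
  s[match(seeds, wm$order)] <- 1
  if (length(seeds) == 0) {
    r <- numeric(n)
  } else {
    A <- Matrix::Diagonal(n) - wm$W
    r <- tryCatch(
      as.numeric(Matrix::solve(A, s)),
      error = function(e) {
        stop("steady-state solve failed (matrix may be singular; ",
             "was the weight matrix rescaled below radius 1?): ",
             conditionMessage(e), call. = FALSE)
      }
    )
    resid <- max(abs(as.numeric(A %*% r) - s))
    if (resid > 1e-8) {
      stop(sprintf("steady-state residual %.3g exceeds 1e-8", resid),
           call. = FALSE)
    }
    # (I - W)^-1 = sum_k W^k is nonnegative; clip solver roundoff
    if (any(r < -1e-9)) {
      stop("steady state has negative entries beyond roundoff", call. = FALSE)
    }
    r[r < 0] <- 0
  }
  names(r) <- wm$order
  r
}

#' Adjusted influence score
#'
#' Log-transforms a (pooled) mean steady-state activity and adds a fixed
#' offset so that typical scores are nonnegative:
#' `adjusted = log(rbar) + offset`, floored at 0. Cells effectively
#' disconnected from the seed (mean activity 0, or log + offset below 0)
#' score exactly 0. The default offset of 24 places scores for
#' well-connected cells in a convenient positive range (natural log).
#'
#' @param mean_activity Nonnegative numeric vector of pooled mean
#'   steady-state activities.
#' @param offset Additive offset constant (default 24).
#' @return Numeric vector of adjusted influence scores (all >= 0).
#' @export
adjusted_influence <- function(mean_activity, offset = 24) {
  if (any(is.na(mean_activity)) || any(mean_activity < 0)) {
    stop("mean_activity must be nonnegative", call. = FALSE)
  }
  out <- ifelse(mean_activity > 0, log(mean_activity) + offset, 0)
  pmax(out, 0)
}

#' Pooled influence of a seed pool on a target pool
#'
#' Averages steady-state responses over a seed pool S (|S| = M) and a
#' target pool T (|T| = N): `rbar = 1/(N*M) * sum_{i in S, j in T} r_ij`.
#' Because the steady state is linear in the seed vector, stimulating all
#' seeds simultaneously in one solve (`mode = "simultaneous"`) gives the
#' same value as averaging M individual-seed solves
#' (`mode = "per-seed-average"`).
#'
#' Targets that are themselves seeds are excluded from the pool mean by
#' default (their self-drive would dominate); set
#' `include_seed_targets = TRUE` to keep them. If every target is a seed,
#' they are included with a message (the mean is otherwise undefined).
#'
#' @param wm A (rescaled) `weight_matrix`.
#' @param seed_pool Character vector of seed ids (nonempty).
#' @param target_pool Character vector of target ids (nonempty).
#' @param mode `"simultaneous"` (one solve) or `"per-seed-average"`.
#' @param include_seed_targets Keep seed cells in the target mean.
#' @param offset Offset passed to [adjusted_influence()].
#' @return List with `mean_activity`, `adjusted`, `targets_used`,
#'   `excluded_seed_targets` and `seed_activity` (per-seed steady-state
#'   self-responses, reported even when excluded from the mean).
#' @export
pooled_influence <- function(wm, seed_pool, target_pool,
                             mode = c("simultaneous", "per-seed-average"),
                             include_seed_targets = FALSE, offset = 24) {
  mode <- match.arg(mode)
  seed_pool <- resolve_ids(wm, seed_pool, "seed id(s)")
  target_pool <- resolve_ids(wm, target_pool, "target id(s)")
  if (length(seed_pool) == 0) stop("seed pool is empty", call. = FALSE)
  if (length(target_pool) == 0) stop("target pool is empty", call. = FALSE)

  excluded <- character(0)
  targets_used <- target_pool
  if (!include_seed_targets) {
    excluded <- intersect(target_pool, seed_pool)
    targets_used <- setdiff(target_pool, seed_pool)
    if (length(targets_used) == 0) {
      message("all targets are seeds; including seed targets in the pool mean")
      targets_used <- target_pool
      excluded <- character(0)
    }
  }
  M <- length(seed_pool)
  N <- length(targets_used)
  t_idx <- match(targets_used, wm$order)

  if (mode == "simultaneous") {
    r <- steady_state_activity(wm, seed_pool)
    total <- sum(r[t_idx])
    seed_activity <- r[match(seed_pool, wm$order)]
  } else {
    total <- 0
    seed_activity <- numeric(M)
    for (k in seq_len(M)) {
      r <- steady_state_activity(wm, seed_pool[k])
      total <- total + sum(r[t_idx])
      seed_activity[k] <- r[match(seed_pool[k], wm$order)]
    }
  }
  names(seed_activity) <- seed_pool
  rbar <- total / (N * M)
  list(
    mean_activity = rbar,
    adjusted = adjusted_influence(rbar, offset),
    targets_used = targets_used,
    excluded_seed_targets = excluded,
    seed_activity = seed_activity
  )
}

#' Batched group-by-group influence matrix
#'
#' Computes the adjusted pooled influence of every seed group onto every
#' target group, using one simultaneous solve per seed group. Entry (g, h)
#' is `adjusted_influence` of the `1/(N*M)` pooled mean of seed group g on
#' target group h. Groups that overlap (a seed group sharing cells with a
#' target group) are reported via the `"overlaps"` attribute, not
#' excluded.
#'
#' @param wm A (rescaled) `weight_matrix`.
#' @param seed_groups Named list of character id vectors.
#' @param target_groups Named list of character id vectors.
#' @param normalize Minmax-normalise each row to `[0, 1]` (a constant row
#'   maps to all zeros).
#' @param include_seed_targets Passed to the pooled mean; default `FALSE`
#'   (seed cells inside a target group are dropped from that group's
#'   mean).
#' @param offset Offset for [adjusted_influence()].
#' @return Numeric matrix (#seed groups x #target groups).
#' @export
influence_matrix <- function(wm, seed_groups, target_groups,
                             normalize = FALSE, include_seed_targets = FALSE,
                             offset = 24) {
  stopifnot(length(seed_groups) > 0, length(target_groups) > 0)
  if (is.null(names(seed_groups))) {
    names(seed_groups) <- paste0("seed_", seq_along(seed_groups))
  }
  if (is.null(names(target_groups))) {
    names(target_groups) <- paste0("target_", seq_along(target_groups))
  }
  out <- matrix(0, length(seed_groups), length(target_groups),
                dimnames = list(names(seed_groups), names(target_groups)))
  overlaps <- list()
  for (g in names(seed_groups)) {
    seeds <- resolve_ids(wm, seed_groups[[g]], "seed id(s)")
    r <- steady_state_activity(wm, seeds)
    M <- length(seeds)
    for (h in names(target_groups)) {
      targets <- resolve_ids(wm, target_groups[[h]], "target id(s)")
      shared <- intersect(seeds, targets)
      if (length(shared) > 0) overlaps[[paste(g, h, sep = "->")]] <- shared
      used <- if (include_seed_targets) targets else setdiff(targets, seeds)
      if (length(used) == 0) used <- targets
      rbar <- sum(r[match(used, wm$order)]) / (length(used) * M)
      out[g, h] <- adjusted_influence(rbar, offset)
    }
  }
  if (normalize) out <- t(apply(out, 1, minmax_scale))
  attr(out, "overlaps") <- overlaps
  out
}

# Minmax scaling of a numeric vector to [0, 1]; a constant vector maps to
# zeros (the row carries no contrast).
minmax_scale <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Direct-connection flags for a seed set
#'
#' A target is "direct" if it receives at least one synapse from any seed
#' cell, i.e. its weight-matrix row has a nonzero entry in a seed column.
#'
#' @param wm A `weight_matrix`.
#' @param seeds Character vector of seed ids.
#' @return Named logical vector over all cells.
#' @export
direct_targets <- function(wm, seeds) {
  seeds <- resolve_ids(wm, seeds, "seed id(s)")
  cols <- match(seeds, wm$order)
  flags <- Matrix::rowSums(wm$W[, cols, drop = FALSE] != 0) > 0
  names(flags) <- wm$order
  flags
}

#' Count body parts under high influence per seed
#'
#' Applies a conservative high-influence cutoff to per-effector adjusted
#' influence scores and, for each seed (cell or cell type), counts the
#' distinct effector body parts retained and reports the sorted
#' combination label. Effectors lacking a body-part label are excluded and
#' counted in the `"n_missing_body_part"` attribute.
#'
#' @param scores Long tibble with columns `seed`, `target`, `adjusted`, or
#'   a seeds-by-targets matrix of adjusted scores.
#' @param effectors Tibble with columns `id` and `body_part_effector`.
#' @param cutoff High-influence cutoff (default 17.18, the elbow of the
#'   cumulative score distribution for behaviourally characterised cells).
#' @return Tibble with `seed`, `n_body_parts`, `combination` (sorted
#'   labels joined by `+`; empty string when nothing passes the cutoff).
#' @export
count_influenced_body_parts <- function(scores, effectors, cutoff = 17.18) {
  if (is.matrix(scores)) {
    scores <- tibble::as_tibble(as.table(scores), .name_repair = "minimal")
    names(scores) <- c("seed", "target", "adjusted")
  }
  scores <- tibble::as_tibble(scores)
  stopifnot(all(c("seed", "target", "adjusted") %in% names(scores)))
  effectors <- tibble::as_tibble(effectors)
  stopifnot(all(c("id", "body_part_effector") %in% names(effectors)))

  joined <- dplyr::left_join(scores, effectors,
                             by = c(target = "id"))
  missing_bp <- is.na(joined$body_part_effector) | joined$body_part_effector == ""
  n_missing <- length(unique(joined$target[missing_bp]))
  joined <- joined[!missing_bp, , drop = FALSE]
  high <- joined[joined$adjusted >= cutoff, , drop = FALSE]

  out <- dplyr::summarise(
    dplyr::group_by(high, .data$seed),
    n_body_parts = dplyr::n_distinct(.data$body_part_effector),
    combination = paste(sort(unique(.data$body_part_effector)), collapse = "+"),
    .groups = "drop"
  )
  all_seeds <- unique(scores$seed)
  absent <- setdiff(all_seeds, out$seed)
  if (length(absent) > 0) {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(seed = absent, n_body_parts = 0L, combination = "")
    )
  }
  out <- out[match(all_seeds, out$seed), ]
  attr(out, "n_missing_body_part") <- n_missing
  out
}
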