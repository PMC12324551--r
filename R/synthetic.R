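# Synthetic connectomes with planted ground truth. These generators
# emulate the statistical structure the analysis pipeline assumes --
# body-part-organised sensor -> interneuron -> effector loops with strong
# local and weaker long-range connections, ascending/descending bridge
# cells between two super-regions, layered feedforward chains, and
# planted community structure -- so every stage is testable without any
# data download.

body_part_pool <- c(
  "pharynx", "antenna", "eye", "neck", "foreleg", "midleg", "hindleg",
  "wing", "haltere", "abdomen", "uterus", "crop"
)

# Heavy-tailed synapse counts: lognormal draw scaled so the expected
# count is ~`strength`, then rounded up to at least 1.
draw_counts <- function(n, strength, meanlog = 1, sdlog = 1) {
  if (n == 0) return(integer(0))
  raw <- stats::rlnorm(n, meanlog, sdlog) / exp(meanlog + sdlog^2 / 2)
  as.integer(ceiling(strength * raw))
}

bernoulli_pairs <- function(from, to, prob, no_self = TRUE) {
  grid <- expand.grid(pre = from, post = to, stringsAsFactors = FALSE)
  if (no_self) grid <- grid[grid$pre != grid$post, , drop = FALSE]
  grid[stats::runif(nrow(grid)) < prob, , drop = FALSE]
}

#' Generate a body-part-organised sensorimotor connectome
#'
#' Builds a connectome of `n_parts` body parts, each containing sensors
#' (afferent, no inputs), interneurons (intrinsic, recurrently connected)
#' and effectors (efferent, outputs only), wired into local
#' sensor -> interneuron -> effector loops with strong expected synapse
#' counts. Parts are split between two super-regions (brain and nerve
#' cord); long-range interneuron-to-interneuron connections between parts
#' and ascending/descending bridge cells between the regions carry weaker
#' expected counts, reflecting that long-range influence is generally
#' weaker than local influence. Synapse counts are heavy-tailed
#' (lognormal, rounded up). Annotations (flow, super class, side,
#' body-part labels) are populated so the full analysis pipeline runs
#' unmodified.
#'
#' @param n_parts Number of body parts (>= 2).
#' @param n_sensors,n_interneurons,n_effectors Cells per role per part
#'   (each >= 1).
#' @param n_bridge Ascending plus descending bridge cells per region
#'   direction (default 4 each way).
#' @param n_hub Central integrative (hub) cells: a strongly recurrent
#'   intrinsic population, weakly coupled to the sensorimotor loops, that
#'   carries the graph's spectral radius (default 16). Mirrors the deep
#'   recurrent "supervisory" populations of a real CNS, which dominate
#'   the leading eigenvalue while exerting only weak influence on
#'   effectors; without it, the stability rescaling would pin one small
#'   local loop at near-unit gain and wash out the local structure.
#' @param local_strength Expected synapse count of within-part edges.
#' @param long_range_strength Expected count of cross-part and bridge
#'   edges; must be smaller than `local_strength`.
#' @param p_local,p_long,p_bridge Edge probabilities for local,
#'   cross-part and bridge wiring.
#' @param count_meanlog,count_sdlog Lognormal parameters for counts.
#' @param rng_seed Integer seed; identical configurations give identical
#'   output.
#' @return List with `connectome` (a [connectome]) and `ground_truth`
#'   (list of `cells` -- id, body_part, role, region -- and `edges` with a
#'   provenance tag local/long_range/bridge).
#' @export
generate_body_plan <- function(n_parts = 4, n_sensors = 8, n_interneurons = 10,
                               n_effectors = 6, n_bridge = 4, n_hub = 16,
                               local_strength = 8, long_range_strength = 2,
                               p_local = 0.6, p_long = 0.05, p_bridge = 0.15,
                               count_meanlog = 1, count_sdlog = 1,
                               rng_seed = 1) {
  stopifnot(n_parts >= 2, n_sensors >= 1, n_interneurons >= 1, n_effectors >= 1)
  if (local_strength <= long_range_strength) {
    stop("local_strength must exceed long_range_strength", call. = FALSE)
  }
  parts <- if (n_parts <= length(body_part_pool)) {
    body_part_pool[seq_len(n_parts)]
  } else {
    paste0("part", seq_len(n_parts))
  }
  region_of <- ifelse(seq_len(n_parts) <= ceiling(n_parts / 2), "brain", "vnc")

  cells <- list()
  for (p in seq_len(n_parts)) {
    part <- parts[p]
    cells[[part]] <- tibble::tibble(
      id = c(sprintf("%s_sen%02d", part, seq_len(n_sensors)),
             sprintf("%s_int%02d", part, seq_len(n_interneurons)),
             sprintf("%s_eff%02d", part, seq_len(n_effectors))),
      body_part = part,
      role = rep(c("sensor", "interneuron", "effector"),
                 c(n_sensors, n_interneurons, n_effectors)),
      region = region_of[p]
    )
  }
  bridge <- tibble::tibble(
    id = c(sprintf("an%02d", seq_len(n_bridge)),
           sprintf("dn%02d", seq_len(n_bridge))),
    body_part = NA_character_,
    role = rep(c("AN-like", "DN-like"), each = n_bridge),
    region = NA_character_
  )
  hub <- tibble::tibble(
    id = sprintf("hub%02d", seq_len(n_hub)),
    body_part = NA_character_,
    role = "hub",
    region = "brain"
  )
  truth_cells <- dplyr::bind_rows(c(cells, list(bridge = bridge, hub = hub)))

  sens <- function(p) cells[[parts[p]]]$id[cells[[parts[p]]]$role == "sensor"]
  ints <- function(p) cells[[parts[p]]]$id[cells[[parts[p]]]$role == "interneuron"]
  effs <- function(p) cells[[parts[p]]]$id[cells[[parts[p]]]$role == "effector"]
  ans <- bridge$id[bridge$role == "AN-like"]
  dns <- bridge$id[bridge$role == "DN-like"]
  brain_parts <- which(region_of == "brain")
  vnc_parts <- which(region_of == "vnc")

  edges <- withr::with_seed(rng_seed, {
    pieces <- list()
    add <- function(pairs, strength, tag) {
      if (nrow(pairs) == 0) return(NULL)
      pairs$count <- draw_counts(nrow(pairs), strength,
                                 count_meanlog, count_sdlog)
      pairs$provenance <- tag
      pairs
    }
    for (p in seq_len(n_parts)) {
      pieces <- c(pieces, list(
        add(bernoulli_pairs(sens(p), ints(p), p_local), local_strength, "local"),
        add(bernoulli_pairs(ints(p), ints(p), p_local * 0.6), local_strength, "local"),
        add(bernoulli_pairs(ints(p), effs(p), p_local), local_strength, "local"),
        # monosynaptic reflex arcs: sensors also contact their part's
        # effectors directly
        add(bernoulli_pairs(sens(p), effs(p), p_local * 0.5), local_strength, "local")
      ))
    }
    for (p in seq_len(n_parts)) {
      for (q in setdiff(seq_len(n_parts), p)) {
        pieces <- c(pieces, list(
          add(bernoulli_pairs(ints(p), ints(q), p_long),
              long_range_strength, "long_range")
        ))
      }
    }
    # DN-like: driven in the brain, act in the cord; AN-like the reverse.
    from_ints <- function(ps) unlist(lapply(ps, ints))
    to_ints_effs <- function(ps) unlist(lapply(ps, function(q) c(ints(q), effs(q))))
    pieces <- c(pieces, list(
      add(bernoulli_pairs(from_ints(brain_parts), dns, p_bridge),
          long_range_strength, "bridge"),
      add(bernoulli_pairs(dns, to_ints_effs(vnc_parts), p_bridge),
          long_range_strength, "bridge"),
      add(bernoulli_pairs(from_ints(vnc_parts), ans, p_bridge),
          long_range_strength, "bridge"),
      add(bernoulli_pairs(ans, to_ints_effs(brain_parts), p_bridge),
          long_range_strength, "bridge")
    ))
    if (n_hub > 0) {
      all_ints <- from_ints(seq_len(n_parts))
      pieces <- c(pieces, list(
        add(bernoulli_pairs(hub$id, hub$id, 0.5), local_strength, "hub"),
        add(bernoulli_pairs(all_ints, hub$id, 0.1), long_range_strength, "hub"),
        add(bernoulli_pairs(hub$id, all_ints, 0.05), long_range_strength, "hub")
      ))
    }
    dplyr::bind_rows(pieces)
  })

  ann <- tibble::tibble(
    id = truth_cells$id,
    flow = dplyr::case_when(
      truth_cells$role == "sensor" ~ "afferent",
      truth_cells$role == "effector" ~ "efferent",
      TRUE ~ "intrinsic"
    ),
    super_class = dplyr::case_when(
      truth_cells$role == "sensor" ~ "sensory",
      truth_cells$role == "effector" ~ "motor",
      truth_cells$role == "AN-like" ~ "ascending",
      truth_cells$role == "DN-like" ~ "descending",
      TRUE ~ "intrinsic"
    ),
    side = rep_len(c("left", "right"), nrow(truth_cells)),
    body_part_sensory = ifelse(truth_cells$role == "sensor",
                               truth_cells$body_part, NA_character_),
    body_part_effector = ifelse(truth_cells$role == "effector",
                                truth_cells$body_part, NA_character_)
  )
  cn <- connectome(edges[, c("pre", "post", "count")], cells = ann)
  list(
    connectome = cn,
    ground_truth = list(
      cells = truth_cells,
      edges = tibble::as_tibble(edges)
    )
  )
}

#' Generate a strictly layered feedforward chain
#'
#' Cells are arranged in `depth` layers; every edge connects a layer to
#' the next (no skips, no recurrence). Each layer holds `width` "signal"
#' cells plus `n_background` background source cells with no inputs.
#' Signal cells in layer l receive synapses from all signal and all
#' background cells of layer l - 1, so only a fraction of each cell's
#' input (about `width / (width + n_background)`) arrives from the
#' seeded pathway. This emulates the unseeded background input every real
#' neuron receives, and is what makes steady-state influence decay
#' geometrically (hence log-linearly) with layer; with `n_background = 0`
#' the input-fraction weights are lossless and activity does not decay.
#'
#' @param depth Number of layers (>= 2).
#' @param width Signal cells per layer.
#' @param n_background Background source cells per layer (default
#'   `width`).
#' @param count_meanlog,count_sdlog Lognormal count parameters.
#' @param rng_seed Integer seed.
#' @return List with `connectome` and `layers` (tibble: id, layer, role =
#'   signal/background).
#' @export
generate_layered_chain <- function(depth, width, n_background = width,
                                   count_meanlog = 1, count_sdlog = 1,
                                   rng_seed = 1) {
  stopifnot(depth >= 2, width >= 1, n_background >= 0)
  layer_ids <- function(l) {
    c(sprintf("L%d_s%02d", l, seq_len(width)),
      if (n_background > 0) sprintf("L%d_b%02d", l, seq_len(n_background)))
  }
  layers <- dplyr::bind_rows(lapply(seq_len(depth) - 1, function(l) {
    tibble::tibble(
      id = layer_ids(l),
      layer = l,
      role = rep(c("signal", "background"), c(width, n_background))
    )
  }))
  edges <- withr::with_seed(rng_seed, {
    dplyr::bind_rows(lapply(seq_len(depth - 1), function(l) {
      pre <- layer_ids(l - 1)
      post <- sprintf("L%d_s%02d", l, seq_len(width))
      grid <- expand.grid(pre = pre, post = post, stringsAsFactors = FALSE)
      grid$count <- draw_counts(nrow(grid), 4, count_meanlog, count_sdlog)
      grid
    }))
  })
  ann <- tibble::tibble(
    id = layers$id,
    flow = ifelse(layers$layer == 0 | layers$role == "background",
                  "afferent", "intrinsic")
  )
  list(
    connectome = connectome(edges, cells = ann),
    layers = layers
  )
}

#' Generate a directed planted-partition graph
#'
#' k blocks of `n_per_block` cells; each ordered cell pair receives a
#' directed edge independently with probability `p_in` (same block) or
#' `p_out` (different blocks), with heavy-tailed synapse counts. The
#' planted block labels are the clustering oracle.
#'
#' @param k Number of blocks.
#' @param n_per_block Cells per block.
#' @param p_in,p_out Within- and between-block edge probabilities
#'   (`p_in > p_out`).
#' @param count_meanlog,count_sdlog Lognormal count parameters.
#' @param rng_seed Integer seed.
#' @return List with `connectome` and `modules` (tibble: id, module).
#' @export
generate_planted_partition <- function(k = 4, n_per_block = 100, p_in = 0.2,
                                       p_out = 0.01, count_meanlog = 1,
                                       count_sdlog = 1, rng_seed = 1) {
  stopifnot(k >= 1, n_per_block >= 2, p_in >= 0, p_in <= 1, p_out >= 0,
            p_out <= 1)
  if (p_in <= p_out) stop("p_in must exceed p_out", call. = FALSE)
  blocks <- lapply(seq_len(k), function(b) {
    sprintf("b%d_c%03d", b, seq_len(n_per_block))
  })
  modules <- tibble::tibble(
    id = unlist(blocks),
    module = rep(seq_len(k), each = n_per_block)
  )
  edges <- withr::with_seed(rng_seed, {
    pieces <- list()
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        prob <- if (a == b) p_in else p_out
        if (prob == 0) next
        pairs <- bernoulli_pairs(blocks[[a]], blocks[[b]], prob)
        if (nrow(pairs) == 0) next
        pairs$count <- draw_counts(nrow(pairs), 3, count_meanlog, count_sdlog)
        pieces <- c(pieces, list(pairs))
      }
    }
    dplyr::bind_rows(pieces)
  })
  list(
    connectome = connectome(edges, cells = tibble::tibble(id = modules$id)),
    modules = modules
  )
}
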