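#' @importFrom rlang .data
NULL

# Canonical annotation columns carried on every cell record.
annotation_columns <- c(
  "flow", "super_class", "cell_class", "cell_sub_class", "cell_type",
  "side", "body_part_sensory", "body_part_effector", "nerve"
)

valid_flows <- c("afferent", "intrinsic", "efferent")

empty_cell_table <- function(ids) {
  cells <- tibble::tibble(id = as.character(ids))
  for (col in annotation_columns) cells[[col]] <- NA_character_
  cells
}

#' Construct a connectome from an edge table
#'
#' A connectome couples a table of cells (with hierarchical annotations:
#' flow, super class, cell class, side, body-part labels) to a table of
#' directed edges carrying synapse counts. Edge endpoints must refer to
#' declared cells, counts must be positive integers, and cell ids must be
#' unique.
#'
#' @param edges Tibble/data.frame with columns `pre`, `post`, `count` and
#'   optionally `side` (-1/+1) and `pre_compartment`/`post_compartment`
#'   (axon/dendrite).
#' @param cells Optional cell table with an `id` column plus any subset of
#'   the annotation taxonomy. Cells appearing only here (not in `edges`)
#'   are kept as isolated nodes.
#' @return An object of class `connectome`: a list with tibbles `cells`
#'   and `edges`.
#' @export
connectome <- function(edges, cells = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("pre", "post", "count") %in% names(edges)))
  edges$pre <- as.character(edges$pre)
  edges$post <- as.character(edges$post)
  if (any(!is.finite(edges$count)) || any(edges$count != floor(edges$count))) {
    stop("edge counts must be integers", call. = FALSE)
  }
  if (any(edges$count < 1)) stop("edge counts must be >= 1", call. = FALSE)
  edges$count <- as.integer(edges$count)

  edge_ids <- unique(c(edges$pre, edges$post))
  if (is.null(cells)) {
    cells <- empty_cell_table(edge_ids)
  } else {
    cells <- tibble::as_tibble(cells)
    stopifnot("id" %in% names(cells))
    cells$id <- as.character(cells$id)
    if (anyDuplicated(cells$id)) stop("cell ids must be unique", call. = FALSE)
    missing <- setdiff(edge_ids, cells$id)
    if (length(missing) > 0) {
      cells <- dplyr::bind_rows(cells, empty_cell_table(missing))
    }
    for (col in annotation_columns) {
      if (!col %in% names(cells)) cells[[col]] <- NA_character_
    }
  }
  structure(list(cells = cells, edges = edges), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf(
    "<connectome> %d cells, %d edges, %d synapses\n",
    nrow(x$cells), nrow(x$edges), sum(x$edges$count)
  ))
  flows <- table(x$cells$flow, useNA = "ifany")
  if (length(flows)) {
    cat("  flow:", paste(names(flows), flows, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty input file: ", path, call. = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a synapse edge list from delimited text
#'
#' Expects a header with columns `pre`, `post` and `count`; comma or tab
#' delimited (auto-detected). Optional columns `side`, `pre_compartment`
#' and `post_compartment` are carried through. Autapses (edges with
#' `pre == post`) are removed by default, following the recommendation to
#' filter self-connections that mostly reflect presynaptic misassignment.
#'
#' @param path Path to the delimited file.
#' @param drop_autapses Remove edges with `pre == post` (default `TRUE`).
#' @return A [connectome] (without annotations).
#' @export
read_edge_list <- function(path, drop_autapses = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- detect_delim(path)
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           show_col_types = FALSE, progress = FALSE)
  required <- c("pre", "post", "count")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("edge list is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0) stop("edge list contains no edges", call. = FALSE)
  if (!is.numeric(tab$count) || any(tab$count != floor(tab$count))) {
    stop("column 'count' must contain integers", call. = FALSE)
  }
  if (drop_autapses) tab <- tab[tab$pre != tab$post, , drop = FALSE]
  if (nrow(tab) == 0) stop("no edges remain after autapse removal", call. = FALSE)
  connectome(tab)
}

#' Write an edge list as delimited text
#'
#' Inverse of [read_edge_list()]: round-tripping reproduces identical
#' edges and counts.
#'
#' @param cn A [connectome].
#' @param path Output path (written as CSV).
#' @export
write_edge_list <- function(cn, path) {
  stopifnot(inherits(cn, "connectome"))
  readr::write_csv(cn$edges, path, progress = FALSE)
  invisible(path)
}

#' Merge a cell annotation table onto a connectome
#'
#' The table must be keyed by `id` and may contain any subset of the
#' taxonomy columns (`flow`, `super_class`, `cell_class`,
#' `cell_sub_class`, `cell_type`, `side`, `body_part_sensory`,
#' `body_part_effector`, `nerve`). Ids absent from the connectome are
#' reported via a warning (and kept as isolated cells, so that influence
#' floors at zero for them); cells without a row keep empty labels.
#'
#' @param path Path to the delimited annotation table, or a data.frame.
#' @param cn A [connectome].
#' @return The connectome with annotations merged; unknown ids are
#'   recorded in `attr(, "unknown_ids")`.
#' @export
read_annotations <- function(path, cn) {
  stopifnot(inherits(cn, "connectome"))
  if (is.character(path)) {
    delim <- detect_delim(path)
    tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                             show_col_types = FALSE, progress = FALSE)
  } else {
    tab <- tibble::as_tibble(path)
  }
  stopifnot("id" %in% names(tab))
  tab$id <- as.character(tab$id)
  if (anyDuplicated(tab$id)) {
    stop("duplicate cell id rows in annotation table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "),
         call. = FALSE)
  }
  if ("flow" %in% names(tab)) {
    bad <- stats::na.omit(setdiff(unique(tab$flow), valid_flows))
    if (length(bad) > 0) {
      stop("invalid flow value(s): ", paste(bad, collapse = ", "),
           "; expected one of ", paste(valid_flows, collapse = "/"),
           call. = FALSE)
    }
  }
  unknown <- setdiff(tab$id, cn$cells$id)
  if (length(unknown) > 0) {
    warning("annotation ids absent from connectome (kept as isolated cells): ",
            paste(unknown, collapse = ", "), call. = FALSE)
    cn$cells <- dplyr::bind_rows(cn$cells, empty_cell_table(unknown))
  }
  use_cols <- intersect(annotation_columns, names(tab))
  idx <- match(tab$id, cn$cells$id)
  for (col in use_cols) {
    cn$cells[[col]][idx] <- as.character(tab[[col]])
  }
  attr(cn, "unknown_ids") <- unknown
  cn
}

#' Iteratively prune a cell population to its reciprocal core
#'
#' Starting from a candidate population, repeatedly removes cells that do
#' not have at least one presynaptic and one postsynaptic partner among
#' the retained cells, until a fixed point is reached. This is the
#' preprocessing applied before partitioning the CNS graph into networks.
#'
#' @param cn A [connectome].
#' @param cells Candidate population: a character vector of cell ids, or a
#'   predicate function applied to the cell table rows (receives the cells
#'   tibble, returns a logical vector). Default: all cells.
#' @return Character vector of retained cell ids (possibly empty).
#' @export
prune_to_reciprocal_core <- function(cn, cells = NULL) {
  stopifnot(inherits(cn, "connectome"))
  if (is.null(cells)) {
    keep <- cn$cells$id
  } else if (is.function(cells)) {
    keep <- cn$cells$id[cells(cn$cells)]
  } else {
    keep <- intersect(as.character(cells), cn$cells$id)
  }
  edges <- cn$edges[cn$edges$pre != cn$edges$post, c("pre", "post")]
  repeat {
    sub <- edges[edges$pre %in% keep & edges$post %in% keep, ]
    has_out <- unique(sub$pre)
    has_in <- unique(sub$post)
    new_keep <- intersect(keep, intersect(has_out, has_in))
    if (length(new_keep) == length(keep)) break
    keep <- new_keep
    if (length(keep) == 0) break
  }
  keep
}
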