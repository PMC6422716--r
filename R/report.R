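#' Circular node layout
#'
#' Nodes equally spaced on the unit circle in declared label order: the
#' first node at the top (angle pi/2), proceeding clockwise.
#'
#' @param labels node names in display order.
#' @return A `layout_spec`: tibble with `node`, `x`, `y` and attribute
#'   `style = "circular"`.
#' @export
layout_circular <- function(labels) {
  p <- length(labels)
  if (p < 1) abort("Need at least one node.")
  angles <- pi / 2 - 2 * pi * (seq_len(p) - 1) / p
  out <- tibble::tibble(node = labels, x = cos(angles), y = sin(angles))
  attr(out, "style") <- "circular"
  out
}

#' Spring-embedded (force-directed) node layout
#'
#' Fruchterman-Reingold layout with attraction proportional to `|weight|`,
#' so strongly (partially) correlated nodes sit close together. The layout
#' is deterministic under `seed`.
#'
#' @param W symmetric weighted adjacency matrix (a `ggm_fit` is accepted).
#' @param seed integer seed.
#' @param iterations number of force iterations (default 200).
#' @return A `layout_spec` tibble with attribute `style = "spring"`.
#' @export
layout_spring <- function(W, seed = 1L, iterations = 200L) {
  if (inherits(W, "ggm_fit")) W <- W$W
  check_square(W, "W")
  labels <- matrix_labels(W)
  g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  weights <- igraph::E(g)$weight
  coords <- withr::with_seed(
    derive_seed(seed, 1L),
    igraph::layout_with_fr(g, niter = iterations,
                           weights = if (length(weights)) weights else NULL)
  )
  out <- tibble::tibble(node = labels, x = coords[, 1], y = coords[, 2])
  attr(out, "style") <- "spring"
  out
}

# internal: constructor for manifest-backed figures
new_figure <- function(plot, manifest, type) {
  structure(list(plot = plot, manifest = c(list(type = type), manifest)),
            class = "cognet_figure")
}

#' @export
print.cognet_figure <- function(x, ...) {
  print(x$plot)
  invisible(x)
}

#' Network plot (circular or spring) with a machine-readable manifest
#'
#' Edges are drawn green for positive and red for negative partial
#' correlations, with width proportional to `|weight|`; node fill encodes
#' the community when a partition is given. Alongside the ggplot, a manifest
#' records exactly what was drawn (nodes with coordinates and communities;
#' edges with weight, sign, color and width), so tests and downstream tools
#' can assert content without image diffing.
#'
#' @param fit a `ggm_fit` or weighted adjacency matrix.
#' @param layout `"spring"`, `"circular"`, or a precomputed layout tibble.
#' @param partition optional `community_partition` for node coloring.
#' @param seed seed for the spring layout.
#' @param max_width maximal line width in plot units (widths scale linearly
#'   in `|weight|` up to the largest edge).
#' @return A `cognet_figure`: list with `plot` (ggplot) and `manifest`.
#' @export
plot_network <- function(fit, layout = c("spring", "circular"),
                         partition = NULL, seed = 1L, max_width = 3) {
  W <- if (inherits(fit, "ggm_fit")) fit$W else fit
  check_square(W, "W")
  labels <- matrix_labels(W)
  if (is.character(layout)) {
    layout <- match.arg(layout)
    coords <- if (layout == "circular") layout_circular(labels)
              else layout_spring(W, seed = seed)
  } else {
    coords <- layout
  }
  edges <- edge_table(W, labels)
  edges <- edges[edges$weight != 0, ]
  wmax <- if (nrow(edges) > 0) max(abs(edges$weight)) else 1
  edges <- dplyr::mutate(
    edges,
    sign = ifelse(.data$weight > 0, "positive", "negative"),
    color = ifelse(.data$weight > 0, "#2E8B57", "#CC3311"),
    width = max_width * abs(.data$weight) / wmax
  )
  edges <- dplyr::left_join(
    edges, dplyr::rename(coords, from = "node", x0 = "x", y0 = "y"),
    by = "from"
  )
  edges <- dplyr::left_join(
    edges, dplyr::rename(coords, to = "node", x1 = "x", y1 = "y"),
    by = "to"
  )
  nodes <- coords
  nodes$community <- if (!is.null(partition)) {
    unname(align_assignment(partition, labels))
  } else {
    rep(1L, length(labels))
  }
  plt <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1),
      color = edges$color, linewidth = edges$width
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   fill = factor(.data$community)),
      shape = 21, size = 10, show.legend = FALSE
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      size = 2.6
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  group <- if (inherits(fit, "ggm_fit")) fit$group_name else NA_character_
  new_figure(
    plt,
    list(group = group, style = attr(coords, "style") %||% "custom",
         nodes = nodes, edges = edges[, c("from", "to", "weight", "sign",
                                          "color", "width")]),
    type = "network"
  )
}

#' @rdname plot_network
#' @param object a `ggm_fit`.
#' @param ... passed to `plot_network()`.
#' @export
autoplot.ggm_fit <- function(object, ...) {
  plot_network(object, ...)$plot
}

# internal: red (0) -> white (1) colormap used by the co-assignment panels
coassignment_color <- function(prop) {
  grDevices::rgb(1, prop, prop)
}

#' Co-assignment stability panel for one node of interest
#'
#' One row per group, one column per remaining node; each cell prints the
#' proportion of bootstrap samples in which the node of interest shared a
#' community with that node, on a red (0) to white (1) fill. The node of
#' interest's own column is excluded.
#'
#' @param coassignments named list of `coassignment` objects (one per
#'   group), or a single object.
#' @param node node of interest (must be a network node).
#' @return A `cognet_figure`; the manifest holds the cell table (`group`,
#'   `node`, `proportion`, `label` = proportion rounded to 2 decimals,
#'   `fill`).
#' @export
plot_coassignment <- function(coassignments, node) {
  if (inherits(coassignments, "coassignment")) {
    coassignments <- list(all = coassignments)
  }
  labels <- coassignments[[1]]$labels
  if (!node %in% labels) {
    abort(sprintf("Unknown node `%s`.", node))
  }
  groups <- names(coassignments) %||% paste0("G", seq_along(coassignments))
  cells <- purrr::map_dfr(groups, function(g) {
    P <- coassignments[[g]]$P
    others <- setdiff(labels, node)
    props <- unname(P[node, others])
    tibble::tibble(group = g, node = others, proportion = props)
  })
  cells <- dplyr::mutate(
    cells,
    label = sprintf("%.2f", round(.data$proportion, 2)),
    fill = coassignment_color(.data$proportion)
  )
  cells$group <- factor(cells$group, levels = groups)
  cells$node <- factor(cells$node, levels = setdiff(labels, node))
  plt <- ggplot2::ggplot(
    cells,
    ggplot2::aes(x = .data$node, y = .data$group)
  ) +
    ggplot2::geom_tile(fill = cells$fill, color = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(groups)) +
    ggplot2::labs(title = paste0("Community co-assignment: ", node),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  new_figure(plt, list(node_of_interest = node, cells = cells),
             type = "coassignment_panel")
}

#' Confidence-band plot for centrality or edge weights
#'
#' Per-group lines of point estimates across items (nodes or edges) with a
#' shaded band spanning the bootstrap percentile interval, the standard way
#' to compare centrality profiles between groups.
#'
#' @param ci tibble from [strength_ci()] or [edge_ci()] (rows from several
#'   groups may be bound together); must contain `point`, `lo`, `hi`,
#'   `group` and an item column (`node`, or `from`/`to`).
#' @return A `cognet_figure`; the manifest holds the plotted table with the
#'   band bounds verbatim.
#' @export
plot_ci <- function(ci) {
  if (nrow(ci) == 0) abort("`ci` is empty.")
  item <- if ("node" %in% names(ci)) {
    ci$node
  } else if (all(c("from", "to") %in% names(ci))) {
    paste(ci$from, ci$to, sep = "-")
  } else {
    abort("`ci` must have a `node` or `from`/`to` columns.")
  }
  dat <- dplyr::mutate(ci, item = item)
  dat$item <- factor(dat$item, levels = unique(item))
  groups <- unique(dat$group)
  dat$group <- factor(dat$group, levels = groups)
  plt <- ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$item, y = .data$point, group = .data$group,
                 color = .data$group, fill = .data$group)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      alpha = 0.25, color = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = NULL, y = "estimate", color = "group",
                  fill = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  new_figure(plt, list(data = dat, groups = as.character(groups)),
             type = "ci_lines")
}

#' Write a figure and its manifest to disk
#'
#' Saves the image (`<prefix>.<format>`) and the JSON manifest
#' (`<prefix>_manifest.json`). The manifest, not the pixels, is the
#' contract: identical inputs produce identical manifests.
#'
#' @param fig a `cognet_figure`.
#' @param prefix output path without extension.
#' @param format `"png"`, `"svg"` or `"pdf"`.
#' @param width,height device size in inches.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_figure <- function(fig, prefix, format = c("png", "svg", "pdf"),
                         width = 7, height = 5) {
  format <- match.arg(format)
  img <- paste0(prefix, ".", format)
  mf <- paste0(prefix, "_manifest.json")
  dir.create(dirname(img), recursive = TRUE, showWarnings = FALSE)
  ggplot2::ggsave(img, plot = fig$plot, width = width, height = height,
                  dpi = 150)
  jsonlite::write_json(fig$manifest, mf, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(image = img, manifest = mf))
}
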