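#' Build and validate a dendritic river network
#'
#' A river network is a rooted binary tree pointing toward a single outlet:
#' source reaches have no upstream links, every other reach is fed by exactly
#' two upstream reaches, and every reach except the outlet drains into exactly
#' one downstream reach. Reaches are represented as nodes; the segment between
#' a node and its downstream neighbour is the reach the node's attributes
#' describe.
#'
#' @param nodes data.frame with columns `id` and `downstream_id`
#'   (`NA`/empty string for the outlet). Optional per-node attribute columns
#'   `B_m` (width, m), `S` (slope, -), `n` (Manning roughness, s m^-1/3) and
#'   `length_m` are carried through and take precedence over any
#'   Strahler-order lookup applied later.
#' @return An object of class `river_network`: a list with the node table
#'   (`$nodes`), the upstream adjacency (`$upstream`, named list of character
#'   vectors), the outlet id (`$outlet`) and a cached topological order from
#'   sources to outlet (`$order`).
#' @examples
#' y <- river_network(data.frame(id = c("A", "B", "C"),
#'                               downstream_id = c("C", "C", NA)))
#' y$outlet
#' @export
river_network <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  if (!all(c("id", "downstream_id") %in% names(nodes))) {
    stop("node table must have columns 'id' and 'downstream_id'")
  }
  ids <- as.character(nodes$id)
  if (anyDuplicated(ids)) {
    stop("duplicate node id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  dn <- as.character(nodes$downstream_id)
  dn[is.na(dn) | dn == ""] <- NA_character_

  bad_ref <- dn[!is.na(dn) & !(dn %in% ids)]
  if (length(bad_ref)) {
    stop("downstream_id refers to undeclared node(s): ",
         paste(unique(bad_ref), collapse = ", "))
  }

  # igraph handles cycle / connectivity checks and the topological order
  if (length(ids) > 1L) {
    edges <- cbind(ids[!is.na(dn)], dn[!is.na(dn)])
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    isolated <- setdiff(ids, igraph::V(g)$name)
    if (length(isolated)) g <- g + igraph::vertices(isolated)
    if (!igraph::is_dag(g)) {
      cyc <- suppressWarnings(igraph::V(g)$name[igraph::girth(g)$circle])
      stop("cycle detected in river network (involving node(s): ",
           paste(utils::head(cyc, 5L), collapse = ", "), ")")
    }
    outlet <- ids[is.na(dn)]
    if (length(outlet) == 0L) {
      stop("no outlet: every node has a downstream id")
    }
    if (length(outlet) > 1L) {
      stop("multiple outlets: ", paste(outlet, collapse = ", "))
    }
    comp <- igraph::components(g, mode = "weak")
    if (comp$no > 1L) {
      main <- comp$membership[outlet]
      orphans <- names(comp$membership)[comp$membership != main]
      stop("disconnected node(s): ", paste(orphans, collapse = ", "))
    }
    topo <- igraph::topo_sort(g, mode = "out")$name
  } else {
    topo <- ids
    outlet <- ids[is.na(dn)]
    if (length(outlet) == 0L) stop("no outlet: every node has a downstream id")
  }

  upstream <- split(ids[!is.na(dn)], factor(dn[!is.na(dn)], levels = ids))
  upstream <- lapply(upstream, as.character)
  n_up <- lengths(upstream)
  bad_deg <- ids[n_up != 0L & n_up != 2L]
  if (length(bad_deg)) {
    stop("node(s) with upstream degree other than 0 or 2: ",
         paste(bad_deg, collapse = ", "))
  }

  tab <- data.frame(id = ids, downstream_id = dn, stringsAsFactors = FALSE)
  for (col in c("B_m", "S", "n", "length_m")) {
    if (col %in% names(nodes)) {
      v <- as.numeric(nodes[[col]])
      if (any(!is.na(v) & v <= 0)) {
        stop("non-positive '", col, "' for node(s): ",
             paste(ids[!is.na(v) & v <= 0], collapse = ", "))
      }
      tab[[col]] <- v
    } else {
      tab[[col]] <- NA_real_
    }
  }
  tab <- tab[match(topo, tab$id), , drop = FALSE]
  rownames(tab) <- NULL

  net <- structure(
    list(nodes = tab,
         upstream = upstream[topo],
         outlet = outlet,
         order = topo),
    class = "river_network"
  )
  net$nodes$strahler_order <- compute_strahler(net)[topo]
  net
}

#' Build a river network from an edge list
#'
#' @param edges data.frame with columns `child_id` and `parent_id`; each row
#'   states that `child_id` drains into `parent_id`.
#' @param attributes optional data.frame of per-node attributes with an `id`
#'   column, merged onto the node table.
#' @return A `river_network` (see [river_network()]).
#' @export
river_network_from_edges <- function(edges, attributes = NULL) {
  stopifnot(is.data.frame(edges))
  if (!all(c("child_id", "parent_id") %in% names(edges))) {
    stop("edge list must have columns 'child_id' and 'parent_id'")
  }
  child <- as.character(edges$child_id)
  parent <- as.character(edges$parent_id)
  if (anyDuplicated(child)) {
    stop("node(s) with more than one downstream link: ",
         paste(unique(child[duplicated(child)]), collapse = ", "))
  }
  ids <- unique(c(child, parent))
  dn <- parent[match(ids, child)]
  tab <- data.frame(id = ids, downstream_id = dn, stringsAsFactors = FALSE)
  if (!is.null(attributes)) {
    stopifnot(is.data.frame(attributes), "id" %in% names(attributes))
    keep <- intersect(c("B_m", "S", "n", "length_m"), names(attributes))
    tab <- merge(tab, attributes[, c("id", keep), drop = FALSE],
                 by = "id", all.x = TRUE, sort = FALSE)
  }
  river_network(tab)
}

#' @export
print.river_network <- function(x, ...) {
  n <- nrow(x$nodes)
  n_src <- sum(lengths(x$upstream) == 0L)
  cat("river_network:", n, "nodes,", n_src, "sources, outlet", x$outlet,
      "| max Strahler order", max(x$nodes$strahler_order), "\n")
  invisible(x)
}

#' Strahler stream order of every node
#'
#' Sources are order 1; a junction of two branches of equal order i has order
#' i + 1, otherwise the larger of the two orders.
#'
#' @param net a `river_network`.
#' @return Named integer vector of Strahler orders, one per node.
#' @export
compute_strahler <- function(net) {
  stopifnot(inherits(net, "river_network"))
  so <- stats::setNames(integer(length(net$order)), net$order)
  for (id in net$order) {
    up <- net$upstream[[id]]
    if (length(up) == 0L) {
      so[id] <- 1L
    } else {
      a <- so[up[1L]]; b <- so[up[2L]]
      so[id] <- if (a == b) a + 1L else max(a, b)
    }
  }
  so
}

#' Route discharge downstream by continuity
#'
#' Each source carries its inflow `q0`; discharge at every other node is the
#' sum of the discharges of its two upstream branches, so that discharge at a
#' node equals the total inflow of all sources upstream of it.
#'
#' @param net a `river_network`.
#' @param q0 a single positive discharge (m^3/s) applied to every source, or
#'   a named vector giving the inflow of each source node.
#' @return Named numeric vector of discharge (m^3/s) per node, in topological
#'   order.
#' @export
route_discharge <- function(net, q0) {
  stopifnot(inherits(net, "river_network"))
  sources <- net$order[lengths(net$upstream[net$order]) == 0L]
  if (length(q0) == 1L && is.null(names(q0))) {
    q0 <- stats::setNames(rep(as.numeric(q0), length(sources)), sources)
  } else {
    missing <- setdiff(sources, names(q0))
    if (length(missing)) {
      stop("q0 missing for source(s): ", paste(missing, collapse = ", "))
    }
    q0 <- q0[sources]
  }
  if (any(!is.finite(q0) | q0 <= 0)) {
    stop("q0 must be positive for every source")
  }
  q <- stats::setNames(numeric(length(net$order)), net$order)
  for (id in net$order) {
    up <- net$upstream[[id]]
    q[id] <- if (length(up) == 0L) q0[id] else q[up[1L]] + q[up[2L]]
  }
  q
}

#' Assign width, slope and roughness from a Strahler-order table
#'
#' Reach attributes follow the Strahler order of the reach, emulating
#' downstream hydraulic-geometry trends (wider, milder, smoother with
#' increasing order). Explicit per-node attributes already present in the node
#' table take precedence over the lookup.
#'
#' @param net a `river_network`.
#' @param so_table data.frame with columns `SO`, `B_m`, `S`, `n`; one row per
#'   Strahler order present in the network.
#' @return The network with `B_m`, `S`, `n` filled on every node.
#' @export
assign_reach_attributes <- function(net, so_table) {
  stopifnot(inherits(net, "river_network"), is.data.frame(so_table))
  if (!all(c("SO", "B_m", "S", "n") %in% names(so_table))) {
    stop("so_table must have columns SO, B_m, S, n")
  }
  if (any(so_table$B_m <= 0 | so_table$S <= 0 | so_table$n <= 0)) {
    stop("so_table attributes must be positive")
  }
  so <- net$nodes$strahler_order
  missing_so <- setdiff(so, so_table$SO)
  if (length(missing_so)) {
    stop("so_table missing Strahler order(s): ",
         paste(sort(missing_so), collapse = ", "))
  }
  row <- match(so, so_table$SO)
  for (col in c("B_m", "S", "n")) {
    fill <- is.na(net$nodes[[col]])
    net$nodes[[col]][fill] <- so_table[[col]][row][fill]
  }
  net
}

#' Read a river network from a node-table CSV
#'
#' Expected columns: `id`, `downstream_id` (empty for the outlet), and
#' optionally `B_m`, `S`, `n`, `length_m`. UTF-8, header row, '.' decimal.
#'
#' @param path file path.
#' @return A `river_network`.
#' @export
read_network_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character",
                                        downstream_id = "character"))
  river_network(tab)
}

#' Write a river network node table to CSV
#'
#' @param net a `river_network`.
#' @param path file path.
#' @export
write_network_csv <- function(net, path) {
  utils::write.csv(net$nodes, path, row.names = FALSE, na = "")
  invisible(path)
}
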