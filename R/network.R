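# Channel-network graphs: construction, boundary tagging, blockage, file I/O.
#
# A network is a pair of tibbles. Edge orientation is from the lower to the
# higher node id; signed flow rates follow that orientation. Blocked edges are
# retained (conductance treated as zero) so that geometry bookkeeping is
# unchanged by a blockage.

new_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "supply_network")
}

#' Build a channel network from node and edge tables
#'
#' @param nodes Data frame with columns `id`, `x`, `y`, `z` (mm) and optional
#'   `bc_type` (`"interior"`, `"pressure"` or `"inflow"`) and `bc_value`
#'   (Pa for pressure, mm^3 s^-1 for inflow, positive into the network).
#' @param edges Data frame with columns `node_a`, `node_b`, `R_c` (inner
#'   radius, mm) and optional `id`, `L` (mm) and `blocked`. When `L` is
#'   omitted it is computed from the node coordinates; a supplied `L` must
#'   agree with the Euclidean distance to 1e-9 mm unless
#'   `allow_length_override = TRUE`.
#' @param allow_length_override Permit edge lengths that differ from the
#'   Euclidean node distance (e.g. coiled channels).
#' @return A `supply_network` object.
#' @export
network_graph <- function(nodes, edges, allow_length_override = FALSE) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  stopifnot(all(c("id", "x", "y", "z") %in% names(nodes)),
            all(c("node_a", "node_b", "R_c") %in% names(edges)))
  if (anyDuplicated(nodes$id)) {
    abort("Duplicate node ids.", class = "perfunet_validation_error")
  }
  if (!"bc_type" %in% names(nodes)) nodes$bc_type <- "interior"
  if (!"bc_value" %in% names(nodes)) nodes$bc_value <- NA_real_
  if (!all(nodes$bc_type %in% c("interior", "pressure", "inflow"))) {
    abort("bc_type must be interior, pressure or inflow.",
          class = "perfunet_validation_error")
  }
  if (!"id" %in% names(edges)) edges$id <- seq_len(nrow(edges))
  if (!"blocked" %in% names(edges)) edges$blocked <- FALSE
  if (!all(edges$node_a %in% nodes$id) || !all(edges$node_b %in% nodes$id)) {
    abort("Edge endpoints reference unknown node ids.",
          class = "perfunet_validation_error")
  }
  # orient from lower to higher node id
  swap <- edges$node_a > edges$node_b
  if (any(swap)) {
    tmp <- edges$node_a[swap]
    edges$node_a[swap] <- edges$node_b[swap]
    edges$node_b[swap] <- tmp
  }
  ia <- match(edges$node_a, nodes$id)
  ib <- match(edges$node_b, nodes$id)
  eucl <- sqrt((nodes$x[ia] - nodes$x[ib])^2 +
               (nodes$y[ia] - nodes$y[ib])^2 +
               (nodes$z[ia] - nodes$z[ib])^2)
  if (!"L" %in% names(edges) || all(is.na(edges$L))) {
    edges$L <- eucl
  } else if (!allow_length_override && any(abs(edges$L - eucl) > 1e-9)) {
    abort("Edge lengths disagree with Euclidean node distances by > 1e-9 mm; pass allow_length_override = TRUE for non-straight channels.",
          class = "perfunet_validation_error")
  }
  if (any(edges$R_c <= 0) || any(edges$L <= 0)) {
    abort("All edges need R_c > 0 and L > 0.",
          class = "perfunet_validation_error")
  }
  new_network(nodes[, c("id", "x", "y", "z", "bc_type", "bc_value")],
              edges[, c("id", "node_a", "node_b", "R_c", "L", "blocked")])
}

#' Build a cuboid honeycomb lattice network
#'
#' Cartesian lattice of `(n_x+1)(n_y+1)(n_z+1)` nodes spaced `s` apart, with
#' primary channels along x and secondary channels along y and z. All nodes
#' start untagged; use [set_face_bc()] to attach reservoirs.
#'
#' @param n_x,n_y,n_z Number of base-unit cells per direction (>= 1).
#' @param s Cell edge length (mm); must exceed the channel diameter.
#' @param R_c Channel inner radius (mm).
#' @return A `supply_network`.
#' @export
#' @examples
#' net <- build_unit_network(4, 4, 4, s = 0.5, R_c = 0.04)
#' nrow(net$nodes); nrow(net$edges)  # 125 nodes, 300 edges
build_unit_network <- function(n_x, n_y, n_z, s, R_c) {
  stopifnot(n_x >= 1, n_y >= 1, n_z >= 1)
  if (s <= 2 * R_c) {
    abort("Cell edge s must exceed the channel diameter 2*R_c.",
          class = "perfunet_geometry_error")
  }
  gx <- 0:n_x; gy <- 0:n_y; gz <- 0:n_z
  grid <- expand.grid(i = gx, j = gy, k = gz)
  node_id <- function(i, j, k) {
    1L + i + (n_x + 1L) * (j + (n_y + 1L) * k)
  }
  nodes <- tibble(
    id = node_id(grid$i, grid$j, grid$k),
    x = grid$i * s, y = grid$j * s, z = grid$k * s,
    bc_type = "interior", bc_value = NA_real_
  )
  nodes <- nodes[order(nodes$id), ]
  ex <- expand.grid(i = 0:(n_x - 1), j = gy, k = gz)
  ey <- expand.grid(i = gx, j = 0:(n_y - 1), k = gz)
  ez <- expand.grid(i = gx, j = gy, k = 0:(n_z - 1))
  edges <- tibble(
    node_a = c(node_id(ex$i, ex$j, ex$k),
               node_id(ey$i, ey$j, ey$k),
               node_id(ez$i, ez$j, ez$k)),
    node_b = c(node_id(ex$i + 1L, ex$j, ex$k),
               node_id(ey$i, ey$j + 1L, ey$k),
               node_id(ez$i, ez$j, ez$k + 1L)),
    R_c = R_c,
    axis = rep(c("x", "y", "z"), c(nrow(ex), nrow(ey), nrow(ez)))
  )
  net <- network_graph(nodes, edges[, c("node_a", "node_b", "R_c")])
  net$edges$axis <- edges$axis
  net
}

#' Tag all nodes on a lattice face with a boundary condition
#'
#' @param net A `supply_network`.
#' @param face One of `"x-"`, `"x+"`, `"y-"`, `"y+"`, `"z-"`, `"z+"`.
#' @param type `"pressure"` (Pa) or `"inflow"` (mm^3 s^-1 into the network).
#' @param value Boundary value.
#' @return The modified network.
#' @export
set_face_bc <- function(net, face, type, value) {
  stopifnot(inherits(net, "supply_network"))
  ax <- substr(face, 1, 1)
  side <- substr(face, 2, 2)
  coord <- net$nodes[[ax]]
  target <- if (side == "-") min(coord) else max(coord)
  sel <- abs(coord - target) < 1e-12
  set_node_bc(net, net$nodes$id[sel], type, value)
}

#' Tag individual nodes with a boundary condition
#'
#' @inheritParams set_face_bc
#' @param ids Node ids to tag.
#' @export
set_node_bc <- function(net, ids, type, value) {
  stopifnot(inherits(net, "supply_network"))
  type <- match.arg(type, c("pressure", "inflow", "interior"))
  sel <- net$nodes$id %in% ids
  net$nodes$bc_type[sel] <- type
  net$nodes$bc_value[sel] <- if (type == "interior") NA_real_ else value
  net
}

# connected components over unblocked edges; returns integer component id per
# node (in nodes$id order)
network_components <- function(net) {
  n <- nrow(net$nodes)
  idx <- setNames(seq_len(n), net$nodes$id)
  live <- net$edges[!net$edges$blocked, ]
  adj <- vector("list", n)
  for (r in seq_len(nrow(live))) {
    a <- idx[[as.character(live$node_a[r])]]
    b <- idx[[as.character(live$node_b[r])]]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' Block a channel segment
#'
#' The edge is retained in the graph with its hydraulic conductance set to
#' zero and its surface treated as impermeable in tissue solves. Errors if the
#' blockage would disconnect the endpoints of the blocked edge from each other
#' (no alternative flow path).
#'
#' @param net A `supply_network`.
#' @param edge_id Edge id to block.
#' @return A modified copy of the network.
#' @export
block_edge <- function(net, edge_id) {
  stopifnot(inherits(net, "supply_network"))
  sel <- net$edges$id == edge_id
  if (!any(sel)) {
    abort(paste0("No edge with id ", edge_id, "."),
          class = "perfunet_validation_error")
  }
  net$edges$blocked[sel] <- TRUE
  comp <- network_components(net)
  e <- net$edges[sel, ]
  ia <- match(e$node_a, net$nodes$id)
  ib <- match(e$node_b, net$nodes$id)
  if (comp[ia] != comp[ib]) {
    abort(paste0("Blocking edge ", edge_id,
                 " disconnects nodes ", e$node_a, " and ", e$node_b,
                 ": no alternative flow path remains."),
          class = "perfunet_wellposedness_error")
  }
  net
}

#' Write a network as two CSV tables
#'
#' @param net A `supply_network`.
#' @param nodes_path,edges_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_network_csv <- function(net, nodes_path, edges_path) {
  write.csv(net$nodes, nodes_path, row.names = FALSE)
  write.csv(net$edges[, c("id", "node_a", "node_b", "R_c", "L", "blocked")],
            edges_path, row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}

#' Read a network from two CSV tables
#'
#' @inheritParams write_network_csv
#' @return A `supply_network`.
#' @export
read_network_csv <- function(nodes_path, edges_path) {
  network_graph(read.csv(nodes_path), read.csv(edges_path),
                allow_length_override = TRUE)
}

#' Write a network as a single JSON document
#'
#' @param net A `supply_network`.
#' @param path Output path.
#' @export
write_network_json <- function(net, path) {
  jsonlite::write_json(list(nodes = net$nodes,
                            edges = net$edges[, c("id", "node_a", "node_b",
                                                  "R_c", "L", "blocked")]),
                       path, digits = NA, na = "null")
  invisible(path)
}

#' Read a network from a JSON document written by [write_network_json()]
#'
#' @param path Input path.
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  network_graph(x$nodes, x$edges, allow_length_override = TRUE)
}

#' @export
print.supply_network <- function(x, ...) {
  cat(sprintf("Supply network: %d nodes, %d edges (%d blocked), %d boundary nodes\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$blocked),
              sum(x$nodes$bc_type != "interior")))
  invisible(x)
}
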