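# Network hydraulics (Kirchhoff current law + Hagen-Poiseuille conductances)
# and downstream solute routing.

#' Solve the network hydraulics
#'
#' Nodal pressures are obtained from a sparse symmetric positive-definite
#' solve of the Kirchhoff balance with edge conductances
#' `G = pi R_c^4 / (8 mu L)` (Hagen-Poiseuille); blocked edges carry no flow.
#' Fixed-pressure nodes anchor the gauge; fixed-inflow nodes inject flow.
#'
#' @param net A `supply_network` with at least one fixed-pressure node per
#'   connected component.
#' @param medium A [medium_params()] (only `mu` is used).
#' @return A `flow_solution`: list with tibbles `nodes` (`id`, `p` in Pa) and
#'   `edges` (`id`, `Q` in mm^3 s^-1 signed from `node_a` to `node_b`,
#'   `v` mean velocity in mm s^-1, `dp` in Pa), plus the maximum relative
#'   nodal imbalance in `balance_residual`.
#' @export
solve_flow <- function(net, medium) {
  stopifnot(inherits(net, "supply_network"), inherits(medium, "medium_params"))
  nodes <- net$nodes
  edges <- net$edges
  n <- nrow(nodes)
  idx <- match(edges$node_a, nodes$id)
  jdx <- match(edges$node_b, nodes$id)
  G <- ifelse(edges$blocked, 0, pi * edges$R_c^4 / (8 * medium$mu * edges$L))

  comp <- network_components(net)
  fixed <- nodes$bc_type == "pressure"
  bad_comp <- setdiff(unique(comp), unique(comp[fixed]))
  if (length(bad_comp)) {
    offenders <- nodes$id[comp %in% bad_comp]
    abort(paste0("Flow problem is ill-posed: no fixed-pressure node in the ",
                 "component(s) containing nodes ",
                 paste(utils::head(offenders, 10), collapse = ", "),
                 if (length(offenders) > 10) ", ..." else "", "."),
          class = "perfunet_wellposedness_error")
  }

  free <- which(!fixed)
  p <- numeric(n)
  p[fixed] <- nodes$bc_value[fixed]
  if (length(free)) {
    live <- which(G > 0)
    ii <- idx[live]; jj <- jdx[live]; gg <- G[live]
    # full weighted Laplacian, then restrict to free nodes
    Lap <- Matrix::sparseMatrix(
      i = c(ii, jj, ii, jj), j = c(jj, ii, ii, jj),
      x = c(-gg, -gg, gg, gg), dims = c(n, n)
    )
    rhs <- numeric(n)
    inflow <- nodes$bc_type == "inflow"
    rhs[inflow] <- nodes$bc_value[inflow]
    A <- Lap[free, free, drop = FALSE]
    b <- rhs[free] - Lap[free, fixed, drop = FALSE] %*% p[fixed]
    sol <- try(Matrix::solve(A, b), silent = TRUE)
    if (inherits(sol, "try-error")) {
      abort("Flow system is singular; check boundary conditions and connectivity.",
            class = "perfunet_wellposedness_error")
    }
    p[free] <- as.numeric(sol)
  }

  Q <- G * (p[idx] - p[jdx])
  v <- ifelse(edges$blocked, 0, Q / (pi * edges$R_c^2))
  dp <- p[idx] - p[jdx]

  # nodal balance check at interior nodes
  divg <- numeric(n)
  for (e in seq_along(Q)) {
    divg[idx[e]] <- divg[idx[e]] - Q[e]
    divg[jdx[e]] <- divg[jdx[e]] + Q[e]
  }
  thru <- numeric(n)
  for (e in seq_along(Q)) {
    thru[idx[e]] <- thru[idx[e]] + abs(Q[e])
    thru[jdx[e]] <- thru[jdx[e]] + abs(Q[e])
  }
  interior <- nodes$bc_type == "interior" & thru > 0
  resid <- if (any(interior)) max(abs(divg[interior]) / pmax(thru[interior], 1e-300)) else 0

  structure(list(
    nodes = tibble(id = nodes$id, p = p),
    edges = tibble(id = edges$id, node_a = edges$node_a, node_b = edges$node_b,
                   R_c = edges$R_c, L = edges$L, blocked = edges$blocked,
                   Q = Q, v = v, dp = dp),
    balance_residual = resid
  ), class = "flow_solution")
}

#' Route a solute through a solved network
#'
#' Nodes are processed in strictly descending pressure order (valid for Stokes
#' flow, which runs from high to low pressure); the mixed concentration at a
#' junction is the flow-weighted mean of incoming edge outlet concentrations
#' and external inflows. Along each edge the outlet concentration is the inlet
#' concentration minus `sink * L / Q` (closed-form integral of the axial
#' balance for a flow-independent per-length loss).
#'
#' @param net A `supply_network`.
#' @param flow A `flow_solution` from [solve_flow()].
#' @param c_inlet Concentration (mol m^-3) of external inflows: a single
#'   value for all inflow boundaries, or a vector named by node id.
#' @param per_edge_sink Optional per-length solute loss, a single value or a
#'   vector named by edge id, in (mol m^-3) mm^2 s^-1 (so that
#'   `sink * L / Q` is a concentration). Default 0 (pure routing).
#' @return A `solute_solution`: tibbles `nodes` (`id`, `c`) and `edges`
#'   (`id`, `c_in`, `c_out`).
#' @export
route_solute <- function(net, flow, c_inlet, per_edge_sink = 0) {
  stopifnot(inherits(flow, "flow_solution"))
  nodes <- flow$nodes
  edges <- flow$edges
  n <- nrow(nodes)
  qtol <- 1e-14 * max(abs(edges$Q), 1e-300)
  c_in_node <- function(nid) {
    if (length(c_inlet) == 1L && is.null(names(c_inlet))) return(c_inlet)
    v <- c_inlet[as.character(nid)]
    if (is.na(v)) {
      abort(paste0("No inlet concentration given for inflow node ", nid, "."),
            class = "perfunet_validation_error")
    }
    as.numeric(v)
  }

  sink <- if (length(per_edge_sink) == 1L) {
    rep(per_edge_sink, nrow(edges))
  } else {
    s <- per_edge_sink[as.character(edges$id)]
    s[is.na(s)] <- 0
    as.numeric(s)
  }

  # orientation: flow from the higher-pressure endpoint to the lower one
  up <- ifelse(edges$Q >= 0, edges$node_a, edges$node_b)
  dn <- ifelse(edges$Q >= 0, edges$node_b, edges$node_a)
  absQ <- abs(edges$Q)

  pu <- nodes$p[match(up, nodes$id)]
  pd <- nodes$p[match(dn, nodes$id)]
  if (any(absQ > qtol & pu <= pd)) {
    abort("Cyclic flow ordering impossible: equal pressures with nonzero flow.",
          class = "perfunet_degeneracy_error")
  }
  if (anyDuplicated(round(nodes$p, 12)) && any(absQ <= qtol)) {
    warn("Pressure ties present; tied nodes ordered by id (zero-flow edges only).")
  }

  # external inflow per node from the nodal imbalance
  ext <- numeric(n)
  for (e in seq_len(nrow(edges))) {
    iu <- match(up[e], nodes$id); idn <- match(dn[e], nodes$id)
    ext[iu] <- ext[iu] + absQ[e]
    ext[idn] <- ext[idn] - absQ[e]
  }
  ext[abs(ext) < qtol] <- 0  # interior

  ord <- order(-nodes$p, nodes$id)
  c_node <- rep(NA_real_, n)
  c_in_edge <- rep(NA_real_, nrow(edges))
  c_out_edge <- rep(NA_real_, nrow(edges))

  for (i in ord) {
    nid <- nodes$id[i]
    incoming <- which(dn == nid & absQ > qtol)
    qin <- absQ[incoming]
    cin <- c_out_edge[incoming]
    wsum <- sum(qin)
    csum <- sum(qin * cin)
    if (ext[i] > 0) {        # external supply mixes in at the inlet value
      wsum <- wsum + ext[i]
      csum <- csum + ext[i] * c_in_node(nid)
    }
    c_node[i] <- if (wsum > 0) csum / wsum else
      (if (length(c_inlet) == 1L && is.null(names(c_inlet))) c_inlet else NA_real_)
    outgoing <- which(up == nid & absQ > qtol)
    for (e in outgoing) {
      c_in_edge[e] <- c_node[i]
      c_out_edge[e] <- c_node[i] - sink[e] * edges$L[e] / absQ[e]
    }
  }
  # stagnant edges carry the upstream node concentration (no transport)
  stagnant <- absQ <= qtol & !edges$blocked
  c_in_edge[stagnant] <- c_node[match(up[stagnant], nodes$id)]
  c_out_edge[stagnant] <- c_in_edge[stagnant]

  structure(list(
    nodes = tibble(id = nodes$id, c = c_node),
    edges = tibble(id = edges$id, Q = edges$Q,
                   c_in = c_in_edge, c_out = c_out_edge)
  ), class = "solute_solution")
}

#' Dimensionless transport numbers for a channel segment
#'
#' Reynolds number `Re = 2 R_c v / nu`, axial Peclet number
#' `Pe_z = v L / D_c` and Graetz number `Gz = v R_c^2 / (D_c L)`. The model's
#' channel assumptions hold for Re small (laminar, fully developed), Pe_z
#' large (axial diffusion negligible) and Gz small (radially well mixed);
#' violations produce warnings, never errors.
#'
#' @param R_c,v,L Channel inner radius (mm), mean velocity (mm s^-1) and
#'   segment length (mm); vectorized.
#' @param nu Kinematic viscosity (mm^2 s^-1).
#' @param D_c Channel-medium diffusivity (mm^2 s^-1).
#' @return A tibble with columns `Re`, `Pe_z`, `Gz`.
#' @export
#' @examples
#' assumption_numbers(R_c = 0.05, v = 8, L = 5, nu = 0.696, D_c = 3e-3)
assumption_numbers <- function(R_c, v, L, nu, D_c) {
  Re <- 2 * R_c * abs(v) / nu
  Pe_z <- abs(v) * L / D_c
  Gz <- abs(v) * R_c^2 / (D_c * L)
  if (any(Re > 10)) {
    warn("Re > 10 on some segments: Hagen-Poiseuille may lose accuracy.")
  }
  if (any(abs(v) > 0 & Pe_z < 10)) {
    warn("Pe_z < 10 on some flowing segments: axial diffusion not negligible.")
  }
  if (any(Gz > 1)) {
    warn("Gz > 1 on some segments: channel not radially well mixed.")
  }
  tibble(Re = Re, Pe_z = Pe_z, Gz = Gz)
}

#' Write per-edge flow and solute results as CSV
#'
#' @param flow A `flow_solution`.
#' @param path Output CSV.
#' @param solute Optional `solute_solution` to merge in by edge id.
#' @export
write_flow_csv <- function(flow, path, solute = NULL) {
  out <- flow$edges
  if (!is.null(solute)) {
    out <- dplyr::left_join(out, solute$edges[, c("id", "c_in", "c_out")],
                            by = "id")
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @method tidy flow_solution
#' @export
tidy.flow_solution <- function(x, ...) x$edges

#' Net external flow per node
#'
#' Positive values are inflows from outside the network (reservoirs), negative
#' values outflows; interior nodes balance to numerical noise.
#'
#' @param flow A `flow_solution`.
#' @return A tibble with columns `id` and `external_flow` (mm^3 s^-1).
#' @export
external_flows <- function(flow) {
  e <- flow$edges
  ids <- flow$nodes$id
  ext <- numeric(length(ids))
  ia <- match(e$node_a, ids)
  ib <- match(e$node_b, ids)
  for (k in seq_len(nrow(e))) {
    ext[ia[k]] <- ext[ia[k]] + e$Q[k]
    ext[ib[k]] <- ext[ib[k]] - e$Q[k]
  }
  tibble(id = ids, external_flow = ext)
}

#' @method glance flow_solution
#' @export
glance.flow_solution <- function(x, ...) {
  ext <- external_flows(x)$external_flow
  tol <- 1e-12 * max(abs(x$edges$Q), 1e-300)
  tibble(
    n_edges = nrow(x$edges),
    n_blocked = sum(x$edges$blocked),
    total_inflow = sum(ext[ext > tol]),
    total_outflow = -sum(ext[ext < -tol]),
    max_velocity = max(abs(x$edges$v)),
    balance_residual = x$balance_residual
  )
}

#' @method tidy solute_solution
#' @export
tidy.solute_solution <- function(x, ...) x$edges
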