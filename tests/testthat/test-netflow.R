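# Kirchhoff/Hagen-Poiseuille network hydraulics and solute routing.

medium <- medium_params()

test_that("lattice construction gives the expected node and edge counts", {
  net <- build_unit_network(4, 4, 4, s = 0.5, R_c = 0.04)
  expect_equal(nrow(net$nodes), 125)
  expect_equal(nrow(net$edges), 300)      # 3 n (n+1)^2 for n = 4
  one <- build_unit_network(1, 1, 1, s = 0.5, R_c = 0.04)
  expect_equal(nrow(one$nodes), 8)
  expect_equal(nrow(one$edges), 12)
  expect_error(build_unit_network(1, 1, 1, s = 0.05, R_c = 0.04),
               class = "perfunet_geometry_error")
  # edge lengths equal the Euclidean node distance
  expect_true(all(abs(net$edges$L - 0.5) < 1e-12))
})

two_edge_line <- function() {
  nodes <- tibble::tibble(id = 1:3, x = c(0, 1, 2), y = 0, z = 0,
                          bc_type = c("inflow", "interior", "pressure"),
                          bc_value = c(0.003, NA, 0))
  edges <- tibble::tibble(node_a = c(1, 2), node_b = c(2, 3), R_c = 0.05)
  network_graph(nodes, edges)
}

test_that("series edges carry the imposed inflow and parallel edges split by R^4", {
  fl <- solve_flow(two_edge_line(), medium)
  expect_equal(fl$edges$Q, c(0.003, 0.003), tolerance = 1e-12)

  nodes <- tibble::tibble(id = 1:2, x = c(0, 1), y = 0, z = 0,
                          bc_type = "pressure", bc_value = c(5, 0))
  edges <- tibble::tibble(node_a = c(1, 1), node_b = c(2, 2),
                          R_c = c(0.05, 0.10))
  net <- network_graph(nodes, edges)
  fl <- solve_flow(net, medium)
  expect_equal(fl$edges$Q[2] / fl$edges$Q[1], 16, tolerance = 1e-12)
  # exact Hagen-Poiseuille pressure drop per edge by construction
  G <- pi * edges$R_c^4 / (8 * medium$mu * 1)
  expect_equal(fl$edges$Q, G * 5, tolerance = 1e-12)
})

test_that("solve_flow matches a dense direct solve on small graphs", {
  set.seed(42)
  for (rep in 1:5) {
    n_nodes <- sample(3:5, 1)
    pos <- matrix(runif(3 * n_nodes, 0, 2), ncol = 3)
    # random connected graph with <= 6 edges: spanning tree + extras
    e <- cbind(2:n_nodes, vapply(2:n_nodes, function(i) sample(i - 1, 1), 1L))
    extra <- matrix(sample(n_nodes, 4, replace = TRUE), ncol = 2)
    extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
    e <- unique(rbind(e, extra))
    e <- e[seq_len(min(6, nrow(e))), , drop = FALSE]
    nodes <- tibble::tibble(id = seq_len(n_nodes), x = pos[, 1], y = pos[, 2],
                            z = pos[, 3], bc_type = "interior",
                            bc_value = NA_real_)
    nodes$bc_type[1] <- "pressure"; nodes$bc_value[1] <- 10
    nodes$bc_type[n_nodes] <- "pressure"; nodes$bc_value[n_nodes] <- 0
    edges <- tibble::tibble(node_a = e[, 1], node_b = e[, 2],
                            R_c = runif(nrow(e), 0.02, 0.08))
    net <- network_graph(nodes, edges)
    fl <- solve_flow(net, medium)
    # dense oracle: assemble the full Laplacian and eliminate fixed nodes
    ia <- match(net$edges$node_a, nodes$id)
    ib <- match(net$edges$node_b, nodes$id)
    G <- pi * net$edges$R_c^4 / (8 * medium$mu * net$edges$L)
    Lap <- matrix(0, n_nodes, n_nodes)
    for (k in seq_along(G)) {
      Lap[ia[k], ia[k]] <- Lap[ia[k], ia[k]] + G[k]
      Lap[ib[k], ib[k]] <- Lap[ib[k], ib[k]] + G[k]
      Lap[ia[k], ib[k]] <- Lap[ia[k], ib[k]] - G[k]
      Lap[ib[k], ia[k]] <- Lap[ib[k], ia[k]] - G[k]
    }
    fixed <- c(1, n_nodes); free <- setdiff(seq_len(n_nodes), fixed)
    pfix <- c(10, 0)
    p <- numeric(n_nodes); p[fixed] <- pfix
    if (length(free)) {
      p[free] <- solve(Lap[free, free, drop = FALSE],
                       -Lap[free, fixed, drop = FALSE] %*% pfix)
    }
    expect_equal(fl$nodes$p, p, tolerance = 1e-12)
    expect_equal(fl$edges$Q, G * (p[ia] - p[ib]), tolerance = 1e-12)
  }
})

lattice_with_bc <- function(block_central = FALSE) {
  net <- build_unit_network(4, 4, 4, s = 0.5, R_c = 0.04)
  net <- set_face_bc(net, "x-", "pressure", 10)
  net <- set_face_bc(net, "x+", "pressure", 0)
  if (block_central) net <- block_edge(net, perfunet:::central_primary_edge(net))
  net
}

test_that("flow is conserved and gauge invariant on the 4x4x4 lattice", {
  net <- lattice_with_bc()
  fl <- solve_flow(net, medium)
  expect_lt(fl$balance_residual, 1e-10)
  g <- glance(fl)
  expect_equal(g$total_inflow, g$total_outflow,
               tolerance = 1e-10)
  # uniform pressure offset leaves flows unchanged
  net2 <- set_face_bc(set_face_bc(net, "x-", "pressure", 110),
                      "x+", "pressure", 100)
  fl2 <- solve_flow(net2, medium)
  expect_equal(fl2$edges$Q, fl$edges$Q, tolerance = 1e-9)
})

test_that("a central blockage reroutes flow through secondary channels", {
  base <- solve_flow(lattice_with_bc(), medium)
  blocked_net <- lattice_with_bc(block_central = TRUE)
  fl <- solve_flow(blocked_net, medium)
  eid <- blocked_net$edges$id[blocked_net$edges$blocked]
  expect_equal(fl$edges$Q[fl$edges$id == eid], 0)
  # without blockage the y/z channels are stagnant; with it they carry flow
  sec_base <- base$edges$Q[base$edges$id %in%
                             blocked_net$edges$id[blocked_net$edges$axis != "x"]]
  expect_lt(max(abs(sec_base)), 1e-12 * max(abs(base$edges$Q)))
  sec <- fl$edges$Q[fl$edges$id %in%
                      blocked_net$edges$id[blocked_net$edges$axis != "x"]]
  expect_gt(max(abs(sec)), 1e-6 * max(abs(fl$edges$Q)))
  # blocking never increases total flow at fixed driving pressure
  expect_lte(glance(fl)$total_inflow, glance(base)$total_inflow * (1 + 1e-12))
})

test_that("blocking requires an alternative path", {
  nodes <- tibble::tibble(id = 1:2, x = c(0, 1), y = 0, z = 0,
                          bc_type = "pressure", bc_value = c(5, 0))
  par2 <- network_graph(nodes, tibble::tibble(node_a = c(1, 1),
                                              node_b = c(2, 2), R_c = 0.05))
  b <- block_edge(par2, 1)
  fl <- solve_flow(b, medium)
  expect_equal(fl$edges$Q[1], 0)
  expect_gt(abs(fl$edges$Q[2]), 0)
  single <- network_graph(nodes, tibble::tibble(node_a = 1, node_b = 2,
                                                R_c = 0.05))
  expect_error(block_edge(single, 1), class = "perfunet_wellposedness_error")
  expect_error(block_edge(single, 99), class = "perfunet_validation_error")
})

test_that("flow solves require a pressure anchor", {
  nodes <- tibble::tibble(id = 1:2, x = c(0, 1), y = 0, z = 0,
                          bc_type = c("inflow", "interior"),
                          bc_value = c(1, NA))
  net <- network_graph(nodes, tibble::tibble(node_a = 1, node_b = 2,
                                             R_c = 0.05))
  err <- expect_error(solve_flow(net, medium),
                      class = "perfunet_wellposedness_error")
  expect_match(conditionMessage(err), "node")
})

test_that("solute routing mixes by flow weight and integrates sinks", {
  # uniform transport: everything at the inlet concentration
  net <- lattice_with_bc()
  fl <- solve_flow(net, medium)
  so <- suppressWarnings(route_solute(net, fl, 0.2))
  flowing <- abs(so$edges$Q) > 1e-12 * max(abs(so$edges$Q))
  expect_equal(so$edges$c_out[flowing], rep(0.2, sum(flowing)))

  # Y junction: (Q=1, c=1) merges with (Q=3, c=0) -> 0.25 downstream
  nodes <- tibble::tibble(id = 1:4,
                          x = c(0, 0, 1, 2), y = c(0, 1, 0.5, 0.5), z = 0,
                          bc_type = c("inflow", "inflow", "interior", "pressure"),
                          bc_value = c(1, 3, NA, 0))
  edges <- tibble::tibble(node_a = c(1, 2, 3), node_b = c(3, 3, 4), R_c = 0.1)
  net <- network_graph(nodes, edges)
  fl <- solve_flow(net, medium)
  so <- route_solute(net, fl, c("1" = 1, "2" = 0))
  expect_equal(so$nodes$c[so$nodes$id == 3], 0.25, tolerance = 1e-12)
  expect_equal(so$edges$c_out[3], 0.25, tolerance = 1e-12)

  # single edge with constant per-length loss: outlet = inlet - phi L / Q
  line <- two_edge_line()
  fl <- solve_flow(line, medium)
  phi <- 1e-4
  so <- route_solute(line, fl, 0.5, per_edge_sink = phi)
  expect_equal(so$edges$c_out[1], 0.5 - phi * 1 / 0.003, tolerance = 1e-12)
})

test_that("solute mass is conserved at junctions and globally with zero sink", {
  net <- lattice_with_bc(block_central = TRUE)
  fl <- solve_flow(net, medium)
  so <- suppressWarnings(route_solute(net, fl, 0.2))
  ed <- dplyr::left_join(so$edges, fl$edges[, c("id", "node_a", "node_b")],
                         by = "id")
  up <- ifelse(ed$Q >= 0, ed$node_a, ed$node_b)
  dn <- ifelse(ed$Q >= 0, ed$node_b, ed$node_a)
  flux_scale <- sum(abs(ed$Q) * 0.2)
  for (nid in so$nodes$id) {
    fin <- sum(abs(ed$Q[dn == nid]) * ed$c_out[dn == nid], na.rm = TRUE)
    fout <- sum(abs(ed$Q[up == nid]) * ed$c_in[up == nid], na.rm = TRUE)
    ext <- external_flows(fl)$external_flow[match(nid, fl$nodes$id)]
    fext <- ext * 0.2 * (ext > 0) +
      ext * so$nodes$c[so$nodes$id == nid] * (ext < 0)
    expect_lt(abs(fin - fout + fext) / flux_scale, 1e-8)
  }
})

test_that("dimensionless numbers match direct evaluation and warn as contracted", {
  nums <- assumption_numbers(R_c = 0.05, v = 8, L = 50, nu = 0.696, D_c = 3e-3)
  expect_equal(nums$Re, 2 * 0.05 * 8 / 0.696)
  expect_equal(round(nums$Re, 2), 1.15)
  expect_equal(nums$Pe_z, 8 * 50 / 3e-3)
  expect_equal(nums$Gz, 8 * 0.05^2 / (3e-3 * 50))
  still <- assumption_numbers(0.05, 0, 5, 0.696, 3e-3)
  expect_equal(unlist(still), c(Re = 0, Pe_z = 0, Gz = 0))
  expect_warning(assumption_numbers(0.05, 80, 2000, 0.696, 3e-3), "Re > 10")
  expect_warning(assumption_numbers(0.05, 0.001, 5, 0.696, 3e-3), "Pe_z < 10")
  expect_warning(assumption_numbers(0.05, 8, 0.5, 0.696, 3e-3), "Gz > 1")
})

test_that("networks round-trip through CSV and JSON", {
  net <- lattice_with_bc(block_central = TRUE)
  nf <- withr::local_tempfile(fileext = ".csv")
  ef <- withr::local_tempfile(fileext = ".csv")
  write_network_csv(net, nf, ef)
  back <- read_network_csv(nf, ef)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges[, c("id", "node_a", "node_b", "R_c", "L", "blocked")],
               net$edges[, c("id", "node_a", "node_b", "R_c", "L", "blocked")])
  jf <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, jf)
  back2 <- read_network_json(jf)
  expect_equal(back2$edges$blocked, net$edges$blocked)
  expect_equal(back2$nodes$bc_value, net$nodes$bc_value)
})
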