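# Config-driven runs, VTK/CSV/JSON export and fixture generation.

#' Write voxel fields as a legacy VTK image-data file
#'
#' ASCII `STRUCTURED_POINTS` with one `SCALARS` block per field; readable by
#' ParaView/VTK. The resolved-config hash (or any caller-supplied tag) is
#' embedded in the header line.
#'
#' @param grid A `voxel_grid`.
#' @param fields Named list of arrays with the grid's shape (numeric or
#'   logical); `NA` is written as -1.
#' @param path Output `.vtk` path.
#' @param tag Free-text header tag (e.g. a config hash).
#' @export
write_vtk <- function(grid, fields, path, tag = "perfunet") {
  stopifnot(inherits(grid, "voxel_grid"), is.list(fields),
            !is.null(names(fields)))
  sh <- grid$shape
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    paste0("perfunet voxel fields | ", tag),
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", sh[1], sh[2], sh[3]),
    sprintf("ORIGIN %.9g %.9g %.9g",
            grid$origin[1] + grid$h / 2, grid$origin[2] + grid$h / 2,
            grid$origin[3] + grid$h / 2),
    sprintf("SPACING %.9g %.9g %.9g", grid$h, grid$h, grid$h),
    sprintf("POINT_DATA %d", prod(sh))
  ), con)
  for (nm in names(fields)) {
    v <- as.numeric(fields[[nm]])
    v[is.na(v)] <- -1
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(paste(formatC(v, format = "g", digits = 9), collapse = " "),
               con)
  }
  invisible(path)
}

config_schema <- list(
  top = c("scenario", "preset", "params", "seed", "resolution", "output",
          "sphere_limit", "unit_max", "sweep", "march", "unit_sim",
          "net_flow"),
  sphere_limit = c("c_surface", "tol"),
  unit_max = c("kind", "R_w", "c_channel", "Pi_w", "tol", "s_cap"),
  sweep = c("c_list", "R_w_list", "Pi_list", "presets", "kind", "tol"),
  march = c("v", "c_in", "L", "n_elem", "R_c", "t_w", "f_p", "s_cap", "tol"),
  unit_sim = c("kind", "size", "R_w", "c_channel", "Pi_w",
               "blocked_segments", "density"),
  net_flow = c("n_x", "n_y", "n_z", "s", "R_c", "p_in", "p_out",
               "blocked_edges", "c_inlet"),
  output = c("dir", "write_vtk", "write_csv")
)

#' Load and validate a run configuration
#'
#' JSON configuration with a `scenario` key naming one of `sphere_limit`,
#' `unit_max`, `sweep`, `march`, `unit_sim`, `net_flow`, plus a section of the
#' same name with the scenario parameters. Unknown keys are rejected before
#' any computation.
#'
#' @param path JSON config file, or a list already in config shape.
#' @return A validated `run_config` list.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else path
  bad <- setdiff(names(cfg), config_schema$top)
  if (length(bad)) {
    abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", "), "."),
          class = "perfunet_validation_error")
  }
  scen <- cfg$scenario
  if (is.null(scen) || !scen %in% c("sphere_limit", "unit_max", "sweep",
                                    "march", "unit_sim", "net_flow")) {
    abort("Config must name a valid `scenario`.",
          class = "perfunet_validation_error")
  }
  sect <- cfg[[scen]]
  if (is.null(sect)) {
    abort(paste0("Config lacks the `", scen, "` section."),
          class = "perfunet_validation_error")
  }
  bad <- setdiff(names(sect), config_schema[[scen]])
  if (length(bad)) {
    abort(paste0("Unknown key(s) in `", scen, "`: ",
                 paste(bad, collapse = ", "), "."),
          class = "perfunet_validation_error")
  }
  if (!is.null(cfg$output)) {
    bad <- setdiff(names(cfg$output), config_schema$output)
    if (length(bad)) {
      abort(paste0("Unknown key(s) in `output`: ",
                   paste(bad, collapse = ", "), "."),
            class = "perfunet_validation_error")
    }
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$preset <- cfg$preset %||% "defaults"
  structure(cfg, class = "run_config")
}

resolve_params <- function(cfg) {
  if (!is.null(cfg$params)) {
    list(tissue = do.call(tissue_params, cfg$params$tissue),
         transport = do.call(species_transport, cfg$params$transport),
         medium = do.call(medium_params, cfg$params$medium %||% list()))
  } else {
    load_preset(cfg$preset)
  }
}

#' Execute a configured scenario
#'
#' Dispatches to the scenario named in the config, optionally writing CSV/VTK
#' artifacts, and returns a machine-readable report. Re-running with the same
#' config and seed reproduces all scalars.
#'
#' @param cfg A `run_config` (or path to one).
#' @param out_dir Output directory override; `NULL` writes no files unless the
#'   config `output$dir` is set.
#' @return A `run_report` list: `config` echo, `config_hash`, `scenario`,
#'   `scalars` (named list), `tables` (named list of tibbles), `artifacts`
#'   (paths written), `elapsed` seconds and `status`
#'   (`"ok"` or `"infeasible"`).
#' @export
run_scenario <- function(cfg, out_dir = NULL) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  t0 <- proc.time()[["elapsed"]]
  hash <- rlang::hash(cfg)
  p <- resolve_params(cfg)
  scen <- cfg$scenario
  sect <- cfg[[scen]]
  h_override <- cfg$resolution
  scalars <- list()
  tables <- list()
  status <- "ok"
  vtk_payload <- NULL

  if (scen == "sphere_limit") {
    r <- max_sphere_diameter(sect$c_surface, p$transport, p$tissue,
                             tol = sect$tol %||% 1e-3)
    scalars <- list(d_max = r$d_max, c_center = r$c_center)
    tables$result <- r
  } else if (scen == "unit_max") {
    r <- max_unit_size(sect$kind %||% "cuboid", sect$R_w, sect$c_channel,
                       p$tissue, p$transport, Pi_w = sect$Pi_w %||% Inf,
                       tol = sect$tol %||% 1e-2, h = h_override,
                       s_cap = sect$s_cap %||% 16)
    scalars <- list(s_max = r$s_max, ratio = r$ratio, min_c = r$min_c)
    tables$result <- tidy(r)
    if (!r$feasible) status <- "infeasible"
  } else if (scen == "sweep") {
    sw <- volume_ratio_sweep(sect$c_list, sect$R_w_list, sect$Pi_list,
                             sect$presets %||% cfg$preset,
                             kind = sect$kind %||% "cuboid",
                             tol = sect$tol %||% 1e-2, h = h_override)
    tables$sweep <- sw
    scalars <- list(n_cases = nrow(sw), n_feasible = sum(sw$feasible))
    if (!any(sw$feasible)) status <- "infeasible"
  } else if (scen == "march") {
    spec <- channel_spec(sect$R_c, sect$t_w %||% 0, sect$f_p %||% 1)
    m <- long_channel_march(sect$v, sect$c_in, sect$L, sect$n_elem %||% 10,
                            spec, p$transport, p$tissue,
                            tol = sect$tol %||% 1e-3,
                            s_cap = sect$s_cap %||% 3, h = h_override)
    scalars <- list(outlet_c = m$outlet_c,
                    s_final = utils::tail(m$elements$s, 1),
                    balance_residual = m$balance_residual)
    tables$march <- tidy(m)
  } else if (scen == "unit_sim") {
    cell <- make_unit_cell(sect$kind %||% "cuboid", sect$size, sect$R_w)
    if (length(sect$blocked_segments)) {
      cell <- block_segment(cell, sect$blocked_segments)
    }
    h <- h_override %||% (sect$R_w / 5)
    grid <- voxelize(cell, h)
    density <- NULL
    if (!is.null(sect$density)) {
      density <- correlated_density_field(grid, sect$density$mean,
                                          sect$density$cv, sect$density$ell,
                                          seed = cfg$seed)
    }
    Pi_w <- sect$Pi_w %||% Inf
    bc <- if (is.infinite(Pi_w)) boundary_spec("dirichlet", sect$c_channel)
          else boundary_spec("robin", sect$c_channel, Pi_w)
    fld <- solve_steady_mm(grid, density, p$transport, p$tissue, bc)
    st <- field_stats(fld, p$tissue$c_H)
    vol <- measure_volumes(grid)
    scalars <- list(min_c = st$min, mean_c = st$mean,
                    hypoxic_fraction = st$hypoxic_fraction,
                    ratio = vol$ratio)
    tables$stats <- dplyr::bind_cols(st, vol)
    vtk_payload <- list(grid = grid,
                        fields = list(concentration = fld$values,
                                      tissue = grid$tissue))
    if (!is.null(density)) vtk_payload$fields$density <- density$values
  } else if (scen == "net_flow") {
    net <- build_unit_network(sect$n_x, sect$n_y, sect$n_z, sect$s, sect$R_c)
    net <- set_face_bc(net, "x-", "pressure", sect$p_in %||% 10)
    net <- set_face_bc(net, "x+", "pressure", sect$p_out %||% 0)
    for (eid in sect$blocked_edges %||% integer()) {
      net <- block_edge(net, eid)
    }
    fl <- solve_flow(net, p$medium)
    so <- route_solute(net, fl, sect$c_inlet %||% p$medium$c_in)
    tables$flow <- fl$edges
    tables$solute <- so$edges
    scalars <- list(max_velocity = max(abs(fl$edges$v)),
                    total_inflow = glance(fl)$total_inflow,
                    balance_residual = fl$balance_residual)
  }

  artifacts <- character()
  dir <- out_dir %||% cfg$output$dir
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_csv_files <- cfg$output$write_csv %||% TRUE
    if (write_csv_files) {
      for (nm in names(tables)) {
        f <- file.path(dir, paste0(scen, "_", nm, ".csv"))
        con <- file(f, "w")
        writeLines(paste0("# config_hash: ", hash), con)
        close(con)
        suppressWarnings(write.table(tables[[nm]], f, sep = ",",
                                     row.names = FALSE, append = TRUE))
        artifacts <- c(artifacts, f)
      }
    }
    if (isTRUE(cfg$output$write_vtk) && !is.null(vtk_payload)) {
      f <- file.path(dir, paste0(scen, ".vtk"))
      write_vtk(vtk_payload$grid, vtk_payload$fields, f, tag = hash)
      artifacts <- c(artifacts, f)
    }
    report_path <- file.path(dir, paste0(scen, "_report.json"))
    jsonlite::write_json(
      list(config = unclass(cfg), config_hash = hash, scenario = scen,
           scalars = scalars, status = status),
      report_path, auto_unbox = TRUE, digits = NA, na = "null", force = TRUE
    )
    artifacts <- c(artifacts, report_path)
  }

  structure(list(config = cfg, config_hash = hash, scenario = scen,
                 scalars = scalars, tables = tables, artifacts = artifacts,
                 elapsed = proc.time()[["elapsed"]] - t0, status = status),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Run report: scenario %s, status %s (%.1f s)\n",
              x$scenario, x$status, x$elapsed))
  for (nm in names(x$scalars)) {
    cat(sprintf("  %s = %.6g\n", nm, x$scalars[[nm]]))
  }
  invisible(x)
}

#' Generate the reference fixture set
#'
#' Writes the test geometries (unit cells, a 4x4x4 lattice with a blocked
#' variant), a seeded density field and the shipped parameter presets to a
#' directory, in the package's plain-text formats.
#'
#' @param out_dir Writable output directory.
#' @param seed Seed for the density-field fixture.
#' @return Tibble of written files (`name`, `path`).
#' @export
generate_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(paste0("Cannot create fixture directory ", out_dir, "."),
          class = "perfunet_io_error")
  }
  paths <- character()
  for (nm in preset_names()) {
    f <- file.path(out_dir, paste0("preset_", nm, ".json"))
    write_params(load_preset(nm), f)
    paths <- c(paths, f)
  }
  net <- build_unit_network(4, 4, 4, s = 0.5, R_c = 0.04)
  net <- set_face_bc(net, "x-", "pressure", 10)
  net <- set_face_bc(net, "x+", "pressure", 0)
  write_network_csv(net, file.path(out_dir, "lattice_nodes.csv"),
                    file.path(out_dir, "lattice_edges.csv"))
  blocked <- block_edge(net, central_primary_edge(net))
  write_network_csv(blocked, file.path(out_dir, "lattice_blocked_nodes.csv"),
                    file.path(out_dir, "lattice_blocked_edges.csv"))
  paths <- c(paths, file.path(out_dir, c("lattice_nodes.csv",
                                         "lattice_edges.csv",
                                         "lattice_blocked_nodes.csv",
                                         "lattice_blocked_edges.csv")))
  for (kind in c("cuboid", "rhombic_dodecahedron")) {
    cell <- make_unit_cell(kind, if (kind == "cuboid") 0.5 else 0.4, 0.05)
    f <- file.path(out_dir, paste0("cell_", kind, "_segments.csv"))
    write.csv(cell$segments, f, row.names = FALSE)
    paths <- c(paths, f)
  }
  grid <- suppressWarnings(voxelize(make_unit_cell("cuboid", 0.5, 0.05),
                                    h = 0.025))
  fld <- correlated_density_field(grid, mean = 2e5, cv = 0.3, ell = 0.1,
                                  seed = seed)
  f <- file.path(out_dir, "density_field.csv")
  write_density_csv(fld, f)
  paths <- c(paths, f)
  tibble(name = basename(paths), path = paths)
}

# the x-directed edge nearest the lattice centroid
central_primary_edge <- function(net) {
  e <- net$edges
  nd <- net$nodes
  ia <- match(e$node_a, nd$id)
  ib <- match(e$node_b, nd$id)
  mid <- cbind((nd$x[ia] + nd$x[ib]) / 2, (nd$y[ia] + nd$y[ib]) / 2,
               (nd$z[ia] + nd$z[ib]) / 2)
  ctr <- c(mean(range(nd$x)), mean(range(nd$y)), mean(range(nd$z)))
  is_x <- abs(nd$x[ia] - nd$x[ib]) > 0
  d <- sqrt(rowSums(sweep(mid, 2, ctr)^2))
  d[!is_x] <- Inf
  e$id[which.min(d)]
}
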