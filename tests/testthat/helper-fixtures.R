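# Shared fixtures, built once per test run.

.fixtures <- new.env()

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

small_tube_seq <- function() {
  fixture("small_tube_seq",
          make_constricting_tube(tube_spec(n_s = 64, n_phi = 32, n_t = 10)))
}

unit_cylinder <- function() {
  fixture("unit_cylinder", mesh_cylinder(10, 100, n_s = 64, n_phi = 48))
}

unit_sphere <- function() {
  fixture("unit_sphere", mesh_icosphere(10, subdiv = 3))
}

cell_records_cyl <- function() {
  fixture("cell_records_cyl", {
    cyl <- mesh_cylinder(30, 200, n_s = 96, n_phi = 64)
    spec <- cell_field_spec(n_cells = 600, mean_area = 60,
                            aspect_profile = 2.5, jitter = 0.1, seed = 7)
    tess <- make_cell_tessellation(spec, cyl)
    list(surface = cyl, tess = tess,
         records = embed_and_measure(tess$polygons, cyl))
  })
}

rotate_z <- function(v, th) {
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  v %*% t(R)
}
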