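# Shared phantom fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Straight canonical phantom: length 30 mm, canal radius 3 mm, 0.8 mm grid.
straight_phantom <- function() {
  fixture("straight", function() {
    spec <- phantom_spec(c(0, 0, 15), c(0, 0, 0), c(0, 0, -15),
                         canal_radius = 3, inner_thickness = 3,
                         outer_thickness = 4, spacing = 0.8)
    c(generate_phantom(spec), list(spec = spec))
  })
}

# Bent phantom: 120 degree elbow, grid-aligned bend plane.
bent_phantom <- function() {
  fixture("bent", function() {
    spec <- phantom_spec(c(0, 0, 0), c(0, 10, 10), c(0, 20, 10),
                         canal_radius = 3, spacing = 0.8)
    c(generate_phantom(spec), list(spec = spec))
  })
}

# A small rendered image/label pair for segmentation and atlas tests.
rendered_phantom <- function(seed = 11) {
  fixture(paste0("rendered", seed), function() {
    ph <- straight_phantom()
    img <- render_intensity(ph$labels, intensity_model(seed = seed))
    list(image = img, labels = ph$labels, truth = ph$truth)
  })
}

expect_points_close <- function(a, b, tol) {
  expect_lt(sqrt(sum((a - b)^2)), tol)
}
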