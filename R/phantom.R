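#' Geometric phantom primitives
#'
#' Ellipse and rectangle primitives for [phantom_spec()].  Coordinates are
#' physical mm with the origin at the canvas center, x to the right and y
#' up; `rotation` is counter-clockwise in degrees.  Later primitives
#' overwrite earlier ones (painter's order).
#'
#' @param center `c(x, y)` in mm.
#' @param axes ellipse semi-axes `c(a, b)` in mm.
#' @param size rectangle `c(width, height)` in mm.
#' @param rotation degrees counter-clockwise.
#' @param material material name, must exist in the spec's material table.
#' @return a primitive list usable in `phantom_spec(primitives = ...)`.
#' @export
phantom_ellipse <- function(center, axes, material, rotation = 0) {
  list(kind = "ellipse", center = center, axes = axes,
       rotation = rotation, material = material)
}

#' @rdname phantom_ellipse
#' @export
phantom_rect <- function(center, size, material, rotation = 0) {
  list(kind = "rect", center = center, size = size,
       rotation = rotation, material = material)
}

#' Material-labeled phantom specification
#'
#' @param shape canvas `c(rows, cols)` in pixels.
#' @param pixel_spacing pixel size in mm.
#' @param primitives list of [phantom_ellipse()] / [phantom_rect()]
#'   primitives, painted in order over an all-air canvas.
#' @param materials a [load_materials()] table.
#' @param name optional phantom name recorded in provenance.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, pixel_spacing = 1, primitives = list(),
                         materials = load_materials(), name = "custom") {
  shape <- as.integer(shape)
  known <- unique(materials$material)
  for (p in primitives) {
    if (!p$material %in% known) {
      abort_mvmar(sprintf("primitive uses unknown material '%s'", p$material),
                  "mvmar_validation_error")
    }
    half <- shape * pixel_spacing / 2
    if (abs(p$center[1]) > half[2] || abs(p$center[2]) > half[1]) {
      abort_mvmar("primitive center lies outside the canvas", "mvmar_validation_error")
    }
  }
  if (!"air" %in% known) {
    abort_mvmar("material table must include 'air' (background)", "mvmar_validation_error")
  }
  structure(list(shape = shape, pixel_spacing = pixel_spacing,
                 primitives = primitives, materials = materials, name = name),
            class = "phantom_spec")
}

#' Rasterize a phantom to a material-label grid
#'
#' Paints each primitive in order onto an all-air canvas; each pixel ends
#' up with exactly one material label.
#'
#' @param spec a [phantom_spec()].
#' @return an integer matrix of class `material_grid` with attributes
#'   `materials` (label names, index 1 = air background) and
#'   `pixel_spacing`.
#' @export
rasterize_phantom <- function(spec) {
  nr <- spec$shape[1]; nc <- spec$shape[2]; ps <- spec$pixel_spacing
  xs <- (seq_len(nc) - (nc + 1) / 2) * ps
  ys <- ((nr + 1) / 2 - seq_len(nr)) * ps
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  levels <- "air"
  grid <- matrix(1L, nr, nc)
  for (p in spec$primitives) {
    idx <- match(p$material, levels)
    if (is.na(idx)) {
      levels <- c(levels, p$material)
      idx <- length(levels)
    }
    th <- p$rotation * pi / 180
    u <- (X - p$center[1]) * cos(th) + (Y - p$center[2]) * sin(th)
    v <- -(X - p$center[1]) * sin(th) + (Y - p$center[2]) * cos(th)
    mask <- if (p$kind == "ellipse") {
      (u / p$axes[1])^2 + (v / p$axes[2])^2 <= 1
    } else {
      abs(u) <= p$size[1] / 2 & abs(v) <= p$size[2] / 2
    }
    grid[mask] <- idx
  }
  structure(grid, materials = levels, pixel_spacing = ps,
            class = "material_grid")
}

#' Multi-metal dental phantom
#'
#' A head-sized soft-tissue ellipse with a bone skull shell, an oral air
#' cavity, a jaw arc of bone, and 2-4 small high-attenuation inserts along
#' the arc emulating metal dentures.  All anatomy is specified in mm, so
#' the same phantom renders at any grid size; the default field of view is
#' 256 mm.
#'
#' @param shape grid `c(rows, cols)`.
#' @param pixel_spacing mm per pixel; default keeps a 256 mm field of view.
#' @param n_inserts number of metal inserts (2-4).
#' @param insert_radius insert radius in mm.
#' @param insert_material metal material for the inserts.
#' @param materials a [load_materials()] table.
#' @return a [phantom_spec()].
#' @export
dental_phantom <- function(shape = c(256, 256),
                           pixel_spacing = 256 / shape[1],
                           n_inserts = 3, insert_radius = 6,
                           insert_material = "amalgam",
                           materials = load_materials()) {
  if (n_inserts < 2 || n_inserts > 4) {
    abort_mvmar("n_inserts must be between 2 and 4", "mvmar_validation_error")
  }
  arch_center <- c(0, -15); arch_r <- 55
  arc_deg <- seq(200, 340, by = 14)
  prims <- c(
    list(
      phantom_ellipse(c(0, 0), c(85, 100), "bone"),        # skull shell
      phantom_ellipse(c(0, 0), c(80, 95), "soft_tissue"),  # head interior
      phantom_ellipse(c(0, -20), c(25, 18), "air")         # oral cavity
    ),
    lapply(arc_deg, function(d) {                          # jaw arc
      th <- d * pi / 180
      phantom_ellipse(arch_center + arch_r * c(cos(th), sin(th)), c(9, 9), "bone")
    }),
    lapply(insert_angles(n_inserts), function(d) {         # metal dentures
      th <- d * pi / 180
      phantom_ellipse(arch_center + arch_r * c(cos(th), sin(th)),
                      rep(insert_radius, 2), insert_material)
    })
  )
  phantom_spec(shape, pixel_spacing, prims, materials, name = "dental")
}

insert_angles <- function(n) {
  switch(as.character(n),
         "2" = c(240, 300),
         "3" = c(230, 270, 310),
         "4" = c(225, 255, 285, 315))
}

#' Named regions of interest for the dental phantom
#'
#' `inter_metal` sits in soft tissue between the dental inserts, inside the
#' corridor where the metal shadows interact; `soft` is a far-from-metal
#' soft-tissue reference; `air` lies outside the head.
#'
#' @param shape grid `c(rows, cols)`.
#' @param pixel_spacing mm per pixel (must match the rendered phantom).
#' @return named list of [roi_circle()] / [roi_rect()] objects in pixels.
#' @export
dental_rois <- function(shape = c(256, 256), pixel_spacing = 256 / shape[1]) {
  list(
    inter_metal = roi_rect(mm_to_px(c(0, -48), shape, pixel_spacing),
                           size = round(c(14, 30) / pixel_spacing), # h x w, mm
                           label = "inter_metal"),
    soft = roi_circle(mm_to_px(c(0, 55), shape, pixel_spacing),
                      radius = round(10 / pixel_spacing), label = "soft"),
    air = roi_circle(mm_to_px(c(100, 80), shape, pixel_spacing),
                     radius = round(8 / pixel_spacing), label = "air")
  )
}

#' Water-body quality-assurance phantom with removable metal rod
#'
#' A synthetic stand-in for a commercial head QA phantom: a water body
#' with a bone shell, a soft-tissue insert (region A), a low-density air
#' cavity (region B) and an optional removable metal rod.  With the rod
#' removed the image is artifact-free and serves as the reference; the
#' named ROIs mirror a two-region (soft / low-density) evaluation layout.
#'
#' @inheritParams dental_phantom
#' @param metal_rod include the titanium rod.
#' @return a [phantom_spec()].
#' @export
cirs_like_phantom <- function(shape = c(256, 256),
                              pixel_spacing = 256 / shape[1],
                              metal_rod = TRUE,
                              materials = load_materials()) {
  prims <- list(
    phantom_ellipse(c(0, 0), c(90, 95), "bone"),
    phantom_ellipse(c(0, 0), c(86, 91), "water"),
    phantom_ellipse(c(35, 20), c(12, 12), "soft_tissue"), # region A insert
    phantom_ellipse(c(-35, 20), c(12, 12), "air")         # region B cavity
  )
  if (metal_rod) {
    prims <- c(prims, list(phantom_ellipse(c(0, -45), c(7, 7), "amalgam")))
  }
  phantom_spec(shape, pixel_spacing, prims, materials, name = "cirs_like")
}

#' @rdname cirs_like_phantom
#' @return `cirs_rois()`: named list with ROIs `A` (soft-tissue insert),
#'   `B` (low-density insert), `water` and `air`.
#' @export
cirs_rois <- function(shape = c(256, 256), pixel_spacing = 256 / shape[1]) {
  r <- function(mm, rad, label) {
    roi_circle(mm_to_px(mm, shape, pixel_spacing),
               radius = round(rad / pixel_spacing), label = label)
  }
  list(
    A = r(c(35, 20), 8, "A"),
    B = r(c(-35, 20), 8, "B"),
    water = r(c(0, 55), 10, "water"),
    air = r(c(105, 85), 8, "air")
  )
}

# mm (x right, y up, origin at center) -> pixel c(row, col)
mm_to_px <- function(xy, shape, pixel_spacing) {
  c(round((shape[1] + 1) / 2 - xy[2] / pixel_spacing),
    round(xy[1] / pixel_spacing + (shape[2] + 1) / 2))
}

#' Read / write a phantom specification as YAML
#'
#' @param spec a [phantom_spec()].
#' @param path YAML file path.
#' @param materials material table used when reading (the YAML stores only
#'   primitive geometry and material names).
#' @return `read_phantom_yaml()` returns a [phantom_spec()].
#' @export
write_phantom_yaml <- function(spec, path) {
  yaml::write_yaml(list(
    name = spec$name, shape = spec$shape, pixel_spacing = spec$pixel_spacing,
    primitives = spec$primitives
  ), path)
  invisible(path)
}

#' @rdname write_phantom_yaml
#' @export
read_phantom_yaml <- function(path, materials = load_materials()) {
  y <- yaml::read_yaml(path)
  prims <- lapply(y$primitives, function(p) {
    p$center <- as.numeric(p$center)
    if (!is.null(p$axes)) p$axes <- as.numeric(p$axes)
    if (!is.null(p$size)) p$size <- as.numeric(p$size)
    p
  })
  phantom_spec(y$shape, y$pixel_spacing, prims, materials,
               name = y$name %||% "custom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
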