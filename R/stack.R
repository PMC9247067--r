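#' Material electrical properties
#'
#' A material is described by its conductivity and relative permittivity.
#' Resistivity is derived as `1/conductivity`; a conductivity of exactly zero
#' is legal and denotes a perfect insulator whose resistive branch carries no
#' current (the derived resistance is `Inf`, never a division-by-zero error).
#'
#' @param name Character label (e.g. `"Culture Medium"`).
#' @param conductivity Conductivity sigma in S/m, `>= 0`.
#' @param rel_permittivity Relative permittivity eps_r, dimensionless, `>= 1`.
#' @return An object of class `cc_material`.
#' @examples
#' material("Culture Medium", 1.5, 80.1)
#' @export
material <- function(name, conductivity, rel_permittivity) {
  stopifnot(is.character(name), length(name) == 1L)
  conductivity <- as.numeric(conductivity)
  rel_permittivity <- as.numeric(rel_permittivity)
  if (!is.finite(conductivity) || conductivity < 0)
    stop("conductivity must be a finite number >= 0", call. = FALSE)
  if (!is.finite(rel_permittivity) || rel_permittivity < 1)
    stop("rel_permittivity must be a finite number >= 1", call. = FALSE)
  structure(
    list(name = name, conductivity = conductivity,
         rel_permittivity = rel_permittivity),
    class = "cc_material"
  )
}

#' A single slab of the layered cylinder
#'
#' @param material A [material()] object.
#' @param thickness Layer thickness in metres, `> 0`.
#' @param role One of `"electrode"`, `"insulator"`, `"medium"`. The role is
#'   metadata used for reporting and for locating the culture-medium layer;
#'   it never changes the physics of the layer.
#' @return An object of class `cc_layer`.
#' @export
layer <- function(material, thickness, role = c("insulator", "electrode", "medium")) {
  role <- match.arg(role)
  if (!inherits(material, "cc_material"))
    stop("material must be a cc_material object", call. = FALSE)
  thickness <- as.numeric(thickness)
  if (!is.finite(thickness) || thickness <= 0)
    stop("invalid geometry: layer thickness must be > 0", call. = FALSE)
  structure(
    list(material = material, thickness = thickness, role = role),
    class = "cc_layer"
  )
}

#' A layered cylindrical stimulation setup
#'
#' The stack is an ordered electrode-to-electrode sequence of coaxial layers
#' sharing one cross-sectional area `A = pi * radius^2`. Exactly one layer
#' must have role `"medium"`: that is the conductive electrolyte whose field
#' is the quantity of interest.
#'
#' @param id Character identifier.
#' @param layers List of [layer()] objects, at least 3, electrode-to-electrode
#'   order.
#' @param radius Cylinder radius in metres, `> 0`.
#' @param waveform Optional applied-voltage waveform (see [wf_sinusoid()] and
#'   friends).
#' @return An object of class `cc_stack`.
#' @examples
#' med <- material("Culture Medium", 1.5, 80.1)
#' gls <- material("Glass", 1e-13, 6.85)
#' stack_setup("demo",
#'   list(layer(gls, 0.16e-3), layer(med, 9.8e-3, role = "medium"),
#'        layer(gls, 0.16e-3)),
#'   radius = 16.5e-3)
#' @export
stack_setup <- function(id, layers, radius, waveform = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.list(layers) || length(layers) < 3L)
    stop("a stack needs at least 3 layers", call. = FALSE)
  if (!all(vapply(layers, inherits, logical(1), what = "cc_layer")))
    stop("layers must all be cc_layer objects", call. = FALSE)
  radius <- as.numeric(radius)
  if (!is.finite(radius) || radius <= 0)
    stop("invalid geometry: radius must be > 0", call. = FALSE)
  roles <- vapply(layers, function(l) l$role, character(1))
  if (sum(roles == "medium") != 1L)
    stop("configuration error: a stack must contain exactly one layer with role 'medium'",
         call. = FALSE)
  if (!is.null(waveform) && !inherits(waveform, "cc_waveform"))
    stop("waveform must be a cc_waveform or NULL", call. = FALSE)
  structure(
    list(id = id, layers = layers, radius = radius, waveform = waveform),
    class = "cc_stack"
  )
}

#' @export
print.cc_stack <- function(x, ...) {
  cat(sprintf("<cc_stack '%s'>  radius %.4g mm, area %.4g m^2\n",
              x$id, x$radius * 1e3, stack_area(x)))
  tab <- stack_table(x)
  tab$thickness_mm <- tab$thickness_m * 1e3
  print(tab[, c("name", "role", "thickness_mm", "sigma_S_per_m", "eps_r")],
        row.names = FALSE)
  if (!is.null(x$waveform)) {
    cat("waveform: ")
    print(x$waveform)
  }
  invisible(x)
}

#' Cross-sectional area of a stack (m^2)
#' @param stack A [stack_setup()] object.
#' @export
stack_area <- function(stack) pi * stack$radius^2

#' Index of the culture-medium layer
#' @param stack A [stack_setup()] object.
#' @export
medium_index <- function(stack) {
  which(vapply(stack$layers, function(l) l$role, character(1)) == "medium")
}

# Plain data.frame view of the layer parameters; internal workhorse.
stack_table <- function(stack) {
  data.frame(
    name = vapply(stack$layers, function(l) l$material$name, character(1)),
    role = vapply(stack$layers, function(l) l$role, character(1)),
    thickness_m = vapply(stack$layers, function(l) l$thickness, numeric(1)),
    sigma_S_per_m = vapply(stack$layers, function(l) l$material$conductivity, numeric(1)),
    eps_r = vapply(stack$layers, function(l) l$material$rel_permittivity, numeric(1)),
    stringsAsFactors = FALSE
  )
}

# Per-layer conductance (S), capacitance (F) and thickness (m) vectors for a
# stack, under either ladder model.
#   full:    every layer keeps both branches, G = sigma*A/l, C = eps0*eps_r*A/l.
#   reduced: electrodes dropped; insulators become pure capacitors (G = 0);
#            the medium becomes a pure resistor (its capacitive branch is
#            dropped, C = 0).  This mirrors the classic C-R-C approximation.
stack_ladder <- function(stack, model = c("full", "reduced")) {
  model <- match.arg(model)
  tab <- stack_table(stack)
  A <- stack_area(stack)
  if (model == "reduced") {
    keep <- tab$role != "electrode"
    tab <- tab[keep, , drop = FALSE]
    tab$sigma_S_per_m[tab$role == "insulator"] <- 0
  }
  G <- tab$sigma_S_per_m * A / tab$thickness_m
  C <- cc_eps0 * tab$eps_r * A / tab$thickness_m
  if (model == "reduced") C[tab$role == "medium"] <- 0
  list(name = tab$name, role = tab$role, l = tab$thickness_m,
       G = G, C = C, medium = which(tab$role == "medium"), model = model)
}
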