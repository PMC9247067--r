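# Stack configuration I/O.  The on-disk format mirrors how rig dimensions are
# reported in the literature: millimetres and volts, one block per setup:
#
#   setup:
#     id: demo
#     radius_mm: 16.5
#     layers:
#       - {name: Glass, role: insulator, thickness_mm: 0.16,
#          sigma_S_per_m: 1.0e-13, eps_r: 6.85}
#       ...
#     waveform:
#       type: sinusoid          # sinusoid|trapezoid|sawtooth|pwl|dc
#       amplitude_V: 44.81
#       frequency_Hz: 60.0e+3
#
# Internally everything is SI (metres).

config_error <- function(fields) {
  stop("malformed stack config; offending fields: ",
       paste(fields, collapse = ", "), call. = FALSE)
}

num_field <- function(x, name, bad) {
  v <- suppressWarnings(as.numeric(x))
  if (length(v) != 1L || is.na(v)) bad(name) else v
}

parse_waveform_config <- function(wc, bad) {
  type <- wc$type
  if (is.null(type)) { bad("waveform.type"); return(NULL) }
  n <- function(f) num_field(wc[[f]], paste0("waveform.", f), bad)
  switch(as.character(type),
    sinusoid = wf_sinusoid(n("amplitude_V"), n("frequency_Hz"),
                           if (is.null(wc$phase_rad)) 0 else n("phase_rad")),
    trapezoid = wf_trapezoid(n("amplitude_V"), n("rise_s"), n("width_s"),
                             if (is.null(wc$fall_s)) n("rise_s") else n("fall_s"),
                             polarity = if (is.null(wc$polarity)) 1 else n("polarity"),
                             period = if (is.null(wc$period_s)) NULL else n("period_s")),
    sawtooth = wf_sawtooth(n("peak_to_peak_V"), n("rise_s"), n("fall_s")),
    pwl = wf_pwl(vapply(wc$t_s, num_field, numeric(1), name = "waveform.t_s", bad = bad),
                 vapply(wc$v_V, num_field, numeric(1), name = "waveform.v_V", bad = bad)),
    dc = wf_dc(n("level_V")),
    bad(paste0("waveform.type (unknown: ", type, ")"))
  )
}

#' Read a stack configuration file
#'
#' Parses the YAML stack schema (millimetre/volt units on disk, SI in R) and
#' validates it. A malformed file raises one error listing every offending
#' field; a stack without exactly one `medium` layer is rejected.
#'
#' @param path Path to a YAML config.
#' @return A [stack_setup()] object.
#' @seealso [write_stack_config()], [build_setup()]
#' @export
read_stack_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$setup)) config_error("setup")
  sc <- raw$setup
  bad_fields <- character(0)
  bad <- function(f) { bad_fields <<- c(bad_fields, f); NA_real_ }
  id <- if (is.null(sc$id)) { bad("id"); "unnamed" } else as.character(sc$id)
  radius <- num_field(sc$radius_mm, "radius_mm", bad) * 1e-3
  if (is.null(sc$layers) || !length(sc$layers)) bad("layers")
  layers <- list()
  for (k in seq_along(sc$layers)) {
    lc <- sc$layers[[k]]
    pre <- sprintf("layers[%d].", k)
    nm <- if (is.null(lc$name)) { bad(paste0(pre, "name")); "?" } else as.character(lc$name)
    role <- if (is.null(lc$role) || !lc$role %in% c("electrode", "insulator", "medium")) {
      bad(paste0(pre, "role")); "insulator"
    } else lc$role
    th <- num_field(lc$thickness_mm, paste0(pre, "thickness_mm"), bad) * 1e-3
    sg <- num_field(lc$sigma_S_per_m, paste0(pre, "sigma_S_per_m"), bad)
    er <- num_field(lc$eps_r, paste0(pre, "eps_r"), bad)
    if (!length(bad_fields))
      layers[[k]] <- layer(material(nm, sg, er), th, role = role)
  }
  wf <- NULL
  if (!is.null(sc$waveform)) wf <- parse_waveform_config(sc$waveform, bad)
  if (length(bad_fields)) config_error(unique(bad_fields))
  roles <- vapply(sc$layers, function(l) as.character(l$role), character(1))
  if (sum(roles == "medium") != 1L)
    config_error("layers (exactly one layer must have role 'medium')")
  stack_setup(id, layers, radius, waveform = wf)
}

waveform_to_config <- function(w) {
  switch(w$variant,
    sinusoid = list(type = "sinusoid", amplitude_V = w$amplitude,
                    frequency_Hz = w$frequency, phase_rad = w$phase),
    trapezoid = c(list(type = "trapezoid", amplitude_V = w$amplitude,
                       rise_s = w$rise, width_s = w$width, fall_s = w$fall,
                       polarity = w$polarity),
                  if (!is.null(w$period)) list(period_s = w$period)),
    sawtooth = list(type = "sawtooth", peak_to_peak_V = w$peak_to_peak,
                    rise_s = w$rise, fall_s = w$fall),
    pwl = list(type = "pwl", t_s = w$t, v_V = w$v),
    constant_dc = list(type = "dc", level_V = w$level))
}

#' Write a stack configuration file
#'
#' Inverse of [read_stack_config()]: serialising a stack and reading it back
#' reproduces identical physics (bit-level field values), which the test
#' suite asserts for every packaged fixture. Floats are written with an
#' explicit decimal point and signed exponent so any YAML 1.1 parser resolves
#' them as numbers.
#'
#' @param stack A [stack_setup()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack_config <- function(stack, path) {
  tab <- stack_table(stack)
  # divide by the reader's conversion factor so mm -> m -> mm -> m is exact
  cfg <- list(setup = list(
    id = stack$id,
    radius_mm = stack$radius / 1e-3,
    layers = lapply(seq_len(nrow(tab)), function(k) list(
      name = tab$name[k], role = tab$role[k],
      thickness_mm = tab$thickness_m[k] / 1e-3,
      sigma_S_per_m = tab$sigma_S_per_m[k],
      eps_r = tab$eps_r[k]
    ))
  ))
  if (!is.null(stack$waveform))
    cfg$setup$waveform <- waveform_to_config(stack$waveform)
  writeLines(yaml::as.yaml(cfg, precision = 17L), path)
  invisible(path)
}
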