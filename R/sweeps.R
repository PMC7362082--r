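#' Specify a geometry sensitivity sweep
#'
#' Defines a sweep of the single-fiber model over fiber radius or fiber
#' length. Defaults follow the model's sensitivity study: radius from 25 to
#' 225 nm (9 values) at 12 um length, or length from 0.5 to 14 um (10
#' values) at 165 nm radius.
#'
#' @param vary `"radius"` or `"length"`.
#' @param values Swept values, strictly increasing and positive: nm for
#'   radius, um for length. `NULL` for the default grid.
#' @param geometry Base [fiber_geometry()] providing the fixed quantities.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(vary = c("radius", "length"), values = NULL,
                       geometry = fiber_geometry()) {
  vary <- match.arg(vary)
  if (is.null(values)) {
    values <- switch(vary,
      radius = seq(25, 225, length.out = 9),
      length = seq(0.5, 14, length.out = 10)
    )
  }
  if (any(!is.finite(values)) || any(values <= 0) ||
      is.unsorted(values, strictly = TRUE)) {
    abort("values must be strictly increasing and positive")
  }
  structure(list(vary = vary, values = values, geometry = geometry),
            class = "sweep_spec")
}

#' Run a geometry sensitivity sweep
#'
#' Regenerates the single-fiber force-stretch curve for every value of the
#' swept geometry parameter. All curves share the force grid of `controls`,
#' so the long-format result is rectangular. A failure for one value is
#' recorded (as zero rows for that value plus an entry in the `failures`
#' attribute), never fatal to the whole sweep.
#'
#' @param spec A [sweep_spec()].
#' @param params A [fibrin_params()] object.
#' @param controls A [sim_controls()] object.
#' @return A tibble of class `fibrin_sweep` in long format with columns
#'   `swept_param`, `swept_value`, `stretch`, `extension_nm`, `force_pN`,
#'   `per_monomer_force_pN`, `monomers_per_cross_section`, `n_elements`.
#' @examples
#' sw <- run_sweep(sweep_spec("radius", c(50, 150)),
#'                 controls = sim_controls(force_max = 50, n_steps = 20))
#' dplyr::count(sw, swept_value)
#' @export
run_sweep <- function(spec, params = fibrin_params(),
                      controls = sim_controls()) {
  stopifnot(inherits(spec, "sweep_spec"))
  g0 <- spec$geometry
  failures <- list()
  rows <- purrr::map(spec$values, function(val) {
    g <- switch(spec$vary,
      radius = fiber_geometry(
        fiber_length = g0$fiber_length, fiber_diameter = 2 * val,
        protein_fraction = g0$protein_fraction,
        monomer_radius = g0$monomer_radius,
        element_rest_length = g0$element_rest_length),
      length = fiber_geometry(
        fiber_length = val * 1000,                       # um -> nm
        fiber_diameter = g0$fiber_diameter,
        protein_fraction = g0$protein_fraction,
        monomer_radius = g0$monomer_radius,
        element_rest_length = g0$element_rest_length)
    )
    crv <- tryCatch(
      fiber_curve(params = params, geometry = g, controls = controls),
      error = function(e) {
        failures[[as.character(val)]] <<- conditionMessage(e)
        NULL
      })
    if (is.null(crv)) return(NULL)
    dplyr::mutate(
      tidy(crv),
      swept_param = spec$vary, swept_value = val,
      monomers_per_cross_section = curve_metadata(crv)$monomers_per_cross_section,
      n_elements = curve_metadata(crv)$n_elements,
      .before = 1
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- failures
  attr(out, "spec") <- spec
  class(out) <- c("fibrin_sweep", class(out))
  out
}

#' Plot a sensitivity sweep
#'
#' Radius sweeps are drawn as fiber force vs stretch, length sweeps as fiber
#' force vs absolute extension (the stretch-force relation of the replicated
#' element chain is length-invariant; absolute extension is what
#' distinguishes fiber lengths).
#'
#' @param object A `fibrin_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fibrin_sweep
#' @export
autoplot.fibrin_sweep <- function(object, ...) {
  spec <- attr(object, "spec")
  xvar <- if (spec$vary == "length") "extension_nm" else "stretch"
  xlab <- if (spec$vary == "length") "extension (nm)" else "stretch λ"
  legend <- if (spec$vary == "length") "length (µm)" else "radius (nm)"
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data[[xvar]], y = .data$force_pN,
                 colour = factor(.data$swept_value),
                 group = .data$swept_value)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = xlab, y = "fiber force (pN)", colour = legend,
                  title = sprintf("Fiber %s sensitivity", spec$vary)) +
    ggplot2::theme_minimal()
}
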