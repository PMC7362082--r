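#' Force-extension curve objects
#'
#' A `force_extension_curve` is a tibble of ordered samples with a `scale`
#' attribute (`"molecule"`, `"fiber"`, `"clot"` or `"reference"`) and a
#' metadata list (parameters, geometry, derived counts, break index, a
#' parameter hash). It behaves as a tibble in every pipeline; [tidy()]
#' drops the attributes, [glance()] gives a one-row summary and
#' [autoplot()] draws the curve.
#'
#' @param data A data frame of samples.
#' @param scale Curve scale.
#' @param metadata Named list of run metadata.
#' @return A `force_extension_curve` tibble.
#' @keywords internal
#' @export
new_force_extension_curve <- function(data, scale, metadata = list()) {
  stopifnot(scale %in% c("molecule", "fiber", "clot", "reference"))
  out <- as_tibble(data)
  attr(out, "scale") <- scale
  metadata$param_hash <- metadata$param_hash %||%
    rlang::hash(metadata[setdiff(names(metadata), "param_hash")])
  attr(out, "metadata") <- metadata
  class(out) <- c("force_extension_curve", class(out))
  out
}

#' Scale and metadata of a curve
#'
#' @param curve A `force_extension_curve`.
#' @return `curve_scale()`: a string; `curve_metadata()`: a named list.
#' @export
curve_scale <- function(curve) attr(curve, "scale")

#' @rdname curve_scale
#' @export
curve_metadata <- function(curve) attr(curve, "metadata")

# (x, y) accessors by scale: independent variable and force column
curve_xy_names <- function(curve) {
  switch(curve_scale(curve),
    molecule  = c("extension_nm", "force_pN"),
    fiber     = c("stretch", "force_pN"),
    clot      = c("lambda1", "clot_force_mN"),
    reference = c("x", "force")
  )
}

#' @method tidy force_extension_curve
#' @export
tidy.force_extension_curve <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "force_extension_curve")
  attr(out, "scale") <- NULL
  attr(out, "metadata") <- NULL
  as_tibble(out)
}

#' @method glance force_extension_curve
#' @export
glance.force_extension_curve <- function(x, ...) {
  nm <- curve_xy_names(x)
  md <- curve_metadata(x)
  tibble(
    scale = curve_scale(x),
    n_samples = nrow(x),
    x_max = if (nrow(x)) max(x[[nm[1]]]) else NA_real_,
    force_max = if (nrow(x)) max(x[[nm[2]]]) else NA_real_,
    break_index = md$break_index %||% NA_integer_,
    param_hash = md$param_hash %||% NA_character_
  )
}

#' @export
print.force_extension_curve <- function(x, ...) {
  md <- curve_metadata(x)
  cat(sprintf("<force_extension_curve> scale = %s, %d samples", curve_scale(x),
              nrow(x)))
  bi <- md$break_index %||% NA_integer_
  if (!is.na(bi)) cat(sprintf(", break at step %d", bi))
  cat("\n")
  NextMethod()
}

#' Plot a force-extension curve
#'
#' @param object A `force_extension_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot force_extension_curve
#' @export
autoplot.force_extension_curve <- function(object, ...) {
  nm <- curve_xy_names(object)
  labs <- switch(curve_scale(object),
    molecule  = c("extension (nm)", "force (pN)", "Fibrinogen monomer"),
    fiber     = c("stretch λ", "fiber force (pN)", "Single fibrin fiber"),
    clot      = c("principal stretch λ1", "clot force (mN)", "Fibrin clot"),
    reference = c("x", "force", "Reference curve")
  )
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data[[nm[1]]], y = .data[[nm[2]]])) +
    ggplot2::geom_line(linewidth = 0.7, colour = "#2c5f8a") +
    ggplot2::labs(x = labs[1], y = labs[2], title = labs[3]) +
    ggplot2::theme_minimal()
}
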