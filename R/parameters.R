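#' Kinetic parameter set for amyloid-beta aggregation
#'
#' Bundles the rate constants and concentrations of the
#' nucleation-elongation-secondary-nucleation model together with the
#' concentration unit convention in force.
#'
#' The primary nucleation constant `k_n` is used with two different
#' conventions by the model families in this package, and the stored tag
#' records which one the numeric value refers to:
#' * `"invitro"`: `k_n` is a constant (heterogeneous, surface-catalysed)
#'   source term with units concentration / time, as it enters the closed
#'   in vitro master equations.
#' * `"homogeneous"`: `k_n` multiplies `m^2` (homogeneous primary
#'   nucleation), with units 1 / (concentration * time), as it enters the
#'   in vivo models with constant monomer supply.
#'
#' Rescaling concentrations by a factor `c` therefore transforms `k_n` by
#' `c` under the in vitro convention and by `1/c` under the homogeneous one.
#'
#' @param k_n primary nucleation rate constant (see Details for units).
#' @param k_plus elongation rate constant, 1 / (concentration * time).
#' @param k_2 secondary nucleation rate constant,
#'   1 / (concentration^2 * time).
#' @param K_m monomer saturation constant of secondary nucleation,
#'   concentration^2.
#' @param K_M mass saturation constant of secondary nucleation,
#'   concentration^2. Defaults to `K_m`; the in vivo models assume the two
#'   are equal unless explicitly overridden.
#' @param m_0 monomer concentration (initial concentration in vitro,
#'   constant supply level in vivo).
#' @param conc_scale dimensionless positive factor recording the scale of
#'   the concentration unit relative to molar (e.g. `1e6` for micromolar
#'   numbers obtained from molar ones).
#' @param k_n_convention `"invitro"` or `"homogeneous"`; see Details.
#'
#' @return An object of class `kinetic_parameters`.
#' @seealso [abeta_parameters()] for the reference Abeta42/HEPES values,
#'   [rescale_parameters()], [validate_parameters()], [read_parameters()].
#' @export
#' @examples
#' p <- kinetic_parameters(k_n = 1.6e-11, k_plus = 1e10, k_2 = 2.1e14,
#'                         K_m = 2.3e-17, m_0 = 3e-6)
#' rescale_parameters(p, 1e6)
kinetic_parameters <- function(k_n, k_plus, k_2, K_m, K_M = K_m, m_0,
                               conc_scale = 1,
                               k_n_convention = c("invitro", "homogeneous")) {
  k_n_convention <- match.arg(k_n_convention)
  p <- structure(
    list(k_n = as.numeric(k_n), k_plus = as.numeric(k_plus),
         k_2 = as.numeric(k_2), K_m = as.numeric(K_m), K_M = as.numeric(K_M),
         m_0 = as.numeric(m_0), conc_scale = as.numeric(conc_scale),
         k_n_convention = k_n_convention,
         K_M_overridden = !missing(K_M) && !isTRUE(all.equal(K_M, K_m))),
    class = "kinetic_parameters")
  bad <- validate_parameters(p)
  bad <- bad[!startsWith(bad, "note:")]
  if (length(bad)) stop("invalid kinetic parameters: ",
                        paste(bad, collapse = "; "), call. = FALSE)
  p
}

#' Reference Abeta42 (HEPES buffer) kinetic parameters
#'
#' The experimentally calibrated rate constants for Abeta42 aggregation in
#' HEPES buffer: `k_n = 1.6e-11 M/h`, `k_2 = 2.1e14 M^-2 h^-1`,
#' `K_m = 2.3e-17 M^2`, `k_plus = 1e10 M^-1 h^-1`, `m_0 = 3e-6 M`,
#' optionally rescaled to another concentration unit.
#'
#' @param conc_scale concentration scale factor applied to the molar values;
#'   the package default working unit is micromolar (`conc_scale = 1e6`),
#'   in which `k_2 = 210`, `k_plus = 1e4`, `K_M = 2.3e-5`, `m_0 = 3`.
#' @param k_n_convention convention tag for `k_n`, see
#'   [kinetic_parameters()].
#' @return A `kinetic_parameters` object.
#' @export
#' @examples
#' abeta_parameters()           # micromolar-hour units
#' abeta_parameters(conc_scale = 1)  # molar-hour units
abeta_parameters <- function(conc_scale = 1e6,
                             k_n_convention = c("invitro", "homogeneous")) {
  p <- kinetic_parameters(k_n = 1.6e-11, k_plus = 1e10, k_2 = 2.1e14,
                          K_m = 2.3e-17, m_0 = 3e-6, conc_scale = 1,
                          k_n_convention = match.arg(k_n_convention))
  rescale_parameters(p, conc_scale)
}

#' Rescale a parameter set to a new concentration unit
#'
#' Re-expresses all rates and concentrations in units where every
#' concentration variable is multiplied by `c`. Trajectories of every model
#' in the package are invariant under this change of units: simulating with
#' the rescaled parameters yields the original concentration trajectories
#' multiplied by `c`.
#'
#' The transformations are `m_0 -> c*m_0`, `K_m -> c^2*K_m`,
#' `K_M -> c^2*K_M`, `k_plus -> k_plus/c`, `k_2 -> k_2/c^2`, and
#' `k_n -> c*k_n` (in vitro convention) or `k_n -> k_n/c` (homogeneous).
#'
#' @param params a `kinetic_parameters` object.
#' @param c positive scale factor.
#' @return The rescaled `kinetic_parameters` object with `conc_scale`
#'   multiplied by `c`.
#' @export
rescale_parameters <- function(params, c) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("`c` must be a single positive number", call. = FALSE)
  params$k_n <- if (params$k_n_convention == "invitro")
    params$k_n * c else params$k_n / c
  params$k_plus <- params$k_plus / c
  params$k_2 <- params$k_2 / c^2
  params$K_m <- params$K_m * c^2
  params$K_M <- params$K_M * c^2
  params$m_0 <- params$m_0 * c
  params$conc_scale <- params$conc_scale * c
  params
}

#' Check a parameter set against its invariants
#'
#' Returns descriptions of violated rules instead of throwing: positivity of
#' every rate and concentration, and a note when the mass saturation
#' constant differs from the monomer saturation constant without having been
#' explicitly overridden.
#'
#' @param params a `kinetic_parameters` object (or a bare list with the same
#'   fields).
#' @return A character vector of violation messages; empty when all
#'   invariants hold. Entries prefixed `"note:"` are advisory.
#' @export
validate_parameters <- function(params) {
  out <- character()
  for (f in c("k_n", "k_plus", "k_2", "K_m", "K_M", "m_0", "conc_scale")) {
    v <- params[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      out <- c(out, sprintf("%s: must be a single finite number", f))
    else if (v <= 0)
      out <- c(out, sprintf("%s: must be strictly positive", f))
  }
  if (is.numeric(params$K_M) && is.numeric(params$K_m) &&
      length(params$K_M) == 1L && length(params$K_m) == 1L &&
      is.finite(params$K_M) && is.finite(params$K_m) &&
      params$K_M != params$K_m && !isTRUE(params$K_M_overridden))
    out <- c(out, "note: K_M differs from K_m without an explicit override")
  out
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameters (conc_scale =", format(x$conc_scale),
      ", k_n convention:", x$k_n_convention, ")\n")
  for (f in c("k_n", "k_plus", "k_2", "K_m", "K_M", "m_0"))
    cat(sprintf("  %-7s %g\n", f, x[[f]]))
  invisible(x)
}

#' Read a kinetic parameter file
#'
#' Loads a flat key/value parameter file in YAML or JSON. Recognised keys
#' are exactly `k_n`, `k_plus`, `k_2`, `K_m`, `K_M`, `m_0`, `conc_scale`
#' (`K_M` and `conc_scale` optional); any other key is an error.
#'
#' @param path file path; `.json` is parsed as JSON, anything else as YAML.
#' @param k_n_convention convention tag for `k_n`, see
#'   [kinetic_parameters()].
#' @return A `kinetic_parameters` object.
#' @export
read_parameters <- function(path,
                            k_n_convention = c("invitro", "homogeneous")) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  allowed <- c("k_n", "k_plus", "k_2", "K_m", "K_M", "m_0", "conc_scale")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  required <- c("k_n", "k_plus", "k_2", "K_m", "m_0")
  missing <- setdiff(required, names(vals))
  if (length(missing))
    stop("missing parameter key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  kinetic_parameters(
    k_n = vals$k_n, k_plus = vals$k_plus, k_2 = vals$k_2, K_m = vals$K_m,
    K_M = if (is.null(vals$K_M)) vals$K_m else vals$K_M, m_0 = vals$m_0,
    conc_scale = if (is.null(vals$conc_scale)) 1 else vals$conc_scale,
    k_n_convention = match.arg(k_n_convention))
}
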