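#' Kinetic bloom model parameters
#'
#' Builds and validates the 12-parameter set of the chill/heat kinetic bloom
#' model. Chill accumulates as dynamic-model chill portions; heat accumulates
#' as growing degree hours (GDH) weighted by a transition function of the
#' chill state. Defaults are the conventional starting values used when
#' calibrating the model to flowering records (see [phenoflex_bounds()] for
#' the matching box constraints).
#'
#' @param yc Chilling requirement: critical accumulated chill portions that
#'   end chill accumulation.
#' @param zc Heating requirement: critical accumulated (weighted) GDH that
#'   triggers bloom.
#' @param s1 Steepness of the chill-to-heat transition.
#' @param Tu Optimal temperature of the GDH response (degrees C).
#' @param E0,E1 Activation energies (divided by the gas constant, so in
#'   Kelvin) of forming and destroying the precursor to the dormancy-breaking
#'   factor.
#' @param A0,A1 Amplitudes (1/h) of the formation and destruction processes.
#' @param Tf Transition temperature (degrees C) of the sigmoidal conversion of
#'   the precursor to chill portions.
#' @param Tc Upper (critical) temperature of the GDH response (degrees C).
#' @param Tb Base temperature of the GDH response (degrees C).
#' @param slope Steepness of the sigmoidal conversion function.
#' @return A named numeric vector of class `"phenoflex_params"`.
#' @export
#' @examples
#' p <- phenoflex_params(yc = 60, zc = 150)
#' gdh_value(15, p)
phenoflex_params <- function(yc = 40, zc = 190, s1 = 0.5, Tu = 25,
                             E0 = 3372.8, E1 = 9900.3, A0 = 6319.5,
                             A1 = 5.939917e13, Tf = 4, Tc = 36, Tb = 4,
                             slope = 1.60) {
  p <- c(yc = yc, zc = zc, s1 = s1, Tu = Tu, E0 = E0, E1 = E1, A0 = A0,
         A1 = A1, Tf = Tf, Tc = Tc, Tb = Tb, slope = slope)
  validate_params(p)
  class(p) <- "phenoflex_params"
  p
}

#' Coerce a named vector or list to a parameter set
#' @param x named numeric vector or list with the 12 parameter names.
#' @return object of class `"phenoflex_params"`.
#' @export
as_phenoflex_params <- function(x) {
  x <- unlist(x)
  missing <- setdiff(.pf_par_names, names(x))
  if (length(missing) > 0)
    stop("missing parameters: ", paste(missing, collapse = ", "))
  p <- x[.pf_par_names]
  validate_params(p)
  class(p) <- "phenoflex_params"
  p
}

validate_params <- function(p) {
  if (any(!is.finite(p))) stop("parameters must be finite")
  if (p[["yc"]] <= 0 || p[["zc"]] <= 0) stop("yc and zc must be positive")
  if (any(p[c("A0", "A1", "E0", "E1")] <= 0))
    stop("A0, A1, E0, E1 must be positive")
  if (!(p[["Tb"]] < p[["Tu"]] && p[["Tu"]] < p[["Tc"]]))
    stop("temperature ordering violated: need Tb < Tu < Tc")
  invisible(p)
}

#' Default parameter box for calibration
#'
#' Lower and upper bounds for each of the 12 model parameters, matching the
#' deliberately wide boxes used when fitting the model to single-season
#' flowering records.
#'
#' @return list with named numeric vectors `lower` and `upper`.
#' @export
phenoflex_bounds <- function() {
  lower <- c(yc = 20, zc = 100, s1 = 0.1, Tu = 0, E0 = 3000, E1 = 9000,
             A0 = 6000, A1 = 5e13, Tf = 0, Tc = 0, Tb = 0, slope = 0.05)
  upper <- c(yc = 80, zc = 500, s1 = 1.0, Tu = 30, E0 = 4000, E1 = 10000,
             A0 = 7000, A1 = 6e13, Tf = 10, Tc = 40, Tb = 10, slope = 50)
  list(lower = lower, upper = upper)
}

#' Reference fitted parameter sets for four British cultivars
#'
#' Calibrated parameter sets for the most-recorded British cultivar of each of
#' the four focal fruit types: apple 'Bramley', cherry 'Stella', pear
#' 'Conference' and plum 'Victoria'. Useful as realistic ground-truth values
#' for the synthetic-data generator and for computing temperature-response
#' curves.
#'
#' @return Named list of four `"phenoflex_params"` objects.
#' @export
#' @examples
#' curves <- chill_response_curve(example_cultivar_params()[["Victoria"]])
#' curves$temp_C[which.max(curves$chill_portions)]
example_cultivar_params <- function() {
  lapply(list(
    Bramley = c(yc = 70.34, zc = 223.59, s1 = 0.99, Tu = 17.82,
                E0 = 3209.96, E1 = 9720.66, A0 = 6021.25, A1 = 5.93e13,
                Tf = 6.55, Tc = 20.59, Tb = 6.87, slope = 14.80),
    Stella = c(yc = 28.84, zc = 165.93, s1 = 0.80, Tu = 17.18,
               E0 = 3348.03, E1 = 9831.58, A0 = 6067.81, A1 = 5.94e13,
               Tf = 7.86, Tc = 20.02, Tb = 7.43, slope = 10.32),
    Conference = c(yc = 32.40, zc = 271.76, s1 = 1.00, Tu = 16.62,
                   E0 = 3391.97, E1 = 9902.75, A0 = 6092.49, A1 = 5.94e13,
                   Tf = 7.13, Tc = 42.94, Tb = 3.90, slope = 5.02),
    Victoria = c(yc = 60.74, zc = 122.08, s1 = 0.80, Tu = 14.80,
                 E0 = 3369.83, E1 = 9893.16, A0 = 6673.28, A1 = 5.94e13,
                 Tf = 7.03, Tc = 36.09, Tb = 6.66, slope = 4.32)
  ), as_phenoflex_params)
}

#' Read/write parameter sets as JSON
#'
#' Parameters are stored keyed by their conventional names so files are
#' portable across tools.
#'
#' @param params a `"phenoflex_params"` object (or coercible).
#' @param path file path.
#' @return `read_params_json` returns a `"phenoflex_params"` object.
#' @export
write_params_json <- function(params, path) {
  params <- as_phenoflex_params(params)
  jsonlite::write_json(as.list(unclass(params)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  as_phenoflex_params(jsonlite::read_json(path, simplifyVector = TRUE))
}
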