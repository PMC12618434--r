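# Built-in fixtures: the worked examples and ecological models shipped with
# the package, plus the slice registry for the coral model.

fixture_dir <- function() {
  p <- system.file("extdata", "models", package = "stabscape")
  if (p == "") p <- file.path("inst", "extdata", "models")
  p
}

#' Registry of built-in models and arrangements
#'
#' Returns exact-rational encodings of the shipped fixtures:
#' \describe{
#'   \item{two_ellipses}{arrangement of two intersecting ellipses in the
#'     plane (six positive-quadrant regions).}
#'   \item{quadratic_discriminant}{one-variable model `a1*x^2 + a2*x + a3`
#'     whose singular boundary is the classical discriminant.}
#'   \item{predator_prey}{Holling type II predation of a prey with strong
#'     Allee effect; `predator_prey_s2` has all parameters but the Allee
#'     threshold `A` fixed to the worked-example values (2, 3/2, 1, 1/2, 1).}
#'   \item{levins_culver}{competition-colonization metapopulation model,
#'     2 variables, 4 parameters.}
#'   \item{coral}{coral-bacteria symbiosis model, 3 variables, 8 parameters;
#'     `coral_fixed` applies d = gamma_y = gamma_z = 1, beta_y = 5, leaving
#'     free b, beta_z, btilde, dtilde.}
#' }
#'
#' @param name optional single fixture name; omit for the full list.
#' @return the named fixture, or a named list of all fixtures.
#' @export
fixtures <- function(name = NULL) {
  dir <- fixture_dir()
  reg <- list(
    two_ellipses = function() parse_arrangement_file(
      file.path(dir, "two_ellipses.json")),
    quadratic_discriminant = function() parse_model_file(
      file.path(dir, "quadratic_discriminant.json")),
    predator_prey = function() parse_model_file(
      file.path(dir, "predator_prey.json")),
    predator_prey_s2 = function() {
      sys <- parse_model_file(file.path(dir, "predator_prey.json"))
      ode_system(sys$variables, sys$parameters_all, sys$rates_text,
                 fixed = list(alpha = "2", beta = "3/2", gamma = "1",
                              m = "1/2", K = "1"),
                 name = "predator_prey_s2")
    },
    levins_culver = function() parse_model_file(
      file.path(dir, "levins_culver.json")),
    coral = function() parse_model_file(file.path(dir, "coral.json")),
    coral_fixed = function() {
      sys <- parse_model_file(file.path(dir, "coral.json"))
      ode_system(sys$variables, sys$parameters_all, sys$rates_text,
                 fixed = list(d = "1", gamma_y = "1", gamma_z = "1",
                              beta_y = "5"),
                 name = "coral_fixed")
    }
  )
  if (is.null(name)) return(lapply(reg, function(f) f()))
  if (!name %in% names(reg))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  reg[[name]]()
}

#' The 16 coral slice parameterizations
#'
#' The slice grid along the intrinsic coral birth rate b (viable, b = 2;
#' non-viable, b = 1/2) and the mutualist colonization rate beta_z.
#'
#' @return data.frame with exact-rational columns `b` and `beta_z`.
#' @export
coral_slices <- function() {
  expand.grid(b = c("2", "1/2"),
              beta_z = c("5/2", "3", "7/2", "39/10", "41/10", "59/10", "61/10", "10"),
              stringsAsFactors = FALSE)[, c("b", "beta_z")]
}
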