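#' Kinetic parameter set for the TBP auto-regulation model
#'
#' Bundles the ten rate constants and the total promoter-site concentration
#' that define one instance of the model. All concentrations are molar and
#' all times are seconds.
#'
#' @param k0 basal synthesis rate (M s^-1).
#' @param k1 dimer association rate constant (M^-1 s^-1).
#' @param k2 dimer dissociation rate constant (s^-1).
#' @param k3 TBP--DNA association rate constant (M^-1 s^-1).
#' @param k4 TBP--DNA dissociation rate constant (s^-1).
#' @param k5 maximal regulated synthesis rate (M s^-1).
#' @param k6 Hill cooperativity coefficient (dimensionless, > 0; swept as a
#'   real number, not restricted to integers).
#' @param k7 bound-TBP concentration at half-maximal synthesis (M).
#' @param k8 first-order degradation rate of the free monomer (s^-1).
#'   Dimers and promoter-bound TBP are not degraded.
#' @param D0 total promoter-site concentration (M).
#'
#' @return An object of class `tbp_parameters` (a named list).
#' @seealso [default_parameters()] for the reference mammalian parameter set.
#' @export
#' @examples
#' p <- tbp_parameters(k0 = 0, k1 = 1e5, k2 = 1e-3, k3 = 2e5, k4 = 4e-4,
#'                     k5 = 5e-13, k6 = 2, k7 = 1.25e-8, k8 = 7.4e-5,
#'                     D0 = 2.5e-8)
tbp_parameters <- function(k0, k1, k2, k3, k4, k5, k6, k7, k8, D0) {
  p <- list(k0 = k0, k1 = k1, k2 = k2, k3 = k3, k4 = k4,
            k5 = k5, k6 = k6, k7 = k7, k8 = k8, D0 = D0)
  validate_parameters(p)
  structure(p, class = "tbp_parameters")
}

validate_parameters <- function(p) {
  need <- c("k0", "k1", "k2", "k3", "k4", "k5", "k6", "k7", "k8", "D0")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  v <- unlist(p[need])
  if (any(!is.finite(v)))
    stop("all parameters must be finite numbers")
  if (any(v < 0))
    stop("all parameters must be >= 0")
  if (p$k6 <= 0) stop("k6 must be > 0")
  if (p$D0 <= 0) stop("D0 must be > 0")
  if (p$k8 <= 0) stop("k8 must be > 0")
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named parameters replaced; the result is
#' re-validated.
#'
#' @param p a `tbp_parameters` object.
#' @param ... name = value pairs of parameters to replace.
#' @return A `tbp_parameters` object.
#' @export
#' @examples
#' p <- default_parameters(k0 = 0)
#' set_parameters(p, k3 = 1e5)
set_parameters <- function(p, ...) {
  upd <- list(...)
  bad <- setdiff(names(upd), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(upd)] <- upd
  validate_parameters(p)
  structure(p, class = "tbp_parameters")
}

#' @export
print.tbp_parameters <- function(x, ...) {
  cat("TBP auto-regulation kinetic parameters (SI units: M, s)\n")
  for (nm in names(x))
    cat(sprintf("  %-3s = %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.tbp_parameters <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Read and write parameter sets as flat JSON
#'
#' Parameter sets are serialized as a flat key--value record using the
#' symbols `k0`..`k8`, `D0` in SI units, so they can be shared between
#' analysis scripts.
#'
#' @param p a `tbp_parameters` object.
#' @param path file path.
#' @return `write_parameters()` returns `path` invisibly;
#'   `read_parameters()` returns a `tbp_parameters` object.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "tbp_parameters"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(tbp_parameters, as.list(p))
}
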