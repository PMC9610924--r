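# Built-in edge-weight schemes. Each maps an unordered endpoint-degree pair
# (d1, d2) to a positive weight phi(d1, d2):
#   B1    = d1 + d2                first K-Banhatti
#   B2    = d1 * d2                second K-Banhatti
#   HB1   = (d1 + d2)^2            first K-hyper Banhatti
#   HB2   = (d1 * d2)^2            second K-hyper Banhatti
#   ReZG1 = (d1 + d2) / (d1 d2)    first redefined Zagreb
#   ReZG2 = (d1 d2) / (d1 + d2)    second redefined Zagreb
#   ReZG3 = (d1 d2) (d1 + d2)      third redefined Zagreb
#   ABS   = sqrt((d1 + d2 - 2) / (d1 + d2))   atom-bond sum-connectivity
# The first seven are rational and carried in exact arithmetic; ABS is a
# surd, carried as its exact radicand (d1+d2-2)/(d1+d2) where needed.

.builtin_schemes <- list(
  B1 = list(rational = TRUE, w = function(d1, d2) rat(d1 + d2)),
  B2 = list(rational = TRUE, w = function(d1, d2) rat(d1 * d2)),
  HB1 = list(rational = TRUE, w = function(d1, d2) rat((d1 + d2)^2)),
  HB2 = list(rational = TRUE, w = function(d1, d2) rat((d1 * d2)^2)),
  ReZG1 = list(rational = TRUE, w = function(d1, d2) rat(d1 + d2, d1 * d2)),
  ReZG2 = list(rational = TRUE, w = function(d1, d2) rat(d1 * d2, d1 + d2)),
  ReZG3 = list(rational = TRUE, w = function(d1, d2) rat(d1 * d2 * (d1 + d2))),
  ABS = list(rational = FALSE, radicand = function(d1, d2) rat(d1 + d2 - 2, d1 + d2))
)

#' Names of the built-in weight schemes
#'
#' @return Character vector in the canonical table order.
#' @export
scheme_names <- function() names(.builtin_schemes)

#' Resolve or build an edge-weight scheme
#'
#' @param scheme A scheme name (one of `scheme_names()`), an existing
#'   `weight_scheme`, or -- together with `name` -- a symmetric function of
#'   two degree vectors returning positive numeric weights (user-defined
#'   scheme; all index and entropy operations are scheme-generic).
#' @param name Name for a user-defined scheme.
#' @return A `weight_scheme` object.
#'
#' @examples
#' weight_scheme("B1")
#' randic <- weight_scheme(function(d1, d2) 1 / sqrt(d1 * d2), name = "Randic")
#' @export
weight_scheme <- function(scheme, name = NULL) {
  if (inherits(scheme, "weight_scheme")) return(scheme)
  if (is.character(scheme) && length(scheme) == 1) {
    if (!scheme %in% names(.builtin_schemes)) {
      stop("unknown scheme '", scheme, "'; built-ins are: ",
           paste(names(.builtin_schemes), collapse = ", "), call. = FALSE)
    }
    s <- .builtin_schemes[[scheme]]
    return(structure(c(list(name = scheme, builtin = TRUE), s),
                     class = "weight_scheme"))
  }
  if (is.function(scheme)) {
    nm <- name %||% "user"
    # spot-check symmetry on a small degree grid
    g <- expand.grid(d1 = 1:4, d2 = 1:4)
    if (!isTRUE(all.equal(scheme(g$d1, g$d2), scheme(g$d2, g$d1)))) {
      stop("user-defined weight function must be symmetric in (d1, d2)",
           call. = FALSE)
    }
    return(structure(list(name = nm, builtin = FALSE, rational = FALSE,
                          fun = scheme),
                     class = "weight_scheme"))
  }
  stop("`scheme` must be a scheme name, weight_scheme, or function", call. = FALSE)
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("<weight_scheme> ", x$name,
      if (isTRUE(x$rational)) " (exact rational)" else "", "\n", sep = "")
  invisible(x)
}

.check_abs_domain <- function(scheme, d1, d2) {
  if (scheme$name == "ABS" && any(d1 + d2 <= 2)) {
    stop("ABS weight is undefined for the degree pair (1,1): ",
         "the radicand (d1+d2-2)/(d1+d2) vanishes", call. = FALSE)
  }
}

# exact rational weights for a rational scheme (vectorized over classes)
scheme_weight_rat <- function(scheme, d1, d2) {
  scheme <- weight_scheme(scheme)
  if (!isTRUE(scheme$rational)) {
    stop("scheme '", scheme$name, "' is not rational-valued", call. = FALSE)
  }
  scheme$w(d1, d2)
}

#' Evaluate an edge-weight scheme on degree pairs
#'
#' @param scheme Scheme name, `weight_scheme`, or symmetric function.
#' @param d1,d2 Positive integer degree vectors.
#' @return Numeric weights. Rational schemes are evaluated exactly and
#'   converted at the end; ABS returns `sqrt((d1+d2-2)/(d1+d2))`.
#'
#' @examples
#' edge_weight("B1", 2, 3)       # 5
#' edge_weight("ReZG1", 4, 4)    # 0.5
#' edge_weight("ABS", 3, 4)      # sqrt(5/7)
#' @export
edge_weight <- function(scheme, d1, d2) {
  scheme <- weight_scheme(scheme)
  if (any(d1 < 1) || any(d2 < 1)) stop("degrees must be >= 1", call. = FALSE)
  if (isTRUE(scheme$rational)) return(rat_numeric(scheme$w(d1, d2)))
  if (scheme$name == "ABS") {
    .check_abs_domain(scheme, d1, d2)
    return(sqrt(rat_numeric(scheme$radicand(d1, d2))))
  }
  w <- scheme$fun(d1, d2)
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weight scheme '", scheme$name, "' produced a non-positive or ",
         "non-finite weight", call. = FALSE)
  }
  w
}
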