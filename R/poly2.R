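# Exact bivariate polynomials in the unit-cell parameters (s, t), with
# rational coefficients. Used for the symbolic closed forms of the family
# indices and for the handshake/total identities. Canonical form: reduced
# coefficients, no zero terms, sorted by descending (s_pow + t_pow, s_pow).

#' Construct an exact bivariate polynomial in (s, t)
#'
#' @param s_pow,t_pow Non-negative integer exponent vectors, one entry per term.
#' @param num,den Coefficient numerators/denominators (exact rationals).
#' @return An object of class `bv_poly`: a tibble with columns `s_pow`,
#'   `t_pow`, `num`, `den` in canonical form.
#'
#' @examples
#' bv_poly(c(1, 1, 0, 0), c(1, 0, 1, 0), c(116, 24, 24, -8))  # 116st+24s+24t-8
#' @export
bv_poly <- function(s_pow = integer(), t_pow = integer(),
                    num = numeric(), den = 1) {
  k <- length(num)
  r <- rat(num, rep_len(den, k))
  out <- tibble::tibble(s_pow = as.integer(rep_len(s_pow, k)),
                        t_pow = as.integer(rep_len(t_pow, k)),
                        num = r$num, den = r$den)
  out <- dplyr::group_by(out, .data$s_pow, .data$t_pow)
  out <- dplyr::summarise(out, {
    s <- rat_sum(rat(.data$num, .data$den))
    tibble::tibble(num = s$num, den = s$den)
  }, .groups = "drop")
  out <- dplyr::filter(out, .data$num != 0)
  out <- dplyr::arrange(out, dplyr::desc(.data$s_pow + .data$t_pow),
                        dplyr::desc(.data$s_pow))
  structure(out, class = c("bv_poly", class(out)))
}

# convenience: polynomial a*st + b*s + c*t + d with integer coefficients
bv_lin <- function(st = 0, s = 0, t = 0, const = 0) {
  bv_poly(c(1, 1, 0, 0), c(1, 0, 1, 0), c(st, s, t, const))
}

bv_add <- function(a, b) {
  bv_poly(c(a$s_pow, b$s_pow), c(a$t_pow, b$t_pow),
          c(a$num, b$num), c(a$den, b$den))
}

bv_scale_rat <- function(a, r) {
  bv_poly(a$s_pow, a$t_pow, a$num * r$num, a$den * r$den)
}

bv_sub <- function(a, b) bv_add(a, bv_scale_rat(b, rat(-1)))

bv_is_zero <- function(a) nrow(a) == 0

bv_equal <- function(a, b) bv_is_zero(bv_sub(a, b))

# exact evaluation at integer (s, t) -> length-1 rat
bv_eval <- function(a, s, t) {
  if (nrow(a) == 0) return(rat(0))
  rat_sum(rat(a$num * s^a$s_pow * t^a$t_pow, a$den))
}

bv_eval_num <- function(a, s, t) rat_numeric(bv_eval(a, s, t))

#' Format a bivariate polynomial as a readable string
#'
#' @param x A [bv_poly()].
#' @return A string such as `"116*s*t + 24*s + 24*t - 8"`.
#' @export
bv_format <- function(x) {
  if (nrow(x) == 0) return("0")
  term <- purrr::pmap_chr(x, function(s_pow, t_pow, num, den) {
    coef <- rat(abs(num), den)
    mono <- paste0(
      if (s_pow > 1) paste0("s^", s_pow) else if (s_pow == 1) "s" else "",
      if (s_pow > 0 && t_pow > 0) "*" else "",
      if (t_pow > 1) paste0("t^", t_pow) else if (t_pow == 1) "t" else ""
    )
    cs <- rat_format(coef)
    if (mono == "") cs else if (cs == "1") mono else paste0(cs, "*", mono)
  })
  sgn <- ifelse(x$num < 0, " - ", " + ")
  paste0(ifelse(x$num[1] < 0, "-", ""), term[1],
         paste0(sgn[-1], term[-1], collapse = ""))
}

#' @export
print.bv_poly <- function(x, ...) {
  cat("<bv_poly> ", bv_format(x), "\n", sep = "")
  invisible(x)
}

#' Tidy a bivariate polynomial into a term table
#'
#' @param x A [bv_poly()].
#' @param ... Unused.
#' @return A tibble with one row per term: `s_pow`, `t_pow`, exact `num`,
#'   `den`, and the double `coefficient`.
#' @method tidy bv_poly
#' @export
tidy.bv_poly <- function(x, ...) {
  tibble::tibble(s_pow = x$s_pow, t_pow = x$t_pow, num = x$num, den = x$den,
                 coefficient = x$num / x$den)
}
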