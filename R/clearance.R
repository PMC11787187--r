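#' Per-size clearance specification
#'
#' Describes the first-order removal rate `lambda_i` applied to aggregates
#' of size `i >= 2`, representing enzymatic, cellular, glymphatic and
#' vascular waste removal. Five variants are supported:
#'
#' * `"constant"`: `lambda_i = lambda` for every size.
#' * `"linear_in_size"`: `lambda_i = i * lambda0` (removal easier for larger
#'   aggregates, e.g. drugs with preferential binding to fibrils).
#' * `"inverse_size"`: `lambda_i = lambda0 / i` (larger aggregates harder to
#'   clear).
#' * `"windowed"`: `lambda_i = lambda_a + lambda_drug` for
#'   `n0 <= i <= n1`, `lambda_a` otherwise (drug targeting a size range on
#'   top of background clearance).
#' * `"tabulated"`: explicit rates for sizes `2, 3, ...`; sizes beyond the
#'   table reuse the last entry.
#'
#' @param variant one of `"constant"`, `"linear_in_size"`, `"inverse_size"`,
#'   `"windowed"`, `"tabulated"`.
#' @param lambda constant-variant rate (1/time).
#' @param lambda0 size-dependent-variant rate coefficient (1/time).
#' @param lambda_a,lambda_drug,n0,n1 windowed-variant background rate, drug
#'   increment and inclusive size window.
#' @param table tabulated-variant numeric vector of rates for sizes
#'   `2, 3, ..., length(table) + 1`.
#' @return An object of class `clearance_spec`.
#' @export
#' @examples
#' clearance_rate(clearance_spec("linear_in_size", lambda0 = 2), 5)  # 10
#' sp <- clearance_spec("windowed", lambda_a = 10, lambda_drug = 1e5,
#'                      n0 = 5, n1 = 15)
#' clearance_rate(sp, c(10, 20))
clearance_spec <- function(variant = c("constant", "linear_in_size",
                                       "inverse_size", "windowed",
                                       "tabulated"),
                           lambda = NULL, lambda0 = NULL, lambda_a = NULL,
                           lambda_drug = NULL, n0 = NULL, n1 = NULL,
                           table = NULL) {
  variant <- match.arg(variant)
  chk <- function(x, nm, len = 1L) {
    if (is.null(x) || !is.numeric(x) || length(x) != len || any(!is.finite(x)))
      stop(sprintf("clearance variant '%s' requires numeric `%s`%s",
                   variant, nm, if (len == 1L) "" else " vector"),
           call. = FALSE)
    if (any(x < 0))
      stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
    x
  }
  sp <- switch(variant,
    constant = list(lambda = chk(lambda, "lambda")),
    linear_in_size = list(lambda0 = chk(lambda0, "lambda0")),
    inverse_size = list(lambda0 = chk(lambda0, "lambda0")),
    windowed = {
      n0 <- n0; n1 <- n1
      if (is.null(n0) || is.null(n1) || n0 < 2 || n1 < n0)
        stop("windowed variant requires integer sizes 2 <= n0 <= n1",
             call. = FALSE)
      list(lambda_a = chk(lambda_a, "lambda_a"),
           lambda_drug = chk(lambda_drug, "lambda_drug"),
           n0 = as.integer(n0), n1 = as.integer(n1))
    },
    tabulated = list(table = chk(table, "table", len = length(table))))
  structure(c(list(variant = variant), sp), class = "clearance_spec")
}

#' Evaluate the clearance rate for given aggregate sizes
#'
#' @param spec a [clearance_spec()].
#' @param i integer vector of aggregate sizes, all `>= 2`.
#' @return Numeric vector of rates `lambda_i` (1/time).
#' @export
clearance_rate <- function(spec, i) {
  stopifnot(inherits(spec, "clearance_spec"))
  if (any(i < 2)) stop("aggregate size `i` must be >= 2", call. = FALSE)
  switch(spec$variant,
    constant = rep_len(spec$lambda, length(i)),
    linear_in_size = i * spec$lambda0,
    inverse_size = spec$lambda0 / i,
    windowed = spec$lambda_a +
      ifelse(i >= spec$n0 & i <= spec$n1, spec$lambda_drug, 0),
    tabulated = spec$table[pmin(i - 1L, length(spec$table))])
}

# lambda_i for i = 2..N as a vector
clearance_vector <- function(spec, N) clearance_rate(spec, 2:N)

#' @export
print.clearance_spec <- function(x, ...) {
  cat("Clearance spec:", x$variant, "\n")
  flds <- setdiff(names(x), "variant")
  for (f in flds)
    cat(sprintf("  %-12s %s\n", f, paste(format(x[[f]]), collapse = " ")))
  invisible(x)
}

# add a uniform increment (drug-enhanced clearance) to any spec;
# returns a tabulated spec unless a closed form exists
shift_clearance <- function(spec, increment, N = NULL) {
  if (increment == 0) return(spec)
  switch(spec$variant,
    constant = clearance_spec("constant", lambda = spec$lambda + increment),
    windowed = clearance_spec("windowed", lambda_a = spec$lambda_a + increment,
                              lambda_drug = spec$lambda_drug,
                              n0 = spec$n0, n1 = spec$n1),
    {
      if (is.null(N))
        stop("`N` required to shift a ", spec$variant, " clearance spec",
             call. = FALSE)
      clearance_spec("tabulated",
                     table = clearance_vector(spec, N) + increment)
    })
}
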