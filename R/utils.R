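#' @importFrom rlang abort warn inform .data .env %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows inner_join across all_of count
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats pnorm pchisq pt qnorm approx lm coef resid vcov sd
#'   p.adjust rnorm runif cor complete.cases setNames
NULL

# strand complement, base-wise so indel strings are handled too
dna_complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

is_palindromic_pair <- function(a1, a2) {
  nchar(a1) == 1L & nchar(a2) == 1L & a1 == dna_complement(a2)
}

assert_columns <- function(x, cols, what = "input") {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "mrliability_config_error")
  }
  invisible(x)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)),
          class = "mrliability_config_error")
  }
  invisible(x)
}

# two-sided normal p-value from an estimate and its standard error
z_pvalue <- function(beta, se) 2 * pnorm(-abs(beta / se))
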