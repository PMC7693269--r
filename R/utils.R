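#' @importFrom rlang .data abort warn %||%
#' @importFrom stats coef lm median optimize pnorm pt qnorm rnorm rpois sd
#'   setNames var complete.cases kruskal.test t.test
#' @importFrom utils head tail
NULL

# re-exports so users get broom-style verbs without loading generics
#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
  invisible(TRUE)
}

# check that a data frame has the named columns
.check_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  .assert(
    length(missing) == 0,
    paste0(what, " is missing column(s): ", paste(missing, collapse = ", "))
  )
}
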