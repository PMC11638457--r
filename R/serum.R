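## Serum comparator indices.

#' FIB-4 index
#'
#' `FIB-4 = (age [years] * AST [U/L]) / (platelet [10^9/L] * sqrt(ALT [U/L]))`
#'
#' @param age years
#' @param ast aspartate aminotransferase, U/L
#' @param platelet platelet count, 10^9/L
#' @param alt alanine aminotransferase, U/L
#' @return FIB-4 score (vectorized)
#' @export
fib4 <- function(age, ast, platelet, alt) {
  if (any(platelet <= 0)) stop("platelet count must be > 0")
  if (any(alt <= 0)) stop("ALT must be > 0")
  (age * ast) / (platelet * sqrt(alt))
}

#' APRI index
#'
#' `APRI = (AST / AST upper limit of normal) / platelet [10^9/L] * 100`
#'
#' @param ast aspartate aminotransferase, U/L
#' @param platelet platelet count, 10^9/L
#' @param ast_uln AST upper limit of normal, U/L (default 40; the source
#'   study does not state its ULN)
#' @return APRI score (vectorized)
#' @export
apri <- function(ast, platelet, ast_uln = 40) {
  if (ast_uln <= 0) stop("ast_uln must be > 0")
  if (any(platelet <= 0)) stop("platelet count must be > 0")
  (ast / ast_uln) / platelet * 100
}

#' Add FIB-4 and APRI columns to a cohort table
#'
#' @param cohort data.frame with columns age, ast, platelet, alt
#' @param ast_uln AST upper limit of normal, U/L
#' @return cohort with `fib4` and `apri` columns appended
#' @export
add_serum_indices <- function(cohort, ast_uln = 40) {
  need <- c("age", "ast", "platelet", "alt")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) stop("cohort lacks column(s): ", paste(missing, collapse = ", "))
  cohort$fib4 <- fib4(cohort$age, cohort$ast, cohort$platelet, cohort$alt)
  cohort$apri <- apri(cohort$ast, cohort$platelet, ast_uln)
  cohort
}
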