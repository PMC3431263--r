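# Round half away from zero to integer, the convention that reproduces the
# printed concordance percentages (e.g. 102/648 -> 16, 259/1393 -> 19).
round_half_up <- function(x) floor(x + 0.5)

#' Per-category concordance percentage
#'
#' The share of common features relative to the smaller of the two models'
#' category sizes, as an integer percentage (rounded half-up). Using the
#' smaller model as denominator bounds the statistic at 100 and asks "of
#' the features the less-responsive model could possibly share, how many
#' are shared?".
#'
#' @param common number of features common to both models in the category.
#' @param a_size,b_size category sizes (e.g. up-regulated counts) in the
#'   two models.
#' @return Integer percent in [0, 100].
#' @export
category_pct <- function(common, a_size, b_size) {
  denom <- min(a_size, b_size)
  if (denom == 0) stop("category is empty in at least one model")
  if (common > denom) stop("common count exceeds the smaller category size")
  round_half_up(100 * common / denom)
}

#' Overall cross-model concordance percentage
#'
#' Common features summed over the up and down categories, divided by the
#' sum of the per-category minima, as an integer percentage.
#'
#' @param common_up,common_down common feature counts per category.
#' @param a_up,a_down,b_up,b_down per-model category sizes.
#' @return Integer percent in [0, 100].
#' @export
overall_concordance <- function(common_up, common_down, a_up, a_down, b_up, b_down) {
  denom <- min(a_up, b_up) + min(a_down, b_down)
  if (denom == 0) stop("both categories empty in at least one model")
  if (common_up > min(a_up, b_up) || common_down > min(a_down, b_down)) {
    stop("common count exceeds the smaller category size")
  }
  round_half_up(100 * (common_up + common_down) / denom)
}

#' Concordance report for two differential sets
#'
#' Intersects the up and down sets of two models and reports common counts,
#' per-category percentages and the overall concordance.
#'
#' @param a,b [differential_set()] objects for the two models.
#' @return An object of class `concordance_report`: a list with
#'   `common_up`, `common_down`, sizes, `denom_up`, `denom_down`,
#'   `category_pct_up`, `category_pct_down` (NA when a category is empty in
#'   one model) and `overall_pct`.
#' @export
compare_sets <- function(a, b) {
  stopifnot(inherits(a, "differential_set"), inherits(b, "differential_set"))
  cu <- length(intersect(a$up, b$up))
  cd <- length(intersect(a$down, b$down))
  du <- min(length(a$up), length(b$up))
  dd <- min(length(a$down), length(b$down))
  structure(list(
    models = c(a$model, b$model),
    common_up = cu, common_down = cd,
    a_up = length(a$up), a_down = length(a$down),
    b_up = length(b$up), b_down = length(b$down),
    denom_up = du, denom_down = dd,
    category_pct_up = if (du > 0) category_pct(cu, length(a$up), length(b$up)) else NA_real_,
    category_pct_down = if (dd > 0) category_pct(cd, length(a$down), length(b$down)) else NA_real_,
    overall_pct = if (du + dd > 0) {
      overall_concordance(
        cu, cd, length(a$up), length(a$down),
        length(b$up), length(b$down)
      )
    } else NA_real_
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<concordance %s vs %s>\n",
      "  up:   %d common of (%d, %d) -> %s%%\n",
      "  down: %d common of (%d, %d) -> %s%%\n",
      "  overall: %s%%\n"
    ),
    x$models[1L], x$models[2L],
    x$common_up, x$a_up, x$b_up, format(x$category_pct_up),
    x$common_down, x$a_down, x$b_down, format(x$category_pct_down),
    format(x$overall_pct)
  ))
  invisible(x)
}
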