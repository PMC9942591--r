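#' @name grading
#' @title Nine-grade conservation binning
#' @description Standardizes per-site rates over the query positions,
#'   bins the scores into the nine conservation grades (1 = most variable,
#'   5 = average, 9 = most conserved), flags sites whose credible interval
#'   or data support is too weak for a confident grade, and attaches the
#'   nine-color scales used for visualization.
NULL

# 9-entry RGB tables, grade 1 (variable) .. grade 9 (conserved).
# Standard scale: teal/cyan through white to maroon.
.COLORS_STANDARD <- matrix(c(
  16, 200, 209,
  140, 255, 255,
  215, 255, 255,
  234, 255, 255,
  255, 255, 255,
  252, 237, 244,
  250, 201, 222,
  240, 125, 171,
  160,  37,  96), ncol = 3L, byrow = TRUE)
# Color-blind-safe scale: green through white to purple.
.COLORS_BLIND <- matrix(c(
  27, 120,  55,
  90, 174,  97,
  166, 219, 160,
  217, 240, 211,
  247, 247, 247,
  231, 212, 232,
  194, 165, 207,
  153, 112, 171,
  118,  42, 131), ncol = 3L, byrow = TRUE)

#' Standardize rates to z-scores
#'
#' Centers and scales with the population standard deviation so the output
#' has mean 0 and standard deviation 1; positive scores mark rapidly
#' evolving sites. A constant input (zero variance) yields all-zero
#' scores.
#'
#' @param rates numeric vector of posterior mean rates (>= 2 values).
#' @return numeric vector of scores.
#' @export
standardize <- function(rates) {
  if (length(rates) < 2L)
    evog_stop("evograde_degenerate_input_error",
              "need >= 2 positions to standardize")
  m <- mean(rates)
  s <- sqrt(mean((rates - m)^2))
  if (s == 0) return(rep(0, length(rates)))
  (rates - m) / s
}

#' Bin standardized scores into grades 1-9
#'
#' Nine equal-width bins symmetric around zero: with
#' `h = max(|min(score)|, |max(score)|)` and width `w = 2h/9`, the grade is
#' `clamp(9 - floor((s + h)/w), 1, 9)`. A score of exactly 0 falls in
#' grade 5; the most conserved site (score `-h`) gets grade 9 and the most
#' variable (`+h`) grade 1. The binning is invariant to rescaling the
#' whole score vector.
#'
#' @param scores numeric vector of standardized scores.
#' @param h optional half-range override; used to bin credible-interval
#'   bounds on the same grid as the point scores.
#' @return integer grades in `1..9`.
#' @export
bin_grades <- function(scores, h = NULL) {
  if (is.null(h)) h <- max(abs(range(scores)))
  if (h == 0) h <- 1
  w <- 2 * h / 9
  g <- 9 - floor((scores + h) / w)
  as.integer(pmin(9, pmax(1, g)))
}

#' Reliability of a grade
#'
#' A grade is considered reliable when the credible interval, mapped
#' through the same binning, spans at most 3 grades and the site has at
#' least `min_informative` non-missing characters. Unreliable grades are
#' still reported, but marked (insufficient evolutionary signal).
#'
#' @param ci_grade_low,ci_grade_high grades of the credible bounds.
#' @param n_informative informative character count per site.
#' @param max_span maximum allowed grade span of the interval.
#' @param min_informative minimum informative characters.
#' @return logical vector.
#' @export
flag_reliability <- function(ci_grade_low, ci_grade_high, n_informative,
                             max_span = 3L, min_informative = 6L) {
  abs(ci_grade_high - ci_grade_low) <= max_span &
    n_informative >= min_informative
}

#' Grade colors
#'
#' @param grade integer grades in `1..9`.
#' @param scale `"standard"` (teal-white-maroon) or `"color_blind"`
#'   (green-white-purple).
#' @return matrix with columns `r`, `g`, `b` (0-255), one row per grade.
#' @export
colorize <- function(grade, scale = c("standard", "color_blind")) {
  scale <- match.arg(scale)
  if (any(is.na(grade)) || any(grade < 1L | grade > 9L | grade != round(grade)))
    evog_stop("evograde_invalid_grade_error",
              "grades must be integers in 1..9")
  tab <- if (scale == "standard") .COLORS_STANDARD else .COLORS_BLIND
  out <- tab[grade, , drop = FALSE]
  colnames(out) <- c("r", "g", "b")
  out
}

#' Grade the query positions of a rate profile
#'
#' Restricts the per-column rates to the ungapped query positions,
#' standardizes, bins into grades, maps the credible bounds through the
#' same binning (note the inversion: a lower rate bound is a more
#' conserved, hence higher, grade), and flags reliability.
#'
#' @param rates a `site_rates` data.frame from [posterior_rates()].
#' @param aln the `evo_msa` the rates belong to.
#' @param scale color scale passed to [colorize()].
#' @return data.frame of class `grade_table`: `query_position`, `residue`,
#'   `site` (alignment column), `score`, `grade`, `ci_grade_low`,
#'   `ci_grade_high` (low/high in grade units, i.e. `ci_grade_low <=
#'   grade <= ci_grade_high`), `reliable`, `color`.
#' @export
grade_sites <- function(rates, aln, scale = c("standard", "color_blind")) {
  scale <- match.arg(scale)
  qmap <- build_query_map(aln)
  idx <- match(qmap, rates$site)
  r <- rates$rate_hat[idx]
  score <- standardize(r)
  h <- max(abs(range(score)))
  grade <- bin_grades(score)

  # credible bounds on the rate scale -> score scale -> grade scale
  m <- mean(r); s <- sqrt(mean((r - m)^2))
  to_score <- function(x) if (s == 0) rep(0, length(x)) else (x - m) / s
  g_from_low_rate <- bin_grades(to_score(rates$ci_low[idx]), h = h)
  g_from_high_rate <- bin_grades(to_score(rates$ci_high[idx]), h = h)
  ci_grade_low <- pmin(g_from_low_rate, g_from_high_rate)
  ci_grade_high <- pmax(g_from_low_rate, g_from_high_rate)

  reliable <- flag_reliability(ci_grade_low, ci_grade_high,
                               rates$n_informative[idx])
  cols <- colorize(grade, scale)
  out <- data.frame(
    query_position = seq_along(qmap),
    residue = aln$mat[aln$query_id, qmap],
    site = qmap,
    score = score,
    grade = grade,
    ci_grade_low = ci_grade_low,
    ci_grade_high = ci_grade_high,
    reliable = reliable,
    color = sprintf("#%02X%02X%02X", cols[, 1L], cols[, 2L], cols[, 3L]),
    stringsAsFactors = FALSE)
  class(out) <- c("grade_table", "data.frame")
  attr(out, "scale") <- scale
  out
}

#' Write a grade table as TSV and JSON
#'
#' The TSV carries POS, SEQ, SCORE, GRADE (with a `*` suffix for
#' unreliable sites), CI_GRADES (`low,high`), and COLOR; the JSON mirrors
#' the same records machine-readably.
#'
#' @param grades a `grade_table`.
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, a list of the paths written.
#' @export
write_grades <- function(grades, tsv_path = NULL, json_path = NULL) {
  written <- list()
  if (!is.null(tsv_path)) {
    out <- data.frame(
      POS = grades$query_position,
      SEQ = grades$residue,
      SCORE = sprintf("%.4f", grades$score),
      GRADE = paste0(grades$grade, ifelse(grades$reliable, "", "*")),
      CI_GRADES = sprintf("%d,%d", grades$ci_grade_low, grades$ci_grade_high),
      COLOR = grades$color)
    write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
    written$tsv <- tsv_path
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      grades[, c("query_position", "residue", "score", "grade",
                 "ci_grade_low", "ci_grade_high", "reliable", "color")],
      json_path, auto_unbox = TRUE, digits = NA)
    written$json <- json_path
  }
  invisible(written)
}
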