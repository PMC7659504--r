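#' Collapse raw substage labels to canonical ordinal levels
#'
#' Case-insensitive prefix mapping: for T/N/M/grade the leading letter plus
#' the first digit determine the level (`"t1b1"` -> 1, `"n3a"` -> 3,
#' `"m1"` -> 1, `"g3"` -> 3); labels without a digit (`"tx"`, `"nx"`,
#' `"mx"`) map to missing. Pathologic/clinical stage labels use roman
#' numerals (`"stage iiia"` -> 3); arabic digits are also accepted. Levels
#' outside the parameter's defined range (T 1-4, N 0-3, M 0-1, grade 1-4,
#' stage 1-4) map to missing. The mapping is total and idempotent.
#'
#' @param raw character vector of raw labels
#' @param parameter one of `"T"`, `"N"`, `"M"`, `"grade"`,
#'   `"pathologic_stage"`, `"clinical_stage"`
#' @return integer vector of levels (NA where unmappable)
#' @export
collapse_substages <- function(raw, parameter) {
  parameter <- match.arg(parameter, c("T", "N", "M", "grade",
                                      "pathologic_stage", "clinical_stage"))
  x <- tolower(trimws(as.character(raw)))
  x[x %in% c("", "na", "not reported", "unknown")] <- NA
  if (parameter %in% c("pathologic_stage", "clinical_stage")) {
    x <- sub("^stage\\s*", "", x)
    x <- sub("[abc][0-9]*$", "", x)   # strip substage suffix
    lev <- match(x, c("i", "ii", "iii", "iv"))
    arab <- suppressWarnings(as.integer(regmatches(x, regexpr("^[0-9]", x))))
    digit1 <- rep(NA_integer_, length(x))
    digit1[grepl("^[0-9]", x)] <- arab
    lev[is.na(lev)] <- digit1[is.na(lev)]
    lev[lev < 1 | lev > 4] <- NA
    return(as.integer(lev))
  }
  letter <- c("T" = "t", "N" = "n", "M" = "m", "grade" = "g")[[parameter]]
  rng <- list("T" = c(1L, 4L), "N" = c(0L, 3L), "M" = c(0L, 1L),
              "grade" = c(1L, 4L))[[parameter]]
  m <- regmatches(x, regexec(paste0("^", letter, "?([0-9])"), x))
  lev <- vapply(m, function(p) if (length(p) == 2) as.integer(p[2]) else NA_integer_,
                integer(1))
  lev[!is.na(lev) & (lev < rng[1] | lev > rng[2])] <- NA
  lev
}

#' One-way fixed-effects ANOVA of expression across stage levels
#'
#' @param expression numeric vector
#' @param levels parallel vector of ordinal levels (NA dropped)
#' @return list: `F`, `df1`, `df2`, `p_value`, `available` (FALSE when
#'   fewer than 2 levels have at least 2 patients each)
#' @export
stage_anova <- function(expression, levels) {
  ok <- !is.na(expression) & !is.na(levels)
  expression <- expression[ok]; levels <- levels[ok]
  tab <- table(levels)
  usable <- names(tab)[tab >= 2]
  if (length(usable) < 2)
    return(list(F = NA_real_, df1 = NA, df2 = NA, p_value = NA_real_,
                available = FALSE))
  keep <- levels %in% as.numeric(usable)
  f <- factor(levels[keep])
  y <- expression[keep]
  if (stats::var(y) == 0)
    return(list(F = 0, df1 = nlevels(f) - 1, df2 = length(y) - nlevels(f),
                p_value = 1, available = TRUE))
  ow <- stats::oneway.test(y ~ f, var.equal = TRUE)
  list(F = unname(ow$statistic), df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]), p_value = unname(ow$p.value),
       available = TRUE)
}

#' Directional pairwise stage score for one parameter
#'
#' For every pair of distinct observed levels i < j (all pairs by default,
#' consecutive pairs optionally), runs a two-sided Welch test; the pair
#' counts iff p < alpha *and* the higher level has the higher mean
#' expression (the score rewards expression that increases with
#' progression). The score is the number of counting pairs divided by the
#' number of tested pairs (0 when none count); with `rule = "any"` it is 1
#' as soon as one pair counts. Always in \[0, 1\].
#'
#' @param expression numeric vector
#' @param levels parallel ordinal levels
#' @param alpha pairwise significance level
#' @param pairs `"all"` or `"consecutive"`
#' @param rule `"average"` or `"any"`
#' @return list: `score`, `n_pairs_tested`, `n_pairs_significant`,
#'   `available`
#' @export
pairwise_stage_score <- function(expression, levels, alpha = 0.05,
                                 pairs = "all", rule = "average") {
  ok <- !is.na(expression) & !is.na(levels)
  expression <- expression[ok]; levels <- levels[ok]
  tab <- table(levels)
  usable <- sort(as.numeric(names(tab)[tab >= 2]))
  if (length(usable) < 2)
    return(list(score = 0, n_pairs_tested = 0L, n_pairs_significant = 0L,
                available = FALSE))
  combos <- utils::combn(usable, 2, simplify = FALSE)
  if (pairs == "consecutive")
    combos <- Filter(function(p) match(p[2], usable) == match(p[1], usable) + 1,
                     combos)
  n_sig <- 0L
  for (pr in combos) {
    a <- expression[levels == pr[1]]
    b <- expression[levels == pr[2]]
    w <- welch_two_sample(b, a)   # mean1 = higher level
    if (!is.na(w$p) && w$p < alpha && w$mean1 > w$mean2) n_sig <- n_sig + 1L
  }
  score <- if (n_sig == 0) 0 else if (rule == "any") 1 else n_sig / length(combos)
  list(score = score, n_pairs_tested = length(combos),
       n_pairs_significant = n_sig, available = TRUE)
}

#' Build per-patient stage assignments from a clinical table
#'
#' @param clinical [clinical_table()] object
#' @param parameters which parameters to collapse (default all six)
#' @return data.frame: `patient_id`, one integer level column per parameter
#'   (NA where unmappable); unmappable label counts in attribute
#'   `"n_unmapped"`
#' @export
stage_assignments <- function(clinical,
                              parameters = c("T", "N", "M", "grade",
                                             "pathologic_stage",
                                             "clinical_stage")) {
  stopifnot(inherits(clinical, "cki_clinical"))
  raw_col <- c("T" = "t_stage", "N" = "n_stage", "M" = "m_stage",
               "grade" = "grade", "pathologic_stage" = "pathologic_stage",
               "clinical_stage" = "clinical_stage")
  out <- data.frame(patient_id = clinical$patient_id, stringsAsFactors = FALSE)
  n_unmapped <- integer(0)
  for (p in parameters) {
    raw <- clinical[[raw_col[[p]]]]
    lev <- collapse_substages(raw, p)
    out[[p]] <- lev
    n_unmapped[p] <- sum(!is.na(raw) & is.na(lev))
  }
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Clinical score of one gene across staging parameters
#'
#' Computes the directional pairwise stage score for each requested
#' parameter and sums them. Parameters without at least 2 levels of 2+
#' patients are unavailable and excluded from both the total and the
#' cohort's maximum score.
#'
#' @param expression named numeric vector (per patient)
#' @param assignments [stage_assignments()] data.frame
#' @param parameters parameter subset (default: all level columns present)
#' @param alpha,pairs,rule passed to [pairwise_stage_score()]
#' @return list: `scores` (named per-parameter, NA when unavailable),
#'   `clinical_total`, `parameters_available`
#' @export
clinical_score <- function(expression, assignments, parameters = NULL,
                           alpha = 0.05, pairs = "all", rule = "average") {
  if (is.null(parameters))
    parameters <- setdiff(names(assignments), "patient_id")
  idx <- match(names(expression), assignments$patient_id)
  scores <- stats::setNames(rep(NA_real_, length(parameters)), parameters)
  for (p in parameters) {
    lev <- assignments[[p]][idx]
    ps <- pairwise_stage_score(expression, lev, alpha = alpha,
                               pairs = pairs, rule = rule)
    if (ps$available) scores[p] <- ps$score
  }
  avail <- !is.na(scores)
  list(scores = scores,
       clinical_total = sum(scores[avail]),
       parameters_available = sum(avail))
}
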