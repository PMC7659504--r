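`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
stop_cki <- function(...) stop(sprintf(...), call. = FALSE)

#' Vectorised Welch two-sample test on matrix rows
#'
#' Computes per-row means, the Welch t statistic and its two-sided p value
#' between two column groups. Degenerate rows (zero pooled standard error)
#' get p = 1 when the group means agree and p = 0 otherwise.
#'
#' @param x numeric matrix
#' @param idx1,idx2 column indices of the two groups (each of length >= 2)
#' @return list with mean1, mean2, t, df, p
#' @keywords internal
#' @noRd
welch_rows <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  x1 <- x[, idx1, drop = FALSE]; x2 <- x[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen)) {
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
    t[degen] <- ifelse(m1[degen] == m2[degen], 0, Inf * sign(m1 - m2)[degen])
  }
  list(mean1 = m1, mean2 = m2, t = t, df = df, p = p)
}

# scalar convenience wrapper
welch_two_sample <- function(a, b) {
  w <- welch_rows(rbind(c(a, b)), seq_along(a), length(a) + seq_along(b))
  list(mean1 = w$mean1[1], mean2 = w$mean2[1], t = w$t[1], df = w$df[1],
       p = w$p[1])
}

# competition ("1224") ranking on descending score
competition_rank <- function(score) rank(-score, ties.method = "min")

# deterministic per-component RNG substreams: adding genes or samples to one
# component must not perturb the draws of another, so each component reseeds
# from a fixed offset of the master seed
substream_seed <- function(seed, component) {
  offsets <- c(counts = 11L, survival = 23L, stages = 37L, mutations = 53L,
               dependency = 71L, annotations = 89L, planting = 97L)
  if (!component %in% names(offsets)) stop_cki("unknown RNG substream '%s'", component)
  (as.integer(seed) + offsets[[component]]) %% .Machine$integer.max
}

# restricted mean survival time: integral of the Kaplan-Meier step function
# on [0, tau]
rmst_from_km <- function(time, event, tau) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- sf$time <= tau & sf$n.event > 0
  times <- c(0, sf$time[keep], tau)
  surv <- c(1, sf$surv[keep])
  sum(diff(times) * surv)
}

#' @importFrom utils write.table read.delim
write_tsv <- function(df, path) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", eol = "\n",
                     fileEncoding = "UTF-8")
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_cki("%s is missing mandatory column(s): %s (expected header: %s)",
             what, paste(miss, collapse = ", "), paste(cols, collapse = ", "))
  invisible(df)
}
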