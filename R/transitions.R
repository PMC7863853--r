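#' Wave-to-wave worry group transitions
#'
#' Classifies each wave of a linked panel, restricts to respondents present
#' and classifiable in both waves, and tabulates movement between the three
#' worry groups. The stability share is the fraction of linked respondents
#' who stayed in the same group — its complement is the share of movers.
#'
#' @param panel a `panel_table` from [link_panel()].
#' @param cfg a [dichotomy_config()].
#' @param scheme `"full"` or `"simplified"` classification.
#' @param weights optional data frame from [compute_weights()] (wave-2
#'   weights); when supplied, a weighted probability matrix is also returned.
#' @return An object of class `transition_matrix`: a list with `counts`
#'   (3x3 integer matrix, wave-2 group in rows), `probabilities`
#'   (row-stochastic; rows with zero count are `NaN` and flagged in
#'   `undefined_rows`), `stability_share`, `n_linked`, and
#'   `n_excluded` (linked respondents unclassifiable in either wave).
#' @export
transitions <- function(panel, cfg = dichotomy_config(), scheme = c("full", "simplified"),
                        weights = NULL) {
  scheme <- match.arg(scheme)
  classify <- if (scheme == "full") classify_full else classify_simplified
  ids <- panel$linkage$respondent_id[panel$linkage$linkage_status == "both_waves"]
  i2 <- match(ids, panel$wave2$respondent_id)
  i3 <- match(ids, panel$wave3$respondent_id)
  g2 <- classify(panel$wave2[i2, , drop = FALSE], cfg)$worry_group
  g3 <- classify(panel$wave3[i3, , drop = FALSE], cfg)$worry_group

  ok <- g2 %in% worry_groups() & g3 %in% worry_groups()
  n_excluded <- sum(!ok)
  g2 <- factor(as.character(g2[ok]), levels = worry_groups())
  g3 <- factor(as.character(g3[ok]), levels = worry_groups())
  n_linked <- length(g2)
  if (n_linked == 0L) stop("no linked, classifiable respondents in both waves")

  counts <- table(wave2 = g2, wave3 = g3)
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(wave2 = worry_groups(), wave3 = worry_groups()))
  probabilities <- counts / rowSums(counts)
  undefined_rows <- worry_groups()[rowSums(counts) == 0]

  out <- list(counts = counts,
              probabilities = probabilities,
              stability_share = sum(diag(counts)) / n_linked,
              n_linked = n_linked,
              n_excluded = n_excluded,
              undefined_rows = undefined_rows)
  if (!is.null(weights)) {
    w <- weights$weight[match(ids[ok], weights$respondent_id)]
    if (anyNA(w)) stop("weights missing for some linked respondents")
    wcounts <- tapply(w, list(g2, g3), sum, default = 0)
    out$weighted_probabilities <- wcounts / rowSums(wcounts)
    out$weighted_stability_share <- sum(diag(wcounts)) / sum(wcounts)
  }
  class(out) <- "transition_matrix"
  out
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> n_linked=%d (excluded %d), stability=%.3f\n",
              x$n_linked, x$n_excluded, x$stability_share))
  print(round(x$probabilities, 3))
  invisible(x)
}

#' Long-format flow table of a transition matrix
#'
#' A tabular stand-in for an alluvial diagram: one row per (source, target)
#' flow, ordered source-major in the fixed group order.
#'
#' @param matrix a `transition_matrix` from [transitions()].
#' @param drop_zero drop flows with zero count.
#' @return Data frame with columns `from`, `to`, `count`, `probability`.
#' @export
sankey_table <- function(matrix, drop_zero = FALSE) {
  g <- worry_groups()
  out <- data.frame(
    from = rep(g, each = 3),
    to = rep(g, times = 3),
    count = as.integer(t(matrix$counts)),
    probability = as.numeric(t(matrix$probabilities)))
  if (drop_zero) out <- out[out$count > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
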