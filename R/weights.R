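#' Population margin targets for quota weighting
#'
#' Targets for the gender and age-band margins (and, optionally, the joint
#' gender x age cells). Quota samples are aligned to these after fieldwork;
#' the weighted margins then match the stated population shares.
#'
#' @param gender named numeric vector of gender shares, summing to 1.
#' @param age_band named numeric vector of age-band shares, summing to 1.
#' @param joint optional matrix of joint cell shares (rows = gender levels,
#'   columns = age bands) summing to 1; when omitted, cell-mode weighting
#'   uses the independence product of the two margins.
#' @param total normalisation total for the weight vector; `NULL` (default)
#'   means sum-preserving — weights sum to the sample size.
#' @return A list of class `margin_targets`.
#' @export
margin_targets <- function(gender, age_band, joint = NULL, total = NULL) {
  check_margin <- function(m, nm) {
    if (is.null(names(m)) || any(!nzchar(names(m)))) stop(nm, " shares must be named")
    if (any(m < 0)) stop(nm, " shares must be nonnegative")
    if (abs(sum(m) - 1) > 1e-9) stop(nm, " shares must sum to 1")
  }
  check_margin(gender, "gender")
  check_margin(age_band, "age_band")
  if (!is.null(joint)) {
    if (!identical(sort(rownames(joint)), sort(names(gender))) ||
        !identical(sort(colnames(joint)), sort(names(age_band))))
      stop("joint target dimnames must match the margin names")
    if (any(joint < 0) || abs(sum(joint) - 1) > 1e-9)
      stop("joint targets must be nonnegative and sum to 1")
  }
  structure(list(gender = gender, age_band = age_band, joint = joint, total = total),
            class = "margin_targets")
}

#' Compute quota / post-stratification weights on gender and age
#'
#' Two modes:
#' * `"cell"` (default): weight = target cell share / sample cell share for
#'   each gender x age cell, then rescaled to the normalisation total. Joint
#'   cell targets are used when supplied, otherwise the independence product
#'   of the two margins.
#' * `"raking"`: iterative proportional fitting on the two margins until the
#'   largest margin error is below `tol` (or `max_iter` sweeps).
#'
#' @param data wave table with nonmissing `gender` and `age_band` columns.
#' @param targets a [margin_targets()].
#' @param mode `"cell"` or `"raking"`.
#' @param tol convergence tolerance on the worst margin error (raking).
#' @param max_iter maximum raking sweeps.
#' @return Data frame with columns `respondent_id` and `weight` (all
#'   positive; weights sum to `targets$total`, defaulting to the sample
#'   size).
#' @export
compute_weights <- function(data, targets, mode = c("cell", "raking"),
                            tol = 1e-8, max_iter = 100L) {
  mode <- match.arg(mode)
  g <- as.character(data$gender)
  a <- as.character(data$age_band)
  if (anyNA(g) || anyNA(a))
    stop("every respondent must have nonmissing gender and age_band")
  bad_g <- setdiff(unique(g), names(targets$gender))
  bad_a <- setdiff(unique(a), names(targets$age_band))
  if (length(bad_g) || length(bad_a))
    stop("sample levels without targets: ", paste(c(bad_g, bad_a), collapse = ", "))
  n <- nrow(data)
  total <- if (is.null(targets$total)) n else targets$total

  if (mode == "cell") {
    joint <- targets$joint
    if (is.null(joint))
      joint <- outer(targets$gender, targets$age_band)  # independence product
    cell_n <- table(factor(g, levels = rownames(joint)),
                    factor(a, levels = colnames(joint)))
    populated <- cell_n > 0
    starved <- populated == FALSE & joint > 0
    if (any(starved)) {
      cells <- paste(rownames(joint)[row(joint)[starved]],
                     colnames(joint)[col(joint)[starved]], sep = " x ")
      stop("empty sample cells with positive targets: ", paste(cells, collapse = "; "))
    }
    if (any(joint[populated] <= 0))
      stop("populated sample cells must have positive targets")
    ratio <- joint / (cell_n / n)
    w <- ratio[cbind(match(g, rownames(joint)), match(a, colnames(joint)))]
  } else {
    w <- rep(1, n)
    for (it in seq_len(max_iter)) {
      for (dim_vals in list(list(x = g, tgt = targets$gender),
                            list(x = a, tgt = targets$age_band))) {
        cur <- tapply(w, factor(dim_vals$x, levels = names(dim_vals$tgt)), sum, default = 0)
        if (any(cur == 0 & dim_vals$tgt > 0))
          stop("empty sample margin with positive target: ",
               paste(names(dim_vals$tgt)[cur == 0 & dim_vals$tgt > 0], collapse = ", "))
        adj <- (dim_vals$tgt * sum(w)) / cur
        adj[!is.finite(adj)] <- 1
        w <- w * adj[dim_vals$x]
      }
      err_g <- max(abs(tapply(w, factor(g, levels = names(targets$gender)), sum,
                              default = 0) / sum(w) - targets$gender))
      err_a <- max(abs(tapply(w, factor(a, levels = names(targets$age_band)), sum,
                              default = 0) / sum(w) - targets$age_band))
      if (max(err_g, err_a) < tol) break
    }
  }
  w <- w * total / sum(w)
  data.frame(respondent_id = data$respondent_id, weight = as.numeric(w))
}

#' Weighted group counts and percentages
#'
#' @param data wave table (or any data frame).
#' @param weights numeric vector aligned with `data` rows, or the data frame
#'   returned by [compute_weights()] (matched on `respondent_id`).
#' @param by name of the grouping column in `data`.
#' @return Data frame with per-group unweighted `n`, `weighted_n`, and
#'   percentage columns over the (weighted) total.
#' @export
weighted_counts <- function(data, weights, by) {
  if (is.data.frame(weights)) {
    w <- weights$weight[match(data$respondent_id, weights$respondent_id)]
  } else w <- weights
  if (anyNA(w)) stop("weights missing for some grouped rows")
  f <- data[[by]]
  f <- if (is.factor(f)) droplevels(f) else factor(f)
  n <- as.integer(table(f))
  wn <- as.numeric(tapply(w, f, sum, default = 0))
  data.frame(group = levels(f), n = n,
             pct = 100 * n / sum(n),
             weighted_n = wn,
             weighted_pct = 100 * wn / sum(wn))
}
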