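#' Dice similarity coefficient
#'
#' `DSC = 2|G intersect S| / (|G| + |S|)` between a reference mask `G`
#' and a predicted mask `S`.  When both masks are empty the correct
#' "no tumor" call returns 1, flagged with attribute
#' `both_empty = TRUE` rather than raising a division error.
#'
#' @param G,S binary matrices (or [seg_mask()]s) of identical shape.
#' @return scalar in `[0, 1]`; symmetric in its arguments.
#' @export
dice <- function(G, S) {
  g <- as_binary_matrix(pixels_of(G))
  s <- as_binary_matrix(pixels_of(S))
  if (!all(dim(g) == dim(s))) {
    stop("masks must have the same shape", call. = FALSE)
  }
  ng <- sum(g); ns <- sum(s)
  if (ng + ns == 0) {
    return(structure(1, both_empty = TRUE))
  }
  2 * sum(g & s) / (ng + ns)
}

#' Pixel-level evaluation of a mask pair
#'
#' Full confusion counts and the four ratios (precision, recall,
#' accuracy, Dice) for a predicted mask against its reference.
#' Zero-denominator ratios are `NA` and listed in `flags`.
#'
#' @param G reference binary mask.
#' @param S predicted binary mask of the same shape.
#' @return a one-row tibble: `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`, `accuracy`, `dsc`, `flags`.
#' @export
evaluate_pair <- function(G, S) {
  g <- as_binary_matrix(pixels_of(G))
  s <- as_binary_matrix(pixels_of(S))
  if (!all(dim(g) == dim(s))) {
    stop("masks must have the same shape", call. = FALSE)
  }
  tp <- sum(g == 1 & s == 1); fp <- sum(g == 0 & s == 1)
  fn <- sum(g == 1 & s == 0); tn <- sum(g == 0 & s == 0)
  flags <- character()
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    flags <- c(flags, "precision_undefined"); NA_real_
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    flags <- c(flags, "recall_undefined"); NA_real_
  }
  d <- dice(g, s)
  if (isTRUE(attr(d, "both_empty"))) flags <- c(flags, "both_empty")
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         precision = precision, recall = recall,
         accuracy = (tp + tn) / length(g),
         dsc = as.numeric(d),
         flags = paste(flags, collapse = ";"))
}

#' Summarize evaluation reports by group
#'
#' Mean and median Dice per group (e.g. lesion-contrast stratum, or
#' before/after post-processing).  Grouping columns that are factors
#' keep empty levels as flagged `n = 0` rows.
#'
#' @param reports tibble with a `dsc` column plus grouping columns.
#' @param grouping character vector of grouping column names.
#' @return tibble with `n`, `mean_dsc`, `median_dsc` and a `flags`
#'   column per group.
#' @export
summarize_runs <- function(reports, grouping = character()) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1,
            "dsc" %in% names(reports))
  if (length(grouping) == 0) {
    return(tibble(n = nrow(reports), mean_dsc = mean(reports$dsc),
                  median_dsc = median(reports$dsc), flags = ""))
  }
  stopifnot(all(grouping %in% names(reports)))
  out <- reports |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping)), .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_dsc = mean(.data$dsc),
                     median_dsc = median(.data$dsc),
                     .groups = "drop")
  out$flags <- ifelse(out$n == 0, "empty_group", "")
  out
}
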