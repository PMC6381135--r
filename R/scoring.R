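#' Default item map for the 40-item psychopathy inventory
#'
#' The 40-item short form is scored on a 1-4 scale. The published factor
#' structure groups seven of the eight subscales into two factors — fearless
#' dominance (social influence, fearlessness, stress immunity) and
#' self-centred impulsivity (machiavellian egocentricity, rebellious
#' nonconformity, blame externalisation, carefree nonplanfulness) — with
#' coldheartedness as a standalone third factor. The observed score ranges
#' of the analysed sample pin the factor item counts under 1-4 sum scoring:
#' a fearless-dominance maximum of 56 = 4 x 14 items, a self-centred
#' impulsivity minimum of 16 = 1 x 16 items, and coldheartedness spanning
#' exactly 5-20 = 5 items. That accounts for 35 of the 40 items; the
#' remaining 5 are carried as a non-factor validity block that contributes
#' to no factor score. The map is a replaceable configuration table, so a
#' licensed copy of the instrument's own key can be dropped in.
#'
#' @return A data frame with columns `item` (1-40), `subscale`, `factor`
#'   (`"fearless_dominance"`, `"self_centred_impulsivity"`,
#'   `"coldheartedness"` or `"none"`), and `reverse_keyed` (logical).
#' @export
default_ppi_item_map <- function() {
  subscales <- c(
    rep("social_influence", 5), rep("fearlessness", 5), rep("stress_immunity", 4),
    rep("machiavellian_egocentricity", 4), rep("rebellious_nonconformity", 4),
    rep("blame_externalisation", 4), rep("carefree_nonplanfulness", 4),
    rep("coldheartedness", 5), rep("validity", 5)
  )
  factors <- c(
    rep("fearless_dominance", 14),
    rep("self_centred_impulsivity", 16),
    rep("coldheartedness", 5),
    rep("none", 5)
  )
  # every third scored item is reverse-keyed in the default map
  rev_keyed <- rep(FALSE, 40)
  rev_keyed[seq(3, 35, by = 3)] <- TRUE
  data.frame(item = 1:40, subscale = subscales, factor = factors,
             reverse_keyed = rev_keyed, stringsAsFactors = FALSE)
}

#' Score the psychopathy inventory factors
#'
#' Reverse-keyed items are flipped on the 1-4 response scale (response r
#' becomes 5 - r), then each factor score is the sum of its items. Items
#' mapped to factor `"none"` (validity/filler items) are ignored. Missing
#' responses are an error — the analysis is complete-case, no imputation.
#'
#' @param responses integer vector of 40 item responses on 1-4, or a matrix/
#'   data frame with 40 columns (one row per participant).
#' @param item_map a data frame as returned by [default_ppi_item_map()].
#' @param scale_min,scale_max bounds of the response scale.
#' @return A data frame with columns `fearless_dominance`,
#'   `self_centred_impulsivity`, `coldheartedness` and
#'   `sum_psychopathic_traits` (their sum), one row per participant.
#' @export
score_ppi <- function(responses, item_map = default_ppi_item_map(),
                      scale_min = 1, scale_max = 4) {
  if (is.null(dim(responses))) responses <- matrix(responses, nrow = 1)
  responses <- as.matrix(responses)
  n_items <- nrow(item_map)
  abort_if(ncol(responses) != n_items,
           sprintf("expected %d item responses per participant, got %d",
                   n_items, ncol(responses)))
  abort_if(anyDuplicated(item_map$item) > 0, "item map assigns an item twice")
  miss <- which(apply(responses, 2, function(x) any(is.na(x))))
  abort_if(length(miss) > 0, sprintf(
    "missing responses for item(s) %s; complete data required (no imputation)",
    paste(miss, collapse = ", ")))
  out_of_range <- responses < scale_min | responses > scale_max
  abort_if(any(out_of_range), "item responses outside the declared scale")

  flipped <- responses
  rev_idx <- item_map$item[item_map$reverse_keyed]
  if (length(rev_idx)) {
    flipped[, rev_idx] <- scale_min + scale_max - responses[, rev_idx]
  }
  factor_sum <- function(fac) {
    idx <- item_map$item[item_map$factor == fac]
    if (!length(idx)) return(rep(0, nrow(flipped)))
    rowSums(flipped[, idx, drop = FALSE])
  }
  fd <- factor_sum("fearless_dominance")
  sci <- factor_sum("self_centred_impulsivity")
  cold <- factor_sum("coldheartedness")
  data.frame(fearless_dominance = fd,
             self_centred_impulsivity = sci,
             coldheartedness = cold,
             sum_psychopathic_traits = fd + sci + cold)
}

#' Score the 16-item narcissism inventory
#'
#' Each of the 16 forced-choice items is coded 1 for the
#' narcissism-consistent choice and 0 otherwise; the score is the proportion
#' of narcissism-consistent choices, optionally rescaled.
#'
#' @param responses integer vector of 16 binary responses, or a matrix with
#'   16 columns.
#' @param scale multiplicative rescaling factor (default 1: raw proportion).
#' @return Numeric vector of narcissism scores.
#' @export
score_npi <- function(responses, scale = 1) {
  if (is.null(dim(responses))) responses <- matrix(responses, nrow = 1)
  responses <- as.matrix(responses)
  abort_if(ncol(responses) != 16, "expected 16 narcissism item responses")
  abort_if(any(is.na(responses)), "missing narcissism responses")
  abort_if(!all(responses %in% c(0, 1)), "narcissism responses must be 0/1")
  rowMeans(responses) * scale
}

#' Exclude inconsistent responders
#'
#' Participants whose inconsistent-responding score (IRS-10) is at or above
#' the cutoff are removed; the cutoff of 13 corresponds to the instrument's
#' 95th percentile. Order of the retained participants is preserved.
#'
#' @param irs10 integer vector of IRS-10 scores, one per participant.
#' @param cutoff exclusion threshold; scores `>= cutoff` are excluded.
#' @return A list with `retained` (logical vector), `n_retained` and
#'   `n_excluded`.
#' @export
apply_irs_exclusion <- function(irs10, cutoff = 13L) {
  abort_if(cutoff < 0, "cutoff must be non-negative")
  abort_if(any(is.na(irs10)) || any(irs10 < 0),
           "IRS-10 scores must be non-negative and complete")
  keep <- irs10 < cutoff
  list(retained = keep, n_retained = sum(keep), n_excluded = sum(!keep))
}

#' Aggregate psychopathy score
#'
#' The arithmetic sum of the three factor scores; the aggregate measure
#' used in the interaction regressions and the correlation matrix.
#'
#' @param fearless_dominance,self_centred_impulsivity,coldheartedness
#'   numeric vectors of factor scores.
#' @return Numeric vector of sums.
#' @export
sum_psychopathy <- function(fearless_dominance, self_centred_impulsivity,
                            coldheartedness) {
  fearless_dominance + self_centred_impulsivity + coldheartedness
}

#' Cronbach's alpha
#'
#' Internal-consistency utility for item blocks:
#' alpha = k/(k-1) * (1 - sum of item variances / variance of the sum).
#'
#' @param items matrix or data frame, one column per item.
#' @return Numeric scalar.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  abort_if(k < 2, "alpha needs at least two items")
  v_total <- stats::var(rowSums(items))
  abort_if(v_total == 0, "total score is constant; alpha undefined")
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / v_total)
}
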