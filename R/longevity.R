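# Longevity quotient (LQ) and species-fraction construction.
#
# LQ relates the maximum reported lifespan (MRLS) of a species to the
# allometric expectation for its adult body mass m (grams):
#     LQ = 100 * MRLS / (4.88 * m^0.153)   [percent]
# A species living exactly as long as expected for its mass has LQ = 100%.
# Upper ("long-lived") and lower ("short-lived") fractions of a group are
# the species with LQ strictly above / strictly below group-specific
# boundaries.

#' Longevity quotient
#'
#' Computes `100 * mrls / (4.88 * bodyMass^0.153)`, the maximum reported
#' lifespan as a percentage of the allometric expectation for the adult body
#' mass.  Vectorized; inputs are recycled.
#'
#' @param mrls Maximum reported lifespan in years (> 0).
#' @param bodyMass Adult body mass in grams (> 0).
#' @param round Round to the nearest integer percent (half away from zero),
#'   the convention used when quoting LQ values.
#' @return LQ in percent.
#' @examples
#' computeLQ(30, 874, round = TRUE)    # 218
#' computeLQ(4.88 * 1000^0.153, 1000)  # 100 by definition
#' @export
computeLQ <- function(mrls, bodyMass, round = FALSE) {
  if (any(!is.finite(mrls)) || any(mrls <= 0))
    stop("mrls must be positive and finite")
  if (any(!is.finite(bodyMass)) || any(bodyMass <= 0))
    stop("bodyMass must be positive and finite")
  lq <- 100 * mrls / (4.88 * bodyMass^0.153)
  if (round) roundLQ(lq) else lq
}

#' @rdname computeLQ
#' @param lq LQ values in percent.
#' @export
roundLQ <- function(lq) {
  # half away from zero (commercial rounding), not banker's rounding
  sign(lq) * floor(abs(lq) + 0.5)
}

#' Split a species group into upper and lower longevity fractions
#'
#' Given life-history records and a [groupSpec()], returns the group members
#' with LQ strictly above the upper threshold (upper fraction) and strictly
#' below the lower threshold (lower fraction).  Explicit fraction lists in
#' the group spec override the thresholds.  Species falling between the
#' boundaries belong to neither fraction and are excluded from the screen.
#'
#' @param records data.frame as returned by [readLifeHistory()] (columns
#'   `species` and `lq_percent`; LQ may have been supplied or computed).
#' @param group A [groupSpec()].
#' @return A list with character vectors `upper` and `lower`, in the order
#'   of `group`'s member list.
#' @examples
#' rec <- data.frame(species = c("a", "b", "c"),
#'                   lq_percent = c(250, 150, 80))
#' partitionFractions(rec, groupSpec("demo", c("a", "b", "c"), 200, 100))
#' @export
partitionFractions <- function(records, group) {
  stopifnot(is(group, "GroupSpec"))
  if (!length(group@members))
    return(list(upper = character(), lower = character()))
  needThresholds <- !length(group@explicitUpper) ||
    !length(group@explicitLower)
  upper <- group@explicitUpper
  lower <- group@explicitLower
  if (needThresholds) {
    idx <- match(group@members, records$species)
    lq <- records$lq_percent[idx]
    bad <- is.na(idx) | is.na(lq)
    if (any(bad))
      stop("no LQ available for species: ",
           paste(group@members[bad], collapse = ", "))
    if (!length(upper)) upper <- group@members[lq > group@upperThreshold]
    if (!length(lower)) lower <- group@members[lq < group@lowerThreshold]
  }
  list(upper = upper, lower = lower)
}
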