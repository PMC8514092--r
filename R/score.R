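# Radical Stability Score: combined thermodynamic + kinetic metric

#' Score configuration
#'
#' The Radical Stability Score is `percent_buried + weight * (1 -
#' max_fraction)`. The default weight of 50 gives the spin term (spanning
#' 0-50) approximately equal leverage to the observed buried-volume range
#' (roughly 13-65%). The percent-buried term always enters on the 0-100
#' percent scale.
#'
#' @param weight Positive multiplier on the delocalization term.
#' @return An object of class `score_config`.
#' @export
score_config <- function(weight = 50) {
  stopifnot(is.numeric(weight), length(weight) == 1L, is.finite(weight))
  if (weight < 0) stop("weight must be non-negative", call. = FALSE)
  out <- list(weight = weight)
  class(out) <- "score_config"
  out
}

#' Radical Stability Score
#'
#' Combines the kinetic descriptor (percent buried volume around the radical
#' center) and the thermodynamic descriptor (maximum heavy-atom fractional
#' spin) into a single number: higher means a sterically more protected
#' and/or more delocalized — hence more plausibly stable — radical. With the
#' default weight the score lies in (0, 150). It is an ordinal stability
#' metric, not a kinetic model: it predicts no half-life.
#'
#' @param percent_buried Percent buried volume, in (0, 100].
#' @param max_fraction Maximum heavy-atom fractional spin, in (0, 1].
#' @param config A [score_config()].
#' @return The score (numeric).
#' @examples
#' radical_stability_score(50, 0.5)  # 75
#' @export
radical_stability_score <- function(percent_buried, max_fraction,
                                    config = score_config()) {
  stopifnot(inherits(config, "score_config"))
  if (!is.numeric(percent_buried) || !all(is.finite(percent_buried)) ||
      any(percent_buried <= 0) || any(percent_buried > 100)) {
    stop("percent_buried must lie in (0, 100]", call. = FALSE)
  }
  if (!is.numeric(max_fraction) || !all(is.finite(max_fraction)) ||
      any(max_fraction <= 0) || any(max_fraction > 1)) {
    stop("max_fraction must lie in (0, 1]", call. = FALSE)
  }
  percent_buried + config$weight * (1 - max_fraction)
}

#' Score one structure end to end
#'
#' Convenience composition of the descriptor pipeline: normalize spins to
#' heavy-atom fractions, assign the radical center, integrate the buried
#' volume around that center, and combine into the stability score.
#'
#' @param structure A [molecular_structure()].
#' @param spins Signed per-atom spin densities aligned to the structure.
#' @param grid A [grid_spec()].
#' @param config A [score_config()].
#' @param id Record identifier; defaults to the structure id.
#' @return A one-row `stability record` data.frame with columns `id`,
#'   `max_fraction`, `percent_buried`, `rss`, `center_element`,
#'   `center_index`.
#' @examples
#' m <- ideal_methyl()
#' score_structure(m$structure, m$spins)
#' @export
score_structure <- function(structure, spins, grid = grid_spec(),
                            config = score_config(), id = NULL) {
  fs <- fractional_spins(structure, spins)
  bv <- buried_volume(structure, radical_center(fs), grid)
  stability_record(
    id = if (is.null(id)) structure$id else id,
    max_fraction = fs$max_fraction,
    percent_buried = bv$percent_buried,
    center_element = fs$center_element,
    center_index = fs$center_index,
    config = config
  )
}

#' Assemble a stability record
#'
#' @param id Identifier string(s).
#' @param max_fraction Maximum heavy-atom fractional spin(s), in (0, 1].
#' @param percent_buried Percent buried volume(s), in (0, 100].
#' @param center_element Element symbol(s) of the radical center.
#' @param center_index Atom index(es) of the radical center (optional).
#' @param config A [score_config()]; the score column is computed with it.
#' @return A data.frame, one row per radical, columns `id`, `max_fraction`,
#'   `percent_buried`, `rss`, `center_element`, `center_index`.
#' @export
stability_record <- function(id, max_fraction, percent_buried,
                             center_element, center_index = NA_integer_,
                             config = score_config()) {
  rss <- radical_stability_score(percent_buried, max_fraction, config)
  data.frame(
    id = as.character(id),
    max_fraction = max_fraction,
    percent_buried = percent_buried,
    rss = rss,
    center_element = as.character(center_element),
    center_index = as.integer(center_index),
    stringsAsFactors = FALSE
  )
}

#' Stability-map coordinates of a record
#'
#' Projects a stability record onto the two descriptor axes of the stability
#' map: x is the maximum fractional spin (decreasing x = more thermodynamic
#' stabilization), y is the percent buried volume (increasing y = more
#' kinetic protection). Experimentally stable radicals cluster in the
#' upper-left of this plane; small unstable radicals like methyl sit in the
#' lower right.
#'
#' @param record A stability-record data.frame (any number of rows).
#' @return A data.frame with columns `id`, `x` (max_fraction), `y`
#'   (percent_buried).
#' @export
map_coordinates <- function(record) {
  stopifnot(is.data.frame(record),
            all(c("max_fraction", "percent_buried") %in% names(record)))
  data.frame(id = record$id, x = record$max_fraction,
             y = record$percent_buried, stringsAsFactors = FALSE)
}

#' Quadrant labels on the stability map
#'
#' Assigns each record to a quadrant of the stability map relative to
#' user-supplied thresholds. The defaults (spin 0.5, buried volume 40%) are
#' heuristic descriptive cutoffs, not universal constants. "NW" (low spin,
#' high buried volume) is the stable-radical corner; "SE" (localized, bare)
#' holds small transient radicals such as methyl.
#'
#' @param record A stability-record data.frame.
#' @param spin_threshold Records with `max_fraction` below this are "west".
#' @param vbur_threshold Records with `percent_buried` at or above this are
#'   "north".
#' @return Character vector of quadrant labels ("NW", "NE", "SW", "SE").
#' @export
map_quadrant <- function(record, spin_threshold = 0.5, vbur_threshold = 40) {
  stopifnot(is.data.frame(record))
  west <- record$max_fraction < spin_threshold
  north <- record$percent_buried >= vbur_threshold
  paste0(ifelse(north, "N", "S"), ifelse(west, "W", "E"))
}
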