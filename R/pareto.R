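# Pareto-front extraction in the (delocalization, steric protection) plane

#' Pareto front of stability records
#'
#' Finds the non-dominated set under the two stability objectives: maximize
#' percent buried volume, minimize maximum fractional spin. A record `a` is
#' dominated iff some record `b` has `b$percent_buried >= a$percent_buried`
#' and `b$max_fraction <= a$max_fraction` with at least one inequality
#' strict. Records duplicated exactly in both coordinates dominate neither
#' each other nor themselves, so all copies are retained on the front.
#'
#' Implemented as a single sorted sweep (sort by buried volume descending,
#' track the running minimum spin), O(n log n).
#'
#' @param records Stability-record data.frame with at least `id`,
#'   `max_fraction` and `percent_buried` columns.
#' @param element_stratum Label recorded on the result (used by
#'   [pareto_by_element()]).
#' @return An object of class `pareto_result`: list with `frontier` (subset
#'   of `records`, input order preserved), `dominated_count`,
#'   `element_stratum`, and `on_front` (logical aligned to the input rows).
#' @examples
#' r <- stability_record(c("a", "b", "c"), c(0.2, 0.5, 0.6), c(60, 65, 30),
#'                       c("C", "C", "C"))
#' pareto_front(r)$frontier$id  # "a" "b"
#' @export
pareto_front <- function(records, element_stratum = "all") {
  stopifnot(is.data.frame(records),
            all(c("max_fraction", "percent_buried") %in% names(records)))
  n <- nrow(records)
  if (n == 0L) stop("cannot take the Pareto front of an empty set",
                    call. = FALSE)
  v <- records$percent_buried
  s <- records$max_fraction
  if (any(!is.finite(v)) || any(!is.finite(s))) {
    stop("non-finite objective values", call. = FALSE)
  }
  ord <- order(-v, s)
  on_front <- logical(n)
  best_prev <- Inf  # min spin among strictly higher buried volumes
  i <- 1L
  while (i <= n) {
    # group of equal buried volume
    j <- i
    while (j < n && v[ord[j + 1L]] == v[ord[i]]) j <- j + 1L
    grp <- ord[i:j]
    grp_min <- s[grp[1L]]  # sorted ascending within group
    on_front[grp] <- s[grp] == grp_min & grp_min < best_prev
    best_prev <- min(best_prev, grp_min)
    i <- j + 1L
  }
  out <- list(frontier = records[on_front, , drop = FALSE],
              dominated_count = sum(!on_front),
              element_stratum = element_stratum,
              on_front = on_front)
  class(out) <- "pareto_result"
  out
}

#' @export
print.pareto_result <- function(x, ...) {
  cat("pareto_result [", x$element_stratum, "]: ", nrow(x$frontier),
      " on front, ", x$dominated_count, " dominated\n", sep = "")
  invisible(x)
}

#' Element-stratified Pareto fronts
#'
#' Splits records by the element of the radical center (C, N, O, S, ...) and
#' extracts an independent Pareto front per stratum — heteroatom-centered
#' radicals compete only among themselves, so strata whose members are all
#' globally dominated still contribute a nonempty front. Elements outside
#' C/N/O/S form their own strata rather than being dropped.
#'
#' @param records Stability-record data.frame with a `center_element` column.
#' @return Named list of `pareto_result`, one per element present.
#' @export
pareto_by_element <- function(records) {
  stopifnot(is.data.frame(records), "center_element" %in% names(records))
  strata <- split(seq_len(nrow(records)), records$center_element)
  out <- lapply(names(strata), function(el) {
    pareto_front(records[strata[[el]], , drop = FALSE], element_stratum = el)
  })
  names(out) <- names(strata)
  out
}
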