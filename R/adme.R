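# ADME screening: Tanimoto drug-likeness and the three-threshold filter
# (oral bioavailability, Caco-2 permeability, drug-likeness) with a
# literature-rescue list.

#' Tanimoto drug-likeness coefficient between descriptor vectors
#'
#' Continuous Tanimoto similarity between a compound's molecular-descriptor
#' vector and a reference vector (conventionally the average descriptor
#' vector of a drug database):
#' \deqn{F(A, B) = \frac{A \cdot B}{|A|^2 + |B|^2 - A \cdot B}}
#' Symmetric in its arguments; for componentwise nonnegative input the
#' value lies in \[0, 1\], with 1 iff the vectors are identical up to the
#' trivial case.
#'
#' @param a,b Numeric vectors of equal length (finite entries, not both
#'   all-zero).
#' @return A single number.
#' @export
#' @examples
#' dl_tanimoto(c(2, 0), c(1, 0))  # 2 / (4 + 1 - 2) = 2/3
dl_tanimoto <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) {
    stop("descriptor vectors have different lengths (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
  if (!length(a) || !all(is.finite(a)) || !all(is.finite(b))) {
    stop("descriptor vectors must be nonempty with finite entries", call. = FALSE)
  }
  ab <- sum(a * b)
  denom <- sum(a * a) + sum(b * b) - ab
  if (denom == 0) {
    stop("Tanimoto coefficient undefined: both descriptor vectors are zero",
         call. = FALSE)
  }
  ab / denom
}

#' ADME filter thresholds
#'
#' Defaults are the screen used for single-herb compound selection:
#' oral bioavailability >= 15%, Caco-2 permeability >= -0.4,
#' drug-likeness >= 0.18. `inclusive = FALSE` switches every comparison
#' to strict `>`.
#'
#' @param ob_min Minimum oral bioavailability, percent.
#' @param caco2_min Minimum Caco-2 permeability score.
#' @param dl_min Minimum drug-likeness index.
#' @param inclusive Use `>=` (default) rather than strict `>`.
#' @return A `filter_thresholds` object.
#' @export
filter_thresholds <- function(ob_min = 15, caco2_min = -0.4, dl_min = 0.18,
                              inclusive = TRUE) {
  vals <- c(ob_min = ob_min, caco2_min = caco2_min, dl_min = dl_min)
  stopifnot(all(is.finite(vals)), is.logical(inclusive), length(inclusive) == 1L)
  structure(list(ob_min = ob_min, caco2_min = caco2_min, dl_min = dl_min,
                 inclusive = inclusive),
            class = "filter_thresholds")
}

passes_thresholds <- function(compounds, thresholds) {
  cmp <- if (thresholds$inclusive) `>=` else `>`
  cmp(compounds$ob_percent, thresholds$ob_min) &
    cmp(compounds$caco2, thresholds$caco2_min) &
    cmp(compounds$dl, thresholds$dl_min)
}

violated_criteria <- function(row, thresholds) {
  cmp <- if (thresholds$inclusive) `>=` else `>`
  out <- character(0)
  if (!cmp(row$ob_percent, thresholds$ob_min)) out <- c(out, "ob_percent")
  if (!cmp(row$caco2, thresholds$caco2_min)) out <- c(out, "caco2")
  if (!cmp(row$dl, thresholds$dl_min)) out <- c(out, "dl")
  out
}

#' Apply the ADME screen with a literature-rescue list
#'
#' A compound passes iff all three ADME values meet their thresholds.
#' Compounds failing the thresholds but named in `rescue_ids` (retained on
#' published bioactivity evidence) are reported as rescued; all other
#' failures are excluded, each with the full list of violated criteria.
#' The three report sets partition the input compound ids.
#'
#' @param compounds Compound table from [read_compound_table()].
#' @param thresholds A [filter_thresholds()] object.
#' @param rescue_ids Character vector of compound ids to retain despite
#'   threshold failure; must be a subset of the table's ids (guards typos).
#' @return A `filter_report`: list with `passed`, `rescued` (character
#'   vectors) and `excluded` (named list of violated-criteria vectors).
#' @export
#' @examples
#' rep <- apply_adme_filter(pr_compounds(), rescue_ids = pr_rescue_ids())
#' length(rep$passed)   # 18
#' length(rep$rescued)  # 14
apply_adme_filter <- function(compounds, thresholds = filter_thresholds(),
                              rescue_ids = character(0)) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  unknown <- setdiff(rescue_ids, compounds$compound_id)
  if (length(unknown)) {
    stop("rescue id(s) not present in compound table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ok <- if (nrow(compounds)) passes_thresholds(compounds, thresholds) else logical(0)
  passed <- compounds$compound_id[ok]
  failing <- compounds$compound_id[!ok]
  rescued <- intersect(failing, rescue_ids)
  excluded_ids <- setdiff(failing, rescue_ids)
  excluded <- lapply(excluded_ids, function(id) {
    violated_criteria(compounds[compounds$compound_id == id, , drop = FALSE],
                      thresholds)
  })
  names(excluded) <- excluded_ids
  structure(list(passed = passed, rescued = rescued, excluded = excluded,
                 thresholds = thresholds),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("ADME filter report: %d passed, %d rescued, %d excluded\n",
              length(x$passed), length(x$rescued), length(x$excluded)))
  invisible(x)
}

#' Check filter monotonicity between nested thresholds
#'
#' For `t2` componentwise at least as strict as `t1`, the set passing `t2`
#' must be contained in the set passing `t1`. Used as a sanity property on
#' threshold configurations.
#'
#' @param compounds Compound table.
#' @param t1,t2 [filter_thresholds()] objects; `t2` at least as strict.
#' @return `TRUE` iff `passed(t2)` is a subset of `passed(t1)`.
#' @export
filter_monotonicity_check <- function(compounds, t1, t2) {
  stopifnot(inherits(t1, "filter_thresholds"), inherits(t2, "filter_thresholds"))
  p1 <- compounds$compound_id[passes_thresholds(compounds, t1)]
  p2 <- compounds$compound_id[passes_thresholds(compounds, t2)]
  all(p2 %in% p1)
}
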