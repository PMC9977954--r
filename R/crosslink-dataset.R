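#' @title Replicate crosslinking measurements and significance filtering
#' @name crosslink-dataset
#' @description
#' Crosslinking yield is the densitometric intensity of the crosslinked band
#' divided by the total intensity of the arrestin signal (crosslinked plus
#' free), a fraction in [0, 1]. A residue pair counts as a validated proximity
#' point when, over n >= 3 replicates, its yields are significantly above a
#' pooled background-noise control by BOTH a one-sided equal-variance t-test
#' (p < 0.02) and a one-sided Welch test (p < 0.05). Both tests are one-sided
#' (pair > control) because only signal above background is evidence of
#' proximity; requiring both to pass is the conservative combination. No
#' multiple-testing correction is applied; the thresholds are used raw.
NULL

#' Crosslinking yield from band densitometry
#'
#' @param band Crosslinked-band intensity (arbitrary units, >= 0).
#' @param total Total arrestin-signal intensity (> 0).
#' @return `band / total`, clipped to `[0, 1]` with a warning when band
#'   exceeds total (a densitometry artifact).
#' @export
crosslink_efficiency <- function(band, total) {
  if (any(!is.finite(total)) || any(total <= 0))
    stop("total intensity must be > 0", call. = FALSE)
  if (any(!is.finite(band)) || any(band < 0))
    stop("band intensity must be >= 0", call. = FALSE)
  y <- band / total
  if (any(y > 1)) {
    warning(sum(y > 1), " yield value(s) above 1 clipped to 1", call. = FALSE)
    y <- pmin(y, 1)
  }
  y
}

#' Read a blot quantification table
#'
#' Expected delimited columns: `pair_id`, `receptor_residue`,
#' `arrestin_residue`, `replicate`, `band`, `total`, `condition`
#' (`pair` or `control`).
#'
#' @param file Path to a TSV/CSV file.
#' @param sep Field separator (default tab).
#' @return A data.frame of measurements.
#' @export
read_blot_table <- function(file, sep = "\t") {
  x <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("pair_id", "replicate", "band", "total", "condition")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("blot table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x
}

# One-sided two-sample test of pair > control, equal or unequal variance.
# Degenerate zero-variance case in both samples: the t statistic is undefined,
# so the verdict falls back to an exact comparison of means (p = 0 or 1).
one_sided_t <- function(pair, control, var_equal) {
  if (stats::sd(pair) < .Machine$double.eps &&
      stats::sd(control) < .Machine$double.eps) {
    return(if (mean(pair) > mean(control)) 0 else 1)
  }
  stats::t.test(pair, control, alternative = "greater",
                var.equal = var_equal)$p.value
}

#' Validate crosslinking pairs against a background-noise control
#'
#' Applies the two-test significance filter: for every pair with at least
#' `min_n` replicates, a one-sided equal-variance t-test and a one-sided
#' Welch test of the pair's yields against the pooled control yields. The
#' verdict is `significant` iff both p-values are strictly below their
#' thresholds; pairs with fewer than `min_n` replicates are `untested`.
#'
#' @param measurements Data.frame as returned by [read_blot_table()], or any
#'   data.frame with columns `pair_id`, `replicate`, `band`, `total`,
#'   `condition` (plus optional `receptor_residue`, `arrestin_residue`).
#' @param control Optional numeric vector of pooled control yields; when
#'   `NULL`, rows with `condition == "control"` supply them.
#' @param alpha_t Threshold for the equal-variance t-test (default 0.02).
#' @param alpha_welch Threshold for the Welch test (default 0.05).
#' @param min_n Minimum replicate count to test a pair (default 3).
#' @return Data.frame of class `xl_pairs` with one row per pair: replicate
#'   count `n`, mean yield `yield` (the restraint weight B), `p_t`,
#'   `p_welch` and `verdict` in `{significant, not-significant, untested}`.
#' @export
validate_pairs <- function(measurements, control = NULL,
                           alpha_t = 0.02, alpha_welch = 0.05, min_n = 3) {
  m <- measurements
  m$yield <- crosslink_efficiency(m$band, m$total)
  if (is.null(control)) {
    control <- m$yield[m$condition == "control"]
    m <- m[m$condition != "control", , drop = FALSE]
  }
  if (!length(control))
    stop("control set is empty", call. = FALSE)
  if (any(control < 0 | control > 1))
    stop("control yields must lie in [0, 1]", call. = FALSE)
  ids <- unique(m$pair_id)
  res <- lapply(ids, function(id) {
    rows <- m[m$pair_id == id, , drop = FALSE]
    if (anyDuplicated(rows$replicate))
      stop("duplicate replicate indices for pair ", id, call. = FALSE)
    y <- rows$yield
    n <- length(y)
    if (n < min_n) {
      p_t <- NA_real_; p_w <- NA_real_; verdict <- "untested"
    } else {
      p_t <- one_sided_t(y, control, var_equal = TRUE)
      p_w <- one_sided_t(y, control, var_equal = FALSE)
      verdict <- if (p_t < alpha_t && p_w < alpha_welch)
        "significant" else "not-significant"
    }
    data.frame(
      pair_id = id,
      receptor_residue = if ("receptor_residue" %in% names(rows))
        rows$receptor_residue[1] else NA_character_,
      arrestin_residue = if ("arrestin_residue" %in% names(rows))
        rows$arrestin_residue[1] else NA_character_,
      n = n, yield = mean(y), p_t = p_t, p_welch = p_w,
      verdict = verdict, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("xl_pairs", "data.frame")
  out
}

#' Summary counts of a validated pair table
#'
#' @param pairs An `xl_pairs` table from [validate_pairs()].
#' @param detection_floor Mean yield above which a pair counts as having a
#'   detectable signal (default 0: any nonzero quantified band).
#' @return Named integer vector: `tested`, `detectable`, `significant`.
#' @export
dataset_summary <- function(pairs, detection_floor = 0) {
  if (is.null(pairs) || !nrow(pairs))
    return(c(tested = 0L, detectable = 0L, significant = 0L))
  c(tested = sum(pairs$verdict != "untested"),
    detectable = sum(pairs$yield > detection_floor),
    significant = sum(pairs$verdict == "significant"))
}

#' Write a validated pair table as TSV
#'
#' @param pairs An `xl_pairs` table.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_pairs <- function(pairs, file) {
  out <- pairs
  names(out)[names(out) == "yield"] <- "yield_fraction"
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
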