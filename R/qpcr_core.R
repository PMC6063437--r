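#' Ct arithmetic: replicate aggregation, delta-Ct and fold changes
#'
#' Shared quantification-cycle (Ct) arithmetic used by both the
#' lesion-density pipeline and ordinary relative-expression analysis.
#' Replicates are aggregated on the Ct (cycle) scale, the standard
#' convention for the delta-delta-Ct method; aggregation of linear
#' quantities is deliberately not offered.
#'
#' @name qpcr_core
NULL

.check_efficiency <- function(efficiency) {
  if (!is.numeric(efficiency) || length(efficiency) != 1L || !is.finite(efficiency)) {
    stop("`efficiency` must be a single finite number", call. = FALSE)
  }
  if (efficiency <= 1 || efficiency > 2) {
    stop("`efficiency` must lie in (1, 2]: got ", efficiency, call. = FALSE)
  }
  invisible(efficiency)
}

.check_ct <- function(ct, what = "Ct") {
  if (!all(is.finite(ct))) stop(what, " values must all be finite", call. = FALSE)
  if (any(ct <= 0 | ct >= 60)) {
    stop(what, " values must lie in (0, 60) cycles", call. = FALSE)
  }
  invisible(ct)
}

#' A single qPCR record: one sample x target with its replicate Cts
#'
#' @param sample_id Sample label.
#' @param target Amplicon or gene name.
#' @param amplicon_length Amplicon length in bp (>= 50).
#' @param treated Logical; `TRUE` for UDG/EndoVIII-treated template
#'   (ignored for expression work).
#' @param cts Numeric vector of replicate Ct values, each in (0, 60).
#' @return An object of class `ct_record`.
#' @examples
#' ct_record("s1", "LYS2_3kb", 3000, treated = TRUE, cts = c(20.1, 20.3, 20.2))
#' @export
ct_record <- function(sample_id, target, amplicon_length, treated, cts) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            is.character(target), length(target) == 1L)
  amplicon_length <- as.integer(amplicon_length)
  if (is.na(amplicon_length) || amplicon_length < 50L) {
    stop("`amplicon_length` must be an integer >= 50 bp", call. = FALSE)
  }
  if (length(cts) < 1L) stop("no replicates", call. = FALSE)
  .check_ct(cts)
  structure(
    list(sample_id = sample_id, target = target,
         amplicon_length = amplicon_length, treated = isTRUE(treated),
         cts = as.numeric(cts)),
    class = "ct_record"
  )
}

#' @export
print.ct_record <- function(x, ...) {
  cat(sprintf("<ct_record> %s / %s (%d bp, %s): %d Ct replicates, mean %.2f\n",
              x$sample_id, x$target, x$amplicon_length,
              if (x$treated) "treated" else "untreated",
              length(x$cts), mean(x$cts)))
  invisible(x)
}

#' Aggregate replicate Ct values
#'
#' Arithmetic mean and sample standard deviation of replicate Cts.
#' With a single replicate the sd is reported as 0.
#'
#' @param cts Numeric vector of replicate Ct values (or a [ct_record()]).
#' @param drop_outliers If `TRUE`, replicates more than 1.0 cycle from the
#'   replicate median are dropped before aggregation (each drop is reported
#'   via a message). Off by default.
#' @return A list with elements `mean`, `sd`, `n`.
#' @examples
#' aggregate_ct(c(20.1, 20.3, 20.2))
#' @export
aggregate_ct <- function(cts, drop_outliers = FALSE) {
  if (inherits(cts, "ct_record")) cts <- cts$cts
  cts <- cts[!is.na(cts)]
  if (length(cts) == 0L) stop("no replicates", call. = FALSE)
  .check_ct(cts)
  if (isTRUE(drop_outliers) && length(cts) >= 3L) {
    keep <- abs(cts - median(cts)) <= 1.0
    if (any(!keep)) {
      message(sprintf("aggregate_ct: dropped %d replicate(s) > 1.0 cycle from the median",
                      sum(!keep)))
      cts <- cts[keep]
    }
  }
  list(mean = mean(cts),
       sd = if (length(cts) > 1L) sd(cts) else 0,
       n = length(cts))
}

#' Delta-Ct between a target and its normalizer
#'
#' @param target_ct,reference_ct Mean Ct of the target and of the reference
#'   (normalizer) amplicon.
#' @return `target_ct - reference_ct`.
#' @examples
#' delta_ct(28, 22)
#' @export
delta_ct <- function(target_ct, reference_ct) {
  if (!is.finite(target_ct) || !is.finite(reference_ct)) {
    stop("Ct values must be finite", call. = FALSE)
  }
  target_ct - reference_ct
}

#' Fold change from a delta-delta-Ct
#'
#' `fold = E^(-ddct)` with per-cycle amplification factor `E`. `E = 2`
#' (perfect doubling) is the default; no standard-curve efficiency
#' estimation is performed here.
#'
#' @param ddct The delta-delta-Ct value.
#' @param efficiency Per-cycle amplification factor in (1, 2].
#' @return Positive fold change.
#' @examples
#' relative_quantity(-3)        # 8
#' relative_quantity(-2, 1.9)   # 3.61
#' @export
relative_quantity <- function(ddct, efficiency = 2) {
  .check_efficiency(efficiency)
  if (!is.finite(ddct)) stop("`ddct` must be finite", call. = FALSE)
  efficiency^(-ddct)
}

#' Delta-delta-Ct fold change from four Ct records
#'
#' Computes `E^-[(Ct_target - Ct_reference)_sample - (Ct_target -
#' Ct_reference)_control]`, averaging replicates on the Ct scale first.
#' This is the standard relative-expression quantity normalized to a
#' housekeeping gene (e.g. ALG9) and a control sample.
#'
#' @param sample_target,sample_reference [ct_record()]s (or bare Ct vectors)
#'   for the target and normalizer in the sample of interest.
#' @param control_target,control_reference Same pair for the control sample.
#' @param efficiency Per-cycle amplification factor in (1, 2].
#' @return Positive fold change relative to the control sample.
#' @examples
#' ddct_fold_change(c(21.0), c(20.0), c(24.0), c(20.0))  # 8
#' @export
ddct_fold_change <- function(sample_target, sample_reference,
                             control_target, control_reference,
                             efficiency = 2) {
  roles <- list(sample_target = sample_target,
                sample_reference = sample_reference,
                control_target = control_target,
                control_reference = control_reference)
  missing_roles <- names(roles)[vapply(roles, is.null, logical(1))]
  if (length(missing_roles) > 0L) {
    stop("missing Ct record(s) for role(s): ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  }
  means <- vapply(roles, function(r) aggregate_ct(r)$mean, numeric(1))
  ddct <- delta_ct(means[["sample_target"]], means[["sample_reference"]]) -
    delta_ct(means[["control_target"]], means[["control_reference"]])
  relative_quantity(ddct, efficiency)
}
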