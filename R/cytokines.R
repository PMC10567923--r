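#' Rank-based inverse-normal transform
#'
#' Maps values to standard-normal quantiles via the plotting position
#' `(rank - 0.5) / n`, with midranks for ties; missing values stay missing.
#' The result is invariant to any strictly monotone transform of the input.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @examples
#' inverse_normal(c(3, 1, 2)) # middle value maps exactly to 0
#' @export
inverse_normal <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0) return(out)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.5) / n)
  out
}

#' Normalize a cytokine panel
#'
#' Prepares a multiplex panel for association analyses, in order: values
#' below a marker's lower detection limit are set to zero and values above
#' the upper limit to the upper limit; markers with missingness above
#' `max_missing` (strictly) are dropped; remaining values are rank-based
#' inverse-normal transformed (ties from clipping handled by midranks); the
#' assay batch is regressed out per marker; remaining missing cells are
#' imputed with the per-marker median of the batch-corrected values (a
#' deliberately simple scheme - a custom `imputer` can be plugged in).
#'
#' @param panel Tibble: `participant_id`, `batch`, one numeric column per
#'   marker (NA = missing).
#' @param detection_limits Optional tibble `marker`, `lower`, `upper`.
#' @param max_missing Maximum tolerated missing fraction per marker
#'   (default 0.16; a marker with more than 16% missing values is excluded).
#' @param imputer Function `(values, panel_row_data) -> values` filling NAs;
#'   default per-marker median imputation.
#' @return Object of class `normalized_panel`: list with `values` (tibble
#'   `participant_id` + retained marker columns), `dropped` (tibble
#'   `marker`, `missing_frac`), and `provenance` (per-marker counts of
#'   censored and imputed cells).
#' @export
prepare_cytokines <- function(panel, detection_limits = NULL, max_missing = 0.16,
                              imputer = NULL) {
  abort_if(!all(c("participant_id", "batch") %in% names(panel)),
           "`panel` needs participant_id and batch columns")
  markers <- setdiff(names(panel), c("participant_id", "batch"))
  abort_if(length(markers) == 0, "empty panel")
  abort_if(anyNA(panel$batch), "batch label missing for some rows")
  n <- nrow(panel)

  censored <- stats::setNames(integer(length(markers)), markers)
  vals <- panel[markers]
  if (!is.null(detection_limits)) {
    for (m in intersect(markers, detection_limits$marker)) {
      lim <- detection_limits[detection_limits$marker == m, ]
      x <- vals[[m]]
      low <- !is.na(x) & x < lim$lower
      high <- !is.na(x) & x > lim$upper
      x[low] <- 0
      x[high] <- lim$upper
      censored[m] <- sum(low) + sum(high)
      vals[[m]] <- x
    }
  }

  miss_frac <- vapply(vals, function(x) mean(is.na(x)), numeric(1))
  drop <- miss_frac > max_missing
  dropped <- tibble::tibble(marker = markers[drop], missing_frac = miss_frac[drop])
  keep <- markers[!drop]
  abort_if(length(keep) == 0, "all markers exceed the missingness threshold")

  batch <- as.factor(panel$batch)
  imputed <- stats::setNames(integer(length(keep)), keep)
  out_vals <- purrr::map(keep, function(m) {
    z <- inverse_normal(vals[[m]])
    ok <- !is.na(z)
    if (nlevels(droplevels(batch[ok])) > 1) {
      fit <- stats::lm(z ~ batch, subset = ok)
      z[ok] <- stats::residuals(fit)
    } else {
      z[ok] <- z[ok] - mean(z[ok])
    }
    na <- is.na(z)
    imputed[m] <<- sum(na)
    if (any(na)) {
      z[na] <- if (is.null(imputer)) stats::median(z[!na]) else imputer(z, panel)
    }
    z
  })
  values <- dplyr::bind_cols(
    tibble::tibble(participant_id = panel$participant_id),
    tibble::as_tibble(stats::setNames(out_vals, keep))
  )
  structure(list(
    values = values,
    dropped = dropped,
    provenance = tibble::tibble(marker = keep,
                                missing_frac = miss_frac[!drop],
                                n_censored = censored[keep],
                                n_imputed = imputed)
  ), class = "normalized_panel")
}

#' @export
print.normalized_panel <- function(x, ...) {
  cat(sprintf("<normalized_panel> %d markers retained, %d dropped (> missing threshold)\n",
              ncol(x$values) - 1, nrow(x$dropped)))
  invisible(x)
}
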