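#' Confusion-matrix counts for one classifier on one test set
#'
#' Stores the observed counts of a 2x2 confusion matrix in the
#' parameterization used throughout this package: `N` classification
#' instances of which `S` are actual positives, with `tp` true positives
#' (out of `S`) and `fp` false positives (out of `N - S`). True negatives
#' and false negatives are derived.
#'
#' @param N Total number of classification instances (positive integer).
#' @param S Number of actual positives, `0 < S < N`.
#' @param tp True positives, `0 <= tp <= S`.
#' @param fp False positives, `0 <= fp <= N - S`.
#'
#' @return An object of class `"confusion_table"`: a list with elements
#'   `N`, `S`, `tp`, `fp` plus derived `tn` and `fn`.
#'
#' @examples
#' ct <- confusion_table(N = 150, S = 60, tp = 54, fp = 33)
#' fbeta_estimate(ct)
#' @export
confusion_table <- function(N, S, tp, fp) {
  for (v in list(N, S, tp, fp)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v)) {
      stop_validation("confusion_table counts must be single non-negative integers")
    }
  }
  N <- as.integer(N); S <- as.integer(S); tp <- as.integer(tp); fp <- as.integer(fp)
  if (!(S > 0L && S < N)) stop_validation("need 0 < S < N")
  if (tp < 0L || tp > S) stop_validation("need 0 <= tp <= S")
  if (fp < 0L || fp > N - S) stop_validation("need 0 <= fp <= N - S")
  structure(list(N = N, S = S, tp = tp, fp = fp,
                 tn = N - S - fp, fn = S - tp),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("Confusion table: N = %d, S = %d\n", x$N, x$S))
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(c("actual -", "actual +"),
                              c("pred -", "pred +")))
  print(m)
  invisible(x)
}

#' Two classifiers evaluated on a shared test set
#'
#' Pairs two [confusion_table()] objects that were obtained on the same
#' dataset, i.e. with identical `N` and `S`. The two classifiers'
#' predictions are assumed independent.
#'
#' @param obs1,obs2 `confusion_table` objects with equal `N` and `S`.
#' @return An object of class `"paired_observation"`.
#' @export
paired_observation <- function(obs1, obs2) {
  stopifnot(inherits(obs1, "confusion_table"), inherits(obs2, "confusion_table"))
  if (obs1$N != obs2$N || obs1$S != obs2$S) {
    stop_validation("paired observations must share N and S")
  }
  structure(list(obs1 = obs1, obs2 = obs2), class = "paired_observation")
}

#' The F-beta score of a (sensitivity, precision) pair
#'
#' `fbeta_score(ps, pp, beta)` is the weighted harmonic mean
#' \eqn{(1+\beta^2) p_p p_s / (\beta^2 p_p + p_s)}; `beta > 1` up-weights
#' sensitivity, `beta < 1` up-weights precision. The limit convention
#' `fbeta_score = 0` applies when `ps * pp == 0`.
#'
#' @param ps Sensitivity (recall) in `[0, 1]`. Vectorized.
#' @param pp Precision (positive predictive value) in `[0, 1]`. Vectorized.
#' @param beta Positive weight; `beta = 1` gives the F1 score.
#' @return Score value(s) in `[0, 1]`.
#' @export
fbeta_score <- function(ps, pp, beta = 1) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0)
  if (any(ps < 0 | ps > 1, na.rm = TRUE) || any(pp < 0 | pp > 1, na.rm = TRUE)) {
    stop_validation("ps and pp must lie in [0, 1]")
  }
  b2 <- beta^2
  ifelse(ps * pp == 0, 0, (1 + b2) * pp * ps / (b2 * pp + ps))
}

#' Estimated F-beta score of an observed confusion table
#'
#' The plug-in estimate \eqn{(1+\beta^2) d / (b + d + \beta^2 S)} with
#' `d = tp`, `b = fp`; for `beta = 1` this is `2 tp / (fp + tp + S)`.
#'
#' @param obs A [confusion_table()].
#' @inheritParams fbeta_score
#' @return The estimated score, a number in `[0, 1]`.
#' @export
fbeta_estimate <- function(obs, beta = 1) {
  stopifnot(inherits(obs, "confusion_table"))
  b2 <- beta^2
  (1 + b2) * obs$tp / (obs$fp + obs$tp + b2 * obs$S)
}

# Sensitivity/precision plug-ins. corrected = TRUE applies the Jeffreys-style
# 0.5 adjustment (and the b = 0 -> 0.5 rule) used for interval construction;
# tests and power use the raw estimates. Raw precision is 0 when tp + fp = 0.
plugin_rates <- function(obs, corrected = FALSE) {
  d <- obs$tp; b <- obs$fp; S <- obs$S
  if (corrected) {
    bb <- if (b == 0) 0.5 else b
    list(ps = (d + 0.5) / (S + 1), pp = (d + 0.5) / (bb + d + 1))
  } else {
    list(ps = d / S, pp = if (b + d == 0) 0 else d / (b + d))
  }
}

#' Read and write confusion tables
#'
#' Plain-text interchange for [confusion_table()] records: a TSV with header
#' columns `N`, `S`, `tp`, `fp` (one row per classifier), or an equivalent
#' JSON record (an object, or an array of objects).
#'
#' @param path File to read from / write to.
#' @param format `"tsv"` or `"json"`; inferred from the file extension when
#'   `NULL`.
#' @return `read_confusion()` returns a `confusion_table` (or a list of them
#'   when the file holds several rows); `write_confusion()` returns `path`
#'   invisibly.
#' @export
read_confusion <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv")
  rec <- switch(format,
    tsv  = utils::read.delim(path, sep = "\t", check.names = FALSE),
    json = {
      x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      if (!is.data.frame(x)) x <- as.data.frame(x)
      x
    },
    stop_validation("format must be 'tsv' or 'json'")
  )
  need <- c("N", "S", "tp", "fp")
  if (!all(need %in% names(rec))) {
    stop_validation("confusion record needs columns N, S, tp, fp")
  }
  out <- lapply(seq_len(nrow(rec)), function(i) {
    confusion_table(rec$N[i], rec$S[i], rec$tp[i], rec$fp[i])
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' @param obs A `confusion_table` or list of them.
#' @rdname read_confusion
#' @export
write_confusion <- function(obs, path, format = NULL) {
  if (inherits(obs, "confusion_table")) obs <- list(obs)
  df <- do.call(rbind, lapply(obs, function(o) {
    data.frame(N = o$N, S = o$S, tp = o$tp, fp = o$fp)
  }))
  format <- format %||% (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv")
  switch(format,
    tsv  = utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE),
    json = jsonlite::write_json(df, path, dataframe = "rows", digits = NA),
    stop_validation("format must be 'tsv' or 'json'")
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("fb_validation_error", "fbinfer_error")))
}

stop_infeasible <- function(msg) {
  stop(errorCondition(msg, class = c("fb_infeasible_error", "fbinfer_error")))
}

stop_resource <- function(msg) {
  stop(errorCondition(msg, class = c("fb_resource_error", "fbinfer_error")))
}
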