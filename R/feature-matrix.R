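#' Feature matrix container
#'
#' A `feature_matrix` is a numeric matrix (features in rows, observations in
#' columns) tagged with the scale its entries live on: `"beta"` for
#' methylation-style proportions in (0,1), `"M"` for their base-2 logit, or
#' `"normal"` for (standard) normal features. The tag lets downstream
#' operations check they are being applied on the scale they expect.
#'
#' @param values Numeric matrix, features x observations.
#' @param scale One of `"beta"`, `"M"`, `"normal"`.
#' @param feature_ids Optional character vector of feature identifiers;
#'   defaults to existing rownames or `f1..fn`.
#' @param obs_ids Optional character vector of observation identifiers;
#'   defaults to existing colnames or `obs1..obsn`.
#'
#' @return A numeric matrix of class `feature_matrix` with a `scale`
#'   attribute and feature/observation ids as dimnames.
#' @export
#' @examples
#' fm <- feature_matrix(matrix(runif(20), nrow = 4), scale = "beta")
#' fm_scale(fm)
feature_matrix <- function(values, scale = c("beta", "M", "normal"),
                           feature_ids = NULL, obs_ids = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_depfdr("`values` must be a numeric matrix", "depfdr_shape_error")
  }
  if (any(!is.finite(values))) {
    stop_depfdr("feature matrix contains non-finite entries",
                "depfdr_invalid_scale_error")
  }
  if (scale == "beta" && (any(values <= 0) || any(values >= 1))) {
    stop_depfdr("beta-scale entries must lie strictly in (0, 1)",
                "depfdr_invalid_scale_error")
  }
  if (is.null(feature_ids)) {
    feature_ids <- rownames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(values)))
  }
  if (is.null(obs_ids)) {
    obs_ids <- colnames(values)
    if (is.null(obs_ids)) obs_ids <- paste0("obs", seq_len(ncol(values)))
  }
  if (anyDuplicated(feature_ids)) {
    stop_depfdr("duplicate feature ids", "depfdr_parse_error")
  }
  dimnames(values) <- list(feature_ids, obs_ids)
  attr(values, "scale") <- scale
  class(values) <- c("feature_matrix", class(values))
  values
}

#' @rdname feature_matrix
#' @param x A `feature_matrix`.
#' @export
fm_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) NA_character_ else sc
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d features x %d observations, %s scale\n",
              nrow(x), ncol(x), fm_scale(x)))
  pr <- unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(5L, ncol(x))),
                   drop = FALSE]
  attr(pr, "scale") <- NULL
  print(pr, ...)
  invisible(x)
}

# internal: consistent classed conditions so callers/tests can catch precisely
stop_depfdr <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "depfdr_error")))
}

assert_scale <- function(x, expected, what = deparse(substitute(x))) {
  sc <- fm_scale(x)
  if (!identical(sc, expected)) {
    stop_depfdr(sprintf("%s must be on the %s scale (got %s)",
                        what, expected, sc %||% "untagged"),
                "depfdr_invalid_scale_error")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
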