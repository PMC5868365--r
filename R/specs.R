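#' Base-learner specification
#'
#' Describes one member of the learner bank. Four families are supported:
#'
#' * `stepwise` — forward selection with p-value entry threshold `p_enter`,
#'   final ordinary-least-squares refit on the selected features.
#' * `ridge` — squared-l2 penalty `lambda2`.
#' * `lasso` — l1 penalty `lambda1`.
#' * `elastic_net` — both penalties with a fixed ratio
#'   `ratio = lambda2 / lambda1`; penalty selection tunes the overall
#'   magnitude while holding the ratio.
#'
#' Leave `lambda1` / `lambda2` as `NULL` to have them chosen by internal
#' cross-validation at fit time ([select_penalty()]).
#'
#' @param kind Learner family.
#' @param lambda1 l1 penalty weight (lasso / elastic net).
#' @param lambda2 Squared-l2 penalty weight (ridge / elastic net).
#' @param ratio `lambda2 / lambda1` for elastic net.
#' @param p_enter Entry p-value threshold for stepwise.
#' @param label Display label; defaults to a readable kind/ratio tag.
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(kind = c("stepwise", "ridge", "lasso", "elastic_net"),
                         lambda1 = NULL, lambda2 = NULL, ratio = NULL,
                         p_enter = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (kind == "stepwise") {
    if (is.null(p_enter)) p_enter <- 0.05
    if (p_enter <= 0 || p_enter >= 1) stop("p_enter must lie in (0, 1)")
    lambda1 <- lambda2 <- ratio <- NULL
  } else if (kind == "elastic_net") {
    if (is.null(ratio) || ratio <= 0) {
      stop("elastic_net requires a positive lambda2/lambda1 ratio")
    }
    p_enter <- NULL
  } else {
    ratio <- NULL
    p_enter <- NULL
  }
  for (l in c(lambda1, lambda2)) {
    if (!is.null(l) && l < 0) stop("penalty weights must be non-negative")
  }
  if (is.null(label)) {
    label <- switch(kind,
      stepwise = "stepwise", ridge = "ridge", lasso = "lasso",
      elastic_net = sprintf("enet_r%g", ratio))
  }
  structure(list(kind = kind, lambda1 = lambda1, lambda2 = lambda2,
                 ratio = ratio, p_enter = p_enter, label = label),
            class = "learner_spec")
}

#' The default nine-learner bank
#'
#' Stepwise, ridge, lasso, and elastic net at six `lambda2/lambda1` ratios
#' (0.1, 0.3, 1, 3, 10, 30 — log-spaced from lasso-like to ridge-like).
#' Penalties are left unset so each fit tunes its own magnitude by internal
#' cross-validation.
#'
#' @param p_enter Stepwise entry threshold.
#' @param ratios Elastic-net `lambda2/lambda1` ratios.
#' @return List of [learner_spec()] objects (length `3 + length(ratios)`).
#' @export
default_learner_specs <- function(p_enter = 0.05,
                                  ratios = c(0.1, 0.3, 1, 3, 10, 30)) {
  c(list(learner_spec("stepwise", p_enter = p_enter),
         learner_spec("ridge"),
         learner_spec("lasso")),
    lapply(ratios, function(r) learner_spec("elastic_net", ratio = r)))
}

#' @export
print.learner_spec <- function(x, ...) {
  cat(sprintf("<learner_spec> %s", x$label))
  if (!is.null(x$lambda1)) cat(sprintf(" lambda1=%g", x$lambda1))
  if (!is.null(x$lambda2)) cat(sprintf(" lambda2=%g", x$lambda2))
  if (!is.null(x$p_enter)) cat(sprintf(" p_enter=%g", x$p_enter))
  cat("\n")
  invisible(x)
}

# Evaluate an expression with a private RNG stream, restoring the caller's
# .Random.seed afterwards so pipeline determinism never depends on call order.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
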