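#' Four-parameter logistic (4PL) parameters
#'
#' Canonical form: `top > bottom`, with the Hill coefficient's sign carrying
#' the direction of the response (positive = response rises with
#' concentration). This removes the (bottom, top, hill) <->
#' (top, bottom, -hill) degeneracy so fitted parameters are comparable.
#'
#' @param bottom,top asymptotic responses (`top != bottom`).
#' @param ec50 half-maximal concentration (> 0, same units as the data, nM
#'   by convention).
#' @param hill Hill coefficient (!= 0).
#' @return object of class `four_pl`.
#' @export
four_pl <- function(bottom, top, ec50, hill) {
  if (ec50 <= 0) stop_field("ec50", "must be > 0")
  if (top == bottom) stop_field("top", "must differ from bottom")
  if (hill == 0) stop_field("hill", "must be non-zero")
  if (top < bottom) { tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill }
  structure(list(bottom = bottom, top = top, ec50 = ec50, hill = hill),
            class = "four_pl")
}

#' @export
print.four_pl <- function(x, ...) {
  cat(sprintf("<four_pl> bottom = %.4g, top = %.4g, EC50 = %.4g, Hill = %.4g\n",
              x$bottom, x$top, x$ec50, x$hill))
  invisible(x)
}

#' Evaluate a four-parameter logistic curve
#'
#' `response = bottom + (top - bottom) / (1 + (ec50 / conc)^hill)`; at
#' `conc == ec50` the response is exactly `(bottom + top) / 2`.
#'
#' @param params a [four_pl()].
#' @param conc strictly positive concentrations.
#' @return numeric responses.
#' @export
eval_4pl <- function(params, conc) {
  stopifnot(inherits(params, "four_pl"))
  if (any(conc <= 0)) stop("concentrations must be > 0")
  params$bottom + (params$top - params$bottom) /
    (1 + (params$ec50 / conc)^params$hill)
}

#' Fit a four-parameter logistic curve to a dose-response table
#'
#' Least-squares Levenberg-Marquardt fit in log-concentration space (the
#' natural scale for ramps spanning decades), with data-driven
#' initialization: bottom/top from the extreme responses, EC50 from the
#' geometric-mean concentration, Hill = +/-1 by response direction. The
#' result is canonicalized with `top > bottom` (see [four_pl()]).
#'
#' @param table data frame with columns `conc_nM` (strictly positive,
#'   >= 4 distinct values) and `response`.
#' @return list with `params` (a `four_pl`), `rss` (residual sum of
#'   squares), `converged`, and `fitted` responses.
#' @export
fit_4pl <- function(table) {
  conc <- table$conc_nM; resp <- table$response
  if (any(conc <= 0)) stop("concentrations must be strictly positive")
  if (length(unique(conc)) < 4L)
    stop("4PL fit requires at least 4 distinct concentrations")
  if (stats::sd(resp) == 0)
    stop("degenerate data: zero response variance")
  lc <- log(conc)
  direction <- if (stats::cor(lc, resp) >= 0) 1 else -1
  st <- list(bottom = min(resp), top = max(resp),
             lec50 = mean(lc), hill = direction)
  fit <- minpack.lm::nlsLM(
    resp ~ bottom + (top - bottom) / (1 + exp(hill * (lec50 - lcv))),
    data = list(resp = resp, lcv = lc), start = st,
    control = minpack.lm::nls.lm.control(maxiter = 500,
                                         ftol = 1e-15, ptol = 1e-15))
  cf <- stats::coef(fit)
  params <- four_pl(cf[["bottom"]], cf[["top"]], exp(cf[["lec50"]]), cf[["hill"]])
  fitted <- eval_4pl(params, conc)
  list(params = params,
       rss = sum((resp - fitted)^2),
       converged = fit$convInfo$isConv %||% TRUE,
       fitted = fitted)
}
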