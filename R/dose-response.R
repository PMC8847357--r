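#' Four-parameter logistic dose-response fit
#'
#' Least-squares fit of response = bottom + (top - bottom) /
#' (1 + (EC50/dose)^hill) using Levenberg-Marquardt. Starting values come
#' from the data (bottom/top from the extreme-dose means, EC50 from
#' interpolation at half-maximal response, hill = 1); EC50 is bounded to
#' \[min dose / 10, max dose x 10\]. The EC50 is reported only when the
#' plateau is sampled (fitted EC50 below the top dose); flat data are
#' flagged as not converged.
#'
#' @param doses µM, strictly positive, >= 4 distinct values.
#' @param responses E_FRET (percent) or delta vs DMSO, one per dose entry
#'   (replicates allowed as repeated dose values).
#' @return a [DoseResponseFit-class].
#' @examples
#' d <- c(5, 10, 15, 20, 30, 40)
#' r <- 1 + (5 - 1) / (1 + (12 / d)^1.5)
#' fit <- fitDoseResponse(d, r)
#' @export
fitDoseResponse <- function(doses, responses) {
  if (any(doses <= 0)) stop("doses must be strictly positive")
  if (length(doses) != length(responses))
    stop("doses and responses must have equal length")
  if (length(unique(doses)) < 4L)
    stop("at least 4 dose points are required")
  fail <- function() new("DoseResponseFit", doses = doses,
                         responses = responses, bottom = NA_real_,
                         top = NA_real_, ec50 = NA_real_,
                         hill = NA_real_, converged = FALSE)
  if (diff(range(responses)) == 0) return(fail())

  ord <- order(doses)
  d <- doses[ord]; r <- responses[ord]
  lowMean <- mean(r[d == min(d)]); highMean <- mean(r[d == max(d)])
  b0 <- lowMean; t0 <- highMean
  half <- (b0 + t0) / 2
  # dose whose mean response is nearest half-maximal
  agg <- tapply(r, d, mean)
  e0 <- as.numeric(names(agg))[which.min(abs(agg - half))]
  lowerEC <- min(d) / 10; upperEC <- max(d) * 10
  dat <- data.frame(dose = d, resp = r)
  oneFit <- function(start) tryCatch(
    minpack.lm::nlsLM(
      resp ~ bottom + (top - bottom) / (1 + (ec50 / dose)^hill),
      data = dat, start = start,
      lower = c(bottom = -Inf, top = -Inf, ec50 = lowerEC, hill = -20),
      upper = c(bottom = Inf, top = Inf, ec50 = upperEC, hill = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  # deterministic multi-start: data-driven EC50 plus the dose-range
  # geometric centre, a shallow and a steep hill, both effect signs
  hillSign <- if (t0 >= b0) 1 else -1
  starts <- list()
  for (e00 in unique(c(max(min(e0, upperEC), lowerEC),
                       sqrt(min(d) * max(d)))))
    for (h00 in c(0.5, 1, 2, 4) * hillSign)
      starts[[length(starts) + 1L]] <-
        list(bottom = b0, top = t0, ec50 = e00, hill = h00)
  best <- NULL; bestSS <- Inf
  for (st in starts) {
    fit <- oneFit(st)
    if (is.null(fit)) next
    ss <- sum(stats::residuals(fit)^2)
    if (ss < bestSS) { best <- fit; bestSS <- ss }
  }
  if (is.null(best)) return(fail())
  cf <- stats::coef(best)
  # canonical orientation: the 4PL is invariant under swapping
  # bottom/top while negating the hill; report the form in which
  # `bottom` is the zero-dose asymptote (positive hill slope direction)
  if (cf["hill"] < 0) {
    cf[c("bottom", "top")] <- cf[c("top", "bottom")]
    cf["hill"] <- -cf["hill"]
  }
  ec50 <- unname(cf["ec50"])
  plateau <- is.finite(ec50) && ec50 < max(d)
  new("DoseResponseFit", doses = doses, responses = responses,
      bottom = unname(cf["bottom"]), top = unname(cf["top"]),
      ec50 = if (plateau) ec50 else NA_real_,
      hill = unname(cf["hill"]), converged = TRUE)
}

#' Predicted responses of a 4PL fit
#'
#' @param fit a [DoseResponseFit-class] (converged).
#' @param doses µM.
#' @return predicted responses.
#' @export
predictDoseResponse <- function(fit, doses = fit@doses) {
  if (!isTRUE(fit@converged)) stop("fit did not converge")
  ec50 <- if (is.na(fit@ec50)) max(fit@doses) * 10 else fit@ec50
  fit@bottom + (fit@top - fit@bottom) / (1 + (ec50 / doses)^fit@hill)
}

setMethod("show", "DoseResponseFit", function(object) {
  if (!object@converged) {
    cat("DoseResponseFit: not converged\n")
  } else {
    cat("DoseResponseFit: bottom ", round(object@bottom, 2), ", top ",
        round(object@top, 2), ", EC50 ",
        if (is.na(object@ec50)) "NA (plateau not sampled)" else
          paste0(round(object@ec50, 3), " uM"),
        ", hill ", round(object@hill, 2), "\n", sep = "")
  }
})
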