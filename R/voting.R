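# Closed-form and simulated accuracy of the 3-voter majority ensemble.

checkScenario <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 3L || anyNA(p))
    stop("domain error: need 3 per-classifier accuracies", call. = FALSE)
  if (any(p <= 0.5) || any(p >= 1))
    stop("domain error: each accuracy must lie strictly in (0.5, 1)",
         call. = FALSE)
  p
}

#' Closed-form accuracy of 3-classifier majority voting
#'
#' For three independent classifiers with accuracies p1, p2, p3 in
#' (0.5, 1), the majority vote is correct when at least two voters are
#' correct:
#' \deqn{P = p_1 p_2 p_3 + p_1 p_2 (1-p_3) + p_1 (1-p_2) p_3 +
#'       (1-p_1) p_2 p_3.}
#' In the equal-accuracy case \eqn{p_1 = p_2 = p_3 = q} this reduces to
#' \eqn{3q^2 - 2q^3}, which always exceeds q on (0.5, 1) — majority voting
#' beats any single equally accurate, independent classifier. The ensemble
#' is not guaranteed to beat \code{max(p)} when the accuracies differ.
#'
#' @param p numeric of length 3: the per-classifier accuracies, each
#'   strictly in (0.5, 1).
#' @return the ensemble accuracy, a single number in (0, 1).
#' @examples
#' votingAccuracyClosedForm(c(0.7, 0.7, 0.7))  # 3q^2 - 2q^3 = 0.784
#' @export
votingAccuracyClosedForm <- function(p) {
  p <- checkScenario(p)
  p[1] * p[2] * p[3] + p[1] * p[2] * (1 - p[3]) +
    p[1] * (1 - p[2]) * p[3] + (1 - p[1]) * p[2] * p[3]
}

#' Monte Carlo estimate of the majority-vote accuracy
#'
#' Draws \code{nTrials} independent rounds in which voter k is correct with
#' probability \code{p[k]}, and returns the fraction of rounds where at
#' least 2 of 3 voters are correct. Converges to
#' \code{\link{votingAccuracyClosedForm}} at the binomial rate.
#'
#' @param p numeric of length 3, each in (0.5, 1]; perfectly accurate
#'   voters (p = 1) are allowed so that degenerate scenarios can be
#'   simulated.
#' @param nTrials number of simulated rounds (>= 1).
#' @param seed integer seed.
#' @return the empirical accuracy in [0, 1].
#' @export
simulateVoting <- function(p, nTrials, seed = 1L) {
  p <- as.numeric(p)
  if (length(p) != 3L || anyNA(p) || any(p <= 0.5) || any(p > 1))
    stop("domain error: each accuracy must lie in (0.5, 1]", call. = FALSE)
  nTrials <- as.integer(nTrials)
  if (is.na(nTrials) || nTrials < 1L)
    stop("domain error: nTrials must be >= 1", call. = FALSE)
  set.seed(seed)
  correct <- matrix(stats::runif(nTrials * 3L), ncol = 3L) <
    matrix(p, nrow = nTrials, ncol = 3L, byrow = TRUE)
  mean(rowSums(correct) >= 2L)
}
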