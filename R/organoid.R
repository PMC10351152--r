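#' Organoid response score
#'
#' RS = (organoid count x mean maximal diameter x viability) at time 0
#' divided by the same product after 72 h of treatment. An RS of 1 means
#' no effect; RS > 1 means the treatment reduced organoid number, size or
#' viability. When no organoids survive at 72 h the score is reported as
#' +Inf with an explicit flag rather than an error. The score is
#' invariant to a common rescaling of the diameters and to expressing
#' viability consistently as percent or fraction.
#'
#' @param t0,t72 \linkS4class{OrganoidTimepoint} measurements at baseline
#'   and after 72 h.
#' @param includeViability use the three-factor product (default); when
#'   FALSE the two-factor count x diameter variant is used.
#' @return List of class \code{ResponseScore}: \code{rs},
#'   \code{components} (the two products), \code{infinite} flag.
#' @examples
#' responseScore(OrganoidTimepoint(100, 200, 0.9),
#'               OrganoidTimepoint(50, 150, 0.6))$rs  # 4
#' @export
responseScore <- function(t0, t72, includeViability = TRUE) {
  prod1 <- function(tp) {
    p <- tp@nOrganoids * tp@meanMaxDiameter
    if (includeViability) p * tp@viability else p
  }
  p0 <- prod1(t0)
  p72 <- prod1(t72)
  if (p72 == 0) {
    warning("no surviving organoid signal at 72 h; RS reported as +Inf")
    return(structure(list(rs = Inf, components = c(t0 = p0, t72 = p72),
                          infinite = TRUE), class = "ResponseScore"))
  }
  structure(list(rs = p0 / p72, components = c(t0 = p0, t72 = p72),
                 infinite = FALSE), class = "ResponseScore")
}

#' @export
print.ResponseScore <- function(x, ...) {
  cat(sprintf("ResponseScore: RS = %s (t0 product %g, 72h product %g)\n",
              format(x$rs), x$components["t0"], x$components["t72"]))
  invisible(x)
}

#' Classify organoid sensitivity from response scores
#'
#' A culture is sensitive when its treated RS exceeds the control RS by
#' more than the relative margin: \code{rsTreated > rsControl * (1 +
#' margin)}; otherwise resistant. A flagged infinite treated score (no
#' surviving organoids) is sensitive.
#'
#' @param rsTreated,rsControl \code{ResponseScore} objects or numeric RS
#'   values.
#' @param margin relative margin (reported in the result).
#' @return List with \code{label} ("sensitive"/"resistant"),
#'   \code{margin}, \code{flagged}.
#' @export
classifySensitivity <- function(rsTreated, rsControl, margin = 0.2) {
  val <- function(x) if (inherits(x, "ResponseScore")) x$rs else as.numeric(x)
  rt <- val(rsTreated)
  rc <- val(rsControl)
  flagged <- is.infinite(rt)
  label <- if (flagged || rt > rc * (1 + margin)) "sensitive" else "resistant"
  list(label = label, margin = margin, flagged = flagged)
}

#' Bliss independence expectation
#'
#' Expected combined inhibition of two independently acting agents with
#' single-agent inhibitions \code{ya} and \code{yb}:
#' \code{ya + yb - ya * yb}.
#'
#' @param ya,yb inhibition fractions in [0, 1] (vectorized).
#' @return Expected inhibition fraction(s).
#' @examples
#' blissExpected(0.3, 0.4)  # 0.58
#' @export
blissExpected <- function(ya, yb) {
  if (any(ya < 0 | ya > 1) || any(yb < 0 | yb > 1))
    stop("inhibition fractions must lie in [0, 1]")
  ya + yb - ya * yb
}

#' Bliss synergy score over a dose grid
#'
#' For every combination cell (both doses positive) the excess over the
#' Bliss expectation of the single-agent margins is computed; the synergy
#' score is 100 times the mean excess (margins excluded from the
#' average). Classification bands: score <= -10 antagonistic, in
#' (-10, 10] additive, > 10 synergistic.
#'
#' @param m a \linkS4class{DoseResponseMatrix}.
#' @param includeMargins also average the (zero-excess by construction)
#'   single-agent cells into the score.
#' @return List of class \code{SynergyResult}: \code{blissScore},
#'   \code{excess} matrix (combination cells), \code{classification}.
#' @export
blissSynergyScore <- function(m, includeMargins = FALSE) {
  inh <- m@inhibition
  ya <- inh[, 1]
  yb <- inh[1, ]
  expected <- outer(ya, yb, blissExpected)
  excess <- inh - expected
  combo <- excess[-1, -1, drop = FALSE]
  dimnames(combo) <- list(m@dosesA[-1], m@dosesB[-1])
  cells <- if (includeMargins) excess else combo
  score <- 100 * mean(cells)
  classification <- if (score <= -10) "antagonistic"
                    else if (score <= 10) "additive"
                    else "synergistic"
  structure(list(blissScore = score, excess = combo,
                 classification = classification),
            class = "SynergyResult")
}

#' @export
print.SynergyResult <- function(x, ...) {
  cat(sprintf("SynergyResult: Bliss score %.2f (%s), %d combination cells\n",
              x$blissScore, x$classification, length(x$excess)))
  invisible(x)
}
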