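#' Steepest-descent energy minimisation
#'
#' Standard step-doubling steepest descent: the trial move displaces the
#' atom with the largest force by the current step size (all other atoms
#' proportionally along their forces). A trial that lowers the energy is
#' accepted and the step grows by 1.2x; otherwise it is rejected and the
#' step halves. Convergence is declared when the maximum atomic force drops
#' below \code{fmaxTol}.
#'
#' @param s a \code{MolecularStructure} with finite initial energy.
#' @param ff a \code{ForceField}.
#' @param topology optional precomputed topology (rebuilt from the input
#'   geometry otherwise and then held fixed during minimisation).
#' @param charges optional per-atom charges (e).
#' @param step0 initial step, nm.
#' @param fmaxTol force tolerance, kJ/mol/nm.
#' @param maxSteps iteration cap.
#' @return list with \code{finalStructure}, \code{energy} (kJ/mol),
#'   \code{nSteps} (accepted steps), \code{converged}, \code{maxForce} and
#'   the accepted-energy \code{trace} (non-increasing by construction).
#' @export
steepestDescent <- function(s, ff = defaultForceField(), topology = NULL,
                            charges = NULL, step0 = 0.01, fmaxTol = 10,
                            maxSteps = 500) {
  if (is.null(topology)) topology <- buildTopology(s)
  e <- potentialEnergy(s, ff, topology, charges)$total
  if (!is.finite(e)) stop("non-finite energy at minimisation start")
  step <- step0
  nAccepted <- 0L
  trace <- e
  converged <- FALSE
  maxF <- NA_real_
  for (it in seq_len(maxSteps)) {
    gr <- .energyGradient(s, ff, topology, charges)
    fAtom <- sqrt(rowSums(gr * gr))
    maxF <- max(fAtom)
    if (maxF < fmaxTol) {
      converged <- TRUE
      break
    }
    trial <- setCoords(s, coords(s) - gr * (step / maxF))
    eTrial <- potentialEnergy(trial, ff, topology, charges)$total
    if (is.finite(eTrial) && eTrial < e) {
      s <- trial
      e <- eTrial
      nAccepted <- nAccepted + 1L
      trace <- c(trace, e)
      step <- step * 1.2
    } else {
      step <- step * 0.5
      if (step < 1e-10) break
    }
  }
  if (!converged && maxF < fmaxTol) converged <- TRUE
  list(finalStructure = s, energy = e, nSteps = nAccepted,
       converged = converged, maxForce = maxF, trace = trace)
}
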