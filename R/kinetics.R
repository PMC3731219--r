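# Mass-action model of riboregulation, quasi-steady-state reduction,
# and the Boltzmann rate model linking the kinetic objective to
# predicted expression fold change.

#' Simulate the three-step riboregulation scheme
#'
#' Numerical integration of the mass-action model: free species A and B
#' associate to the transition-state intermediate `[A:B]*` (rates
#' `kOn`, `kOff`), which hybridizes irreversibly to the final complex
#' `A:B` (rate `kHyb`); free species degrade with `delta1` and the
#' final complex with `delta2`.
#'
#' @param params a [KineticParameters-class].
#' @param A0,B0 nonnegative initial concentrations of the free species.
#' @param horizon integration end time.
#' @param clampAB hold A and B at their initial values (useful to read
#'   off steady states).
#' @param nOut number of output time points.
#' @param rtol,atol solver tolerances (adaptive stiff-capable lsoda).
#' @return Data frame with columns `time, A, B, I, AB` (`I` the
#'   transition-state intermediate).
#' @examples
#' p <- kineticParameters(kOn = 1, kOff = 9, kHyb = 1, delta1 = 0.01)
#' head(simulateKinetics(p, 10, 10, horizon = 5, clampAB = TRUE))
#' @export
simulateKinetics <- function(params, A0, B0, horizon, clampAB = FALSE,
                             nOut = 200L, rtol = 1e-8, atol = 1e-10) {
  if (A0 < 0 || B0 < 0) stop(.paramError("initial conditions must be nonnegative"))
  if (horizon <= 0) stop(.paramError("horizon must be > 0"))
  deriv <- function(t, y, p) {
    A <- y[1]; B <- y[2]; I <- y[3]; AB <- y[4]
    assoc <- p@kOn * A * B
    dI <- assoc - (p@kOff + p@kHyb) * I
    dAB <- p@kHyb * I - p@delta2 * AB
    if (clampAB) {
      dA <- 0
      dB <- 0
    } else {
      dA <- -assoc + p@kOff * I - p@delta1 * A
      dB <- -assoc + p@kOff * I - p@delta1 * B
    }
    list(c(dA, dB, dI, dAB))
  }
  times <- seq(0, horizon, length.out = nOut)
  out <- deSolve::ode(y = c(A = A0, B = B0, I = 0, AB = 0), times = times,
                      func = deriv, parms = params, method = "lsoda",
                      rtol = rtol, atol = atol)
  df <- as.data.frame(out)
  names(df) <- c("time", "A", "B", "I", "AB")
  df
}

#' Quasi-steady-state intermediate concentration
#'
#' Under the assumption `kOff + kHyb >> delta1` (sRNA degradation is
#' slow against the binding equilibrium), the transition-state
#' intermediate settles at `A * B / KM` with
#' `KM = (kOff + kHyb)/kOn`. The returned validity flag is `TRUE` when
#' `(kOff + kHyb)/delta1 >= 10`.
#'
#' @param params a [KineticParameters-class].
#' @param A,B free-species concentrations.
#' @return `list(intermediate=, valid=)`.
#' @examples
#' p <- kineticParameters(kOn = 1, kOff = 9, kHyb = 1, delta1 = 0.01)
#' qssaIntermediate(p, 10, 10)   # 10, valid
#' @export
qssaIntermediate <- function(params, A, B) {
  if (params@kOn <= 0) stop(.paramError("QSSA requires kOn > 0"))
  ratio <- if (params@delta1 > 0) {
    (params@kOff + params@kHyb) / params@delta1
  } else {
    Inf
  }
  list(intermediate = A * B / params@KM, valid = ratio >= 10)
}

#' Predicted expression fold change from the kinetic objective
#'
#' The fold change scales exponentially with the free energy:
#' `fold = scale * exp(-dGkin/RT)`. The proportionality constant is a
#' free parameter; only ratios between predictions are meaningful, and
#' the ratio of two predictions depends only on their `dGkin`
#' difference.
#'
#' @param dGkinValue kinetic objective, kcal/mol.
#' @param RT thermal energy, kcal/mol (default 0.61).
#' @param scale free multiplicative constant.
#' @return A [FoldPrediction-class].
#' @examples
#' predictedFold(-0.61)@fold / predictedFold(0)@fold   # = e
#' @export
predictedFold <- function(dGkinValue, RT = 0.61, scale = 1) {
  if (RT <= 0) stop(.paramError("RT must be > 0"))
  if (scale <= 0) stop(.paramError("scale must be > 0"))
  new("FoldPrediction", dGkin = dGkinValue, RT = RT, scale = scale,
      fold = scale * exp(-dGkinValue / RT))
}
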