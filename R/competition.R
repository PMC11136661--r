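## Coupled logistic competition between two species sharing a resource:
##   dX/dt = a X (1 - (X + Y)/m),   dY/dt = b Y (1 - (X + Y)/n).
## Three stages: unperturbed growth; a perturbation stage whose entry
## multiplies Y by rho instantly and X by the same factor after a delay
## (the asynchronous crash); unperturbed recovery.  Fixed-step integration
## (deSolve rk4/euler) so that every event time lands exactly on a grid
## point.

.compRhs <- function(t, state, parms) {
  X <- state[1]; Y <- state[2]
  tot <- X + Y
  list(c(parms$a * X * (1 - tot / parms$m),
         parms$b * Y * (1 - tot / parms$n)))
}

.onGrid <- function(x, dt) abs(x / dt - round(x / dt)) < 1e-8

#' Simulate the coupled logistic competition model
#'
#' Integrates the two-species coupled logistic ODE through the three
#' stages of the configuration.  At stage-2 entry species 2 (Y) is
#' instantaneously multiplied by `rho`; species 1 (X) receives the
#' identical perturbation `delay` time units later.  Event times must lie
#' on the dt grid (they do by construction when boundaries and delay are
#' multiples of dt).
#'
#' @param config a [CompetitionConfig-class].
#' @return A [Trajectory-class]; at an event time the stored value is the
#'   post-perturbation one, and the event log records the exact times.
#' @export
simulateCompetition <- function(config) {
  stopifnot(is(config, "CompetitionConfig"))
  validObject(config)
  dt <- config@dt
  tP2 <- config@tStage1End                 # species 2 (Y) perturbed
  tP1 <- config@tStage1End + config@delay  # species 1 (X) perturbed
  if (tP1 >= config@tFinal)
    stop("delayed perturbation falls beyond tFinal")
  marks <- c(config@tStage1End, config@tStage2End, config@tFinal,
             config@delay)
  if (!all(.onGrid(marks, dt)))
    stop("stage boundaries and delay must be multiples of dt")
  parms <- list(a = config@a, b = config@b, m = config@m, n = config@n)
  method <- config@integrator

  segBounds <- sort(unique(c(0, tP2, tP1, config@tFinal)))
  state <- c(X = config@X0, Y = config@Y0)
  time <- numeric(0); X <- numeric(0); Y <- numeric(0)
  events <- data.frame(time = numeric(0), species = character(0),
                       factor = numeric(0))
  for (s in seq_len(length(segBounds) - 1)) {
    t0 <- segBounds[s]; t1 <- segBounds[s + 1]
    ## apply perturbations scheduled at this segment's entry
    if (t0 == tP2) {
      state["Y"] <- state["Y"] * config@rho
      events <- rbind(events, data.frame(time = t0, species = "Y",
                                         factor = config@rho))
    }
    if (t0 == tP1) {
      state["X"] <- state["X"] * config@rho
      events <- rbind(events, data.frame(time = t0, species = "X",
                                         factor = config@rho))
    }
    times <- seq(t0, t1, by = dt)
    sol <- deSolve::ode(y = state, times = times, func = .compRhs,
                        parms = parms, method = method)
    if (any(!is.finite(sol[, -1])) || any(sol[, -1] < 0))
      stop("unstable integration produced negative/non-finite sizes; ",
           "use a smaller dt")
    keep <- if (s < length(segBounds) - 1)
      seq_len(nrow(sol) - 1) else seq_len(nrow(sol))
    time <- c(time, sol[keep, "time"])
    X <- c(X, sol[keep, "X"])
    Y <- c(Y, sol[keep, "Y"])
    state <- c(X = unname(sol[nrow(sol), "X"]),
               Y = unname(sol[nrow(sol), "Y"]))
  }
  new("Trajectory", time = time, X = X, Y = Y, events = events)
}

#' Closed-form single-species logistic growth
#'
#' X(t) = m X0 e^(a t) / (m + X0 (e^(a t) - 1)), the exact solution of
#' dX/dt = a X (1 - X/m); the Y0 = 0 limit of the coupled model.
#'
#' @param X0 initial size (>= 0); @param a growth rate; @param m carrying
#'   capacity (> 0); @param t time (vectorised).
#' @return X(t).
#' @export
logisticClosedForm <- function(X0, a, m, t) {
  stopifnot(X0 >= 0, m > 0)
  if (X0 == 0) return(rep(0, length(t)))
  ## algebraically identical form that stays finite as a*t grows large
  m / (1 + (m / X0 - 1) * exp(-a * t))
}
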