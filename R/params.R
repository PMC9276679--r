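#' Model parameters for the tumour-immune lattice simulation
#'
#' Constructs the full parameter set of the agent-based model. Defaults are
#' the model's calibrated operating point: per-step action probabilities for
#' immune (CD8) and tumour cells, capacity limits, and the immune influx
#' process. Probabilities are per simulation step; one simulated day comprises
#' `steps_per_day` steps.
#'
#' @param IMpprol Immune cell proliferation probability.
#' @param IMpkill Immune cell killing probability (attempt per step when a
#'   tumour cell is Moore-adjacent).
#' @param IMpdeath Natural death probability of immune cells.
#' @param IMrwalk Randomness of the biased random walk of immune cells;
#'   each move is random with this probability, otherwise directed toward
#'   the nearest tumour cell.
#' @param TUpprol Tumour cell proliferation probability.
#' @param TUpmig Tumour cell migration probability.
#' @param TUpdeath Tumour cell natural death probability.
#' @param TUpmax Tumour cell proliferation capacity (divisions before death;
#'   daughters of stem cells start here).
#' @param TUintmax Tumour cell interaction capacity: number of immune attacks
#'   survived before dying (multi-hit resilience).
#' @param IMpmax Immune cell proliferation capacity assigned to newly
#'   arriving (influx) immune cells.
#' @param IMpmig Expected number of immune migration moves per step; the
#'   integer part is guaranteed, the fractional part probabilistic.
#' @param IMinfluxProb Probability per step of an immune influx event.
#' @param IMinflRate Number of immune cells arriving per influx event.
#' @param steps_per_day Simulation steps per 24 h of modelled time. The
#'   default of 1 treats the action probabilities as daily probabilities,
#'   the time base at which their magnitudes (tumour death 0.12, immune
#'   proliferation 0.049) produce biologically plausible multi-week
#'   dynamics; finer step sizes require correspondingly rescaled
#'   probabilities.
#' @param end_day Default simulation horizon in days.
#' @param seed Default RNG seed (`NULL` = leave the RNG stream alone).
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params(IMpprol = 0.1)
#' p$IMpprol
#' @export
model_params <- function(IMpprol = 0.049, IMpkill = 0.1, IMpdeath = 0.0147,
                         IMrwalk = 0.8, TUpprol = 0.5, TUpmig = 0.35,
                         TUpdeath = 0.12, TUpmax = 10, TUintmax = 2,
                         IMpmax = 6, IMpmig = 2, IMinfluxProb = 0.2,
                         IMinflRate = 1, steps_per_day = 1L, end_day = 20L,
                         seed = NULL) {
  p <- list(IMpprol = IMpprol, IMpkill = IMpkill, IMpdeath = IMpdeath,
            IMrwalk = IMrwalk, TUpprol = TUpprol, TUpmig = TUpmig,
            TUpdeath = TUpdeath, TUpmax = TUpmax, TUintmax = TUintmax,
            IMpmax = IMpmax, IMpmig = IMpmig, IMinfluxProb = IMinfluxProb,
            IMinflRate = IMinflRate,
            steps_per_day = as.integer(steps_per_day),
            end_day = as.integer(end_day), seed = seed)
  validate_params(p)
  structure(p, class = "model_params")
}

validate_params <- function(p) {
  probs <- c("IMpprol", "IMpkill", "IMpdeath", "IMrwalk", "TUpprol",
             "TUpmig", "TUpdeath", "IMinfluxProb")
  for (nm in probs)
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", nm))
  for (nm in c("IMpmig", "IMinflRate"))
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0)
      stop(sprintf("'%s' must be a non-negative rate", nm))
  for (nm in c("TUpmax", "TUintmax", "IMpmax"))
    if (!is.numeric(p[[nm]]) || p[[nm]] < 1 || p[[nm]] != round(p[[nm]]))
      stop(sprintf("'%s' must be a positive integer capacity", nm))
  if (p$steps_per_day < 1L) stop("'steps_per_day' must be >= 1")
  if (p$end_day < 1L) stop("'end_day' must be >= 1")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Tumour-immune model parameters:\n")
  v <- unlist(x[setdiff(names(x), "seed")])
  print(v)
  invisible(x)
}

# named numeric vector for the compiled stepper
as_param_vector <- function(p) {
  nm <- c("IMpprol", "IMpkill", "IMpdeath", "IMrwalk", "TUpprol", "TUpmig",
          "TUpdeath", "TUpmax", "TUintmax", "IMpmax", "IMpmig",
          "IMinfluxProb", "IMinflRate")
  setNames(vapply(nm, function(n) as.numeric(p[[n]]), numeric(1)), nm)
}

#' Parameter scan specifications
#'
#' Ranges and sampling scales for the one-at-a-time sensitivity analysis
#' (all 13 model parameters) and for the rejection-based optimisation
#' (the four free immune parameters: IMpprol, IMpkill, IMpdeath, IMrwalk).
#'
#' @param role `"sensitivity"` or `"optimisation"`.
#' @return A data.frame with columns `name`, `min`, `max`, `scale`
#'   (`"linear"` or `"log"`), and `integer` (whether sampled values are
#'   rounded to integers).
#' @examples
#' param_specs("optimisation")
#' @export
param_specs <- function(role = c("sensitivity", "optimisation")) {
  role <- match.arg(role)
  if (role == "sensitivity") {
    out <- data.frame(
      name = c("IMpprol", "IMpkill", "IMpdeath", "IMrwalk", "TUpprol",
               "TUpmig", "TUpdeath", "TUpmax", "TUintmax", "IMpmax",
               "IMpmig", "IMinfluxProb", "IMinflRate"),
      min = c(0.01, 0.001, 0.001, 0.5, 0.05, 0, 0.01, 6, 1, 3, 0.05, 0.01, 1),
      max = c(0.15, 0.3, 0.076, 1, 0.5, 0.35, 0.12, 15, 10, 12, 0.7, 0.5, 10),
      scale = c("log", "log", "log", rep("linear", 10)),
      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      name = c("IMpprol", "IMpkill", "IMpdeath", "IMrwalk"),
      min = c(0.01, 0.001, 0.001, 0.7),
      max = c(0.4, 0.5, 0.2, 1),
      scale = c("log", "log", "log", "linear"),
      stringsAsFactors = FALSE)
  }
  out$integer <- out$name %in% c("TUpmax", "TUintmax", "IMpmax", "IMinflRate")
  out
}
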