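#' Single-step mutation model for Y-STR markers
#'
#' Per meiosis and per marker, an allele changes by -1, 0 or +1 repeat unit
#' with probabilities mu/2, 1 - mu and mu/2, where mu is the marker's total
#' mutation rate. Larger jumps, extremely rare in reality, are assigned
#' probability zero. z = mu/2 is the unidirectional rate used in the
#' closed-form results of the validation catalogue. The model is symmetric,
#' mu(A, B) = mu(B, A), which is what licenses re-rooting the pedigree at the
#' suspect.
#'
#' @param rates named numeric vector of per-marker mutation rates (probability
#'   per meiosis, each in (0, 1)). Typical forensic values are well below 0.5;
#'   a warning is issued above 0.2 as outside the tested regime.
#' @param markers marker names; defaults to `names(rates)`.
#' @return object of class `ystr_mutation_model` with fields `markers`,
#'   `rates` and `z` (= rates/2).
#' @examples
#' mutation_model(c(DYS570 = 0.0124, DYS576 = 0.0143))
#' @export
mutation_model <- function(rates, markers = names(rates)) {
  if (is.null(markers)) markers <- paste0("M", seq_along(rates))
  rates <- stats::setNames(as.numeric(rates), markers)
  if (any(!is.finite(rates)) || any(rates <= 0) || any(rates >= 1))
    stop_validation("mutation rates must lie strictly between 0 and 1")
  if (any(rates > 0.2))
    warning("mutation rate(s) above 0.2 are outside the tested regime: ",
            paste(markers[rates > 0.2], collapse = ", "))
  structure(list(markers = markers, rates = rates, z = rates / 2),
            class = "ystr_mutation_model")
}

#' @export
print.ystr_mutation_model <- function(x, ...) {
  cat("Single-step mutation model, ", length(x$markers), " marker(s):\n", sep = "")
  print(x$rates)
  invisible(x)
}

#' Read per-marker mutation rates
#'
#' Accepts either a CSV file with header `marker,rate` or a JSON object
#' `{"marker": rate, ...}`.
#'
#' @param file path to the rates file.
#' @return a [mutation_model()].
#' @export
read_mutation_rates <- function(file) {
  first <- trimws(readLines(file, n = 1L, warn = FALSE))
  if (startsWith(first, "{")) {
    obj <- jsonlite::fromJSON(file)
    return(mutation_model(unlist(obj)))
  }
  df <- utils::read.csv(file, check.names = FALSE, strip.white = TRUE)
  if (!all(c("marker", "rate") %in% names(df)))
    stop_parse(if (is.character(file)) file else "rates file",
               ": expected CSV columns `marker,rate` or a JSON object")
  mutation_model(stats::setNames(as.numeric(df$rate), df$marker))
}

#' Per-marker step probabilities
#'
#' @param rate mutation rate mu in (0, 1).
#' @return numeric vector `c(p_loss, p_stay, p_gain)` = (mu/2, 1 - mu, mu/2).
#' @examples
#' step_probs(0.1) # 0.05 0.90 0.05
#' @export
step_probs <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate <= 0 || rate >= 1)
    stop_validation("rate must be a single number in (0, 1)")
  c(p_loss = rate / 2, p_stay = 1 - rate, p_gain = rate / 2)
}

# vectorized per-marker transition factor for an allele difference `delta`
step_factor <- function(delta, mu) {
  ifelse(delta == 0, 1 - mu, ifelse(abs(delta) == 1, mu / 2, 0))
}

#' Haplotype transition probability across one meiosis
#'
#' Product over markers of mu_i/2 (one-step change), 1 - mu_i (no change) or 0
#' (two or more steps), assuming independent mutation across markers. The
#' function is symmetric in its first two arguments.
#'
#' @param parent,child integer haplotypes on the model's panel.
#' @param model a [mutation_model()].
#' @return a probability.
#' @examples
#' m <- mutation_model(c(A = 0.1, B = 0.02))
#' transition_prob(c(0, 0), c(1, 0), m) # 0.05 * 0.98
#' @export
transition_prob <- function(parent, child, model) {
  stopifnot(inherits(model, "ystr_mutation_model"))
  L <- length(model$markers)
  if (length(parent) != L || length(child) != L)
    stop_validation("haplotype length does not match the marker panel (", L, ")")
  prod(step_factor(as.integer(child) - as.integer(parent), model$rates))
}

#' Simulate a son's haplotype from his father's
#'
#' Draws an independent step in \{-1, 0, +1\} for every marker with the
#' step probabilities of the model. Deterministic under a fixed RNG seed.
#'
#' @param parent integer haplotype.
#' @param model a [mutation_model()].
#' @return integer haplotype differing from `parent` by at most 1 per marker.
#' @export
simulate_child <- function(parent, model) {
  stopifnot(inherits(model, "ystr_mutation_model"))
  L <- length(model$markers)
  if (length(parent) != L)
    stop_validation("haplotype length does not match the marker panel (", L, ")")
  steps <- vapply(model$rates, function(mu)
    sample.int(3L, 1L, prob = c(mu / 2, 1 - mu, mu / 2)) - 2L, integer(1))
  stats::setNames(as.integer(parent) + steps, model$markers)
}

#' Match probability after m meioses
#'
#' Probability that a patrilineal relative separated from the suspect by `m`
#' meioses carries the identical haplotype: per marker, the chance of zero net
#' change after m independent single steps,
#' sum_j m! / (j! j! (m-2j)!) z^(2j) (1-2z)^(m-2j), multiplied across markers.
#' This is the exact upper bound used for males outside the pedigree whose
#' relatedness to the suspect is at most m meioses.
#'
#' @param m non-negative integer number of meioses.
#' @param model a [mutation_model()].
#' @return a probability; 1 when `m = 0`.
#' @examples
#' meiosis_match_prob(2, mutation_model(c(M = 0.1))) # 0.815
#' @export
meiosis_match_prob <- function(m, model) {
  stopifnot(inherits(model, "ystr_mutation_model"))
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 || m != trunc(m))
    stop_validation("m must be a single non-negative integer")
  per_marker <- vapply(model$z, function(z) {
    j <- 0:(m %/% 2)
    sum(exp(lfactorial(m) - 2 * lfactorial(j) - lfactorial(m - 2 * j)
            + 2 * j * log(z) + (m - 2 * j) * log1p(-2 * z)))
  }, numeric(1))
  if (m == 0) 1 else prod(per_marker)
}
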