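# Importance-sampling estimators for P(h^v) and the match-count probabilities
# p_x. All estimators are vectorized across simulations: per untyped member
# one allele matrix (n_sims x markers) is simulated, and weights are
# accumulated in log space so that deep pedigrees or many markers cannot
# underflow a per-edge product.

new_is_result <- function(estimate, n_sims, std_error, seed, n_nonzero,
                          exact = FALSE, warnings = character(0)) {
  structure(list(estimate = estimate, n_sims = n_sims, std_error = std_error,
                 seed = seed, n_nonzero = n_nonzero, exact = exact,
                 warnings = warnings),
            class = "ystr_is_result")
}

#' @export
print.ystr_is_result <- function(x, ...) {
  cat(if (x$exact) "Exact result: " else "Importance-sampling estimate: ",
      format(x$estimate, digits = 6), sep = "")
  if (!x$exact)
    cat("  (SE ", format(x$std_error, digits = 3), ", ", x$n_nonzero, "/",
        x$n_sims, " nonzero weights)", sep = "")
  cat("\n")
  invisible(x)
}

# constant allele matrix helper
const_mat <- function(h, n_sims) matrix(rep(as.integer(h), each = n_sims),
                                        nrow = n_sims)

# Simulate every untyped member (level order) from his father; members flagged
# in `forced` (named list member -> logical vector over sims) are pinned to
# the suspect haplotype (all-zero after shifting) instead.
# Returns a named list of n_sims x L integer matrices.
simulate_untyped <- function(prep, model, n_sims, forced = NULL) {
  L <- length(model$markers)
  mats <- list()
  for (id in prep$order) {
    fa <- prep$pedigree$father[[id]]
    fmat <- if (!is.null(mats[[fa]])) mats[[fa]]
            else const_mat(prep$typed_shifted[[fa]], n_sims)
    child <- fmat
    for (j in seq_len(L)) {
      mu <- prep_rate(model, j)
      steps <- sample.int(3L, n_sims, replace = TRUE,
                          prob = c(mu / 2, 1 - mu, mu / 2)) - 2L
      child[, j] <- fmat[, j] + steps
    }
    if (!is.null(forced[[id]])) child[forced[[id]], ] <- 0L
    mats[[id]] <- child
  }
  mats
}

prep_rate <- function(model, j) unname(model$rates[[j]])

# log transition probability between two allele matrices / constant rows,
# summed over markers; returns a vector over simulations (-Inf where the
# single-step model forbids the pair)
log_trans_vec <- function(parent_mat, child_mat, model) {
  out <- 0
  for (j in seq_along(model$markers)) {
    f <- step_factor(child_mat[, j] - parent_mat[, j], prep_rate(model, j))
    out <- out + log(f)
  }
  out
}

# father allele matrix for member `id` given simulated matrices `mats`
father_values <- function(prep, id, mats, n_sims) {
  fa <- prep$pedigree$father[[id]]
  if (!is.null(mats[[fa]])) mats[[fa]] else const_mat(prep$typed_shifted[[fa]], n_sims)
}

check_panel <- function(prep, model) {
  if (!identical(length(prep$panel), length(model$markers)) ||
      !setequal(prep$panel, model$markers))
    stop_validation("case panel and mutation-model markers differ")
}

#' Estimate P(h^v), the probability of the observed typed haplotypes
#'
#' Runs the reduced-weight importance-sampling scheme: per simulation every
#' untyped haplotype is drawn from its father in level order, and the
#' simulation weight is the product of the transition probabilities over
#' exactly those father-son edges whose son is typed. The estimate is the mean
#' weight. Two degenerate cases are exact: with no typed members besides the
#' suspect the weight is the empty product (P(h^v) = 1), and with no untyped
#' members the full product over all edges is returned without simulation.
#'
#' @param case a [case_configuration()] (or an internally prepared case).
#' @param model a [mutation_model()].
#' @param n_sims number of simulations (>= 1).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return an `ystr_is_result` with fields `estimate`, `n_sims`, `std_error`,
#'   `seed`, `n_nonzero` and `exact`.
#' @export
estimate_pv <- function(case, model, n_sims = 1e5, seed = NULL) {
  prep <- prepare_case(case)
  check_panel(prep, model)
  typed_sons <- setdiff(prep$typed_ids, prep$suspect)
  warn <- validate_case(prep$case, model)

  if (length(typed_sons) == 0)  # k = 1: empty product
    return(new_is_result(1, 0L, 0, seed, 0L, exact = TRUE, warnings = warn))
  if (length(prep$order) == 0) {  # no untyped members: exact product
    lw <- 0
    for (id in setdiff(prep$pedigree$members, prep$pedigree$root)) {
      fa <- prep$pedigree$father[[id]]
      lw <- lw + log(transition_prob(prep$typed_shifted[[fa]],
                                     prep$typed_shifted[[id]], model))
    }
    return(new_is_result(exp(lw), 0L, 0, seed, as.integer(exp(lw) > 0),
                         exact = TRUE, warnings = warn))
  }
  if (n_sims < 1) stop_validation("n_sims must be >= 1")
  n_sims <- as.integer(n_sims)

  with_seed(seed, {
    mats <- simulate_untyped(prep, model, n_sims)
    logw <- 0
    for (id in typed_sons) {
      pmat <- father_values(prep, id, mats, n_sims)
      logw <- logw + log_trans_vec(pmat, const_mat(prep$typed_shifted[[id]], n_sims), model)
    }
    if (length(logw) == 1L) logw <- rep(logw, n_sims)  # all factors constant
    w <- exp(logw)
    new_is_result(mean(w), n_sims, stats::sd(w) / sqrt(n_sims), seed,
                  sum(w > 0), exact = FALSE, warnings = warn)
  })
}

# choose a uniformly random size-x subset of the untyped members for every
# simulation; returns a named list member -> logical vector over sims
draw_forced <- function(untyped, x, n_sims, combo_cap = 2e5) {
  U <- length(untyped)
  forced <- stats::setNames(rep(list(logical(n_sims)), U), untyped)
  if (x == 0) return(forced)
  n_combos <- choose(U, x)
  if (n_combos <= combo_cap) {
    combos <- utils::combn(U, x)                     # x by n_combos
    pick <- sample.int(ncol(combos), n_sims, replace = TRUE)
    for (r in seq_len(x)) {
      member_idx <- combos[r, pick]                  # per-sim member index
      for (u in unique(member_idx))
        forced[[untyped[u]]][member_idx == u] <- TRUE
    }
  } else {
    # very wide pedigrees: per-simulation sampling without enumeration
    for (s in seq_len(n_sims)) {
      sel <- sample.int(U, x)
      for (u in sel) forced[[untyped[u]]][s] <- TRUE
    }
  }
  forced
}

#' Estimate p_x, the probability of exactly x matching untyped members
#'
#' One importance-sampling pass for a fixed target count `x`: per simulation a
#' uniformly random size-x subset of the untyped members is pinned to the
#' suspect haplotype, the remaining untyped members are simulated from their
#' fathers in level order, and the proposal weight
#' binom(n-k, x) * prod(edges not simulated) / P(h^v) is accumulated for
#' simulations in which the total number of matching untyped members (pinned
#' plus coincidental) equals x. The transition factors of the simulated edges
#' cancel algebraically between the target numerator and the proposal
#' denominator and are therefore never evaluated.
#'
#' @param case a [case_configuration()].
#' @param model a [mutation_model()].
#' @param x target number of matching untyped members, 1 <= x <= n-k.
#' @param pv the value of P(h^v) (exact, or estimated once via
#'   [estimate_pv()]); must be positive.
#' @param n_sims number of simulations.
#' @param seed optional integer seed.
#' @return an `ystr_is_result`.
#' @export
estimate_px <- function(case, model, x, pv, n_sims = 1e5, seed = NULL) {
  prep <- prepare_case(case)
  check_panel(prep, model)
  U <- length(prep$order)
  if (!is.numeric(pv) || length(pv) != 1L || !(pv > 0))
    stop(errorCondition(
      "P(h^v) must be positive: the conditional match distribution is undefined",
      class = c("ystr_undefined_conditional", "error")))
  if (!is.numeric(x) || length(x) != 1L || x < 1 || x > U || x != trunc(x))
    stop_validation("x must be an integer in 1..", U, " (number of untyped members)")
  if (n_sims < 1) stop_validation("n_sims must be >= 1")
  n_sims <- as.integer(n_sims)
  typed_sons <- setdiff(prep$typed_ids, prep$suspect)

  with_seed(seed, {
    forced <- draw_forced(prep$order, x, n_sims)
    mats <- simulate_untyped(prep, model, n_sims, forced = forced)

    logw <- rep(lchoose(U, x) - log(pv), n_sims)
    # edges whose son is typed
    for (id in typed_sons) {
      pmat <- father_values(prep, id, mats, n_sims)
      logw <- logw + log_trans_vec(pmat, const_mat(prep$typed_shifted[[id]], n_sims), model)
    }
    # edges whose son is a pinned untyped member (value = suspect haplotype)
    zero <- matrix(0L, n_sims, length(model$markers))
    for (id in prep$order) {
      rows <- forced[[id]]
      if (!any(rows)) next
      pmat <- father_values(prep, id, mats, n_sims)
      lt <- log_trans_vec(pmat, zero, model)
      logw[rows] <- logw[rows] + lt[rows]
    }
    # indicator: total matches (pinned + coincidental) must equal x, i.e. no
    # simulated (non-pinned) untyped member may coincide with the suspect
    coincident <- rep(FALSE, n_sims)
    for (id in prep$order) {
      is_match <- rowSums(mats[[id]] != 0L) == 0L
      coincident <- coincident | (is_match & !forced[[id]])
    }
    w <- exp(logw)
    w[coincident] <- 0
    new_is_result(mean(w), n_sims, stats::sd(w) / sqrt(n_sims), seed,
                  sum(w > 0), exact = FALSE)
  })
}

new_match_distribution <- function(probs, exact) {
  stopifnot(!is.null(names(probs)))
  structure(list(probs = probs, exact = exact), class = "ystr_match_distribution")
}

#' @export
print.ystr_match_distribution <- function(x, ...) {
  cat(if (x$exact) "Exact" else "Estimated", "match-count distribution:\n")
  print(x$probs)
  invisible(x)
}

#' Estimate the full match-count distribution
#'
#' Runs [estimate_pv()] once, then [estimate_px()] independently for each
#' x = 1..n-k on its own RNG substream (seed + x), and finally sets
#' p_0 = 1 - sum of the p_x estimates, clamped at zero with a warning if the
#' estimates happen to sum above one.
#'
#' @param case a [case_configuration()].
#' @param model a [mutation_model()].
#' @param n_sims simulations per estimated quantity.
#' @param seed optional integer seed; substream s uses seed + s.
#' @return list with `pv` (an `ystr_is_result`), `dist` (an
#'   `ystr_match_distribution` over x = 0..n-k) and `px_results` (per-x
#'   `ystr_is_result`s).
#' @export
estimate_distribution <- function(case, model, n_sims = 1e5, seed = NULL) {
  prep <- prepare_case(case)
  U <- length(prep$order)
  if (U == 0) {
    pv <- estimate_pv(prep, model, n_sims = 1, seed = seed)
    return(list(pv = pv,
                dist = new_match_distribution(c(`0` = 1), exact = TRUE),
                px_results = list()))
  }
  pv <- estimate_pv(prep, model, n_sims = n_sims, seed = seed)
  if (!(pv$estimate > 0))
    stop(errorCondition(
      paste0("estimated P(h^v) is zero: the conditional match distribution is ",
             "undefined (", paste(pv$warnings, collapse = "; "), ")"),
      class = c("ystr_undefined_conditional", "error")))
  px <- lapply(seq_len(U), function(x)
    estimate_px(prep, model, x, pv$estimate, n_sims = n_sims,
                seed = if (is.null(seed)) NULL else seed + x))
  probs <- vapply(px, function(r) r$estimate, numeric(1))
  p0 <- 1 - sum(probs)
  if (p0 < 0) {
    warning("p_x estimates sum above one (", format(sum(probs), digits = 6),
            "); clamping p_0 to 0 without renormalizing")
    p0 <- 0
  }
  all_probs <- stats::setNames(c(p0, probs), 0:U)
  list(pv = pv,
       dist = new_match_distribution(all_probs, exact = FALSE),
       px_results = stats::setNames(px, seq_len(U)))
}

#' Repeat-based accuracy experiment against exact values
#'
#' Re-estimates P(h^v) and every applicable p_x `repeats` times on
#' independent substreams and reports the mean and standard deviation, over
#' repeats, of the percentage difference 100 * (estimate - exact) / exact.
#' Quantities whose exact value is zero cannot carry a percentage difference;
#' for those the report instead records whether every repeat returned exactly
#' zero. Escalation to a larger `n_sims` (e.g. one million) is the caller's
#' choice via the argument.
#'
#' @param case a [case_configuration()].
#' @param model a [mutation_model()].
#' @param exact list with fields `pv` (number) and `dist` (an
#'   `ystr_match_distribution`), e.g. from [exact_distribution_enum()] or
#'   [scenario_exact()].
#' @param repeats number of independent repeats.
#' @param n_sims simulations per repeat and quantity.
#' @param seed integer seed; repeat r runs on substream seed + 1009 * r.
#' @return data.frame with one row per quantity: `quantity`, `exact`,
#'   `mean_estimate`, `mean_pct`, `sd_pct`, `all_zero`.
#' @export
run_accuracy_experiment <- function(case, model, exact, repeats = 10,
                                    n_sims = 1e5, seed = 1) {
  prep <- prepare_case(case)
  U <- length(prep$order)
  quantities <- c("P(h^v)", if (U > 0) paste0("p_", seq_len(U)))
  exact_vals <- c(exact$pv,
                  if (U > 0) unname(exact$dist$probs[as.character(seq_len(U))]))
  est <- matrix(NA_real_, nrow = repeats, ncol = length(quantities),
                dimnames = list(NULL, quantities))
  for (r in seq_len(repeats)) {
    res <- estimate_distribution(prep, model, n_sims = n_sims,
                                 seed = seed + 1009L * r)
    est[r, 1L] <- res$pv$estimate
    if (U > 0)
      est[r, -1L] <- vapply(res$px_results, function(p) p$estimate, numeric(1))
  }
  pct <- sweep(sweep(est, 2L, exact_vals, `-`), 2L, exact_vals, `/`) * 100
  data.frame(
    quantity = quantities,
    exact = exact_vals,
    mean_estimate = colMeans(est),
    mean_pct = ifelse(exact_vals > 0, colMeans(pct), NA_real_),
    sd_pct = ifelse(exact_vals > 0 & repeats > 1, apply(pct, 2L, stats::sd), NA_real_),
    all_zero = ifelse(exact_vals > 0, NA, colSums(est != 0) == 0),
    repeats = repeats,
    n_sims = n_sims,
    row.names = NULL)
}
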